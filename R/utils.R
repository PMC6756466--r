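#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

is_prob <- function(p) is.numeric(p) && length(p) == 1L && !is.na(p) && p >= 0 && p <= 1

stop_if_not_prob <- function(p, what) {
  if (!is_prob(p)) stop(sprintf("'%s' must be a single probability in [0, 1]", what), call. = FALSE)
  invisible(p)
}

# Quantile of a log-normal parameterised by (median, sdlog); sdlog = 0 is the
# point mass at the median, used for "fixed, no variation" scenario times.
qlnorm_med <- function(u, median, sdlog) {
  if (sdlog == 0) return(rep(median, length(u)))
  stats::qlnorm(u, meanlog = log(median), sdlog = sdlog)
}

# Quantile conditional on the value being <= upper.
qlnorm_med_trunc <- function(u, median, sdlog, upper) {
  if (sdlog == 0) {
    if (median > upper) stop("degenerate time distribution lies beyond its truncation bound", call. = FALSE)
    return(rep(median, length(u)))
  }
  p_up <- stats::plnorm(upper, meanlog = log(median), sdlog = sdlog)
  stats::qlnorm(u * p_up, meanlog = log(median), sdlog = sdlog)
}

# Quantile conditional on the value being > lower (late-arrival tail).
qlnorm_med_above <- function(u, median, sdlog, lower) {
  if (sdlog == 0) return(pmax(rep(median, length(u)), lower + 1))
  p_lo <- stats::plnorm(lower, meanlog = log(median), sdlog = sdlog)
  out <- stats::qlnorm(p_lo + u * (1 - p_lo), meanlog = log(median), sdlog = sdlog)
  # guard against p_lo ~ 1 overflowing to Inf
  pmin(pmax(out, lower + 1), lower + 24 * 60)
}

# Maximum-likelihood fit of a log-normal from observations subject to known
# per-observation upper truncation (observed only because x <= upper).
# upper may be a scalar or a vector aligned with x; Inf gives the plain MLE.
fit_lnorm_trunc <- function(x, upper = Inf) {
  stopifnot(length(x) >= 2L, all(x > 0))
  upper <- rep_len(upper, length(x))
  lx <- log(x)
  m0 <- mean(lx)
  s0 <- stats::sd(lx)
  if (all(!is.finite(upper)) || all(upper > max(x) * 1e6)) {
    n <- length(x)
    return(list(meanlog = m0, sdlog = s0 * sqrt((n - 1) / n),
                se_meanlog = s0 / sqrt(n), se_sdlog = s0 / sqrt(2 * n)))
  }
  if (s0 < 1e-8) {
    return(list(meanlog = m0, sdlog = 0, se_meanlog = 0, se_sdlog = 0))
  }
  nll <- function(par) {
    m <- par[1]; s <- exp(par[2])
    -sum(stats::dlnorm(x, m, s, log = TRUE)) +
      sum(stats::plnorm(upper, m, s, log.p = TRUE))
  }
  fit <- stats::optim(c(m0, log(s0)), nll, method = "BFGS", hessian = TRUE)
  se <- tryCatch({
    v <- solve(fit$hessian)
    c(sqrt(v[1, 1]), sqrt(v[2, 2]) * exp(fit$par[2]))
  }, error = function(e) c(NA_real_, NA_real_))
  list(meanlog = fit$par[1], sdlog = exp(fit$par[2]),
       se_meanlog = se[1], se_sdlog = se[2])
}

# mean and normal-approximation 95% CI over replicate values
ci_normal <- function(x) {
  m <- mean(x)
  half <- 1.96 * stats::sd(x) / sqrt(length(x))
  c(mean = m, lo = m - half, hi = m + half)
}

ci_percentile <- function(x) {
  q <- stats::quantile(x, c(0.025, 0.975), names = FALSE, type = 7)
  c(mean = mean(x), lo = q[1], hi = q[2])
}
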