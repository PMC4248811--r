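#' Simulate a bleach-recovery (FRAP) trace
#'
#' Generates a normalised post-bleach recovery curve
#' `F(t) = mobile_fraction * (1 - exp(-t / tau)) + noise`, on the
#' convention that the pre-bleach fluorescence is 1 and the value at the
#' end of the bleach is 0, so the asymptote equals the mobile fraction.
#'
#' @param tau Recovery time constant in seconds (> 0).
#' @param mobile_fraction Recovering fraction in `[0, 1]`.
#' @param noise_sigma Gaussian noise SD added per sample (>= 0).
#' @param dt Sampling interval in seconds.
#' @param duration Trace duration in seconds (>= 3 * tau recommended;
#'   shorter runs are rejected).
#' @param seed Integer seed (same seed, same trace); `NULL` leaves the
#'   RNG state untouched.
#' @return A `frap_trace`: data frame with columns `t` (s since bleach
#'   end, starting at 0) and `f`.
#' @examples
#' tr <- simulate_frap_trace(tau = 7.1, mobile_fraction = 0.6,
#'                           noise_sigma = 0, dt = 0.1, duration = 40)
#' @export
simulate_frap_trace <- function(tau, mobile_fraction, noise_sigma = 0,
                                dt = 0.1, duration = 40, seed = NULL) {
  if (tau <= 0) stop("'tau' must be positive")
  if (mobile_fraction < 0 || mobile_fraction > 1)
    stop("'mobile_fraction' must be in [0, 1]")
  if (duration < 3 * tau)
    stop("'duration' must span at least 3 recovery time constants")
  t <- seq(0, duration, by = dt)
  f <- mobile_fraction * (1 - exp(-t / tau))
  if (noise_sigma > 0) {
    if (!is.null(seed)) {
      old <- get_rng_state(); on.exit(set_rng_state(old))
      set.seed(seed)
    }
    f <- f + stats::rnorm(length(t), 0, noise_sigma)
  }
  structure(data.frame(t = t, f = f), class = c("frap_trace", "data.frame"),
            tau_true = tau, mobile_true = mobile_fraction)
}

#' Normalise a raw bleach-recovery trace
#'
#' Rebases time to zero at the end of the bleach and maps fluorescence
#' affinely so that the value at the bleach end is 0 and the recovered
#' level is 1:
#' `f = (raw - raw[bleach_end]) / (F_max - raw[bleach_end])`.
#' `F_max` is either the literal post-bleach maximum
#' (`method = "max"`) or, by default, a shot-noise robust plateau
#' estimate, the mean of the final 10% of samples
#' (`method = "plateau"`).
#'
#' @param raw Numeric vector of raw fluorescence, including pre-bleach
#'   samples.
#' @param bleach_end_index Index (1-based) of the first post-bleach
#'   sample.
#' @param dt Sampling interval in seconds.
#' @param method Plateau convention, `"plateau"` (default) or `"max"`.
#' @return A `frap_trace` (columns `t`, `f`) starting at `t = 0`.
#' @examples
#' normalize_frap(c(10, 2, 4, 6, 8), bleach_end_index = 2, dt = 1,
#'                method = "max")   # f = 0, 1/3, 2/3, 1
#' @export
normalize_frap <- function(raw, bleach_end_index, dt = 1,
                           method = c("plateau", "max")) {
  method <- match.arg(method)
  n <- length(raw)
  if (bleach_end_index < 1L || bleach_end_index > n - 1L)
    stop("'bleach_end_index' must leave at least one post-bleach sample")
  post <- raw[bleach_end_index:n]
  f0 <- post[1]
  fmax <- switch(method,
    max = max(post),
    plateau = mean(post[(length(post) - max(1L, ceiling(0.1 * length(post))) + 1L):length(post)]))
  if (fmax <= f0)
    stop("flat or falling post-bleach trace: zero dynamic range, nothing to normalise")
  structure(data.frame(t = (seq_along(post) - 1) * dt,
                       f = (post - f0) / (fmax - f0)),
            class = c("frap_trace", "data.frame"))
}

#' Fit the single-exponential recovery model to a FRAP trace
#'
#' Least-squares fit of `f(t) = A * (1 - exp(-t / tau))`. The reported
#' mobile fraction is `A / pre_bleach` when a pre-bleach reference level
#' (on the same intensity scale as the trace) is supplied, i.e. relative
#' to the total pre-bleach signal; otherwise the fitted plateau `A`
#' itself is reported, i.e. relative to whatever the trace was
#' normalised to. Both conventions are kept in the result.
#'
#' @param trace A `frap_trace` or data frame with columns `t` and `f`,
#'   `t[1] = 0`, at least 10 points.
#' @param pre_bleach Optional pre-bleach fluorescence reference.
#' @return A `frap_fit`: list with `tau`, `mobile_fraction`, `amplitude`
#'   (fitted plateau A), `se_tau`, `se_mobile`, `converged`, `rss`.
#' @examples
#' tr <- simulate_frap_trace(7.1, 0.6, 0, dt = 0.1, duration = 40)
#' fit_frap(tr, pre_bleach = 1)   # tau = 7.1 s, mobile = 0.6
#' @export
fit_frap <- function(trace, pre_bleach = NULL) {
  stopifnot(is.data.frame(trace), all(c("t", "f") %in% names(trace)))
  if (nrow(trace) < 10L) stop("need at least 10 samples to fit a recovery")
  if (abs(trace$t[1]) > 1e-9) stop("'t' must start at 0 (bleach end)")
  a0 <- max(mean(trace$f[trace$t >= max(trace$t) * 0.8]), 1e-3)
  i <- which(trace$f >= a0 * (1 - exp(-1)))[1]
  tau0 <- if (is.na(i) || trace$t[i] <= 0) max(trace$t) / 3 else trace$t[i]
  fit <- tryCatch(
    minpack.lm::nlsLM(f ~ A * (1 - exp(-t / tau)), data = trace,
                      start = list(A = a0, tau = tau0),
                      lower = c(0, 1e-9),
                      control = stats::nls.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    res <- list(tau = NA_real_, mobile_fraction = NA_real_,
                amplitude = NA_real_, se_tau = NA_real_,
                se_mobile = NA_real_, converged = FALSE,
                rss = NA_real_, message = conditionMessage(fit))
    class(res) <- "frap_fit"
    return(res)
  }
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) c(A = NA, tau = NA))
  scale <- if (is.null(pre_bleach)) 1 else pre_bleach
  res <- list(tau = unname(cf["tau"]),
              mobile_fraction = min(max(unname(cf["A"]) / scale, 0), 1),
              amplitude = unname(cf["A"]),
              se_tau = unname(se["tau"]),
              se_mobile = unname(se["A"]) / scale,
              converged = fit$convInfo$isConv,
              rss = sum(stats::residuals(fit)^2))
  class(res) <- "frap_fit"
  res
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("<frap_fit> tau = %.3g +/- %.2g s, mobile fraction = %.3g +/- %.2g%s\n",
              x$tau, x$se_tau, x$mobile_fraction, x$se_mobile,
              if (isTRUE(x$converged)) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Average normalised FRAP traces across cells
#'
#' Point-wise mean of normalised recovery traces on a common time base,
#' with per-point standard errors; averaging precedes fitting when
#' pooling cells.
#'
#' @param traces List of `frap_trace`s with identical time bases.
#' @return A `frap_trace` with columns `t`, `f` and `se`.
#' @export
average_frap <- function(traces) {
  stopifnot(length(traces) >= 1L)
  t0 <- traces[[1]]$t
  for (tr in traces)
    if (length(tr$t) != length(t0) || any(abs(tr$t - t0) > 1e-9))
      stop("all traces must share the same time base")
  fm <- vapply(traces, function(tr) tr$f, numeric(length(t0)))
  fm <- matrix(fm, nrow = length(t0))
  structure(data.frame(t = t0, f = rowMeans(fm),
                       se = apply(fm, 1L, stats::sd) / sqrt(length(traces))),
            class = c("frap_trace", "data.frame"))
}
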