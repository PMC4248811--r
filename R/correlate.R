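#' Auto- and cross-correlation of intensity traces
#'
#' `autocorrelate()` estimates the normalised fluorescence autocorrelation
#' \deqn{g(\tau) = \langle\delta F(t)\,\delta F(t+\tau)\rangle /
#'       \langle F\rangle^2, \qquad \delta F = F - \langle F\rangle,}
#' and `crosscorrelate()` the two-channel analogue
#' \deqn{g_{cc}(\tau) = \langle\delta P_1(t)\,\delta P_2(t+\tau)\rangle /
#'       (\langle P_1\rangle\langle P_2\rangle).}
#' Both use the zero-baseline convention: an uncorrelated trace gives
#' g = 0, and the amplitude g(0+) of a diffusing species equals
#' gamma/N (the reciprocal apparent molecule number).
#'
#' Two lag schemes are available. `"direct"` evaluates the estimator by
#' brute-force summation at every integer lag up to `max_lag` and is the
#' reference implementation. `"multiple-tau"` evaluates the *same*
#' estimator on a quasi-logarithmic lag ladder (m linear lags, then m/2
#' lags per doubling), using an FFT to keep long traces fast; at any lag
#' present in both schemes the two values agree to floating-point
#' precision because no rebinning is applied to the trace.
#'
#' @param trace,trace1,trace2 `intensity_trace` objects (equal `dt` and
#'   length for cross-correlation).
#' @param max_lag Largest lag in seconds; must be below half the trace
#'   duration. Default: one quarter of the duration.
#' @param scheme `"multiple-tau"` (default) or `"direct"`.
#' @param m Lags per level of the multiple-tau ladder (even, >= 4).
#' @param n_blocks If >= 5, the trace is cut into this many contiguous
#'   blocks and per-lag standard errors are estimated from the spread of
#'   the per-block curves.
#' @return A `correlation_curve`: data frame with columns `lag`, `g` and
#'   optionally `se`, plus attributes `dt`, `offset_convention`
#'   (`"zero-baseline"`) and `n`.
#' @examples
#' tr <- intensity_trace(rep(c(2, 0), 4), dt = 1)
#' autocorrelate(tr, max_lag = 2, scheme = "direct")  # g(1) = -1, g(2) = +1
#' @export
autocorrelate <- function(trace, max_lag = NULL,
                          scheme = c("multiple-tau", "direct"),
                          m = 16L, n_blocks = 0L) {
  trace <- as_trace(trace)
  correlate_pair(trace, trace, max_lag, match.arg(scheme), m, n_blocks,
                 cross = FALSE)
}

#' @rdname autocorrelate
#' @export
crosscorrelate <- function(trace1, trace2, max_lag = NULL,
                           scheme = c("multiple-tau", "direct"),
                           m = 16L, n_blocks = 0L) {
  trace1 <- as_trace(trace1); trace2 <- as_trace(trace2)
  if (length(trace1) != length(trace2))
    stop("traces must have equal length")
  if (attr(trace1, "dt") != attr(trace2, "dt"))
    stop("traces must have equal bin width 'dt'")
  correlate_pair(trace1, trace2, max_lag, match.arg(scheme), m, n_blocks,
                 cross = TRUE)
}

correlate_pair <- function(t1, t2, max_lag, scheme, m, n_blocks, cross) {
  dt <- attr(t1, "dt")
  n <- length(t1)
  dur <- n * dt
  if (is.null(max_lag)) max_lag <- dur / 4
  if (max_lag >= dur / 2)
    stop("'max_lag' must be below half the trace duration")
  if (mean(t1) == 0 || mean(t2) == 0)
    stop("trace mean is zero: the correlation normalisation <F>^2 is undefined")
  kmax <- max(1L, floor(max_lag / dt))
  lags_k <- switch(scheme,
    "direct" = seq_len(kmax),
    "multiple-tau" = mtau_lags(kmax, m))
  g <- corr_at_lags(as.numeric(t1), as.numeric(t2), lags_k)
  curve <- data.frame(lag = lags_k * dt, g = g)
  if (n_blocks >= 5L) {
    blen <- floor(n / n_blocks)
    if (kmax >= blen / 2)
      stop("'max_lag' too large for per-block standard errors; reduce n_blocks or max_lag")
    per <- vapply(seq_len(n_blocks), function(b) {
      i <- ((b - 1L) * blen + 1L):(b * blen)
      corr_at_lags(as.numeric(t1)[i], as.numeric(t2)[i], lags_k)
    }, numeric(length(lags_k)))
    curve$se <- apply(per, 1L, stats::sd) / sqrt(n_blocks)
  }
  structure(curve, dt = dt, offset_convention = "zero-baseline", n = n,
            class = c("correlation_curve", "data.frame"))
}

# Multiple-tau lag ladder: 1..m, then (m/2+1..m)*2^L, capped at kmax.
mtau_lags <- function(kmax, m = 16L) {
  m <- as.integer(m)
  if (m < 4L || m %% 2L != 0L) stop("'m' must be an even integer >= 4")
  lags <- seq_len(min(m, kmax))
  lev <- 1L
  repeat {
    nxt <- (m %/% 2L + seq_len(m %/% 2L)) * 2L^lev
    nxt <- nxt[nxt <= kmax]
    if (!length(nxt)) break
    lags <- c(lags, nxt)
    lev <- lev + 1L
  }
  unique(lags)
}

# Normalised correlation <dF1 dF2>(k) / (<F1><F2>) at integer lags.
# Small problems are summed directly; large ones go through one FFT
# (identical estimator, ~1e-15 apart numerically).
corr_at_lags <- function(f1, f2, lags_k) {
  n <- length(f1)
  m1 <- mean(f1); m2 <- mean(f2)
  d1 <- f1 - m1; d2 <- f2 - m2
  if (as.double(n) * length(lags_k) <= 2e7) {
    s <- vapply(lags_k, function(k)
      sum(d1[seq_len(n - k)] * d2[(k + 1L):n]) / (n - k), numeric(1))
  } else {
    L <- stats::nextn(2L * n, 2L)
    a <- c(d1, numeric(L - n))
    b <- c(d2, numeric(L - n))
    cc <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE)) / L
    s <- cc[lags_k + 1L] / (n - lags_k)
  }
  s / (m1 * m2)
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf("<correlation_curve> %d lags, %.3g s .. %.3g s (%s)\n",
              nrow(x), min(x$lag), max(x$lag), attr(x, "offset_convention")))
  print.data.frame(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat("  ...\n")
  invisible(x)
}

#' Average correlation curves across measurements
#'
#' Point-wise mean of curves sharing a common lag grid (e.g. repeated
#' measurements or cells), with per-lag standard errors from the spread
#' across curves; fitting the averaged curve is the standard population
#' protocol for slow species whose single-trace correlation estimates
#' are dominated by particle-number fluctuations.
#'
#' @param curves List of `correlation_curve`s with identical lags.
#' @return A `correlation_curve` with columns `lag`, `g`, `se`.
#' @export
average_curves <- function(curves) {
  stopifnot(length(curves) >= 1L)
  l0 <- curves[[1]]$lag
  for (cv in curves)
    if (length(cv$lag) != length(l0) || any(abs(cv$lag - l0) > 1e-12))
      stop("all curves must share the same lag grid")
  gm <- vapply(curves, function(cv) cv$g, numeric(length(l0)))
  gm <- matrix(gm, nrow = length(l0))
  out <- data.frame(lag = l0, g = rowMeans(gm),
                    se = apply(gm, 1L, stats::sd) / sqrt(length(curves)))
  structure(out, dt = attr(curves[[1]], "dt"),
            offset_convention = "zero-baseline", n = attr(curves[[1]], "n"),
            class = c("correlation_curve", "data.frame"))
}

#' Read or write correlation curves as CSV (`lag_s, g[, se]`)
#' @param path File path.
#' @param curve A `correlation_curve`.
#' @export
write_curve_csv <- function(path, curve) {
  df <- data.frame(lag_s = curve$lag, g = curve$g)
  if (!is.null(curve$se)) df$se <- curve$se
  write_csv_full(df, path)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  df <- utils::read.csv(path)
  out <- data.frame(lag = df$lag_s, g = df$g)
  if ("se" %in% names(df)) out$se <- df$se
  structure(out, dt = NA_real_, offset_convention = "zero-baseline",
            n = NA_integer_, class = c("correlation_curve", "data.frame"))
}
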