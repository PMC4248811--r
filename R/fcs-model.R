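#' 3D diffusion model for FCS correlation curves
#'
#' Evaluates the standard single- or two-component 3D Gaussian-volume
#' diffusion autocorrelation with optional triplet (blinking) correction:
#' \deqn{g(\tau) = b + \Big(1 + \frac{T}{1-T} e^{-\tau/\tau_T}\Big)
#'   \frac{\gamma}{N} \sum_i w_i
#'   \Big(1+(\tau/\tau_{D,i})^a\Big)^{-1}
#'   \Big(1+\frac{(\tau/\tau_{D,i})^a}{s^2}\Big)^{-1/2}}
#' with `s = z/r0` the axial-to-lateral beam ratio and `a` an anomalous
#' diffusion exponent (1 for free diffusion). For two components the
#' weights are `Y` and `1 - Y`, with `tau_d < tau_d2` by convention.
#'
#' With `as_printed = TRUE` the literal published rendering is used
#' instead: lateral term without the exponent `a`, axial term to the
#' power -1, and a fixed trailing `+ 1` baseline (single component), or
#' the lateral-only two-component form without axial term or offset.
#'
#' @param tau Lag times in seconds (>= 0 allowed; g(0) is the amplitude).
#' @param N Apparent molecule number (> 0).
#' @param tau_d Diffusion (residence) time in seconds; the fast component
#'   when `tau_d2` is given.
#' @param T Triplet fraction in `[0, 1)`.
#' @param tau_t Triplet correlation time in seconds (required if `T > 0`).
#' @param s_ratio Axial/lateral beam waist ratio z/r0 (> 0).
#' @param a Anomalous diffusion exponent (> 0), default 1.
#' @param gamma Shape factor; default 1 (folded into the apparent N),
#'   `2^(-3/2)` selectable for the 3D Gaussian convention.
#' @param baseline Additive offset b.
#' @param Y Fraction of the fast component for two-component models.
#' @param tau_d2 Slow diffusion time (two-component models; > `tau_d`).
#' @param as_printed Reproduce the literal printed equations (see above).
#' @return Numeric vector of correlation amplitudes, same length as `tau`.
#' @examples
#' fcs_model_g(0, N = 5, tau_d = 1, baseline = 1)      # 1 + 1/5
#' fcs_model_g(1, N = 1, tau_d = 1, s_ratio = Inf)     # 0.5
#' @export
fcs_model_g <- function(tau, N, tau_d, T = 0, tau_t = NULL, s_ratio = 5,
                        a = 1, gamma = 1, baseline = 0, Y = NULL,
                        tau_d2 = NULL, as_printed = FALSE) {
  if (N <= 0) stop("'N' must be positive")
  if (tau_d <= 0) stop("'tau_d' must be positive")
  if (T < 0 || T >= 1) stop("'T' must be in [0, 1)")
  if (T > 0 && (is.null(tau_t) || tau_t <= 0))
    stop("'tau_t' must be a positive triplet time when T > 0")
  two <- !is.null(tau_d2)
  if (two) {
    if (is.null(Y)) stop("'Y' is required for a two-component model")
    if (Y < 0 || Y > 1) stop("'Y' must be in [0, 1]")
    if (tau_d2 <= 0) stop("'tau_d2' must be positive")
  }
  trip <- if (T > 0) 1 + T / (1 - T) * exp(-tau / tau_t) else rep(1, length(tau))
  if (as_printed) {
    if (two) {
      diff_part <- Y / (1 + tau / tau_d) + (1 - Y) / (1 + tau / tau_d2)
      return(trip * (gamma / N) * diff_part)
    }
    lat <- 1 / (1 + tau / tau_d)
    ax <- 1 / (1 + (1 / s_ratio^2) * (tau / tau_d)^a)
    return(trip * (gamma / N) * lat * ax + 1)
  }
  comp <- function(td) {
    u <- (tau / td)^a
    1 / (1 + u) / sqrt(1 + u / s_ratio^2)
  }
  diff_part <- if (two) Y * comp(tau_d) + (1 - Y) * comp(tau_d2) else comp(tau_d)
  baseline + trip * (gamma / N) * diff_part
}

.fcs_par_names <- c("N", "tau_d", "T", "tau_t", "s_ratio", "a", "gamma",
                    "baseline", "Y", "tau_d2")

.fcs_lower <- c(N = 1e-10, tau_d = 1e-12, T = 0, tau_t = 1e-12,
                s_ratio = 1e-6, a = 1e-3, gamma = 1e-6, baseline = -Inf,
                Y = 0, tau_d2 = 1e-12)
.fcs_upper <- c(N = Inf, tau_d = Inf, T = 1 - 1e-9, tau_t = Inf,
                s_ratio = Inf, a = Inf, gamma = Inf, baseline = Inf,
                Y = 1, tau_d2 = Inf)

#' Fit a diffusion model to a correlation curve
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}) of [fcs_model_g()] against a measured
#' [autocorrelate()]/[crosscorrelate()] curve. Parameter bounds enforce
#' the model invariants; non-convergence is flagged, never silent.
#'
#' @param curve A `correlation_curve` (columns `lag`, `g`, optional `se`).
#' @param components 1 (default) or 2 diffusing components.
#' @param init Named list of starting values; anything not supplied is
#'   auto-initialised from the curve (amplitude -> N, half-amplitude lag
#'   -> tau_d).
#' @param fixed Character vector of parameter names to hold at their
#'   `init`/default values. Defaults fix `T`, `tau_t`, `s_ratio`, `a`
#'   and `gamma`, leaving `N`, `tau_d` (+ `Y`, `tau_d2`) and `baseline`
#'   free.
#' @param weights `"none"` (uniform, default) or `"se"` (1/se^2, needs a
#'   curve with per-lag standard errors).
#' @param as_printed Fit the literal printed model rendering.
#' @return A `diffusion_fit`: list with elements `params` (full named
#'   list), `se` (per free parameter), `converged`, `rss`, `components`,
#'   `amplitude` (fitted g(0+) above baseline = gamma/N) and `fitted`.
#' @seealso [diffusion_coefficient()] to convert `tau_d` to D.
#' @export
fit_correlation <- function(curve, components = 1L, init = list(),
                            fixed = NULL,
                            weights = c("none", "se"),
                            as_printed = FALSE) {
  weights <- match.arg(weights)
  stopifnot(is.data.frame(curve), all(c("lag", "g") %in% names(curve)))
  two <- components == 2L
  par <- list(N = NA_real_, tau_d = NA_real_, T = 0, tau_t = 1e-5,
              s_ratio = 5, a = 1, gamma = 1, baseline = 0,
              Y = if (two) 0.5 else NULL, tau_d2 = if (two) NA_real_ else NULL)
  if (is.null(fixed)) {
    fixed <- c("T", "tau_t", "s_ratio", "a", "gamma")
    if (!is.null(init$T) && init$T > 0) fixed <- setdiff(fixed, c("T", "tau_t"))
  }
  for (nm in names(init)) par[[nm]] <- init[[nm]]

  # auto-init from the curve
  amp <- max(curve$g) - min(0, min(curve$g))
  if (is.na(par$N)) par$N <- max(par$gamma / max(amp, 1e-12), 1e-6)
  if (is.na(par$tau_d)) {
    half <- max(curve$g) / 2
    i <- which(curve$g <= half)[1]
    par$tau_d <- if (is.na(i)) max(curve$lag) / 2 else curve$lag[i]
  }
  if (two && is.na(par$tau_d2)) par$tau_d2 <- par$tau_d * 10
  if (two) par$tau_d <- par$tau_d / 10

  pool <- if (two) .fcs_par_names else setdiff(.fcs_par_names, c("Y", "tau_d2"))
  free <- setdiff(pool, fixed)
  if (nrow(curve) < 2L * length(free))
    stop("need at least twice as many lag points as free parameters")
  w <- if (weights == "se") {
    if (is.null(curve$se)) stop("curve has no 'se' column for weighting")
    1 / pmax(curve$se, 1e-12)^2
  } else rep(1, nrow(curve))

  fn <- function(p) {
    pl <- par
    for (nm in free) pl[[nm]] <- p[[nm]]
    do.call(fcs_model_g, c(list(tau = curve$lag), pl,
                           list(as_printed = as_printed)))
  }
  start <- unlist(par[free])
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start,
                       lower = unname(.fcs_lower[free]),
                       upper = unname(.fcs_upper[free]),
                       fn = function(p) sqrt(w) * (curve$g - fn(as.list(p))),
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    res <- list(params = par, se = stats::setNames(rep(NA_real_, length(free)), free),
                converged = FALSE, rss = NA_real_, components = components,
                amplitude = NA_real_, fitted = NULL, message = conditionMessage(fit))
    class(res) <- "diffusion_fit"
    return(res)
  }
  est <- as.list(fit$par)
  for (nm in free) par[[nm]] <- est[[nm]]
  if (two && par$tau_d > par$tau_d2) {  # enforce tau_d < tau_d2
    tmp <- par$tau_d; par$tau_d <- par$tau_d2; par$tau_d2 <- tmp
    par$Y <- 1 - par$Y
  }
  se <- tryCatch({
    covm <- tryCatch(solve(fit$hessian) * fit$deviance / max(1, nrow(curve) - length(free)),
                     error = function(e) NULL)
    if (is.null(covm)) stats::setNames(rep(NA_real_, length(free)), free)
    else stats::setNames(sqrt(pmax(diag(covm), 0)) * sqrt(2), free)
  }, error = function(e) stats::setNames(rep(NA_real_, length(free)), free))
  res <- list(params = par, se = se,
              converged = fit$info %in% 1:4,
              rss = fit$deviance, components = components,
              amplitude = par$gamma / par$N,
              fitted = fn(par[free]))
  class(res) <- "diffusion_fit"
  res
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> %d component(s), %s\n", x$components,
              if (isTRUE(x$converged)) "converged" else "NOT CONVERGED"))
  p <- x$params
  cat(sprintf("  N = %.4g, tau_d = %.4g s", p$N, p$tau_d))
  if (!is.null(p$tau_d2))
    cat(sprintf(" (Y = %.3f), tau_d2 = %.4g s", p$Y, p$tau_d2))
  cat(sprintf(", amplitude g(0+) = %.4g, rss = %.3g\n", x$amplitude, x$rss))
  invisible(x)
}

#' Diffusion coefficient from the FCS residence time
#'
#' `D = r0^2 / (factor * tau_d)` with `factor = 4` for lateral diffusion
#' through a Gaussian beam waist (default) or `factor = 2` selectable.
#' `beam_radius()` is the inverse: the waist implied by a known (D,
#' tau_d) calibration pair, `r0 = sqrt(factor * D * tau_d)`.
#'
#' @param tau_d Residence time in seconds (> 0).
#' @param r0 Lateral 1/e^2 beam radius in micrometres (> 0).
#' @param geometry_factor 4 (default) or 2.
#' @param D Diffusion coefficient in um^2/s (> 0), for `beam_radius()`.
#' @return `diffusion_coefficient()`: D in um^2 s^-1; `beam_radius()`:
#'   r0 in um.
#' @examples
#' diffusion_coefficient(tau_d = 1, r0 = 0.2)        # 0.01
#' beam_radius(D = 0.005, tau_d = 4.61)              # 0.3036
#' @export
diffusion_coefficient <- function(tau_d, r0, geometry_factor = 4) {
  if (any(tau_d <= 0)) stop("'tau_d' must be positive")
  if (any(r0 <= 0)) stop("'r0' must be positive")
  if (!geometry_factor %in% c(2, 4)) stop("'geometry_factor' must be 2 or 4")
  r0^2 / (geometry_factor * tau_d)
}

#' @rdname diffusion_coefficient
#' @export
beam_radius <- function(D, tau_d, geometry_factor = 4) {
  if (any(D <= 0) || any(tau_d <= 0)) stop("'D' and 'tau_d' must be positive")
  if (!geometry_factor %in% c(2, 4)) stop("'geometry_factor' must be 2 or 4")
  sqrt(geometry_factor * D * tau_d)
}

#' Bound-species number from FCCS amplitudes
#'
#' Number of double-labelled (co-diffusing) molecules from the apparent
#' per-channel numbers and the reciprocal cross-correlation amplitude,
#' with correction for spectral crosstalk of the green fluorophore into
#' the red channel:
#' \deqn{N_{bound} = \frac{N_g (N_r + Q N_g)}{N_{cc}} - Q N_g.}
#' Here `n_cc` is 1/g_cc(0+), so at `q = 0` the expression reduces to
#' the textbook relation g_cc(0) = N_bound / (N_g N_r). A negative
#' corrected value (crosstalk overcorrection) is clipped to 0 with a
#' warning flag.
#'
#' @param n_g,n_r Apparent molecule numbers of the green/red channel
#'   (reciprocal autocorrelation amplitudes, > 0).
#' @param n_cc Reciprocal cross-correlation amplitude (> 0).
#' @param q Crosstalk ratio in `[0, 1)`: red-channel counts per molecule
#'   of the green fluorophore under green excitation divided by its
#'   red-channel counts under red excitation.
#' @return An `fccs_result`: list with `n_bound`, `frac_green_bound`
#'   (= n_bound/n_g), `frac_red_bound` (= n_bound/n_r), both clipped to
#'   `[0, 1]`, the inputs, and a `clipped` flag.
#' @examples
#' n_bound(10, 10, 20)            # 5 bound, fractions 0.5/0.5
#' n_bound(10, 10, 20, q = 0.1)   # 4.5
#' @export
n_bound <- function(n_g, n_r, n_cc, q = 0) {
  if (n_g <= 0 || n_r <= 0 || n_cc <= 0)
    stop("'n_g', 'n_r' and 'n_cc' must be positive")
  if (q < 0 || q >= 1) stop("'q' must be in [0, 1)")
  nb <- n_g * (n_r + q * n_g) / n_cc - q * n_g
  clipped <- FALSE
  if (nb < 0) {
    warning("crosstalk overcorrection: negative bound number clipped to 0")
    nb <- 0
    clipped <- TRUE
  }
  res <- list(n_g = n_g, n_r = n_r, n_cc = n_cc, q = q,
              n_bound = nb,
              frac_green_bound = min(max(nb / n_g, 0), 1),
              frac_red_bound = min(max(nb / n_r, 0), 1),
              clipped = clipped)
  class(res) <- "fccs_result"
  res
}

#' @export
print.fccs_result <- function(x, ...) {
  cat(sprintf("<fccs_result> N_bound = %.4g (Ng = %.4g, Nr = %.4g, Ncc = %.4g, Q = %.3g)\n",
              x$n_bound, x$n_g, x$n_r, x$n_cc, x$q))
  cat(sprintf("  bound fraction: %.1f%% of green, %.1f%% of red%s\n",
              100 * x$frac_green_bound, 100 * x$frac_red_bound,
              if (x$clipped) "  [clipped]" else ""))
  invisible(x)
}

#' Full dual-colour cross-correlation analysis of a trace pair
#'
#' Correlates both channels and their cross-correlation, fits the
#' diffusion model to each curve, reads the amplitudes g(0+) from the
#' fitted models (never from the noisy first lag bin), and applies the
#' crosstalk-corrected bound-number relation.
#'
#' @param green,red `intensity_trace` objects, equal length and `dt`.
#' @param max_lag Largest lag in seconds for all three curves.
#' @param q Crosstalk ratio (see [n_bound()]).
#' @param s_ratio Axial/lateral beam ratio fixed in all fits.
#' @param init Optional shared initial parameter list for the fits.
#' @param m Multiple-tau lags per level.
#' @return An `fccs_result` (see [n_bound()]) with the three
#'   `diffusion_fit`s attached as `fits`.
#' @export
fccs_analysis <- function(green, red, max_lag = NULL, q = 0, s_ratio = 5,
                          init = list(), m = 16L) {
  g_ac <- autocorrelate(green, max_lag = max_lag, m = m)
  r_ac <- autocorrelate(red, max_lag = max_lag, m = m)
  cc <- crosscorrelate(green, red, max_lag = max_lag, m = m)
  ini <- utils::modifyList(list(s_ratio = s_ratio), init)
  fg <- fit_correlation(g_ac, init = ini)
  fr <- fit_correlation(r_ac, init = ini)
  fc <- fit_correlation(cc, init = ini)
  if (!all(fg$converged, fr$converged, fc$converged))
    warning("one or more correlation fits did not converge")
  res <- n_bound(n_g = fg$params$gamma / fg$amplitude,
                 n_r = fr$params$gamma / fr$amplitude,
                 n_cc = fc$params$gamma / fc$amplitude,
                 q = q)
  res$fits <- list(green = fg, red = fr, cross = fc)
  res
}
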