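#' Fit exponential decay kinetics to a response trace
#'
#' Least-squares fit of a single (`A e^{-t/tau}`) or double
#' (`A (p e^{-t/tau_fast} + (1-p) e^{-t/tau_slow})`) exponential decay
#' to a trace that starts at its maximum (the recovery phase of an
#' accumulation or fusion response). `model = "auto"` fits both and
#' keeps the double form only when it reduces the residual sum of
#' squares significantly under an F-ratio test at `alpha`; a double fit
#' whose time constants nearly coincide (ratio below `collapse_ratio`)
#' or whose fast fraction is pinned at 0/1 collapses to the single fit
#' with a warning.
#'
#' @param t Time since the trace peak, seconds (first sample 0).
#' @param y Trace values; `y[1]` must be the maximum.
#' @param model `"auto"`, `"single"` or `"double"`.
#' @param alpha F-test level for auto selection (default 0.05).
#' @param collapse_ratio Minimum tau_slow/tau_fast ratio for a genuine
#'   double fit (default 1.5).
#' @return A `decay_fit`: list with `model`, `amplitude`, `tau` (single)
#'   or `fraction_fast`, `tau_fast`, `tau_slow` (double,
#'   `tau_fast < tau_slow` enforced), `rss`, `converged`, and for auto
#'   mode the F statistic and p value.
#' @examples
#' t <- seq(0, 30, 0.1)
#' fit_decay(t, exp(-t / 3.2))$tau                       # 3.2
#' fit_decay(t, 0.3 * exp(-t / 2.5) + 0.7 * exp(-t / 13))$model  # "double"
#' @export
fit_decay <- function(t, y, model = c("auto", "single", "double"),
                      alpha = 0.05, collapse_ratio = 1.5) {
  model <- match.arg(model)
  stopifnot(length(t) == length(y), length(t) >= 10L)
  if (abs(t[1]) > 1e-9) stop("'t' must start at 0 (the trace peak)")
  rng <- diff(range(y))
  if (max(y) > y[1] + 0.1 * rng)  # tolerate noise-level excursions
    warning("trace does not start at its maximum; decay fit assumes the peak at t = 0")
  df <- data.frame(t = t, y = y)
  a0 <- max(y[1], 1e-12)
  i <- which(y <= a0 * exp(-1))[1]
  tau0 <- if (is.na(i) || t[i] <= 0) max(t) / 3 else t[i]

  fit_single <- function() {
    tryCatch(minpack.lm::nlsLM(y ~ A * exp(-t / tau), data = df,
                               start = list(A = a0, tau = tau0),
                               lower = c(1e-12, 1e-9),
                               control = stats::nls.control(maxiter = 200)),
             error = function(e) NULL)
  }
  fit_double <- function() {
    tryCatch(minpack.lm::nlsLM(
      y ~ A * (p * exp(-t / t1) + (1 - p) * exp(-t / t2)), data = df,
      start = list(A = a0, p = 0.5, t1 = tau0 / 4, t2 = tau0 * 4),
      lower = c(1e-12, 0, 1e-9, 1e-9), upper = c(Inf, 1, Inf, Inf),
      control = stats::nls.control(maxiter = 400)),
      error = function(e) NULL)
  }
  pack_single <- function(fs) {
    cf <- stats::coef(fs)
    out <- list(model = "single", amplitude = unname(cf["A"]),
                tau = unname(cf["tau"]),
                se = tryCatch(sqrt(diag(stats::vcov(fs))), error = function(e) NULL),
                rss = sum(stats::residuals(fs)^2),
                converged = isTRUE(fs$convInfo$isConv))
    class(out) <- "decay_fit"
    out
  }
  pack_double <- function(fd) {
    cf <- stats::coef(fd)
    p <- unname(cf["p"]); t1 <- unname(cf["t1"]); t2 <- unname(cf["t2"])
    if (t1 > t2) { tmp <- t1; t1 <- t2; t2 <- tmp; p <- 1 - p }
    out <- list(model = "double", amplitude = unname(cf["A"]),
                fraction_fast = p, tau_fast = t1, tau_slow = t2,
                se = tryCatch(sqrt(diag(stats::vcov(fd))), error = function(e) NULL),
                rss = sum(stats::residuals(fd)^2),
                converged = isTRUE(fd$convInfo$isConv))
    class(out) <- "decay_fit"
    out
  }
  not_conv <- function(msg) {
    out <- list(model = model, converged = FALSE, rss = NA_real_, message = msg)
    class(out) <- "decay_fit"
    out
  }

  if (model == "single") {
    fs <- fit_single()
    return(if (is.null(fs)) not_conv("single-exponential fit failed") else pack_single(fs))
  }
  if (model == "double") {
    fd <- fit_double()
    if (is.null(fd)) return(not_conv("double-exponential fit failed"))
    out <- pack_double(fd)
    if (out$tau_slow / out$tau_fast < collapse_ratio ||
        out$fraction_fast < 0.02 || out$fraction_fast > 0.98) {
      warning("double-exponential fit collapsed (tau_fast ~ tau_slow); returning single fit")
      fs <- fit_single()
      if (!is.null(fs)) return(pack_single(fs))
    }
    return(out)
  }
  # auto: nested F-ratio test
  fs <- fit_single(); fd <- fit_double()
  if (is.null(fs) && is.null(fd)) return(not_conv("both fits failed"))
  if (is.null(fd)) return(pack_single(fs))
  if (is.null(fs)) return(pack_double(fd))
  s1 <- pack_single(fs); s2 <- pack_double(fd)
  collapsed <- s2$tau_slow / s2$tau_fast < collapse_ratio ||
    s2$fraction_fast < 0.02 || s2$fraction_fast > 0.98
  n <- length(t)
  Fstat <- ((s1$rss - s2$rss) / 2) / (s2$rss / (n - 4))
  pval <- stats::pf(Fstat, 2, n - 4, lower.tail = FALSE)
  if (!collapsed && is.finite(Fstat) && Fstat > 0 && pval < alpha) {
    s2$f_statistic <- Fstat; s2$p_value <- pval
    s2
  } else {
    s1$f_statistic <- Fstat; s1$p_value <- pval
    s1
  }
}

#' @export
print.decay_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("<decay_fit> NOT CONVERGED\n")
    return(invisible(x))
  }
  if (x$model == "single") {
    cat(sprintf("<decay_fit> single: A = %.4g, tau = %.4g s (rss %.3g)\n",
                x$amplitude, x$tau, x$rss))
  } else {
    cat(sprintf("<decay_fit> double: A = %.4g, %.0f%% tau = %.4g s + %.0f%% tau = %.4g s (rss %.3g)\n",
                x$amplitude, 100 * x$fraction_fast, x$tau_fast,
                100 * (1 - x$fraction_fast), x$tau_slow, x$rss))
  }
  invisible(x)
}

#' Compare recovery kinetics and event counts between conditions
#'
#' Fold changes between a control and a treated condition (e.g. a
#' clathrin inhibitor): `fold_change_tau` is the ratio of mean fitted
#' recovery time constants treated/control (> 1 means slowed), and
#' `fold_change_event_count` the ratio of event counts control/treated
#' (> 1 means fewer events under treatment). Counts may be raw totals
#' or per-terminal vectors; both total and per-terminal-mean folds are
#' reported when vectors are given.
#'
#' @param control,treated Lists with elements `taus` (numeric vector of
#'   fitted time constants, optional), `counts` (scalar total or
#'   per-terminal vector) and optionally `half_times` (empirical
#'   half-recovery times), since a "k-fold slowing" can be read as a
#'   ratio of fitted time constants or of half-recovery times; both are
#'   reported when available.
#' @return A `condition_comparison`: list with `fold_change_tau`,
#'   `fold_change_half_time`, `fold_change_event_count`,
#'   `fold_change_count_per_terminal` (when resolvable), and
#'   per-condition `n`.
#' @examples
#' compare_conditions(list(counts = 203), list(counts = 109))
#' @export
compare_conditions <- function(control, treated) {
  fold_tau <- NA_real_
  if (!is.null(control$taus) && !is.null(treated$taus) &&
      length(control$taus) && length(treated$taus))
    fold_tau <- mean(treated$taus) / mean(control$taus)
  fold_half <- NA_real_
  if (!is.null(control$half_times) && !is.null(treated$half_times) &&
      length(control$half_times) && length(treated$half_times))
    fold_half <- mean(treated$half_times) / mean(control$half_times)
  fold_count <- NA_real_
  fold_per_terminal <- NA_real_
  if (!is.null(control$counts) && !is.null(treated$counts)) {
    tc <- sum(treated$counts)
    if (tc == 0) stop("treated event count is zero; fold change undefined")
    fold_count <- sum(control$counts) / tc
    if (length(control$counts) > 1L || length(treated$counts) > 1L)
      fold_per_terminal <- mean(control$counts) / mean(treated$counts)
  }
  res <- list(fold_change_tau = fold_tau,
              fold_change_half_time = fold_half,
              fold_change_event_count = fold_count,
              fold_change_count_per_terminal = fold_per_terminal,
              n_control = c(taus = length(control$taus), counts = length(control$counts)),
              n_treated = c(taus = length(treated$taus), counts = length(treated$counts)))
  class(res) <- "condition_comparison"
  res
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat("<condition_comparison>\n")
  if (is.finite(x$fold_change_tau))
    cat(sprintf("  recovery slowed %.2g-fold (mean treated tau / mean control tau)\n",
                x$fold_change_tau))
  if (is.finite(x$fold_change_event_count))
    cat(sprintf("  event count reduced %.3g-fold (control / treated)\n",
                x$fold_change_event_count))
  invisible(x)
}
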