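#' Uniformly binned intensity trace
#'
#' Container for a single-channel fluorescence or photon-count time series
#' with a fixed bin width, the elementary input of the correlation analysis.
#'
#' @param values Numeric vector of counts (or arbitrary intensity units),
#'   length at least 2, all finite.
#' @param dt Bin width in seconds (> 0).
#' @param channel Optional channel label (e.g. `"green"`).
#' @return An object of class `intensity_trace`: the numeric vector with
#'   attributes `dt` and `channel`.
#' @examples
#' tr <- intensity_trace(rpois(1000, 5), dt = 1e-4, channel = "green")
#' trace_duration(tr)
#' @export
intensity_trace <- function(values, dt, channel = "") {
  values <- as.numeric(values)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number (seconds)")
  if (length(values) < 2L)
    stop("an intensity trace needs at least 2 samples")
  if (!all(is.finite(values)))
    stop("intensity trace contains non-finite values")
  structure(values, dt = dt, channel = as.character(channel),
            class = "intensity_trace")
}

#' @rdname intensity_trace
#' @param x An `intensity_trace`.
#' @export
trace_duration <- function(x) length(x) * attr(x, "dt")

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("<intensity_trace> %d bins x %.3g s (%.4g s total)%s\n",
              length(x), attr(x, "dt"), trace_duration(x),
              if (nzchar(attr(x, "channel")))
                paste0(", channel '", attr(x, "channel"), "'") else ""))
  cat(sprintf("  mean %.4g counts/bin, rate %.4g counts/s\n",
              mean(x), mean(x) / attr(x, "dt")))
  invisible(x)
}

as_trace <- function(x, dt = NULL) {
  if (inherits(x, "intensity_trace")) return(x)
  if (is.null(dt)) stop("'dt' required when the input is a bare vector")
  intensity_trace(x, dt)
}

#' Read or write intensity traces as CSV
#'
#' Traces are stored as `time_s, counts[, counts_ch2]` with a header row.
#'
#' @param path File path.
#' @param green,red `intensity_trace` objects (red optional).
#' @return `read_trace_csv` returns a list with elements `green` and
#'   (when present in the file) `red`.
#' @export
write_trace_csv <- function(path, green, red = NULL) {
  stopifnot(inherits(green, "intensity_trace"))
  dt <- attr(green, "dt")
  df <- data.frame(time_s = (seq_along(green) - 1) * dt,
                   counts = as.numeric(green))
  if (!is.null(red)) {
    stopifnot(inherits(red, "intensity_trace"))
    if (length(red) != length(green) || attr(red, "dt") != dt)
      stop("green and red traces must share length and bin width")
    df$counts_ch2 <- as.numeric(red)
  }
  write_csv_full(df, path)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "counts") %in% names(df)))
    stop("trace CSV must have columns 'time_s' and 'counts'")
  if (nrow(df) < 2L) stop("trace CSV has fewer than 2 rows")
  dt <- df$time_s[2] - df$time_s[1]
  out <- list(green = intensity_trace(df$counts, dt, "green"))
  if ("counts_ch2" %in% names(df))
    out$red <- intensity_trace(df$counts_ch2, dt, "red")
  out
}

# Full-precision CSV writer: doubles are serialised with 17 significant
# digits so numeric tables round-trip exactly through read.csv.
write_csv_full <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
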