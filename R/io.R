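#' Write and read TIRF movies as multi-page TIFF with a JSON sidecar
#'
#' Movies are stored as 16-bit multi-page TIFF (one page per frame,
#' integer counts scaled by 1/65535 as the format requires) together
#' with a `<path>.json` sidecar holding the acquisition metadata.
#' Integer-valued stacks round-trip exactly.
#'
#' @param movie A [tirf_movie()] with values in `[0, 65535]`.
#' @param path Output TIFF path.
#' @return `write_movie` returns the path invisibly; `read_movie`
#'   returns a [tirf_movie()].
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "tirf_movie"))
  st <- movie$stack
  if (min(st) < 0 || max(st) > 65535)
    stop("stack values must lie in [0, 65535] for 16-bit storage")
  pages <- lapply(seq_len(dim(st)[1]), function(f) st[f, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(frame_interval = movie$frame_interval,
               pixel_size = movie$pixel_size,
               stimulus_onset_frame = movie$stimulus_onset_frame,
               stimulus_duration = movie$stimulus_duration,
               scale = 65535)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_movie
#' @param frame_interval,pixel_size,stimulus_onset_frame,stimulus_duration
#'   Metadata overrides; required when no sidecar JSON is present.
#' @export
read_movie <- function(path, frame_interval = NULL, pixel_size = NULL,
                       stimulus_onset_frame = NULL, stimulus_duration = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      stop("failed to read TIFF (truncated or invalid): ",
                           conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list()
  pick <- function(arg, name) if (!is.null(arg)) arg else meta[[name]]
  fi <- pick(frame_interval, "frame_interval")
  px <- pick(pixel_size, "pixel_size")
  so <- pick(stimulus_onset_frame, "stimulus_onset_frame")
  sd_ <- pick(stimulus_duration, "stimulus_duration")
  missing <- c("frame_interval", "pixel_size")[c(is.null(fi), is.null(px))]
  if (length(missing))
    stop("missing movie metadata (no sidecar JSON and no arguments): ",
         paste(missing, collapse = ", "))
  scale <- if (!is.null(meta$scale)) meta$scale else 65535
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  st <- array(0, dim = c(length(pages), H, W))
  for (f in seq_along(pages)) st[f, , ] <- round(pages[[f]] * scale)
  tirf_movie(st, fi, px,
             if (is.null(so)) NA_integer_ else so,
             if (is.null(sd_)) NA_real_ else sd_)
}

#' Write and read ground-truth tables
#'
#' Full-precision CSV (17 significant digits) so numeric ground truth
#' round-trips losslessly through the file.
#'
#' @param truth Data frame (e.g. from [simulate_tirf_movie()] or
#'   [simulate_fcs_trace()]).
#' @param path CSV path.
#' @export
write_ground_truth <- function(truth, path) {
  write_csv_full(truth, path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a label image as TIFF
#' @param labels Integer H x W label matrix (0 = background).
#' @param path Output path.
#' @export
write_labels <- function(labels, path) {
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}
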