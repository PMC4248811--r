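#' Laplace enhancement of a 2D image
#'
#' Discrete 5-point Laplacian with replicated borders, after optional
#' Gaussian pre-smoothing; sharpens punctate structure against low
#' spatial-frequency background before threshold segmentation. A
#' constant image maps to zero everywhere and a linear ramp to zero in
#' the interior; a single bright pixel maps to a negative centre whose
#' four neighbours are positive and sum to minus the centre.
#'
#' @param image Numeric matrix.
#' @param smooth_sigma Gaussian pre-smoothing radius in pixels (0 = no
#'   smoothing, default).
#' @return Matrix of the same shape.
#' @export
laplace_enhance <- function(image, smooth_sigma = 0) {
  if (!is.matrix(image)) stop("'image' must be a 2D matrix")
  laplacian5(gaussian_smooth(image, smooth_sigma))
}

#' Threshold segmentation into regions of interest
#'
#' Thresholds an image (typically Laplace-enhanced, or a temporal
#' SD/relative-change projection of a movie) at
#' `median + threshold_sd * MAD` of its values, labels 8-connected
#' components in deterministic raster order, and discards components
#' below `min_pixels`.
#'
#' @param image Numeric matrix.
#' @param threshold_sd Threshold as a multiple of the robust background
#'   SD (MAD, normal-consistent).
#' @param min_pixels Minimum component size in pixels.
#' @param pixel_size Pixel size in um (for centroids).
#' @param mask Optional logical matrix restricting segmentation.
#' @param split_peaks Split components containing several well-separated
#'   intensity maxima (above 40% of the component's peak-over-threshold
#'   prominence, at least 3 px apart) by nearest-maximum assignment, so
#'   neighbouring puncta merged by thresholding become separate ROIs
#'   (default `TRUE`).
#' @return A `roi_set`: list with `labels` (H x W integer matrix, 0 =
#'   background) and `rois` (data frame: `id`, `n_pixels`, `x`, `y`
#'   centroids in um). An empty segmentation is a valid empty set.
#' @export
segment_rois <- function(image, threshold_sd = 5, min_pixels = 4L,
                         pixel_size = 1, mask = NULL, split_peaks = TRUE) {
  if (!is.matrix(image)) stop("'image' must be a 2D matrix")
  med <- stats::median(image)
  # absolute floor at 0.1% of the dynamic range keeps noise-free synthetic
  # images from segmenting through vanishing Gaussian tails; it is far
  # below the noise level of any real image
  thr <- med + max(threshold_sd * robust_sd(image),
                   1e-3 * (max(image) - med))
  above <- image > thr
  if (!is.null(mask)) above <- above & mask
  lab <- label_components(above)
  if (split_peaks && max(lab) > 0L)
    lab <- split_label_peaks(lab, image, thr)
  ids <- seq_len(max(lab, 0L))
  keep <- ids[tabulate(lab[lab > 0L], nbins = length(ids)) >= min_pixels]
  relab <- matrix(0L, nrow(lab), ncol(lab))
  rois <- data.frame(id = integer(0), n_pixels = integer(0),
                     x = numeric(0), y = numeric(0))
  for (new_id in seq_along(keep)) {
    sel <- lab == keep[new_id]
    relab[sel] <- new_id
    idx <- which(sel, arr.ind = TRUE)
    rois <- rbind(rois, data.frame(
      id = new_id, n_pixels = nrow(idx),
      x = mean(idx[, 2] - 0.5) * pixel_size,
      y = mean(idx[, 1] - 0.5) * pixel_size))
  }
  structure(list(labels = relab, rois = rois, pixel_size = pixel_size),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d ROIs on a %d x %d label image\n",
              nrow(x$rois), nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Extract background-corrected relative-change traces per ROI
#'
#' For each ROI the mean intensity per frame is background-subtracted
#' and converted to a relative change `dF/F = (F - F0)/F0`, with `F0`
#' the mean over a pre-stimulus baseline window. The background trace is
#' either taken from a supplied mask or from the darkest decile of
#' pixels (by baseline mean). A whole-footprint `dF/F` trace over the
#' union of all ROI-eligible pixels is returned alongside.
#'
#' @param movie A [tirf_movie()].
#' @param rois A `roi_set` from [segment_rois()].
#' @param baseline_frames Number of frames immediately before the
#'   stimulus onset used as baseline (default 20, at least 5 within the
#'   movie).
#' @param background Either `"auto"` (darkest-decile pixels) or a
#'   logical H x W matrix marking background pixels.
#' @param footprint Optional logical matrix defining the footprint for
#'   the whole-footprint trace; default: pixels brighter than the
#'   midpoint between background and bright baseline levels.
#' @return List with `dff` (frames x n_roi matrix), `footprint_dff`
#'   (vector), `f0` (per-roi baselines), `excluded` (ids flagged for
#'   non-positive baseline) and `time` (s).
#' @export
extract_traces <- function(movie, rois, baseline_frames = 20L,
                           background = "auto", footprint = NULL) {
  stopifnot(inherits(movie, "tirf_movie"))
  st <- movie$stack
  fr <- dim(st)[1]
  onset <- movie$stimulus_onset_frame
  if (is.na(onset)) stop("movie has no stimulus onset frame")
  b0 <- max(1L, onset - baseline_frames); b1 <- onset - 1L
  if (b1 - b0 + 1L < 5L) stop("baseline window must contain at least 5 frames")
  base_img <- apply(st[b0:b1, , , drop = FALSE], c(2, 3), mean)

  bg_mask <- if (is.matrix(background)) background
             else base_img <= stats::quantile(base_img, 0.1)
  flat <- matrix(st, nrow = fr)  # frames x (H*W), column-major pixels
  bg_trace <- if (any(bg_mask))
    rowMeans(flat[, as.vector(bg_mask), drop = FALSE]) else numeric(fr)

  if (is.null(footprint)) {
    lo <- if (any(bg_mask)) mean(base_img[bg_mask]) else min(base_img)
    hi <- stats::quantile(base_img, 0.9)
    footprint <- base_img >= (lo + hi) / 2
  }

  nroi <- nrow(rois$rois)
  dff <- matrix(NA_real_, fr, max(nroi, 0L))
  f0 <- numeric(max(nroi, 0L))
  excluded <- integer(0)
  for (i in seq_len(nroi)) {
    sel <- as.vector(rois$labels == rois$rois$id[i])
    tr <- rowMeans(flat[, sel, drop = FALSE]) - bg_trace
    f0i <- mean(tr[b0:b1])
    f0[i] <- f0i
    if (!is.finite(f0i) || f0i <= 0) {
      excluded <- c(excluded, rois$rois$id[i])
      next
    }
    dff[, i] <- (tr - f0i) / f0i
  }
  fp <- rowMeans(flat[, as.vector(footprint), drop = FALSE]) - bg_trace
  fp0 <- mean(fp[b0:b1])
  list(dff = dff,
       footprint_dff = if (fp0 > 0) (fp - fp0) / fp0 else rep(NA_real_, fr),
       f0 = f0, excluded = excluded,
       time = (seq_len(fr) - 1L) * movie$frame_interval,
       baseline_window = c(b0, b1))
}

#' Select responding ROIs by baseline-SD threshold crossing
#'
#' A ROI responds when any post-onset sample of its `dF/F` trace exceeds
#' `+k_sd` times the baseline SD (positive response) or falls below
#' `-k_sd` times it (negative response). Following the averaged-SD
#' selection rule, the SD used is by default the mean of the per-ROI
#' baseline SDs; per-ROI SDs are selectable.
#'
#' @param dff Frames x n_roi matrix of `dF/F` traces (from
#'   [extract_traces()]).
#' @param baseline_window Integer `c(first, last)` baseline frame range.
#' @param onset_frame Stimulus onset frame; samples from this frame on
#'   are tested.
#' @param k_sd Threshold multiple (default 4).
#' @param sd_mode `"average"` (default) or `"per-roi"`.
#' @return Data frame: `roi`, `responder`, `sign` (+1/-1/0), `peak`
#'   (signed extreme `dF/F`), `sd_baseline`.
#' @export
detect_responders <- function(dff, baseline_window, onset_frame, k_sd = 4,
                              sd_mode = c("average", "per-roi")) {
  sd_mode <- match.arg(sd_mode)
  if (is.null(dim(dff))) dff <- matrix(dff, ncol = 1L)
  if (diff(baseline_window) + 1L < 5L)
    stop("baseline window must contain at least 5 frames")
  if (ncol(dff) == 0L)
    return(data.frame(roi = integer(0), responder = logical(0),
                      sign = integer(0), peak = numeric(0),
                      sd_baseline = numeric(0)))
  bl <- dff[baseline_window[1]:baseline_window[2], , drop = FALSE]
  sds <- apply(bl, 2L, stats::sd)
  if (sd_mode == "average") sds <- rep(mean(sds, na.rm = TRUE), length(sds))
  post <- dff[onset_frame:nrow(dff), , drop = FALSE]
  out <- data.frame(roi = seq_len(ncol(dff)), responder = FALSE, sign = 0L,
                    peak = NA_real_, sd_baseline = sds)
  for (i in seq_len(ncol(dff))) {
    x <- post[, i]
    if (all(is.na(x))) next
    hi <- max(x, na.rm = TRUE); lo <- min(x, na.rm = TRUE)
    pos <- hi > k_sd * sds[i]; neg <- lo < -k_sd * sds[i]
    if (pos || neg) {
      out$responder[i] <- TRUE
      out$sign[i] <- if (abs(hi) >= abs(lo)) 1L else -1L
      if (pos && !neg) out$sign[i] <- 1L
      if (neg && !pos) out$sign[i] <- -1L
      out$peak[i] <- if (out$sign[i] > 0) hi else lo
    }
  }
  out
}

#' Classify responding ROIs as accumulation or loss events
#'
#' Responders whose significant excursion inside the classification
#' window (default 10 s from stimulus onset) is positive are classed
#' `accumulation`, negative `loss`, others `none`. Each event record
#' carries the onset frame (first threshold crossing), the signed peak
#' `dF/F`, the intensity-weighted centre of mass of its ROI during the
#' response window, and a single-exponential recovery time constant
#' fitted from the trace peak (left unset when the fit fails).
#'
#' @param movie A [tirf_movie()].
#' @param rois A `roi_set`.
#' @param traces Output of [extract_traces()] for these ROIs.
#' @param window_s Classification window in seconds (default 10).
#' @param k_sd Threshold multiple of baseline SD (default 4).
#' @param sd_mode Passed to [detect_responders()].
#' @return An `event_record` data frame: `roi`, `class`, `onset_frame`,
#'   `peak_dff`, `x`, `y` (um), `recovery_tau` (s or NA),
#'   `distance_to_ribbon` (NA until [event_ribbon_distances()]).
#' @export
classify_events <- function(movie, rois, traces, window_s = 10, k_sd = 4,
                            sd_mode = "average") {
  onset <- movie$stimulus_onset_frame
  fr <- dim(movie$stack)[1]
  wend <- min(fr, onset + ceiling(window_s / movie$frame_interval) - 1L)
  if (wend <= onset) stop("classification window does not fit in the movie")
  dffw <- traces$dff
  if (wend < fr) dffw[(wend + 1L):fr, ] <- NA  # classify inside the window only
  det <- detect_responders(dffw, traces$baseline_window, onset, k_sd, sd_mode)

  px <- movie$pixel_size
  resp_mean <- apply(movie$stack[onset:wend, , , drop = FALSE], c(2, 3), mean)
  base_mean <- apply(movie$stack[traces$baseline_window[1]:traces$baseline_window[2],
                                 , , drop = FALSE], c(2, 3), mean)
  dimg <- abs(resp_mean - base_mean)
  recs <- data.frame(roi = integer(0), class = character(0),
                     onset_frame = integer(0), peak_dff = numeric(0),
                     x = numeric(0), y = numeric(0),
                     recovery_tau = numeric(0),
                     distance_to_ribbon = numeric(0))
  for (i in which(det$responder)) {
    cls <- if (det$sign[i] > 0) "accumulation" else "loss"
    tr <- traces$dff[, i]
    thr <- k_sd * det$sd_baseline[i]
    cross <- which(abs(tr[onset:wend]) > thr)[1]
    onset_frame <- onset + cross - 1L
    # intensity-weighted centre of mass of the ROI over the response window
    sel <- which(rois$labels == det$roi[i], arr.ind = TRUE)
    w <- dimg[sel]
    if (sum(w) <= 0) w <- rep(1, nrow(sel))
    xy <- c(sum((sel[, 2] - 0.5) * w), sum((sel[, 1] - 0.5) * w)) / sum(w) * px
    # recovery fit from the trace peak
    ipk <- onset - 1L + which.max(abs(tr[onset:fr]))
    tau <- NA_real_
    if (fr - ipk + 1L >= 10L) {
      dec <- fit_decay((seq_len(fr - ipk + 1L) - 1L) * movie$frame_interval,
                       abs(tr[ipk:fr]), model = "single")
      if (isTRUE(dec$converged)) tau <- dec$tau
    }
    recs <- rbind(recs, data.frame(
      roi = det$roi[i], class = cls, onset_frame = onset_frame,
      peak_dff = det$peak[i], x = xy[1], y = xy[2],
      recovery_tau = tau, distance_to_ribbon = NA_real_))
  }
  class(recs) <- c("event_record", "data.frame")
  recs
}

#' One-call TIRF movie analysis
#'
#' Runs the full imaging chain: temporal-SD projection of the
#' classification window, Laplace enhancement, threshold segmentation
#' restricted to the (eroded) footprint, trace extraction, responder
#' selection and event classification; optionally attaches
#' event-to-ribbon distances when a ribbon-channel image is given.
#'
#' @param movie A [tirf_movie()].
#' @param ribbon_image Optional H x W ribbon-channel image.
#' @param k_seg Segmentation threshold (multiples of robust SD of the
#'   enhanced projection).
#' @param k_sd Responder threshold (multiples of baseline SD).
#' @param window_s Classification window (s).
#' @param baseline_frames Baseline frames before the stimulus.
#' @param min_pixels Minimum ROI size.
#' @param smooth_sigma Pre-smoothing for the Laplace step (px).
#' @return List with `rois`, `traces`, `events` and (with ribbons)
#'   `ribbons` plus per-event distances filled in.
#' @export
analyze_movie <- function(movie, ribbon_image = NULL, k_seg = 6, k_sd = 4,
                          window_s = 10, baseline_frames = 20L,
                          min_pixels = 4L, smooth_sigma = 1) {
  st <- movie$stack
  fr <- dim(st)[1]
  onset <- movie$stimulus_onset_frame
  wend <- min(fr, onset + ceiling(window_s / movie$frame_interval) - 1L)
  proj <- apply(st[onset:wend, , , drop = FALSE], c(2, 3), stats::sd)
  enh <- -laplace_enhance(proj, smooth_sigma = smooth_sigma)

  b0 <- max(1L, onset - baseline_frames)
  base_img <- apply(st[b0:(onset - 1L), , , drop = FALSE], c(2, 3), mean)
  lo <- stats::quantile(base_img, 0.1); hi <- stats::quantile(base_img, 0.9)
  foot <- erode3(base_img > (lo + hi) / 2, iterations = 2L)

  rois <- segment_rois(enh, threshold_sd = k_seg, min_pixels = min_pixels,
                       pixel_size = movie$pixel_size, mask = foot)
  traces <- extract_traces(movie, rois, baseline_frames = baseline_frames)
  events <- classify_events(movie, rois, traces, window_s = window_s, k_sd = k_sd)
  out <- list(rois = rois, traces = traces, events = events)
  if (!is.null(ribbon_image)) {
    rib <- detect_ribbons(ribbon_image, pixel_size = movie$pixel_size)
    out$ribbons <- rib
    if (nrow(rib$centers) && nrow(events))
      out$events <- event_ribbon_distances(out$events, rib)
  }
  out
}
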