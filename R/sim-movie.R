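#' TIRF movie container
#'
#' An image stack with the acquisition metadata the event analysis
#' needs. Pixel coordinates are `[row, col]`; physical coordinates are
#' micrometres with the origin at the outer corner of pixel `[1, 1]`
#' (pixel centres at half-integer multiples of the pixel size).
#'
#' @param stack Numeric array `frames x H x W` (>= 2 frames).
#' @param frame_interval Frame interval in seconds (> 0).
#' @param pixel_size Pixel size in micrometres (> 0).
#' @param stimulus_onset_frame Frame index (1-based) of stimulus onset.
#' @param stimulus_duration Stimulus duration in seconds.
#' @return A `tirf_movie` list.
#' @export
tirf_movie <- function(stack, frame_interval = 0.1, pixel_size = 0.1,
                       stimulus_onset_frame = NA_integer_,
                       stimulus_duration = NA_real_) {
  if (length(dim(stack)) != 3L)
    stop("'stack' must be a 3D array (frames x H x W)")
  if (dim(stack)[1] < 2L)
    stop("a movie needs at least 2 frames for event analysis")
  if (frame_interval <= 0 || pixel_size <= 0)
    stop("'frame_interval' and 'pixel_size' must be positive")
  structure(list(stack = stack, frame_interval = frame_interval,
                 pixel_size = pixel_size,
                 stimulus_onset_frame = as.integer(stimulus_onset_frame),
                 stimulus_duration = stimulus_duration),
            class = "tirf_movie")
}

#' @export
print.tirf_movie <- function(x, ...) {
  d <- dim(x$stack)
  cat(sprintf("<tirf_movie> %d frames x %d x %d px, %.3g s/frame, %.3g um/px\n",
              d[1], d[2], d[3], x$frame_interval, x$pixel_size))
  if (!is.na(x$stimulus_onset_frame))
    cat(sprintf("  stimulus: onset frame %d, duration %.3g s\n",
                x$stimulus_onset_frame, x$stimulus_duration))
  invisible(x)
}

#' Configuration for the synthetic TIRF movie generator
#'
#' Describes a synaptic-terminal footprint imaged at fixed frame
#' interval, with static ribbon puncta and three kinds of planted
#' stimulus-locked events: vesicle-fusion hotspots (positive-going,
#' peaking ~300 ms after stimulus end, decaying as a double
#' exponential), clathrin accumulation regions (positive-going, onset
#' within one frame of the stimulus, decaying over 10-20 s) and clathrin
#' loss regions (negative-going). Event centres are placed at radial
#' distances from a randomly chosen ribbon drawn from
#' `N(radial_mean, radial_sd)`, emulating fusion peaking ~0.4 um and
#' clathrin turnover ~0.8 um from the ribbon centre.
#'
#' Event amplitudes are expressed as multiples (`amp_sd`) of the
#' baseline temporal noise SD inside the footprint. The camera model is
#' `ADU = round(gain * Poisson(rate) + N(0, read_noise_sd) + offset)`,
#' clipped at zero, so written movies are integer-valued.
#'
#' @param shape `c(frames, H, W)`.
#' @param frame_interval Seconds per frame (default 0.1).
#' @param pixel_size Micrometres per pixel (default 0.1).
#' @param stimulus_onset_frame Stimulus onset frame (1-based).
#' @param stimulus_duration Stimulus duration in seconds (0.5 or 3 in
#'   the emulated protocol; any positive value accepted).
#' @param n_ribbons,ribbon_amplitude,ribbon_sigma Number, peak
#'   brightness (counts) and Gaussian radius (um) of the static ribbon
#'   puncta.
#' @param n_fusion,n_accumulation,n_loss Planted event counts by class.
#' @param fusion_radial_mean,fusion_radial_sd Radial placement of
#'   fusion events around their ribbon (um).
#' @param clathrin_radial_mean,clathrin_radial_sd Radial placement of
#'   accumulation and loss events (um).
#' @param amp_sd Event peak amplitude as a multiple of the footprint
#'   baseline noise SD.
#' @param fusion_rise_s Fusion rise time: the peak sits this long after
#'   stimulus end (s).
#' @param fusion_frac_fast,fusion_tau_fast,fusion_tau_slow Fusion decay:
#'   double-exponential fast fraction and time constants (s).
#' @param accum_rise_s,accum_tau_decay Accumulation rise span and decay
#'   time constant (s).
#' @param psf_sigma Spatial Gaussian radius of planted events (um); the
#'   evanescent-field axial decay is collapsed into the amplitude.
#' @param baseline,background Footprint and off-footprint mean count
#'   levels.
#' @param gain,offset,read_noise_sd Camera model parameters.
#' @param min_separation Minimum distance between planted event centres
#'   (um).
#' @param seed Integer seed.
#' @return A `movie_sim_config` list.
#' @export
movie_sim_config <- function(shape = c(300L, 80L, 80L),
                             frame_interval = 0.1, pixel_size = 0.1,
                             stimulus_onset_frame = 21L,
                             stimulus_duration = 0.5,
                             n_ribbons = 2L, ribbon_amplitude = 400,
                             ribbon_sigma = 0.2,
                             n_fusion = 5L, n_accumulation = 5L, n_loss = 3L,
                             fusion_radial_mean = 0.4, fusion_radial_sd = 0.08,
                             clathrin_radial_mean = 0.8, clathrin_radial_sd = 0.08,
                             amp_sd = 8,
                             fusion_rise_s = 0.3,
                             fusion_frac_fast = 0.3, fusion_tau_fast = 2.5,
                             fusion_tau_slow = 13.0,
                             accum_rise_s = 1.0, accum_tau_decay = 15,
                             psf_sigma = 0.15,
                             baseline = 150, background = 20,
                             gain = 1, offset = 0, read_noise_sd = 3,
                             min_separation = 0.35,
                             seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 2L))
  total_s <- shape[1] * frame_interval
  stim_end_s <- (stimulus_onset_frame - 1L) * frame_interval + stimulus_duration
  if (total_s < stim_end_s + 20)
    stop("movie must cover the stimulus plus at least 20 s of recovery")
  if (stimulus_onset_frame < 6L)
    stop("need at least 5 pre-stimulus baseline frames")
  cfg <- as.list(environment())
  structure(cfg, class = "movie_sim_config")
}

# Per-class event time profile (unit peak) over frame times t (s),
# relative to stimulus onset/end.
event_profile <- function(type, t, onset_s, stim_dur, cfg) {
  p <- numeric(length(t))
  if (type == "fusion") {
    t_peak <- onset_s + stim_dur + cfg$fusion_rise_s
    rise <- t >= onset_s & t < t_peak
    p[rise] <- (t[rise] - onset_s) / (t_peak - onset_s)
    dec <- t >= t_peak
    td <- t[dec] - t_peak
    p[dec] <- cfg$fusion_frac_fast * exp(-td / cfg$fusion_tau_fast) +
      (1 - cfg$fusion_frac_fast) * exp(-td / cfg$fusion_tau_slow)
  } else {  # accumulation and loss share the rise/decay skeleton
    t_peak <- onset_s + stim_dur + cfg$accum_rise_s
    rise <- t >= onset_s & t < t_peak
    p[rise] <- (t[rise] - onset_s) / (t_peak - onset_s)
    dec <- t >= t_peak
    p[dec] <- exp(-(t[dec] - t_peak) / cfg$accum_tau_decay)
    if (type == "loss") p <- -p
  }
  p
}

#' Simulate a TIRF movie with planted events and known ground truth
#'
#' Builds `baseline + footprint + ribbons + Gaussian events`, applies the
#' Poisson + Gaussian-read camera model, and returns the movie together
#' with a noiseless ribbon-channel image and a ground-truth table listing
#' every planted event (class, centre, true ribbon distance, kinetic
#' parameters).
#'
#' @param config A [movie_sim_config()].
#' @return List with elements `movie` ([tirf_movie()]), `ribbon_image`
#'   (H x W matrix, the ribbon channel), `truth` (data frame, one row
#'   per planted event) and `ribbons` (data frame of true ribbon
#'   centres in um).
#' @export
simulate_tirf_movie <- function(config) {
  stopifnot(inherits(config, "movie_sim_config"))
  cfg <- config
  fr <- cfg$shape[1]; H <- cfg$shape[2]; W <- cfg$shape[3]
  px <- cfg$pixel_size
  with_seed(cfg$seed, {
    # footprint: centred ellipse covering ~70% of the field
    rc <- (seq_len(H) - 0.5); cc <- (seq_len(W) - 0.5)
    ey <- H / 2; ex <- W / 2
    ry <- 0.42 * H; rx <- 0.42 * W
    foot <- outer(rc, cc, function(r, c) ((r - ey) / ry)^2 + ((c - ex) / rx)^2 <= 1)
    base_img <- ifelse(foot, cfg$baseline, cfg$background)

    # ribbons: evenly spread inside an inner ellipse, jittered
    margin <- max(cfg$clathrin_radial_mean + 4 * cfg$clathrin_radial_sd,
                  cfg$fusion_radial_mean + 4 * cfg$fusion_radial_sd) + 3 * cfg$psf_sigma
    ang <- seq(0, 2 * pi, length.out = cfg$n_ribbons + 1L)[seq_len(cfg$n_ribbons)] +
      stats::runif(1, 0, 2 * pi)
    rpos <- 0.55 * (min(ry, rx) - margin / px)  # stay clear of the margin
    if (rpos <= 0)
      stop("ribbon placement outside the usable footprint; enlarge the field ",
           "or reduce the radial event distances")
    rib_y <- (ey + rpos * sin(ang)) * px
    rib_x <- (ex + rpos * cos(ang)) * px
    inside_foot <- function(x, y) {
      r <- y / px; c <- x / px
      ((r - ey) / (ry - margin / px))^2 + ((c - ex) / (rx - margin / px))^2 <= 1
    }
    if (!all(inside_foot(rib_x, rib_y)))
      stop("ribbon placement outside the usable footprint; enlarge the field ",
           "or reduce the radial event distances")
    ribbons <- data.frame(id = seq_len(cfg$n_ribbons), x = rib_x, y = rib_y)

    # plant events around ribbons with minimum mutual separation
    classes <- c(rep("fusion", cfg$n_fusion),
                 rep("accumulation", cfg$n_accumulation),
                 rep("loss", cfg$n_loss))
    ex_ <- numeric(0); ey_ <- numeric(0); erib <- integer(0); edist <- numeric(0)
    for (cl in classes) {
      mu <- if (cl == "fusion") cfg$fusion_radial_mean else cfg$clathrin_radial_mean
      sd_ <- if (cl == "fusion") cfg$fusion_radial_sd else cfg$clathrin_radial_sd
      ok <- FALSE
      for (try in 1:400) {
        k <- sample.int(cfg$n_ribbons, 1L)
        d <- abs(stats::rnorm(1, mu, sd_))
        th <- stats::runif(1, 0, 2 * pi)
        x <- ribbons$x[k] + d * cos(th); y <- ribbons$y[k] + d * sin(th)
        if (!inside_foot(x, y)) next
        if (length(ex_) && min(sqrt((ex_ - x)^2 + (ey_ - y)^2)) < cfg$min_separation) next
        ex_ <- c(ex_, x); ey_ <- c(ey_, y)
        erib <- c(erib, k); edist <- c(edist, d)
        ok <- TRUE
        break
      }
      if (!ok) stop("could not place all events inside the footprint; ",
                    "reduce event count or min_separation")
    }
    # true distance is to the *nearest* ribbon, which may differ from the parent
    true_dist <- vapply(seq_along(ex_), function(i)
      min(sqrt((ribbons$x - ex_[i])^2 + (ribbons$y - ey_[i])^2)), numeric(1))

    noise_sd <- sqrt(cfg$gain^2 * cfg$baseline + cfg$read_noise_sd^2)
    amp <- cfg$amp_sd * noise_sd

    onset_s <- (cfg$stimulus_onset_frame - 1L) * cfg$frame_interval
    t <- (seq_len(fr) - 1L) * cfg$frame_interval

    # signal stack: baseline + ribbons (static) + events (space x time)
    stack <- array(rep(base_img, each = fr), dim = c(fr, H, W))
    add_spot <- function(stack, x, y, sigma, amp_t) {
      # amp_t: per-frame amplitude vector; Gaussian spot at (x, y) um
      rad <- ceiling(4 * sigma / px)
      r0 <- max(1L, round(y / px + 0.5) - rad); r1 <- min(H, round(y / px + 0.5) + rad)
      c0 <- max(1L, round(x / px + 0.5) - rad); c1 <- min(W, round(x / px + 0.5) + rad)
      rs <- (r0:r1 - 0.5) * px; cs <- (c0:c1 - 0.5) * px
      spot <- exp(-(outer((rs - y)^2, (cs - x)^2, "+")) / (2 * sigma^2))
      stack[, r0:r1, c0:c1] <- stack[, r0:r1, c0:c1] +
        outer(amp_t, spot)
      stack
    }
    rib_img <- matrix(0, H, W)
    for (k in seq_len(cfg$n_ribbons)) {
      rad <- ceiling(4 * cfg$ribbon_sigma / px)
      rs <- (seq_len(H) - 0.5) * px; cs <- (seq_len(W) - 0.5) * px
      rib_img <- rib_img + cfg$ribbon_amplitude *
        exp(-(outer((rs - ribbons$y[k])^2, (cs - ribbons$x[k])^2, "+")) /
              (2 * cfg$ribbon_sigma^2))
    }
    profiles <- matrix(0, fr, length(classes))
    for (i in seq_along(classes)) {
      prof <- event_profile(classes[i], t, onset_s, cfg$stimulus_duration, cfg)
      profiles[, i] <- prof
      stack <- add_spot(stack, ex_[i], ey_[i], cfg$psf_sigma, amp * prof)
    }
    stack <- pmax(stack, 0)

    # camera model
    counts <- array(stats::rpois(length(stack), lambda = stack), dim = dim(stack))
    adu <- cfg$gain * counts + cfg$offset +
      array(stats::rnorm(length(stack), 0, cfg$read_noise_sd), dim = dim(stack))
    adu <- pmax(round(adu), 0)

    n_ev <- length(classes)
    truth <- data.frame(
      event = seq_len(n_ev),
      class = classes,
      response_sign = ifelse(classes == "loss", -1, 1),
      x = ex_, y = ey_,
      ribbon = erib,
      ribbon_distance = true_dist,
      amplitude_counts = rep(amp, n_ev),
      amplitude_dff = rep(amp / cfg$baseline, n_ev),
      onset_s = rep(onset_s, n_ev),
      peak_s = onset_s + cfg$stimulus_duration +
        ifelse(classes == "fusion", cfg$fusion_rise_s, cfg$accum_rise_s),
      frac_fast = ifelse(classes == "fusion", cfg$fusion_frac_fast, NA_real_),
      tau_fast = ifelse(classes == "fusion", cfg$fusion_tau_fast, NA_real_),
      tau_slow = ifelse(classes == "fusion", cfg$fusion_tau_slow,
                        cfg$accum_tau_decay),
      seed = rep(cfg$seed, n_ev))

    list(movie = tirf_movie(adu, cfg$frame_interval, px,
                            cfg$stimulus_onset_frame, cfg$stimulus_duration),
         ribbon_image = rib_img + matrix(stats::rnorm(H * W, 0, cfg$read_noise_sd), H, W),
         truth = truth,
         ribbons = ribbons)
  })
}

#' Match detected events to planted ground truth
#'
#' One-to-one greedy matching by centre distance; used to score
#' detection precision/recall and class assignment on simulated movies.
#'
#' @param events Data frame of detected events with columns `x`, `y`
#'   (um) and `class`.
#' @param truth Ground-truth table from [simulate_tirf_movie()].
#' @param max_dist Maximum matching distance in um.
#' @return List with `pairs` (data frame: detected index, truth index,
#'   distance, class_match), `precision`, `recall` and
#'   `class_exact` (all matched classes agree, with planted fusion
#'   counted as positive-going accumulation).
#' @export
match_events <- function(events, truth, max_dist = 0.3) {
  nd <- nrow(events); nt <- nrow(truth)
  if (nd == 0L || nt == 0L)
    return(list(pairs = data.frame(), precision = if (nd) 0 else NA_real_,
                recall = if (nt) 0 else NA_real_, class_exact = NA))
  dmat <- outer(seq_len(nd), seq_len(nt), function(i, j)
    sqrt((events$x[i] - truth$x[j])^2 + (events$y[i] - truth$y[j])^2))
  pairs <- data.frame()
  used_d <- logical(nd); used_t <- logical(nt)
  repeat {
    dmat2 <- dmat
    dmat2[used_d, ] <- Inf; dmat2[, used_t] <- Inf
    i <- which.min(dmat2)
    if (!length(i) || dmat2[i] > max_dist) break
    di <- (i - 1L) %% nd + 1L; ti <- (i - 1L) %/% nd + 1L
    truth_cls <- if (truth$class[ti] == "loss") "loss" else "accumulation"
    pairs <- rbind(pairs, data.frame(
      detected = di, truth = ti, distance = dmat2[i],
      class_match = events$class[di] == truth_cls))
    used_d[di] <- TRUE; used_t[ti] <- TRUE
    if (all(used_d) || all(used_t)) break
  }
  list(pairs = pairs,
       precision = nrow(pairs) / nd,
       recall = nrow(pairs) / nt,
       class_exact = if (nrow(pairs)) all(pairs$class_match) else NA)
}
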