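#' Species and beam specifications for the FCS simulator
#'
#' `fcs_species()` describes one diffusing labelled species: its expected
#' occupancy of the detection volume, diffusion coefficient, molecular
#' brightness per channel, and optional triplet blinking. A species with
#' both brightnesses positive is double-labelled and contributes to the
#' cross-correlation. `fcs_beam()` describes the confocal detection
#' volume as a 3D Gaussian with lateral and axial 1/e^2 radii.
#'
#' The expected molecule number is defined over the effective volume
#' `V_eff = pi^(3/2) r0^2 z`, so the simulated autocorrelation amplitude
#' is `g(0+) = 1/n_mean` (gamma = 1 convention).
#'
#' @param n_mean Expected molecules in the detection volume (> 0).
#' @param D Diffusion coefficient in um^2/s (> 0).
#' @param brightness_g,brightness_r Mean counts per molecule per bin at
#'   the beam centre in the green/red channel (>= 0; at least one
#'   positive).
#' @param triplet_fraction Triplet (dark-state) fraction in `[0, 1)`.
#' @param triplet_tau Triplet correlation time in s (> 0 when the
#'   fraction is positive).
#' @return A `fcs_species` / `fcs_beam` list.
#' @export
fcs_species <- function(n_mean, D, brightness_g = 1, brightness_r = 0,
                        triplet_fraction = 0, triplet_tau = NULL) {
  if (n_mean <= 0) stop("'n_mean' must be positive")
  if (D <= 0) stop("'D' must be positive")
  if (brightness_g < 0 || brightness_r < 0) stop("brightness must be >= 0")
  if (brightness_g == 0 && brightness_r == 0)
    stop("at least one channel brightness must be positive")
  if (triplet_fraction < 0 || triplet_fraction >= 1)
    stop("'triplet_fraction' must be in [0, 1)")
  if (triplet_fraction > 0 && (is.null(triplet_tau) || triplet_tau <= 0))
    stop("'triplet_tau' must be positive when 'triplet_fraction' > 0")
  structure(list(n_mean = n_mean, D = D, brightness_g = brightness_g,
                 brightness_r = brightness_r,
                 triplet_fraction = triplet_fraction,
                 triplet_tau = if (is.null(triplet_tau)) 0 else triplet_tau),
            class = "fcs_species")
}

#' @rdname fcs_species
#' @param r0 Lateral 1/e^2 radius in um (> 0).
#' @param z Axial 1/e^2 radius in um (> 0; typically several times `r0`).
#' @export
fcs_beam <- function(r0 = 0.25, z = 5 * r0) {
  if (r0 <= 0 || z <= 0) stop("beam radii must be positive")
  if (z < r0) warning("axial radius below lateral radius is unusual for a confocal volume")
  structure(list(r0 = r0, z = z), class = "fcs_beam")
}

#' Configuration for a Brownian-dynamics FCS/FCCS simulation
#'
#' Bundles species, beam geometry, simulation box, binning and noise
#' settings. Defaults follow desk-scale practice: the box extends three
#' beam radii per axis (particles re-enter periodically, preserving
#' constant concentration) and the bin width is chosen per run well
#' below the fastest residence time rather than at instrument-level
#' sub-microsecond binning.
#'
#' @param species A single `fcs_species` or a list of them.
#' @param beam An `fcs_beam`.
#' @param dt Bin width in seconds (> 0).
#' @param duration Trace duration in seconds (> 0). A warning is issued
#'   below 100x the slowest expected residence time, where correlation
#'   estimates become unreliable.
#' @param box_half_widths Half-widths of the simulation box in um,
#'   `c(x, y, z)`; default three beam radii per axis (the minimum
#'   accepted).
#' @param crosstalk_q Fraction of the green molecular signal leaking
#'   into the red channel, `[0, 1)`.
#' @param background Per-channel background rate `c(green, red)` in
#'   counts/bin.
#' @param seed Integer seed; same seed, same trace.
#' @param allow_empty Permit a configuration with no species and zero
#'   background (all-zero traces), which is otherwise rejected.
#' @return An `fcs_sim_config` list.
#' @export
fcs_sim_config <- function(species, beam = fcs_beam(), dt, duration,
                           box_half_widths = NULL, crosstalk_q = 0,
                           background = c(0, 0), seed = 1L,
                           allow_empty = FALSE) {
  if (inherits(species, "fcs_species")) species <- list(species)
  stopifnot(all(vapply(species, inherits, logical(1), "fcs_species")))
  if (!inherits(beam, "fcs_beam")) stop("'beam' must be an fcs_beam")
  if (!is.numeric(dt) || dt <= 0) stop("'dt' must be positive")
  if (!is.numeric(duration) || duration <= 0) stop("'duration' must be positive")
  if (length(background) == 1L) background <- rep(background, 2L)
  if (crosstalk_q < 0 || crosstalk_q >= 1) stop("'crosstalk_q' must be in [0, 1)")
  if (length(species) == 0L && all(background == 0) && !allow_empty)
    stop("no species and zero background gives a degenerate all-zero trace; ",
         "set allow_empty = TRUE if intended")
  min_half <- 3 * c(beam$r0, beam$r0, beam$z)
  if (is.null(box_half_widths)) box_half_widths <- min_half
  if (length(box_half_widths) != 3L || any(box_half_widths < min_half - 1e-12))
    stop("box half-widths must be >= 3x the beam radii per axis")
  if (length(species)) {
    tau_slow <- max(vapply(species, function(s) beam$r0^2 / (4 * s$D), numeric(1)))
    if (duration < 100 * tau_slow)
      warning(sprintf(paste0("duration %.3g s is below 100x the slowest residence ",
                             "time (%.3g s); correlation estimates may be noisy"),
                      duration, tau_slow))
  }
  structure(list(species = species, beam = beam, dt = dt, duration = duration,
                 box_half_widths = box_half_widths, crosstalk_q = crosstalk_q,
                 background = background, seed = as.integer(seed),
                 allow_empty = allow_empty),
            class = "fcs_sim_config")
}

#' Simulate dual-channel photon traces from diffusing species
#'
#' Brownian-dynamics simulation of labelled molecules in a periodic box
#' observed through a 3D Gaussian confocal detection volume. Each step
#' displaces every particle by Gaussian increments of variance `2 D dt`
#' per axis; the per-bin molecular rate is the brightness-weighted sum of
#' detection weights `exp(-2(x^2+y^2)/r0^2 - 2 z^2/z0^2)`; counts are
#' Poisson around that rate plus background, and the red channel receives
#' a fraction `crosstalk_q` of the green molecular rate. Triplet blinking
#' is a per-molecule two-state telegraph process.
#'
#' @param config An [fcs_sim_config()].
#' @return A list with `green` and `red` [intensity_trace()]s and
#'   `truth`, a data frame of per-species ground truth (box particle
#'   counts, realised occupancies, all generator parameters and the
#'   seed).
#' @examples
#' cfg <- fcs_sim_config(fcs_species(n_mean = 5, D = 5),
#'                       beam = fcs_beam(r0 = 0.2, z = 1),
#'                       dt = 1e-4, duration = 2, seed = 1)
#' sim <- simulate_fcs_trace(cfg)
#' @export
simulate_fcs_trace <- function(config) {
  stopifnot(inherits(config, "fcs_sim_config"))
  nbins <- floor(config$duration / config$dt)
  hw <- config$box_half_widths
  beam <- config$beam
  v_eff <- pi^1.5 * beam$r0^2 * beam$z
  v_box <- prod(2 * hw)
  sp <- config$species
  ns <- length(sp)
  get <- function(f) vapply(sp, function(s) s[[f]], numeric(1))
  n_box <- if (ns) pmax(1L, as.integer(round(get("n_mean") * v_box / v_eff)))
           else integer(0)
  raw <- sim_fcs_cpp(n_box = n_box,
                     D = if (ns) get("D") else numeric(0),
                     eps_g = if (ns) get("brightness_g") else numeric(0),
                     eps_r = if (ns) get("brightness_r") else numeric(0),
                     trip_T = if (ns) get("triplet_fraction") else numeric(0),
                     trip_tau = if (ns) get("triplet_tau") else numeric(0),
                     r0 = beam$r0, zr = beam$z,
                     hx = hw[1], hy = hw[2], hz = hw[3],
                     dt = config$dt, nbins = nbins,
                     crosstalk_q = config$crosstalk_q,
                     bg_g = config$background[1], bg_r = config$background[2],
                     seed = config$seed)
  truth <- data.frame(
    species = seq_len(ns),
    n_mean = if (ns) get("n_mean") else numeric(0),
    n_mean_realised = if (ns) n_box * v_eff / v_box else numeric(0),
    n_box = as.numeric(n_box),
    D = if (ns) get("D") else numeric(0),
    brightness_g = if (ns) get("brightness_g") else numeric(0),
    brightness_r = if (ns) get("brightness_r") else numeric(0),
    triplet_fraction = if (ns) get("triplet_fraction") else numeric(0),
    triplet_tau = if (ns) get("triplet_tau") else numeric(0),
    tau_d = if (ns) beam$r0^2 / (4 * get("D")) else numeric(0),
    r0 = rep(beam$r0, ns), z = rep(beam$z, ns),
    dt = rep(config$dt, ns), duration = rep(config$duration, ns),
    crosstalk_q = rep(config$crosstalk_q, ns),
    seed = rep(config$seed, ns))
  list(green = intensity_trace(raw$green, config$dt, "green"),
       red = intensity_trace(raw$red, config$dt, "red"),
       truth = truth)
}
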