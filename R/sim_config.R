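#' Simulation configuration for the synthetic cohort
#'
#' Collects the ground-truth parameters of the synthetic movie generator:
#' cell-cycle duration distribution, sampling scheme, cohort layout,
#' cell-cycle programs for protein level and nuclear localization, and
#' measurement noise.  Defaults reproduce the study conditions the analysis
#' assumes: cycles of 21 +/- 4 h, 24 h movies sampled every 20 min, 4
#' fields of view per protein with 10-20 tracked cells each.
#'
#' @param mean_cycle_h mean cell-cycle duration in hours.
#' @param sd_cycle_h cell-to-cell standard deviation of cycle duration (h).
#' @param sampling_interval_min time between frames, minutes.
#' @param movie_duration_h movie length in hours.
#' @param n_fov number of fields of view (independent movies) per protein.
#' @param cells_per_fov integer range (length-2) or single count of tracked
#'   cells per field of view.
#' @param level_amplitude amplitude of the cell-cycle modulation of protein
#'   level, as a fraction of baseline; 0 means non-cycling.
#' @param level_peak_tau cycle fraction in `[0,1]` at which the level
#'   modulation peaks.
#' @param level_width full width of the raised-cosine modulation bump, in
#'   cycle fractions.
#' @param nr_baseline baseline nuclear ratio (nuclear / total fluorescence)
#'   in `[0,1]` for programs `"shuttling"`, `"diffuse"` and `"punctate"`.
#' @param nr_amplitude amplitude of the cell-cycle modulation of the
#'   nuclear ratio (same raised-cosine bump and peak as the level program);
#'   the modulated ratio is clipped to `[0,1]`.
#' @param nr_noise_sd additive Gaussian measurement noise on the observed
#'   nuclear ratio.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   measurement noise on total fluorescence.
#' @param localization_program one of `"diffuse"`, `"nuclear"`,
#'   `"cytoplasmic"`, `"shuttling"`, `"punctate"`.  `"nuclear"` pins the
#'   nuclear ratio at 1 and `"cytoplasmic"` at 0.05; the others use
#'   `nr_baseline`/`nr_amplitude`.
#' @param censor_fraction fraction of cells whose traces are truncated at a
#'   uniform random frame, emulating cells that leave the field of view.
#' @param min_cycle_h lower truncation bound for sampled cycle durations.
#' @param seed integer seed consumed by [simulate_cohort()]; `NULL` leaves
#'   the RNG state alone.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(level_amplitude = 0.5, noise_cv = 0)
#' cfg$mean_cycle_h
#' @export
sim_config <- function(mean_cycle_h = 21, sd_cycle_h = 4,
                       sampling_interval_min = 20, movie_duration_h = 24,
                       n_fov = 4, cells_per_fov = c(10, 20),
                       level_amplitude = 0, level_peak_tau = 0.5,
                       level_width = 0.3,
                       nr_baseline = 0.5, nr_amplitude = 0,
                       nr_noise_sd = 0.02, noise_cv = 0.05,
                       localization_program = c("diffuse", "nuclear",
                                                "cytoplasmic", "shuttling",
                                                "punctate"),
                       censor_fraction = 0.2, min_cycle_h = 8,
                       seed = NULL) {
  localization_program <- match.arg(localization_program)
  if (mean_cycle_h <= 0 || sampling_interval_min <= 0 || movie_duration_h <= 0)
    stop("mean_cycle_h, sampling_interval_min and movie_duration_h must be positive")
  if (sd_cycle_h < 0) stop("sd_cycle_h must be non-negative")
  if (level_amplitude < 0) stop("level_amplitude must be non-negative")
  if (level_peak_tau < 0 || level_peak_tau > 1)
    stop("level_peak_tau must lie in [0,1]")
  if (nr_baseline < 0 || nr_baseline > 1) stop("nr_baseline must lie in [0,1]")
  if (nr_amplitude < 0) stop("nr_amplitude must be non-negative")
  if (noise_cv < 0 || nr_noise_sd < 0) stop("noise levels must be non-negative")
  if (censor_fraction < 0 || censor_fraction > 1)
    stop("censor_fraction must lie in [0,1]")
  if (length(cells_per_fov) == 1L) cells_per_fov <- rep(cells_per_fov, 2L)
  if (length(cells_per_fov) != 2L || any(cells_per_fov < 1) ||
      cells_per_fov[1] > cells_per_fov[2])
    stop("cells_per_fov must be a count or an increasing length-2 range")
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(
    mean_cycle_h = mean_cycle_h, sd_cycle_h = sd_cycle_h,
    sampling_interval_min = sampling_interval_min,
    movie_duration_h = movie_duration_h,
    n_fov = as.integer(n_fov), cells_per_fov = as.integer(cells_per_fov),
    level_amplitude = level_amplitude, level_peak_tau = level_peak_tau,
    level_width = level_width,
    nr_baseline = nr_baseline, nr_amplitude = nr_amplitude,
    nr_noise_sd = nr_noise_sd, noise_cv = noise_cv,
    localization_program = localization_program,
    censor_fraction = censor_fraction, min_cycle_h = min_cycle_h,
    seed = seed
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  cycle: %g +/- %g h (min %g); movie %g h @ %g min\n",
              x$mean_cycle_h, x$sd_cycle_h, x$min_cycle_h,
              x$movie_duration_h, x$sampling_interval_min))
  cat(sprintf("  layout: %d FOV x %d-%d cells; censoring %g\n",
              x$n_fov, x$cells_per_fov[1], x$cells_per_fov[2],
              x$censor_fraction))
  cat(sprintf("  level: amplitude %g, peak tau %g, width %g; noise CV %g\n",
              x$level_amplitude, x$level_peak_tau, x$level_width, x$noise_cv))
  cat(sprintf("  localization: %s (NR %g +/- %g, noise sd %g)\n",
              x$localization_program, x$nr_baseline, x$nr_amplitude,
              x$nr_noise_sd))
  invisible(x)
}

#' Raised-cosine cell-cycle modulation bump
#'
#' Smooth, periodic, unimodal bump on the fractional cell-cycle axis:
#' `cycle_bump(0) = 1`, zero outside a window of the given full width
#' around 0 (circular distance), period 1.  Used to modulate protein level
#' and nuclear ratio in the generator.
#'
#' @param x phase offset(s), cycle fractions (wrapped to the circle).
#' @param width full width of the bump in cycle fractions.
#' @return numeric vector of bump values in `[0,1]`.
#' @examples
#' cycle_bump(c(0, 0.1, 0.3), width = 0.3)
#' @export
cycle_bump <- function(x, width = 0.3) {
  d <- abs(((x + 0.5) %% 1) - 0.5)  # circular distance to phase 0
  ifelse(d < width / 2, 0.5 * (1 + cos(2 * pi * d / width)), 0)
}

# nuclear-ratio program: baseline/amplitude presets per localization program
nr_program <- function(tau, config) {
  base <- switch(config$localization_program,
                 nuclear = 1, cytoplasmic = 0.05, config$nr_baseline)
  amp <- switch(config$localization_program,
                nuclear = 0, cytoplasmic = 0, config$nr_amplitude)
  pmin(1, pmax(0, base + amp * cycle_bump(tau - config$level_peak_tau,
                                          config$level_width)))
}
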