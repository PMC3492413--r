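#' Simulate one tracked cell's fluorescence trace
#'
#' Generates the time series of total and nuclear fluorescence, cell area
#' and eccentricity for a single tracked cell, together with its true
#' division times.  Between divisions total fluorescence grows
#' exponentially (doubling over one cycle), modulated by a raised-cosine
#' cell-cycle program of the configured amplitude; at each division the
#' level drops by exactly a factor of two (before noise).  Multiplicative
#' lognormal noise with the configured CV is applied per frame.  The
#' nuclear ratio follows the localization program, with additive Gaussian
#' measurement noise, and cells round up (eccentricity drops) on the frame
#' preceding a division.
#'
#' Frame values are built recursively (per-frame growth factor
#' `2^(dt/T)`, division step an exact halving of the previous frame's
#' noise-free value) so that the twofold drop across the sampled division
#' frames is exact, as the downstream division detector assumes.
#'
#' @param config a [sim_config()] object.  The function consumes the
#'   current RNG state; seed handling belongs to the caller (see
#'   [simulate_cohort()]).
#' @param baseline baseline fluorescence scale of this cell (arbitrary
#'   units).
#' @param censor logical; apply the configured random truncation.
#' @return list with elements
#'   \describe{
#'     \item{observations}{data.frame with columns `time_min`,
#'       `total_fluor`, `nuclear_fluor`, `area_px`, `eccentricity`, and the
#'       hidden ground-truth column `true_tau`.}
#'     \item{division_times_min}{true division times (minutes), strictly
#'       inside the observed window.}
#'     \item{cycle_durations_h}{sampled per-cycle durations.}
#'   }
#' @examples
#' set.seed(1)
#' tr <- simulate_cell_trace(sim_config(noise_cv = 0))
#' head(tr$observations)
#' tr$division_times_min
#' @export
simulate_cell_trace <- function(config, baseline = 1000, censor = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  dt <- config$sampling_interval_min
  total_min <- config$movie_duration_h * 60
  if (total_min < dt)
    stop("movie shorter than one sampling interval: empty trace")
  times <- seq(0, total_min, by = dt)
  n <- length(times)

  # enough cycles to cover the movie with margin
  n_cycles <- ceiling(total_min / 60 / config$min_cycle_h) + 2L
  durations <- rnorm(n_cycles, config$mean_cycle_h, config$sd_cycle_h)
  while (any(durations < config$min_cycle_h))
    durations[durations < config$min_cycle_h] <-
      rnorm(sum(durations < config$min_cycle_h),
            config$mean_cycle_h, config$sd_cycle_h)

  tau0 <- runif(1)                       # phase at movie start
  div <- cumsum(c((1 - tau0) * durations[1] * 60, durations[-1] * 60))

  # per-frame cycle index and fractional phase
  cyc <- findInterval(times, div) + 1L   # frames at a division start cycle+1
  prev_div <- c(-tau0 * durations[1] * 60, div)[cyc]
  tau <- (times - prev_div) / (durations[cyc] * 60)

  amp <- config$level_amplitude
  modv <- 1 + amp * cycle_bump(tau - config$level_peak_tau, config$level_width)
  shape <- 2^tau * modv                  # within-cycle target shape

  # recursive build: exact /2 at divisions, shape-consistent growth between
  value <- numeric(n)
  value[1] <- baseline * shape[1]
  for (k in seq_len(n - 1L)) {
    value[k + 1L] <- if (cyc[k + 1L] > cyc[k])
      value[k] / 2 else value[k] * shape[k + 1L] / shape[k]
  }

  if (config$noise_cv > 0) {
    sig <- sqrt(log(1 + config$noise_cv^2))
    value <- value * rlnorm(n, meanlog = -sig^2 / 2, sdlog = sig)
  }

  nr <- nr_program(tau, config)
  if (config$nr_noise_sd > 0)
    nr <- pmin(1, pmax(0, nr + rnorm(n, 0, config$nr_noise_sd)))

  area0 <- rnorm(1, 900, 120)
  area <- round(pmax(200, area0 * 2^tau * (1 + rnorm(n, 0, 0.03))))
  ecc <- pmin(0.95, pmax(0.5, rnorm(n, 0.82, 0.05)))
  pre_div <- which(diff(cyc) > 0L)       # frame right before each division
  if (length(pre_div)) ecc[pre_div] <- runif(length(pre_div), 0.1, 0.3)

  keep <- n
  if (censor && config$censor_fraction > 0 && runif(1) < config$censor_fraction)
    keep <- sample(seq(min(6L, n), n), 1L)

  obs <- data.frame(time_min = times[seq_len(keep)],
                    total_fluor = value[seq_len(keep)],
                    nuclear_fluor = nr[seq_len(keep)] * value[seq_len(keep)],
                    area_px = area[seq_len(keep)],
                    eccentricity = ecc[seq_len(keep)],
                    true_tau = tau[seq_len(keep)])
  window_end <- times[keep]
  list(observations = obs,
       division_times_min = div[div > 0 & div < window_end],
       cycle_durations_h = durations)
}

#' Simulate a cohort of proteins with known ground truth
#'
#' Wraps [simulate_cell_trace()] into the cohort layout of the study: each
#' protein gets `n_fov` fields of view with a random number of tracked
#' cells each.  The first `round(fraction_cycling * n_proteins)` proteins
#' receive the configured cell-cycle amplitudes and localization program
#' (cycling), each with a peak phase drawn uniformly in `[0.15, 0.85]`;
#' the rest get amplitude zero (non-cycling).
#'
#' @param config a [sim_config()]; `config$seed`, when non-`NULL`, seeds
#'   the RNG so identical configs reproduce identical cohorts.
#' @param n_proteins number of proteins.
#' @param fraction_cycling fraction (deterministically rounded) of proteins
#'   that carry the cycling program.
#' @return list with
#'   \describe{
#'     \item{traces}{data.frame: `protein_id`, `fov_id`, `cell_id`,
#'       `time_min`, `total_fluor`, `nuclear_fluor`, `area_px`,
#'       `eccentricity` (one row per cell per frame).}
#'     \item{divisions}{data.frame of true division times:
#'       `protein_id`, `fov_id`, `cell_id`, `division_time_min`.}
#'     \item{truth}{per-protein ground truth: `protein_id`,
#'       `is_level_cycling`, `is_nr_cycling`, `is_texture_cycling`,
#'       `peak_tau`.}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' coh <- simulate_cohort(sim_config(seed = 1, level_amplitude = 0.5),
#'                        n_proteins = 4, fraction_cycling = 0.5)
#' table(coh$truth$is_level_cycling)
#' @export
simulate_cohort <- function(config, n_proteins, fraction_cycling = 0) {
  stopifnot(inherits(config, "sim_config"))
  if (fraction_cycling < 0 || fraction_cycling > 1)
    stop("fraction_cycling must lie in [0,1]")
  if (!is.null(config$seed)) set.seed(config$seed)
  n_proteins <- as.integer(n_proteins)
  empty <- list(
    traces = data.frame(protein_id = character(), fov_id = integer(),
                        cell_id = integer(), time_min = numeric(),
                        total_fluor = numeric(), nuclear_fluor = numeric(),
                        area_px = numeric(), eccentricity = numeric()),
    divisions = data.frame(protein_id = character(), fov_id = integer(),
                           cell_id = integer(), division_time_min = numeric()),
    truth = data.frame(protein_id = character(), is_level_cycling = logical(),
                       is_nr_cycling = logical(),
                       is_texture_cycling = logical(), peak_tau = numeric()),
    config = config)
  if (n_proteins == 0L) return(empty)

  n_cyc <- round(fraction_cycling * n_proteins)
  ids <- sprintf("P%03d", seq_len(n_proteins))
  traces <- vector("list", 0L)
  divs <- vector("list", 0L)
  truth <- vector("list", n_proteins)

  for (p in seq_len(n_proteins)) {
    cycling <- p <= n_cyc
    pcfg <- config
    if (!cycling) {
      pcfg$level_amplitude <- 0
      pcfg$nr_amplitude <- 0
    } else {
      pcfg$level_peak_tau <- runif(1, 0.15, 0.85)
    }
    prot_base <- rlnorm(1, log(1000), 0.4)
    for (f in seq_len(config$n_fov)) {
      n_cells <- sample(seq(config$cells_per_fov[1], config$cells_per_fov[2]), 1L)
      for (cl in seq_len(n_cells)) {
        cell_base <- prot_base * rlnorm(1, 0, 0.2)
        tr <- simulate_cell_trace(pcfg, baseline = cell_base)
        o <- tr$observations
        traces[[length(traces) + 1L]] <- data.frame(
          protein_id = ids[p], fov_id = f, cell_id = cl,
          time_min = o$time_min, total_fluor = o$total_fluor,
          nuclear_fluor = o$nuclear_fluor, area_px = o$area_px,
          eccentricity = o$eccentricity)
        if (length(tr$division_times_min))
          divs[[length(divs) + 1L]] <- data.frame(
            protein_id = ids[p], fov_id = f, cell_id = cl,
            division_time_min = tr$division_times_min)
      }
    }
    truth[[p]] <- data.frame(
      protein_id = ids[p],
      is_level_cycling = cycling && pcfg$level_amplitude > 0,
      is_nr_cycling = cycling && pcfg$nr_amplitude > 0 &&
        pcfg$localization_program %in% c("shuttling", "diffuse", "punctate"),
      is_texture_cycling = cycling && pcfg$localization_program == "punctate",
      peak_tau = pcfg$level_peak_tau)
  }
  list(traces = do.call(rbind, traces),
       divisions = if (length(divs)) do.call(rbind, divs) else empty$divisions,
       truth = do.call(rbind, truth),
       config = config)
}
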