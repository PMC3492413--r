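#' Place observation times on the fractional cell-cycle axis
#'
#' Each observation is mapped to a cycle fraction `tau` in `[0,1]`
#' anchored at the cell's detected divisions: times after a division get
#' `tau = (t - t_div) / T_cc`, times before a division get
#' `tau = 1 - (t_div - t) / T_cc`, and times bracketed by two divisions
#' are rescaled exactly, `tau = (t - t_div1) / (t_div2 - t_div1)` (the
#' exact rescaling takes precedence when both anchors exist).  Points
#' falling outside `[0,1]` are dropped.
#'
#' @param times_min observation times, minutes.
#' @param division_times_min the cell's division times, minutes (sorted).
#' @param T_cc_h assumed average cell-cycle duration, hours (the study's
#'   21 h default; conclusions are insensitive over roughly 18-23 h).
#' @return data.frame with columns `time_min`, `tau` for the retained
#'   observations.  A cell with no detected division is excluded from
#'   synchronization: a zero-row frame is returned with a message.
#' @examples
#' assign_tau(c(480, 690), division_times_min = 480)
#' @export
assign_tau <- function(times_min, division_times_min, T_cc_h = 21) {
  if (length(division_times_min) == 0) {
    message("cell has no detected division; excluded from synchronization")
    return(data.frame(time_min = numeric(0), tau = numeric(0)))
  }
  d <- sort(division_times_min)
  Tm <- T_cc_h * 60
  tau <- vapply(times_min, function(t) {
    prev <- d[d <= t]
    nxt <- d[d > t]
    if (length(prev) && length(nxt))
      (t - prev[length(prev)]) / (nxt[1] - prev[length(prev)])
    else if (length(prev))
      (t - prev[length(prev)]) / Tm
    else
      1 - (nxt[1] - t) / Tm
  }, numeric(1))
  keep <- tau >= 0 & tau <= 1
  data.frame(time_min = times_min[keep], tau = tau[keep])
}

#' Normalize a cell's fluorescence trace at its mitosis anchor
#'
#' Divides the whole trace by the fluorescence at the cell's mitosis
#' anchor so profiles become dimensionless: near 1 just before a division,
#' about 0.5 just after, returning to about 1 at the next division.  The
#' anchor is the value at the last frame before the first division; cells
#' observed only after their division use twice the value at the first
#' post-division frame (via the twofold-drop identity) instead.
#'
#' @param values fluorescence values, time-ordered.
#' @param times_min matching observation times.
#' @param division_times_min the cell's division times.
#' @return normalized numeric vector, or `NULL` (with a warning) when the
#'   anchor value is not positive, in which case the cell is excluded.
#' @examples
#' normalize_at_mitosis(c(100, 200, 100, 150), c(0, 20, 40, 60),
#'                      division_times_min = 30)
#' @export
normalize_at_mitosis <- function(values, times_min, division_times_min) {
  if (length(division_times_min) == 0)
    stop("normalization requires at least one division anchor")
  d1 <- min(division_times_min)
  pre <- which(times_min < d1)
  anchor <- if (length(pre)) values[pre[length(pre)]] else {
    post <- which(times_min >= d1)
    if (!length(post)) stop("no observations around the division anchor")
    2 * values[post[1]]
  }
  if (!is.finite(anchor) || anchor <= 0) {
    warning("non-positive mitosis anchor; cell excluded")
    return(NULL)
  }
  values / anchor
}

#' Bin synchronized points into a cell-cycle profile
#'
#' Averages the synchronized values of one protein (all cells, all fields
#' of view) in `n_bins` equal bins of the cycle fraction.  Bins left empty
#' are filled by linear interpolation from their neighbors and flagged.
#'
#' @param tau cycle fractions in `[0,1]`.
#' @param value matching values.
#' @param n_bins number of bins partitioning `[0,1]`.
#' @return data.frame of class `cycle_profile`: `bin_center`, `mean`,
#'   `std`, `n`, `interpolated`.
#' @examples
#' build_profile(runif(100), rnorm(100, 1, 0.1), n_bins = 10)
#' @export
build_profile <- function(tau, value, n_bins = 50) {
  if (length(tau) == 0) stop("no synchronized points to bin")
  stopifnot(length(tau) == length(value))
  bin <- pmin(pmax(ceiling(tau * n_bins), 1L), n_bins)
  centers <- (seq_len(n_bins) - 0.5) / n_bins
  m <- tapply(value, factor(bin, levels = seq_len(n_bins)), mean)
  s <- tapply(value, factor(bin, levels = seq_len(n_bins)), sd)
  n <- tapply(value, factor(bin, levels = seq_len(n_bins)), length)
  n[is.na(n)] <- 0L
  out <- data.frame(bin_center = centers, mean = as.numeric(m),
                    std = as.numeric(s), n = as.integer(n),
                    interpolated = n == 0L)
  if (any(out$interpolated)) {
    pop <- which(!out$interpolated)
    if (!length(pop)) stop("no synchronized points to bin")
    filled <- if (length(pop) == 1L) rep(out$mean[pop], n_bins) else
      approx(centers[pop], out$mean[pop], xout = centers, rule = 2)$y
    out$mean[out$interpolated] <- filled[out$interpolated]
  }
  class(out) <- c("cycle_profile", "data.frame")
  out
}

#' Build per-protein cell-cycle profiles for a cohort
#'
#' For every protein in a trace table: detects (or takes) division times
#' per cell, assigns cycle fractions, applies the quantity-appropriate
#' per-cell normalization (mitosis anchoring for `level` and
#' `median_pixel`; none for the already scale-free `nuclear_ratio` and
#' texture features), pools points over cells and fields of view, and bins
#' them into a profile.
#'
#' @param traces trace table: `protein_id`, `fov_id`, `cell_id`,
#'   `time_min`, `total_fluor`, `nuclear_fluor`, plus `median_pixel` or
#'   texture columns when those quantities are requested.
#' @param quantity one of `"level"`, `"median_pixel"`, `"nuclear_ratio"`,
#'   `"contrast"`, `"energy"`, `"homogeneity"`, `"correlation"`.
#' @param divisions either `NULL` (divisions are detected per cell with
#'   [detect_divisions()]) or a data.frame `protein_id`, `fov_id`,
#'   `cell_id`, `division_time_min`.
#' @param T_cc_h assumed cycle duration, hours.
#' @param n_bins profile bins.
#' @param ... passed to [detect_divisions()].
#' @return named list of `cycle_profile` data.frames, one per protein.
#' @export
cohort_profiles <- function(traces, quantity = "level", divisions = NULL,
                            T_cc_h = 21, n_bins = 50, ...) {
  qcol <- switch(quantity,
                 level = "total_fluor",
                 median_pixel = "median_pixel",
                 nuclear_ratio = NULL,
                 contrast = "contrast", energy = "energy",
                 homogeneity = "homogeneity", correlation = "correlation",
                 stop("unknown quantity: ", quantity))
  if (!is.null(qcol) && !qcol %in% names(traces))
    stop("trace table lacks required column: ", qcol)
  normalize <- quantity %in% c("level", "median_pixel")

  profiles <- list()
  for (pid in unique(traces$protein_id)) {
    tp <- traces[traces$protein_id == pid, , drop = FALSE]
    taus <- list(); vals <- list()
    for (key in unique(paste(tp$fov_id, tp$cell_id))) {
      tc <- tp[paste(tp$fov_id, tp$cell_id) == key, , drop = FALSE]
      tc <- tc[order(tc$time_min), , drop = FALSE]
      dv <- if (is.null(divisions)) {
        detect_divisions(tc, ...)
      } else {
        di <- divisions[divisions$protein_id == pid &
                        paste(divisions$fov_id, divisions$cell_id) == key, ]
        di$division_time_min
      }
      if (length(dv) == 0) next
      st <- suppressMessages(assign_tau(tc$time_min, dv, T_cc_h))
      if (nrow(st) == 0) next
      v <- if (quantity == "nuclear_ratio") {
        ok <- tc$total_fluor > 0
        ifelse(ok, tc$nuclear_fluor / pmax(tc$total_fluor, .Machine$double.eps),
               NA_real_)
      } else if (normalize) {
        normalize_at_mitosis(tc[[qcol]], tc$time_min, dv)
      } else {
        tc[[qcol]]
      }
      if (is.null(v)) next
      idx <- match(st$time_min, tc$time_min)
      taus[[length(taus) + 1L]] <- st$tau
      vals[[length(vals) + 1L]] <- v[idx]
    }
    if (!length(taus)) next
    tau <- unlist(taus); val <- unlist(vals)
    ok <- is.finite(val)
    if (!any(ok)) next
    profiles[[pid]] <- build_profile(tau[ok], val[ok], n_bins)
  }
  profiles
}
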