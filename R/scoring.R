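#' Cohort-average cell-cycle profile
#'
#' Bin-wise unweighted mean over all proteins' profiles of one quantity.
#' The average level profile represents the common growth behavior (the
#' drop to one half at division followed by accumulation back to one) and
#' serves as the baseline that individual proteins are compared against.
#'
#' @param profiles list of `cycle_profile` data.frames on identical bins.
#' @return a `cycle_profile` data.frame; `std` is the across-protein
#'   standard deviation and `n` the number of proteins.
#' @export
average_profile <- function(profiles) {
  if (length(profiles) < 2) stop("need at least 2 profiles to average")
  centers <- profiles[[1]]$bin_center
  for (p in profiles)
    if (!isTRUE(all.equal(p$bin_center, centers)))
      stop("profiles are on mismatched bin grids")
  mat <- vapply(profiles, function(p) p$mean, numeric(length(centers)))
  out <- data.frame(bin_center = centers,
                    mean = rowMeans(mat),
                    std = apply(mat, 1, sd),
                    n = length(profiles),
                    interpolated = FALSE)
  class(out) <- c("cycle_profile", "data.frame")
  out
}

#' Normalize a protein's profile by the cohort-average profile
#'
#' Bin-wise ratio of a protein's profile to the cohort average.  A protein
#' with no cell-cycle program of its own yields a normalized profile equal
#' to one in every bin, up to noise; deviations from one are what the
#' scores quantify.
#'
#' @param profile a `cycle_profile` for one protein.
#' @param avg_profile the [average_profile()] on the same bins.
#' @return data.frame with `bin_center`, `value` (the ratio).
#' @export
normalize_by_average <- function(profile, avg_profile) {
  if (!isTRUE(all.equal(profile$bin_center, avg_profile$bin_center)))
    stop("profiles are on mismatched bin grids")
  if (any(avg_profile$mean <= 0))
    stop("average profile has non-positive bins; cannot normalize")
  data.frame(bin_center = profile$bin_center,
             value = profile$mean / avg_profile$mean)
}

#' Deviation scores of a normalized profile
#'
#' Measures how far a normalized profile strays from the constant vector
#' of ones: `s90` is the 90th percentile of the absolute deviations
#' (tolerant of outlier bins), `rms` the root-mean-square deviation.
#' Percentiles use linear interpolation between order statistics
#' (`stats::quantile` type 7); the bootstrap calibration uses the same
#' convention, so classifications are convention-consistent.
#'
#' @param values normalized profile values (at least 10 bins).
#' @return list with `s90` and `rms`, both non-negative.
#' @examples
#' deviation_scores(rep(1.5, 20))
#' @export
deviation_scores <- function(values) {
  if (length(values) < 10)
    stop("deviation scores need at least 10 bins")
  d <- abs(values - 1)
  list(s90 = quantile(d, 0.9, names = FALSE, type = 7),
       rms = sqrt(mean(d^2)))
}

#' Nuclear-ratio variability score
#'
#' Standard deviation of the per-bin mean nuclear ratio over the retained
#' part of the cycle.  Bins in the first and last `exclusion_fraction` of
#' the cycle are excluded, because nucleus and cytoplasm cannot be told
#' apart while the cell rounds up and the nuclear envelope is down around
#' mitosis.  The population standard deviation (divisor `n`) is used, so
#' a profile stepping between two values of equal weight `a` apart scores
#' exactly `a/2`.
#'
#' @param nr_profile `cycle_profile` of the nuclear ratio.
#' @param exclusion_fraction fraction of the cycle trimmed at each end.
#' @return non-negative scalar score.
#' @export
nr_std_score <- function(nr_profile, exclusion_fraction = 0.1) {
  keep <- nr_profile$bin_center > exclusion_fraction &
          nr_profile$bin_center < 1 - exclusion_fraction
  if (!any(keep)) stop("all bins excluded; shrink exclusion_fraction")
  x <- nr_profile$mean[keep]
  sqrt(mean((x - mean(x))^2))
}

#' Bootstrap significance threshold from replicate movies
#'
#' Estimates the experimental-noise distribution of a score from many
#' replicate movies of a single (non-cycling) protein: draws `n_sets`
#' random sets of `set_size` movies (without replacement within a set),
#' averages each set into a profile, scores it against the average over
#' all replicates, and returns the `confidence` quantile of the `n_sets`
#' scores.  A protein whose score exceeds this threshold deviates more
#' than replicate noise at the chosen confidence.
#'
#' @param movie_profiles list of `cycle_profile` data.frames, one per
#'   replicate movie, on common bins.
#' @param n_sets number of bootstrap sets.
#' @param set_size movies per set (the per-protein field-of-view count).
#' @param confidence quantile of the score distribution returned.
#' @param score_fn scoring function `function(set_means, all_means)`
#'   returning a scalar.  The default scores the set profile normalized by
#'   the all-replicates average with [deviation_scores()]'s `s90`; for
#'   nuclear-ratio profiles use [nr_score_fn()].
#' @return list with `threshold` and the `n_sets` bootstrap `scores`.
#' @export
bootstrap_threshold <- function(movie_profiles, n_sets = 100, set_size = 4,
                                confidence = 0.99, score_fn = NULL) {
  n <- length(movie_profiles)
  if (n < set_size)
    stop("need at least ", set_size, " replicate movies")
  centers <- movie_profiles[[1]]$bin_center
  mat <- vapply(movie_profiles, function(p) p$mean, numeric(length(centers)))
  all_means <- rowMeans(mat)
  if (is.null(score_fn))
    score_fn <- function(set_means, all_means)
      deviation_scores(set_means / all_means)$s90
  scores <- vapply(seq_len(n_sets), function(i) {
    idx <- sample.int(n, set_size)
    score_fn(rowMeans(mat[, idx, drop = FALSE]), all_means)
  }, numeric(1))
  list(threshold = quantile(scores, confidence, names = FALSE, type = 7),
       scores = scores)
}

#' Score function for nuclear-ratio bootstrap calibration
#'
#' Scores a bootstrap set's nuclear-ratio profile by the mid-cycle
#' standard deviation (no normalization by the cohort average, since
#' nuclear and cytoplasmic proteins sit at different baselines).
#'
#' @param n_bins bins of the profiles being scored.
#' @param exclusion_fraction end trim, see [nr_std_score()].
#' @return a `function(set_means, all_means)` for [bootstrap_threshold()].
#' @export
nr_score_fn <- function(n_bins = 50, exclusion_fraction = 0.1) {
  centers <- (seq_len(n_bins) - 0.5) / n_bins
  function(set_means, all_means) {
    prof <- data.frame(bin_center = centers, mean = set_means)
    nr_std_score(prof, exclusion_fraction)
  }
}

#' Default classification thresholds
#'
#' The bootstrap-calibrated cutoffs of the original study, excluding
#' experimental noise at 99% confidence: level score 0.3, nuclear-ratio
#' std 0.08, and texture-score cutoffs 0.4 (contrast), 0.15 (energy),
#' 0.02 (homogeneity), 0.05 (correlation).  These constants are derived
#' from that study's replicate movies; for synthetic or re-measured
#' cohorts, recalibrate with [bootstrap_threshold()].
#'
#' @return named list: `level`, `median_pixel`, `nr`, `contrast`,
#'   `energy`, `homogeneity`, `correlation`, `confidence`.
#' @export
default_thresholds <- function() {
  list(level = 0.3, median_pixel = 0.3, nr = 0.08,
       contrast = 0.4, energy = 0.15, homogeneity = 0.02,
       correlation = 0.05, confidence = 0.99)
}

#' Classify proteins as cell-cycle dependent
#'
#' Applies strict-inequality thresholds to the per-protein scores: a
#' protein is level-cycling when `s90_level > level` threshold,
#' NR-cycling when `nr_std > nr` threshold, texture-cycling when any of
#' the four texture scores exceeds its threshold, and cycling overall
#' when any flag is set.  Scores absent (`NA`) for a protein leave that
#' flag `NA` and are excluded from the disjunction.
#'
#' @param scores data.frame with `protein_id` and any of `s90_level`,
#'   `s90_median_pixel`, `nr_std`, `s90_contrast`, `s90_energy`,
#'   `s90_homogeneity`, `s90_correlation`.
#' @param thresholds see [default_thresholds()].
#' @return data.frame: `protein_id`, `level_cycling`, `nr_cycling`,
#'   `texture_cycling`, `any_cycling`.
#' @export
classify_cohort <- function(scores, thresholds = default_thresholds()) {
  gt <- function(col, thr)
    if (col %in% names(scores)) scores[[col]] > thr else
      rep(NA, nrow(scores))
  level <- gt("s90_level", thresholds$level)
  nr <- gt("nr_std", thresholds$nr)
  tex <- cbind(gt("s90_contrast", thresholds$contrast),
               gt("s90_energy", thresholds$energy),
               gt("s90_homogeneity", thresholds$homogeneity),
               gt("s90_correlation", thresholds$correlation))
  texture <- apply(tex, 1, function(r)
    if (all(is.na(r))) NA else any(r, na.rm = TRUE))
  flags <- cbind(level, nr, texture)
  any_cycling <- apply(flags, 1, function(r)
    if (all(is.na(r))) NA else any(r, na.rm = TRUE))
  data.frame(protein_id = scores$protein_id,
             level_cycling = level, nr_cycling = nr,
             texture_cycling = texture, any_cycling = any_cycling)
}

#' Summarize a cohort classification
#'
#' Counts and fractions of proteins flagged cycling per category and in
#' the level/localization intersection; optionally a confusion summary
#' against simulation ground truth.
#'
#' @param records output of [classify_cohort()].
#' @param truth optional ground-truth data.frame with `protein_id` and
#'   `is_level_cycling`, `is_nr_cycling`, `is_texture_cycling`.
#' @return list with `counts`, `fractions` (named vectors) and, with
#'   `truth`, `recall` and `specificity` of the `any_cycling` call plus
#'   the `confusion` table.
#' @export
summarize_classification <- function(records, truth = NULL) {
  if (nrow(records) == 0) stop("no classification records")
  cnt <- function(x) sum(x, na.rm = TRUE)
  localization <- apply(cbind(records$nr_cycling, records$texture_cycling),
                        1, function(r)
                          if (all(is.na(r))) NA else any(r, na.rm = TRUE))
  counts <- c(n = nrow(records),
              level = cnt(records$level_cycling),
              nuclear_ratio = cnt(records$nr_cycling),
              texture = cnt(records$texture_cycling),
              localization = cnt(localization),
              level_and_localization = cnt(records$level_cycling & localization),
              any = cnt(records$any_cycling))
  out <- list(counts = counts,
              fractions = counts[-1] / counts[["n"]])
  if (!is.null(truth)) {
    m <- merge(records, truth, by = "protein_id")
    truth_any <- m$is_level_cycling | m$is_nr_cycling | m$is_texture_cycling
    pred <- m$any_cycling %in% TRUE
    out$confusion <- table(truth = truth_any, predicted = pred)
    out$recall <- if (any(truth_any)) sum(pred & truth_any) / sum(truth_any)
                  else NA_real_
    out$specificity <- if (any(!truth_any))
      sum(!pred & !truth_any) / sum(!truth_any) else NA_real_
  }
  out
}
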