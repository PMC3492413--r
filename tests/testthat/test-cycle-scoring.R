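make_profile <- function(means, n_bins = length(means)) {
  structure(data.frame(bin_center = (seq_len(n_bins) - 0.5) / n_bins,
                       mean = means, std = 0, n = 1, interpolated = FALSE),
            class = c("cycle_profile", "data.frame"))
}

test_that("the cohort average is the bin-wise unweighted mean", {
  p <- make_profile(rep(1.3, 20))
  expect_equal(average_profile(list(p, p))$mean, p$mean)
  q <- average_profile(list(make_profile(rep(0.8, 20)),
                            make_profile(rep(1.2, 20))))
  expect_equal(q$mean, rep(1, 20))
  expect_error(average_profile(list(p, make_profile(rep(1, 10)))),
               "mismatched bin grids")
})

test_that("normalization by the average gives bin-wise ratios", {
  avg <- make_profile(seq(0.5, 1, length.out = 20))
  expect_equal(normalize_by_average(avg, avg)$value, rep(1, 20))
  dbl <- make_profile(2 * avg$mean)
  expect_equal(normalize_by_average(dbl, avg)$value, rep(2, 20))
  zero <- make_profile(c(0, rep(1, 19)))
  expect_error(normalize_by_average(avg, zero), "non-positive")
})

test_that("the bin-wise mean of all normalized profiles is exactly one", {
  set.seed(501)
  profiles <- lapply(1:15, function(i)
    make_profile(runif(50, 0.5, 1.5)))
  avg <- average_profile(profiles)
  normed <- vapply(profiles, function(p)
    normalize_by_average(p, avg)$value, numeric(50))
  expect_equal(rowMeans(normed), rep(1, 50), tolerance = 1e-12)
})

test_that("deviation scores measure distance from the unit profile", {
  z <- deviation_scores(rep(1, 20))
  expect_equal(z$s90, 0)
  expect_equal(z$rms, 0)
  h <- deviation_scores(rep(1.5, 20))
  expect_equal(h$s90, 0.5)
  expect_equal(h$rms, 0.5)
  expect_error(deviation_scores(rep(1, 5)), "at least 10 bins")
})

test_that("the percentile convention matches a sort-based oracle", {
  # 100 bins, 10 at deviation 0.6: oracle gives the interpolated value
  v <- c(rep(1, 90), rep(1.6, 10))
  want <- oracle_percentile(abs(v - 1), 0.9)
  expect_equal(want, 0.06)  # frozen from the oracle
  expect_equal(deviation_scores(v)$s90, want, tolerance = 1e-12)
  set.seed(502)
  for (i in 1:20) {
    x <- 1 + rnorm(sample(10:80, 1))
    expect_equal(deviation_scores(x)$s90,
                 oracle_percentile(abs(x - 1), 0.9), tolerance = 1e-12)
  }
})

test_that("scores dominate neither each other nor the max deviation", {
  set.seed(503)
  for (i in 1:20) {
    v <- 1 + rnorm(50, 0, 0.3)
    sc <- deviation_scores(v)
    expect_gte(sc$s90, 0)
    expect_gte(sc$rms, 0)
    expect_lte(sc$s90, max(abs(v - 1)) + 1e-12)
    expect_lte(sc$rms, max(abs(v - 1)) + 1e-12)
  }
})

test_that("the NR std score trims the cycle ends and uses population sd", {
  flat <- make_profile(rep(0.4, 50))
  expect_equal(nr_std_score(flat), 0)
  # step 0.2 -> 0.8 at tau = 0.5 over the retained 40 bins: sd exactly 0.3
  step <- make_profile(c(rep(0.2, 25), rep(0.8, 25)))
  expect_equal(nr_std_score(step), 0.3)
  # deviations confined to the trimmed ends are invisible
  ends <- make_profile(c(rep(0.9, 5), rep(0.4, 40), rep(0.9, 5)))
  expect_equal(nr_std_score(ends), 0)
  expect_error(nr_std_score(flat, exclusion_fraction = 0.5), "all bins excluded")
})

shuttling_nr_score <- function(nr_amplitude, seed) {
  set.seed(seed)
  cfg <- sim_config(nr_amplitude = nr_amplitude,
                    localization_program = "shuttling",
                    level_peak_tau = 0.5)
  taus <- c(); vals <- c()
  for (cell in 1:48) {
    tr <- simulate_cell_trace(cfg)
    dv <- tr$division_times_min
    if (!length(dv)) next
    st <- suppressMessages(assign_tau(tr$observations$time_min, dv))
    idx <- match(st$time_min, tr$observations$time_min)
    taus <- c(taus, st$tau)
    vals <- c(vals, tr$observations$nuclear_fluor[idx] /
                tr$observations$total_fluor[idx])
  }
  nr_std_score(build_profile(taus, vals))
}

test_that("a strong mid-cycle shuttle crosses the NR threshold and the
           score grows with the shuttling amplitude", {
  # phase smearing from the 21 +/- 4 h cycle dispersion attenuates the
  # profile, so detectability sets in at moderate amplitude
  scores <- vapply(c(0, 0.2, 0.4), shuttling_nr_score, numeric(1), seed = 504)
  expect_true(all(diff(scores) > 0))
  expect_lt(scores[1], 0.08)
  expect_gt(scores[3], 0.08)
})

test_that("bootstrap thresholds are reproducible and zero for identical movies", {
  p <- make_profile(rep(1, 50))
  bt <- bootstrap_threshold(rep(list(p), 10), n_sets = 20)
  expect_equal(bt$threshold, 0)
  expect_true(all(bt$scores == 0))
  profs <- lapply(1:10, function(i) make_profile(runif(50, 0.9, 1.1)))
  set.seed(505); a <- bootstrap_threshold(profs)
  set.seed(505); b <- bootstrap_threshold(profs)
  expect_identical(a, b)
  expect_error(bootstrap_threshold(profs[1:3], set_size = 4),
               "at least 4 replicate movies")
})

test_that("the 99% threshold excludes 99% of noise-only replicate scores", {
  coh <- simulate_cohort(sim_config(seed = 506, noise_cv = 0.05, n_fov = 48),
                         1, 0)
  profs <- movie_profiles(coh$traces)
  set.seed(507)
  bt <- bootstrap_threshold(profs, n_sets = 100, set_size = 4,
                            confidence = 0.99)
  expect_equal(mean(bt$scores <= bt$threshold), 0.99)
})

test_that("classification applies strict thresholds per category", {
  sc <- data.frame(protein_id = c("a", "b", "c", "d"),
                   s90_level = c(0, 0.31, 0.3, NA),
                   nr_std = c(0, 0.05, 0.08, 0.2),
                   s90_contrast = c(0, 0, 0.41, NA),
                   s90_energy = c(0, 0, 0, NA))
  cl <- classify_cohort(sc)
  expect_equal(cl$level_cycling, c(FALSE, TRUE, FALSE, NA))
  expect_equal(cl$nr_cycling, c(FALSE, FALSE, FALSE, TRUE))  # 0.08 is boundary
  expect_equal(cl$texture_cycling, c(FALSE, FALSE, TRUE, NA))
  expect_equal(cl$any_cycling, c(FALSE, TRUE, TRUE, TRUE))
})

test_that("summaries count categories and compare against ground truth", {
  rec <- data.frame(protein_id = sprintf("p%d", 1:10),
                    level_cycling = c(rep(TRUE, 4), rep(FALSE, 6)),
                    nr_cycling = c(TRUE, rep(FALSE, 9)),
                    texture_cycling = rep(FALSE, 10),
                    any_cycling = c(rep(TRUE, 4), rep(FALSE, 6)))
  s <- summarize_classification(rec)
  expect_equal(unname(s$counts[["any"]]), 4)
  expect_equal(unname(s$fractions[["any"]]), 0.4)
  expect_equal(unname(s$counts[["level_and_localization"]]), 1)
  truth <- data.frame(protein_id = sprintf("p%d", 1:10),
                      is_level_cycling = c(rep(TRUE, 5), rep(FALSE, 5)),
                      is_nr_cycling = FALSE, is_texture_cycling = FALSE)
  st <- summarize_classification(rec, truth)
  expect_equal(st$recall, 4 / 5)
  expect_equal(st$specificity, 1)
})

test_that("detection power is monotone in the simulated level amplitude", {
  amps <- c(0, 0.3, 0.8)
  scores <- vapply(seq_along(amps), function(k) {
    cfg <- noise_free_config(seed = 510 + k, level_amplitude = amps[k],
                             n_fov = 2, cells_per_fov = c(8, 10))
    # one candidate protein against a non-cycling baseline cohort
    coh <- simulate_cohort(cfg, 6, 1 / 6)
    res <- score_cohort(coh$traces, divisions = coh$divisions,
                        quantities = "level")
    res$scores$s90_level[res$scores$protein_id == "P001"]
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
})
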