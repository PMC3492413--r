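test_that("segmentation recovers a rendered single cell and its nucleus", {
  img <- render_cell_image(cell_state(1e4), program = "diffuse")
  seg <- segment_cells(img$red)
  expect_equal(max(seg$cell_mask), 1)
  expect_gte(jaccard(seg$cell_mask > 0, img$cell_mask), 0.8)
  expect_gte(jaccard(seg$nucleus_mask > 0, img$nucleus_mask), 0.8)
  # nucleus label equals the enclosing cell label
  expect_true(all(seg$cell_mask[seg$nucleus_mask > 0] ==
                    seg$nucleus_mask[seg$nucleus_mask > 0]))
})

test_that("an all-zero image yields empty masks with a warning", {
  expect_warning(seg <- segment_cells(matrix(0, 32, 32)), "empty foreground")
  expect_equal(max(seg$cell_mask), 0)
  expect_equal(max(seg$nucleus_mask), 0)
})

test_that("two disjoint rendered cells give two labels", {
  a <- render_cell_image(cell_state(1e4, center = c(20, 32),
                                    cell_axes = c(12, 10),
                                    nucleus_axes = c(6, 5),
                                    nucleus_center = c(20, 32)),
                         size = c(96, 64), program = "diffuse")
  b <- render_cell_image(cell_state(1e4, center = c(70, 32),
                                    cell_axes = c(12, 10),
                                    nucleus_axes = c(6, 5),
                                    nucleus_center = c(70, 32)),
                         size = c(96, 64), program = "diffuse")
  seg <- segment_cells(a$red + b$red - 0.02)  # single shared background
  expect_equal(max(seg$cell_mask), 2)
})

test_that("measure_cell sums background-subtracted intensities", {
  cell <- matrix(FALSE, 16, 16); cell[4:12, 4:12] <- TRUE
  nuc <- matrix(FALSE, 16, 16); nuc[6:10, 6:10] <- TRUE
  img <- matrix(3, 16, 16)
  obs <- measure_cell(img, cell, nuc)
  expect_equal(obs$total_fluor, 3 * sum(cell))
  expect_equal(obs$nuclear_fluor, 3 * sum(nuc))
  expect_equal(obs$area_px, sum(cell))
  # background equal to the image value zeroes the measurement
  expect_equal(measure_cell(img, cell, nuc, background = 3)$total_fluor, 0)
  # nucleus must sit inside the cell
  bad <- matrix(FALSE, 16, 16); bad[1:3, 1:3] <- TRUE
  expect_error(measure_cell(img, cell, bad), "not a subset")
})

test_that("measure_cell is additive over a partition of the cell mask", {
  set.seed(201)
  img <- matrix(runif(256, 0, 10), 16, 16)
  cell <- matrix(FALSE, 16, 16); cell[3:14, 3:14] <- TRUE
  left <- cell; left[, 9:16] <- FALSE
  right <- cell & !left
  none <- matrix(FALSE, 16, 16)
  whole <- measure_cell(img, cell, none)$total_fluor
  parts <- measure_cell(img, left, none)$total_fluor +
    measure_cell(img, right, none)$total_fluor
  expect_equal(parts, whole, tolerance = 1e-12)
})

test_that("segmentation plus measurement recovers the rendered total within 5%", {
  img <- render_cell_image(cell_state(2e4, nr = 0.4), program = "shuttling")
  seg <- segment_cells(img$red)
  obs <- measure_cell(img$yellow, seg$cell_mask > 0, seg$nucleus_mask > 0)
  expect_equal(obs$total_fluor, 2e4, tolerance = 0.05)
})

test_that("division detection calls the twofold drop at the right time", {
  set.seed(202)
  cfg <- noise_free_config()
  checked <- 0L
  for (i in 1:20) {
    tr <- simulate_cell_trace(cfg)
    calls <- detect_divisions(tr$observations)
    expect_equal(length(calls), length(tr$division_times_min))
    if (length(calls)) {
      expect_true(all(abs(calls - tr$division_times_min) <=
                        cfg$sampling_interval_min))
      checked <- checked + length(calls)
    }
  }
  expect_gt(checked, 5)
})

test_that("monotone traces yield no division calls", {
  tr <- data.frame(time_min = seq(0, 200, 20),
                   total_fluor = seq(100, 200, length.out = 11))
  expect_length(detect_divisions(tr), 0)
})

test_that("a 44 h movie with two divisions yields two ordered calls", {
  set.seed(203)
  cfg <- noise_free_config(movie_duration_h = 44)
  found <- FALSE
  for (i in 1:20) {
    tr <- simulate_cell_trace(cfg)
    if (length(tr$division_times_min) == 2) {
      calls <- detect_divisions(tr$observations)
      expect_length(calls, 2)
      expect_true(calls[1] < calls[2])
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("division recall and precision are 1 on a noise-free cohort", {
  coh <- simulate_cohort(noise_free_config(seed = 204, cells_per_fov = c(4, 6),
                                           n_fov = 2), 2, 0)
  tp <- 0L; fp <- 0L; fn <- 0L
  for (key in unique(paste(coh$traces$protein_id, coh$traces$fov_id,
                           coh$traces$cell_id))) {
    sel <- paste(coh$traces$protein_id, coh$traces$fov_id,
                 coh$traces$cell_id) == key
    tc <- coh$traces[sel, ]
    dsel <- paste(coh$divisions$protein_id, coh$divisions$fov_id,
                  coh$divisions$cell_id) == key
    true_d <- coh$divisions$division_time_min[dsel]
    calls <- detect_divisions(tc[order(tc$time_min), ])
    matched <- outer(calls, true_d, function(a, b) abs(a - b) <= 20)
    tp <- tp + sum(apply(matched, 2, any))
    fn <- fn + sum(!apply(matched, 2, any))
    fp <- fp + sum(!apply(matched, 1, any))
  }
  expect_gt(tp, 0)
  expect_equal(fn, 0L)
  expect_equal(fp, 0L)
})

test_that("morphology gating requires a rounded pre-division frame", {
  tr <- data.frame(time_min = c(0, 20, 40), total_fluor = c(100, 110, 55),
                   eccentricity = c(0.8, 0.8, 0.8))
  expect_length(detect_divisions(tr, use_morphology = TRUE), 0)
  tr$eccentricity[2] <- 0.2
  expect_length(detect_divisions(tr, use_morphology = TRUE), 1)
})

test_that("non-positive fluorescence frames are skipped with a warning", {
  tr <- data.frame(time_min = c(0, 20, 40, 60),
                   total_fluor = c(100, -5, 110, 55))
  expect_warning(calls <- detect_divisions(tr), "skipped")
  expect_length(calls, 1)
})
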