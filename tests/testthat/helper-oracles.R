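# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# GLCM + Haralick by explicit pair enumeration over every pixel.
oracle_glcm_features <- function(level_image, n_levels,
                                 offset = c(0, 1), symmetric = TRUE) {
  counts <- matrix(0, n_levels, n_levels)
  nr <- nrow(level_image); nc <- ncol(level_image)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    r2 <- r + offset[1]; c2 <- cc + offset[2]
    if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
    a <- level_image[r, cc]; b <- level_image[r2, c2]
    if (is.na(a) || is.na(b)) next
    counts[a + 1, b + 1] <- counts[a + 1, b + 1] + 1
    if (symmetric) counts[b + 1, a + 1] <- counts[b + 1, a + 1] + 1
  }
  p <- counts / sum(counts)
  contrast <- 0; energy <- 0; homogeneity <- 0
  for (i in seq_len(n_levels)) for (j in seq_len(n_levels)) {
    contrast <- contrast + p[i, j] * (i - j)^2
    energy <- energy + p[i, j]^2
    homogeneity <- homogeneity + p[i, j] / (1 + abs(i - j))
  }
  mi <- 0; mj <- 0
  for (i in seq_len(n_levels)) for (j in seq_len(n_levels)) {
    mi <- mi + (i - 1) * p[i, j]; mj <- mj + (j - 1) * p[i, j]
  }
  vi <- 0; vj <- 0; cov <- 0
  for (i in seq_len(n_levels)) for (j in seq_len(n_levels)) {
    vi <- vi + (i - 1 - mi)^2 * p[i, j]
    vj <- vj + (j - 1 - mj)^2 * p[i, j]
    cov <- cov + (i - 1 - mi) * (j - 1 - mj) * p[i, j]
  }
  correlation <- if (vi == 0 || vj == 0) 0 else cov / sqrt(vi * vj)
  c(contrast = contrast, energy = energy, homogeneity = homogeneity,
    correlation = correlation)
}

# Percentile by explicit sorting and linear interpolation between order
# statistics: h = (n-1)p + 1, x = x_(floor(h)) + (h - floor(h)) * diff.
oracle_percentile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(s[n])
  s[lo] + (h - lo) * (s[lo + 1] - s[lo])
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# noise-free configuration shared by deterministic tests
noise_free_config <- function(...) {
  sim_config(noise_cv = 0, nr_noise_sd = 0, censor_fraction = 0, ...)
}

# per-movie level profiles for one protein's trace table
movie_profiles <- function(traces, fovs = sort(unique(traces$fov_id)),
                           quantity = "level", ...) {
  lapply(fovs, function(f)
    cohort_profiles(traces[traces$fov_id == f, , drop = FALSE],
                    quantity = quantity, ...)[[1]])
}
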