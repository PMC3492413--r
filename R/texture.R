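#' Quantize image intensities into gray levels within a mask
#'
#' Linearly bins the intensities inside the mask into `n_levels` levels
#' (0-based) between the masked minimum and maximum.  Constant regions map
#' entirely to level 0.  Pixels outside the mask are marked invalid (`NA`)
#' and are excluded from co-occurrence counting.
#'
#' @param image 2-D numeric matrix.
#' @param mask logical matrix; `NULL` uses the full image.
#' @param n_levels number of gray levels, at least 2.
#' @return integer matrix of levels in `0 .. n_levels-1` with `NA` outside
#'   the mask; carries attribute `n_levels`.
#' @examples
#' q <- quantize_levels(matrix(1:16, 4), n_levels = 4)
#' table(q)
#' @export
quantize_levels <- function(image, mask = NULL, n_levels = 8) {
  image <- as.matrix(image)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  mask <- as.matrix(mask) > 0
  if (!any(mask)) stop("mask is empty")
  if (n_levels < 2) stop("n_levels must be at least 2")
  vals <- image[mask]
  rng <- range(vals)
  lev <- matrix(NA_integer_, nrow(image), ncol(image))
  if (diff(rng) == 0) {
    lev[mask] <- 0L
  } else {
    lev[mask] <- pmin(n_levels - 1L,
                      as.integer(floor((vals - rng[1]) / diff(rng) * n_levels)))
  }
  attr(lev, "n_levels") <- as.integer(n_levels)
  lev
}

#' Gray-level co-occurrence matrix
#'
#' Counts, over all valid pixel pairs at the given offset (default: the
#' horizontally adjacent neighbor), how often gray level *i* co-occurs
#' with gray level *j*.  Pairs involving out-of-mask pixels are excluded.
#' In symmetric mode each pair is counted in both orders, making the
#' matrix orientation-stable.
#'
#' @param level_image quantized level matrix from [quantize_levels()].
#' @param offset integer `(row, col)` displacement of the second pixel of
#'   each pair; `c(0, 1)` is the horizontal neighbor.
#' @param symmetric count each pair in both orders.
#' @param n_levels number of gray levels; taken from the `n_levels`
#'   attribute of `level_image` when present.
#' @return object of class `glcm`: list with `counts` (integer matrix),
#'   `p` (probabilities summing to 1), `n_levels`, `offset`, `symmetric`.
#' @examples
#' q <- quantize_levels(matrix(rep(0:1, 8), 4), n_levels = 2)
#' compute_glcm(q)$p
#' @export
compute_glcm <- function(level_image, offset = c(0, 1), symmetric = TRUE,
                         n_levels = attr(level_image, "n_levels")) {
  if (is.null(n_levels)) n_levels <- max(level_image, na.rm = TRUE) + 1L
  nr <- nrow(level_image); nc <- ncol(level_image)
  dr <- offset[1]; dc <- offset[2]
  r1 <- seq_len(nr - abs(dr)); c1 <- seq_len(nc - abs(dc))
  if (dr < 0) r1 <- r1 + abs(dr)
  if (dc < 0) c1 <- c1 + abs(dc)
  if (!length(r1) || !length(c1))
    stop("degenerate region: offset larger than image")
  a <- level_image[r1, c1, drop = FALSE]
  b <- level_image[r1 + dr, c1 + dc, drop = FALSE]
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep))
    stop("degenerate region: no valid pixel pairs at this offset")
  lv <- 0:(n_levels - 1L)
  counts <- table(factor(a[keep], levels = lv), factor(b[keep], levels = lv))
  counts <- matrix(as.integer(counts), n_levels, n_levels)
  if (symmetric) counts <- counts + t(counts)
  structure(list(counts = counts, p = counts / sum(counts),
                 n_levels = n_levels, offset = offset, symmetric = symmetric),
            class = "glcm")
}

#' Haralick texture features of a co-occurrence matrix
#'
#' The four summaries used to score localization changes:
#' \describe{
#'   \item{contrast}{\eqn{\sum_{i,j} p(i,j)\,(i-j)^2}; 0 for a constant
#'     image, large when adjacent pixels differ.}
#'   \item{energy}{\eqn{\sum_{i,j} p(i,j)^2}; 1 for a constant image,
#'     bounded in `(0, 1]`.}
#'   \item{homogeneity}{\eqn{\sum_{i,j} p(i,j)/(1+|i-j|)}.}
#'   \item{correlation}{\eqn{\sum_{i,j} p(i,j)\,(i-\mu_i)(j-\mu_j)/
#'     (\sigma_i\sigma_j)} with marginal means and standard deviations of
#'     `p`; reported as 0 by convention when either marginal standard
#'     deviation is 0.}
#' }
#'
#' @param glcm a [compute_glcm()] result.
#' @return one-row data.frame with columns `contrast`, `energy`,
#'   `homogeneity`, `correlation`.
#' @examples
#' q <- quantize_levels(matrix(1, 8, 8))
#' haralick_features(compute_glcm(q))
#' @export
haralick_features <- function(glcm) {
  stopifnot(inherits(glcm, "glcm"))
  p <- glcm$p
  L <- glcm$n_levels
  i <- matrix(0:(L - 1L), L, L)
  j <- t(i)
  contrast <- sum(p * (i - j)^2)
  energy <- sum(p^2)
  homogeneity <- sum(p / (1 + abs(i - j)))
  pi_ <- rowSums(p); pj_ <- colSums(p)
  mu_i <- sum((0:(L - 1L)) * pi_); mu_j <- sum((0:(L - 1L)) * pj_)
  sd_i <- sqrt(sum((0:(L - 1L) - mu_i)^2 * pi_))
  sd_j <- sqrt(sum((0:(L - 1L) - mu_j)^2 * pj_))
  correlation <- if (sd_i == 0 || sd_j == 0) 0 else
    sum(p * (i - mu_i) * (j - mu_j)) / (sd_i * sd_j)
  data.frame(contrast = contrast, energy = energy,
             homogeneity = homogeneity, correlation = correlation)
}

#' Texture features of a masked cell image
#'
#' Convenience wrapper: quantize within the cell mask, build the
#' horizontal-offset GLCM, return the four Haralick features.
#'
#' @param image yellow-channel matrix.
#' @param mask logical cell mask.
#' @param n_levels gray levels for quantization.
#' @param ... passed to [compute_glcm()].
#' @return one-row data.frame, see [haralick_features()].
#' @export
cell_texture <- function(image, mask = NULL, n_levels = 8, ...) {
  haralick_features(compute_glcm(quantize_levels(image, mask, n_levels), ...))
}
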