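#' Segment cells and nuclei from the red (constitutive marker) channel
#'
#' Foreground is found by a global threshold (Otsu by default), holes are
#' filled, small specks removed, and touching cells are split by a
#' watershed on the distance map of the foreground.  Within each cell the
#' nucleus is segmented as the high-intensity core: a 2-means split of the
#' smoothed red intensities inside the cell, keeping the largest connected
#' component of the brighter class.  Nucleus labels equal the enclosing
#' cell label.
#'
#' @param red 2-D numeric matrix (single-channel image), non-negative.
#' @param threshold_method `"otsu"` or a numeric threshold on the
#'   min-max-rescaled image in `[0,1]`.
#' @param smooth_sigma Gaussian smoothing (pixels) applied before the
#'   nuclear-core split.
#' @param min_size minimum object area in pixels; smaller foreground
#'   components are dropped.
#' @return list with `cell_mask` and `nucleus_mask`, integer label
#'   matrices (0 = background).  Empty foreground yields all-zero masks
#'   with a warning.
#' @examples
#' img <- render_cell_image(cell_state(1e4), program = "diffuse")
#' seg <- segment_cells(img$red)
#' max(seg$cell_mask)
#' @export
segment_cells <- function(red, threshold_method = "otsu", smooth_sigma = 1,
                          min_size = 50) {
  red <- as.matrix(red)
  if (any(red < 0)) stop("red image must be non-negative")
  zero <- matrix(0L, nrow(red), ncol(red))
  rng <- range(red)
  if (diff(rng) == 0) {
    warning("empty foreground: constant image")
    return(list(cell_mask = zero, nucleus_mask = zero))
  }
  xn <- (red - rng[1]) / diff(rng)
  thr <- if (identical(threshold_method, "otsu"))
    EBImage::otsu(EBImage::Image(xn)) else as.numeric(threshold_method)
  fg <- xn > thr
  if (!any(fg)) {
    warning("empty foreground after thresholding")
    return(list(cell_mask = zero, nucleus_mask = zero))
  }
  fg <- EBImage::fillHull(EBImage::Image(fg))
  lab <- EBImage::bwlabel(fg)
  sizes <- table(lab[lab > 0])
  drop <- as.integer(names(sizes)[sizes < min_size])
  if (length(drop)) lab[lab %in% drop] <- 0L
  if (!any(lab > 0)) {
    warning("empty foreground: all objects below min_size")
    return(list(cell_mask = zero, nucleus_mask = zero))
  }
  fg <- lab > 0
  cells <- EBImage::watershed(EBImage::distmap(fg))
  cells <- matrix(as.integer(EBImage::imageData(cells)),
                  nrow(red), ncol(red))

  sm <- if (smooth_sigma > 0)
    as.matrix(EBImage::gblur(xn, sigma = smooth_sigma)) else xn
  nuc <- zero
  for (L in sort(unique(cells[cells > 0]))) {
    inside <- cells == L
    vals <- sm[inside]
    if (length(unique(vals)) < 2) next
    km <- kmeans(vals, centers = range(vals))
    hi <- which.max(km$centers)
    core <- inside & sm >= min(vals[km$cluster == hi])
    core <- EBImage::fillHull(EBImage::Image(core))
    core_lab <- EBImage::bwlabel(core)
    tab <- table(core_lab[core_lab > 0])
    if (!length(tab)) next
    keep <- as.integer(names(tab)[which.max(tab)])
    nuc[core_lab == keep] <- L
  }
  list(cell_mask = cells, nucleus_mask = nuc)
}

mask_eccentricity <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 2) return(0)
  cv <- stats::cov(idx)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] <= 0) return(0)
  sqrt(max(0, 1 - ev[2] / ev[1]))
}

#' Measure one cell's fluorescence and morphology
#'
#' Computes, for a single cell, the total and nuclear background-subtracted
#' fluorescence (pixel values clipped at zero after subtraction), the
#' median background-subtracted pixel (the concentration proxy of the
#' alternative level measure), and area/eccentricity from the cell mask.
#'
#' @param yellow 2-D numeric matrix, the tagged-protein channel.
#' @param cell_mask,nucleus_mask logical matrices for one cell; the
#'   nucleus must be a subset of the cell.
#' @param background constant background level subtracted per pixel.
#' @param time_min frame time stamp carried into the output.
#' @return one-row data.frame: `time_min`, `total_fluor`, `nuclear_fluor`,
#'   `median_pixel`, `area_px`, `eccentricity`.
#' @examples
#' img <- render_cell_image(cell_state(1e4), program = "diffuse")
#' measure_cell(img$yellow, img$cell_mask, img$nucleus_mask)
#' @export
measure_cell <- function(yellow, cell_mask, nucleus_mask, background = 0,
                         time_min = NA_real_) {
  yellow <- as.matrix(yellow)
  cell_mask <- as.matrix(cell_mask) > 0
  nucleus_mask <- as.matrix(nucleus_mask) > 0
  if (!any(cell_mask)) stop("empty cell mask")
  if (any(nucleus_mask & !cell_mask))
    stop("nucleus mask is not a subset of the cell mask")
  vals <- pmax(0, yellow - background)
  data.frame(time_min = time_min,
             total_fluor = sum(vals[cell_mask]),
             nuclear_fluor = sum(vals[nucleus_mask]),
             median_pixel = median(vals[cell_mask]),
             area_px = sum(cell_mask),
             eccentricity = mask_eccentricity(cell_mask))
}

#' Measure a rendered or recorded two-channel movie into a trace
#'
#' Segments every frame's red channel, keeps the largest cell object, and
#' measures the yellow channel over its masks.  Background is estimated
#' per frame as the median yellow intensity outside the segmented cells.
#'
#' @param red_frames,yellow_frames lists of matrices, one per frame.
#' @param times_min frame time stamps (minutes).
#' @param ... passed to [segment_cells()].
#' @return data.frame of per-frame [measure_cell()] rows; frames whose
#'   segmentation found no cell are dropped with a warning.
#' @export
measure_movie <- function(red_frames, yellow_frames, times_min, ...) {
  stopifnot(length(red_frames) == length(yellow_frames),
            length(times_min) == length(red_frames))
  rows <- vector("list", length(red_frames))
  dropped <- 0L
  for (i in seq_along(red_frames)) {
    seg <- withCallingHandlers(
      segment_cells(red_frames[[i]], ...),
      warning = function(w) invokeRestart("muffleWarning"))
    if (!any(seg$cell_mask > 0)) { dropped <- dropped + 1L; next }
    tab <- table(seg$cell_mask[seg$cell_mask > 0])
    L <- as.integer(names(tab)[which.max(tab)])
    cm <- seg$cell_mask == L
    nm <- seg$nucleus_mask == L
    bg <- median(yellow_frames[[i]][seg$cell_mask == 0])
    rows[[i]] <- measure_cell(yellow_frames[[i]], cm, nm,
                              background = bg, time_min = times_min[i])
  }
  if (dropped > 0)
    warning(dropped, " frame(s) dropped: no cell segmented")
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Detect division events from the twofold fluorescence drop
#'
#' A division is called between consecutive frames whose total-fluorescence
#' ratio lies within `drop_tolerance` of `drop_factor` (default: a drop to
#' one half).  Optionally the call additionally requires the cell to be
#' rounded on the pre-division frame (eccentricity below
#' `eccentricity_max`), mirroring the morphological mitosis cue.  The
#' division time is reported as the midpoint of the frame interval.
#'
#' @param trace data.frame with `time_min`, `total_fluor` and (if
#'   `use_morphology`) `eccentricity`, time-ordered.
#' @param drop_factor expected fluorescence ratio across a division.
#' @param drop_tolerance relative tolerance around `drop_factor`.
#' @param use_morphology require a rounded pre-division frame.
#' @param eccentricity_max rounding threshold on eccentricity.
#' @return numeric vector of division times (minutes), possibly empty.
#' @examples
#' tr <- data.frame(time_min = c(0, 20, 40, 60),
#'                  total_fluor = c(100, 110, 55, 60))
#' detect_divisions(tr)
#' @export
detect_divisions <- function(trace, drop_factor = 2, drop_tolerance = 0.25,
                             use_morphology = FALSE, eccentricity_max = 0.6) {
  if (nrow(trace) < 2) stop("trace needs at least 2 observations")
  ok <- trace$total_fluor > 0
  if (!all(ok)) {
    warning(sum(!ok), " frame(s) with non-positive fluorescence skipped")
    trace <- trace[ok, , drop = FALSE]
    if (nrow(trace) < 2) return(numeric(0))
  }
  v <- trace$total_fluor
  t <- trace$time_min
  ratio <- v[-length(v)] / v[-1]
  hit <- ratio >= drop_factor * (1 - drop_tolerance) &
         ratio <= drop_factor * (1 + drop_tolerance)
  if (use_morphology) {
    if (is.null(trace$eccentricity))
      stop("use_morphology requires an eccentricity column")
    hit <- hit & trace$eccentricity[-length(v)] < eccentricity_max
  }
  (t[-length(t)][hit] + t[-1][hit]) / 2
}
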