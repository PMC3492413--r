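#' Describe the geometry and content of one synthetic cell
#'
#' @param total_fluor total fluorescence to distribute over the cell.
#' @param nr nuclear ratio in `[0,1]` (fraction of `total_fluor` placed in
#'   the nucleus) for programs that split signal between compartments.
#' @param center cell center `(x, y)` in pixels.
#' @param cell_axes semi-axes `(a, b)` of the cell ellipse, pixels.
#' @param nucleus_axes semi-axes of the nucleus ellipse.
#' @param nucleus_center nucleus center; defaults to the cell center.
#' @param n_spots number of punctae for the `"punctate"` program.
#' @param spot_sigma Gaussian width (pixels) of each punctum.
#' @return list of class `cell_state`.
#' @examples
#' st <- cell_state(total_fluor = 5e4, nr = 1)
#' @export
cell_state <- function(total_fluor, nr = 0.5, center = c(32, 32),
                       cell_axes = c(18, 14), nucleus_axes = c(9, 7),
                       nucleus_center = center, n_spots = 5,
                       spot_sigma = 1.5) {
  if (total_fluor < 0) stop("total_fluor must be non-negative")
  if (nr < 0 || nr > 1) stop("nr must lie in [0,1]")
  structure(list(total_fluor = total_fluor, nr = nr, center = center,
                 cell_axes = cell_axes, nucleus_axes = nucleus_axes,
                 nucleus_center = nucleus_center, n_spots = n_spots,
                 spot_sigma = spot_sigma),
            class = "cell_state")
}

ellipse_mask <- function(size, center, axes) {
  x <- matrix(seq_len(size[1]), size[1], size[2])
  y <- matrix(seq_len(size[2]), size[1], size[2], byrow = TRUE)
  ((x - center[1]) / axes[1])^2 + ((y - center[2]) / axes[2])^2 <= 1
}

#' Render a two-channel synthetic cell image tile
#'
#' Draws one cell on a dark background: the "red" (segmentation) channel
#' has near-uniform intensity over the cell with a brighter nuclear core
#' (the constitutive marker concentrates in the nucleus), the "yellow"
#' channel distributes the cell's total fluorescence according to the
#' localization program.  Optionally applies Poisson shot noise by
#' converting intensities to photon counts at the given gain.
#'
#' @param state a [cell_state()].
#' @param size tile size `(nx, ny)` in pixels.
#' @param program localization program: `"diffuse"` (uniform over the
#'   cell), `"nuclear"` (all signal in the nucleus), `"cytoplasmic"` (all
#'   outside the nucleus), `"shuttling"` (split by `state$nr`),
#'   `"punctate"` (`state$n_spots` Gaussian spots inside the cell).
#' @param red_cyto,red_nucleus,red_background red-channel intensities of
#'   cytoplasm, nucleus and background.
#' @param red_blur_sigma Gaussian blur applied to the red channel
#'   (pixels); 0 disables.
#' @param photon_gain photons per intensity unit for Poisson shot noise;
#'   `NULL` (default) renders noise-free.
#' @return list with `red`, `yellow` (numeric matrices), `cell_mask`,
#'   `nucleus_mask` (logical matrices: the ground truth).
#' @examples
#' img <- render_cell_image(cell_state(1e4, nr = 1), program = "nuclear")
#' sum(img$yellow[img$nucleus_mask]) / sum(img$yellow[img$cell_mask])
#' @export
render_cell_image <- function(state, size = c(64, 64),
                              program = c("diffuse", "nuclear",
                                          "cytoplasmic", "shuttling",
                                          "punctate"),
                              red_cyto = 0.5, red_nucleus = 1,
                              red_background = 0.02, red_blur_sigma = 1,
                              photon_gain = NULL) {
  stopifnot(inherits(state, "cell_state"))
  program <- match.arg(program)
  cell <- ellipse_mask(size, state$center, state$cell_axes)
  nuc <- ellipse_mask(size, state$nucleus_center, state$nucleus_axes)
  if (!any(cell)) stop("cell lies outside the tile")
  if (any(nuc & !cell)) stop("nucleus not contained in cell boundary")
  cyto <- cell & !nuc

  red <- matrix(red_background, size[1], size[2])
  red[cyto] <- red_cyto
  red[nuc] <- red_nucleus
  if (red_blur_sigma > 0)
    red <- as.matrix(EBImage::gblur(red, sigma = red_blur_sigma))

  tf <- state$total_fluor
  yellow <- matrix(0, size[1], size[2])
  if (program == "diffuse") {
    yellow[cell] <- tf / sum(cell)
  } else if (program == "nuclear") {
    yellow[nuc] <- tf / sum(nuc)
  } else if (program == "cytoplasmic") {
    yellow[cyto] <- tf / sum(cyto)
  } else if (program == "shuttling") {
    yellow[nuc] <- state$nr * tf / sum(nuc)
    yellow[cyto] <- (1 - state$nr) * tf / sum(cyto)
  } else {                               # punctate
    k <- state$n_spots
    pos <- matrix(NA_real_, k, 2)
    inner <- ellipse_mask(size, state$center, pmax(1, state$cell_axes - 3))
    cand <- which(inner, arr.ind = TRUE)
    min_d2 <- (4 * state$spot_sigma)^2
    placed <- 0L
    for (tries in seq_len(500L)) {
      if (placed == k) break
      cpt <- cand[sample.int(nrow(cand), 1L), ]
      if (placed == 0L ||
          all((pos[seq_len(placed), 1] - cpt[1])^2 +
              (pos[seq_len(placed), 2] - cpt[2])^2 >= min_d2)) {
        placed <- placed + 1L
        pos[placed, ] <- cpt
      }
    }
    if (placed < k) stop("could not place ", k, " separated spots in the cell")
    x <- matrix(seq_len(size[1]), size[1], size[2])
    y <- matrix(seq_len(size[2]), size[1], size[2], byrow = TRUE)
    for (s in seq_len(k)) {
      g <- exp(-((x - pos[s, 1])^2 + (y - pos[s, 2])^2) /
                 (2 * state$spot_sigma^2))
      g[!cell] <- 0
      yellow <- yellow + (tf / k) * g / sum(g)
    }
  }

  if (!is.null(photon_gain)) {
    yellow <- rpois(length(yellow), photon_gain * yellow) / photon_gain
    dim(yellow) <- size
    red <- rpois(length(red), photon_gain * 100 * red) / (photon_gain * 100)
    dim(red) <- size
  }
  list(red = red, yellow = yellow, cell_mask = cell, nucleus_mask = nuc)
}

#' Render a two-channel movie for one simulated cell
#'
#' Renders one image tile per frame of a simulated trace, holding the cell
#' geometry fixed and taking total fluorescence and nuclear ratio from the
#' trace.  Used to test the full image path (segmentation, measurement,
#' synchronization) against the trace ground truth.
#'
#' @param observations data.frame with `time_min`, `total_fluor`,
#'   `nuclear_fluor` (as produced by [simulate_cell_trace()]).
#' @param program localization program passed to [render_cell_image()].
#' @param state_template a [cell_state()] providing the geometry.
#' @param ... further arguments to [render_cell_image()].
#' @return list of per-frame render results (see [render_cell_image()]).
#' @export
render_cell_movie <- function(observations,
                              program = "shuttling",
                              state_template = cell_state(1), ...) {
  lapply(seq_len(nrow(observations)), function(i) {
    st <- state_template
    st$total_fluor <- observations$total_fluor[i]
    st$nr <- if (observations$total_fluor[i] > 0)
      min(1, max(0, observations$nuclear_fluor[i] /
                   observations$total_fluor[i])) else 0
    render_cell_image(st, program = program, ...)
  })
}
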