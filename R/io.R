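trace_schema <- c("protein_id", "fov_id", "cell_id", "time_min",
                  "total_fluor", "nuclear_fluor")

#' Read and validate a trace table CSV
#'
#' Expected columns: `protein_id`, `fov_id`, `cell_id`, `time_min`,
#' `total_fluor`, `nuclear_fluor` (one row per cell per frame), plus any
#' optional columns (`area_px`, `eccentricity`, `median_pixel`, texture
#' features).
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_trace_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(trace_schema, names(x))
  if (length(missing))
    stop("trace table is missing required column(s): ",
         paste(missing, collapse = ", "))
  x
}

#' Write a trace table CSV
#'
#' Numeric columns are written with 17 significant digits so that a table
#' written and re-read reproduces the original doubles exactly (the
#' pipeline's replay-determinism contract).
#'
#' @param traces trace table data.frame.
#' @param path output path.
#' @export
write_trace_csv <- function(traces, path) {
  out <- traces[, c(trace_schema, setdiff(names(traces), trace_schema)),
                drop = FALSE]
  for (cl in names(out))
    if (is.double(out[[cl]])) out[[cl]] <- sprintf("%.17g", out[[cl]])
  write.csv(out, path, row.names = FALSE)
}

#' Read a division-event table CSV
#'
#' Expected columns: `protein_id`, `fov_id`, `cell_id`,
#' `division_time_min`.
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_division_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "fov_id", "cell_id", "division_time_min")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("division table is missing required column(s): ",
         paste(missing, collapse = ", "))
  x
}

#' Write a rendered cell movie as paired multi-page TIFFs
#'
#' Writes `<prefix>_red.tif` and `<prefix>_yellow.tif` (one page per
#' frame, intensities rescaled to the file's dynamic range with the scale
#' recorded alongside in `<prefix>_scale.csv`) plus 8-bit
#' `<prefix>_cellmask.tif` / `<prefix>_nucmask.tif` ground-truth masks of
#' the first frame.
#'
#' @param frames list of [render_cell_image()] results.
#' @param times_min frame time stamps.
#' @param prefix output path prefix.
#' @return (invisibly) the file paths written.
#' @export
write_cell_movie_tiff <- function(frames, times_min, prefix) {
  stopifnot(length(frames) == length(times_min))
  scale_of <- function(chan) max(1e-12, max(vapply(frames, function(f)
    max(f[[chan]]), numeric(1))))
  sr <- scale_of("red"); sy <- scale_of("yellow")
  red <- lapply(frames, function(f) f$red / sr)
  yel <- lapply(frames, function(f) f$yellow / sy)
  paths <- paste0(prefix, c("_red.tif", "_yellow.tif", "_cellmask.tif",
                            "_nucmask.tif", "_scale.csv"))
  tiff::writeTIFF(red, paths[1], bits.per.sample = 16)
  tiff::writeTIFF(yel, paths[2], bits.per.sample = 16)
  tiff::writeTIFF(frames[[1]]$cell_mask * 1, paths[3], bits.per.sample = 8)
  tiff::writeTIFF(frames[[1]]$nucleus_mask * 1, paths[4], bits.per.sample = 8)
  write.csv(data.frame(time_min = times_min, red_scale = sr,
                       yellow_scale = sy),
            paths[5], row.names = FALSE)
  invisible(paths)
}

#' Read a paired TIFF cell movie written by [write_cell_movie_tiff()]
#'
#' @param prefix the path prefix used when writing.
#' @return list with `red_frames`, `yellow_frames` (lists of matrices on
#'   the original intensity scale) and `times_min`.
#' @export
read_cell_movie_tiff <- function(prefix) {
  meta <- read.csv(paste0(prefix, "_scale.csv"))
  as_mats <- function(path, scale) {
    pages <- tiff::readTIFF(path, all = TRUE)
    lapply(pages, function(p) p * scale)
  }
  list(red_frames = as_mats(paste0(prefix, "_red.tif"), meta$red_scale[1]),
       yellow_frames = as_mats(paste0(prefix, "_yellow.tif"),
                               meta$yellow_scale[1]),
       times_min = meta$time_min)
}

#' Measure a directory of per-cell TIFF movies into a trace table
#'
#' Expects movies written by [write_cell_movie_tiff()] with prefixes
#' `<protein>_f<fov>_c<cell>`; each is segmented and measured with
#' [measure_movie()].
#'
#' @param dir directory of TIFF movie pairs.
#' @return trace table data.frame.
#' @export
images_to_traces <- function(dir) {
  scales <- list.files(dir, pattern = "_scale\\.csv$", full.names = TRUE)
  if (!length(scales)) stop("no cell movies found in ", dir)
  rows <- lapply(scales, function(sc) {
    prefix <- sub("_scale\\.csv$", "", sc)
    id <- basename(prefix)
    m <- regmatches(id, regexec("^(.+)_f(\\d+)_c(\\d+)$", id))[[1]]
    if (length(m) != 4)
      stop("cannot parse protein/fov/cell from movie prefix: ", id)
    mov <- read_cell_movie_tiff(prefix)
    obs <- measure_movie(mov$red_frames, mov$yellow_frames, mov$times_min)
    data.frame(protein_id = m[2], fov_id = as.integer(m[3]),
               cell_id = as.integer(m[4]), time_min = obs$time_min,
               total_fluor = obs$total_fluor,
               nuclear_fluor = obs$nuclear_fluor,
               median_pixel = obs$median_pixel,
               area_px = obs$area_px, eccentricity = obs$eccentricity)
  })
  do.call(rbind, rows)
}

#' Read a simulation configuration from a YAML file
#'
#' Keys mirror the arguments of [sim_config()].
#' @param path YAML file.
#' @return a [sim_config()].
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}

#' Write a simulation configuration to YAML
#' @param config a [sim_config()].
#' @param path output path.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path)
}
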