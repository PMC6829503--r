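#' Read and write puncta images and cell volumes as TIFF
#'
#' Thin wrappers over the `tiff` package. Volumes are stored as one
#' directory per (z, channel) plane in z-major order; physical pixel and
#' voxel sizes are not stored in the file and must be supplied on read.
#'
#' @param img A [puncta_image()].
#' @param path File path.
#' @export
write_puncta_tiff <- function(img, path) {
  stopifnot(inherits(img, "PunctaImage"))
  px <- img$pixels
  px <- pmin(pmax(px, 0), 1) # float TIFF on the unit scale
  tiff::writeTIFF(px, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_puncta_tiff
#' @param pixel_size_um Pixel side in micrometres.
#' @export
read_puncta_tiff <- function(path, pixel_size_um = 0.063) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  puncta_image(as.matrix(px), pixel_size_um)
}

#' @rdname write_puncta_tiff
#' @param volume A [cell_volume()].
#' @export
write_volume_tiff <- function(volume, path) {
  stopifnot(inherits(volume, "CellVolume"))
  d <- dim(volume$voxels)
  planes <- list()
  for (z in seq_len(d[3]))
    for (ch in seq_len(d[4]))
      planes[[length(planes) + 1L]] <-
        pmin(pmax(volume$voxels[, , z, ch], 0), 1)
  tiff::writeTIFF(planes, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_puncta_tiff
#' @param n_channels Number of interleaved channels in the stack.
#' @param voxel_size_um Voxel pitch `c(x, y, z)` in micrometres.
#' @param channels Optional channel names.
#' @export
read_volume_tiff <- function(path, n_channels = 1,
                             voxel_size_um = c(0.8, 0.8, 2.0),
                             channels = NULL) {
  planes <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(planes)) planes <- list(planes)
  nz <- length(planes) / n_channels
  if (nz != round(nz))
    stop("plane count not divisible by n_channels", call. = FALSE)
  d <- dim(planes[[1]])
  vol <- array(0, c(d[1], d[2], nz, n_channels))
  k <- 1L
  for (z in seq_len(nz))
    for (ch in seq_len(n_channels)) {
      p <- planes[[k]]
      if (length(dim(p)) == 3) p <- p[, , 1]
      vol[, , z, ch] <- p
      k <- k + 1L
    }
  cell_volume(vol, voxel_size_um, channels)
}

#' Write ground truth to JSON
#'
#' @param truth A `GroundTruth`.
#' @param path Output path.
#' @export
write_ground_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "GroundTruth"))
  jsonlite::write_json(unclass(truth)[!vapply(truth, is.null, logical(1))],
                       path, dataframe = "columns", digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}
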