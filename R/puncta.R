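#' Synaptic puncta section image
#'
#' @param pixels 2-D numeric intensity matrix.
#' @param pixel_size_um Physical pixel side in micrometres (default 0.063,
#'   the 40x confocal acquisition pitch).
#' @return An object of class `PunctaImage`.
#' @export
puncta_image <- function(pixels, pixel_size_um = 0.063) {
  stopifnot(is.matrix(pixels), is.numeric(pixels), pixel_size_um > 0)
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um),
            class = "PunctaImage")
}

#' @export
print.PunctaImage <- function(x, ...) {
  cat(sprintf("PunctaImage: %d x %d px at %g um/px (%.1f x %.1f um)\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              nrow(x$pixels) * x$pixel_size_um,
              ncol(x$pixels) * x$pixel_size_um))
  invisible(x)
}

# 8-connected component labeling. Foreground pixels become graph vertices
# connected to their 8-neighbours; components come from igraph. (The
# common 2-D labeler in EBImage is 4-connected, and the filter below is
# specified on 8-connectivity.)
.label_components_8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  labels <- matrix(0L, nr, nc)
  if (length(idx) == 0) return(labels)
  row_i <- ((idx - 1L) %% nr) + 1L
  col_i <- ((idx - 1L) %/% nr) + 1L
  pos <- integer(nr * nc); pos[idx] <- seq_along(idx)
  edges <- list()
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  for (s in shifts) {
    r2 <- row_i + s[1]; c2 <- col_i + s[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    has <- pos[nb] > 0L
    edges[[length(edges) + 1L]] <-
      cbind(pos[idx[ok]][has], pos[nb][has])
  }
  e <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(e) && nrow(e) > 0) g <- igraph::add_edges(g, t(e))
  comp <- igraph::components(g)$membership
  labels[idx] <- as.integer(comp)
  labels
}

#' Segment puncta by intensity thresholding
#'
#' Thresholds the section (Otsu's method by default, or a fixed value) and
#' labels the resulting foreground with 8-connected component analysis,
#' so diagonally touching pixels belong to one punctum.
#'
#' @param img A [puncta_image()].
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param threshold Fixed intensity threshold, required when
#'   `threshold_method = "fixed"`.
#' @return A list of class `PunctaSegmentation`: `mask` (logical matrix),
#'   `labels` (integer matrix), `threshold`, `pixel_size_um`, and
#'   `components`, a data frame with one row per component (`label`,
#'   `n_pixels`, `area_um2`, centroids in um, `mean_intensity`).
#' @export
segment_puncta <- function(img, threshold_method = c("otsu", "fixed"),
                           threshold = NULL) {
  stopifnot(inherits(img, "PunctaImage"))
  threshold_method <- match.arg(threshold_method)
  px <- img$pixels
  if (threshold_method == "otsu") {
    rng <- range(px)
    if (diff(rng) == 0)
      stop("constant image: Otsu thresholding is undefined; ",
           "use threshold_method = \"fixed\" with an explicit threshold",
           call. = FALSE)
    scaled <- (px - rng[1]) / diff(rng)
    thr <- rng[1] + EBImage::otsu(scaled, range = c(0, 1)) * diff(rng)
  } else {
    if (is.null(threshold))
      stop("threshold must be given for threshold_method = \"fixed\"",
           call. = FALSE)
    thr <- threshold
  }
  mask <- px > thr
  labels <- .label_components_8(mask)
  n_comp <- max(labels)
  comps <- if (n_comp == 0) {
    data.frame(label = integer(), n_pixels = integer(), area_um2 = numeric(),
               centroid_x_um = numeric(), centroid_y_um = numeric(),
               mean_intensity = numeric())
  } else {
    idx <- which(labels > 0L)
    lab <- labels[idx]
    ri <- ((idx - 1L) %% nrow(px)) + 1L
    ci <- ((idx - 1L) %/% nrow(px)) + 1L
    n_px <- as.integer(tabulate(lab, n_comp))
    data.frame(label = seq_len(n_comp), n_pixels = n_px,
               area_um2 = n_px * img$pixel_size_um^2,
               centroid_x_um = (tapply(ri, lab, mean) - 0.5) * img$pixel_size_um,
               centroid_y_um = (tapply(ci, lab, mean) - 0.5) * img$pixel_size_um,
               mean_intensity = as.numeric(tapply(px[idx], lab, mean)))
  }
  structure(list(mask = mask, labels = labels, threshold = thr,
                 pixel_size_um = img$pixel_size_um, components = comps),
            class = "PunctaSegmentation")
}

#' Filter segmented components by physical area
#'
#' Keeps components whose area (`pixel count * pixel_size_um^2`) lies in
#' the punctum band, 0.018 to 3.14 um^2 inclusive on both ends. At the
#' default 0.063 um pixel size this excludes single-pixel specks
#' (0.003969 um^2) and large blobs above ~791 pixels.
#'
#' @param segmentation A `PunctaSegmentation` (or its `components` data
#'   frame plus `pixel_size_um`).
#' @param pixel_size_um Pixel side in um; taken from the segmentation when
#'   omitted.
#' @param min_area_um2,max_area_um2 Inclusive area bounds (defaults 0.018
#'   and 3.14).
#' @return A `PunctaSet` data frame: `centroid_x_um`, `centroid_y_um`,
#'   `area_um2`, `n_pixels`, `mean_intensity`.
#' @export
filter_puncta <- function(segmentation, pixel_size_um = NULL,
                          min_area_um2 = 0.018, max_area_um2 = 3.14) {
  if (min_area_um2 >= max_area_um2)
    stop("min_area_um2 must be below max_area_um2", call. = FALSE)
  comps <- if (inherits(segmentation, "PunctaSegmentation")) {
    if (is.null(pixel_size_um)) pixel_size_um <- segmentation$pixel_size_um
    segmentation$components
  } else segmentation
  if (is.null(pixel_size_um))
    stop("pixel_size_um is required", call. = FALSE)
  area <- comps$n_pixels * pixel_size_um^2
  keep <- area >= min_area_um2 & area <= max_area_um2
  out <- data.frame(centroid_x_um = comps$centroid_x_um[keep],
                    centroid_y_um = comps$centroid_y_um[keep],
                    area_um2 = area[keep],
                    n_pixels = comps$n_pixels[keep],
                    mean_intensity = comps$mean_intensity[keep])
  rownames(out) <- NULL
  class(out) <- c("PunctaSet", "data.frame")
  out
}

#' Puncta density over a region of interest
#'
#' @param puncta A `PunctaSet` (or any data frame with one row per kept
#'   punctum).
#' @param roi_area_um2 Surface area of the region of interest in um^2.
#' @return A list of class `PunctaResult`: `n_puncta`, `roi_area_um2`,
#'   `density_per_um2`.
#' @export
puncta_density <- function(puncta, roi_area_um2) {
  if (!is.numeric(roi_area_um2) || roi_area_um2 <= 0)
    stop("roi_area_um2 must be > 0", call. = FALSE)
  n <- nrow(puncta)
  structure(list(n_puncta = n, roi_area_um2 = roi_area_um2,
                 density_per_um2 = n / roi_area_um2),
            class = "PunctaResult")
}

#' @export
print.PunctaResult <- function(x, ...) {
  cat(sprintf("PunctaResult: %d puncta / %.1f um^2 = %.4g per um^2\n",
              x$n_puncta, x$roi_area_um2, x$density_per_um2))
  invisible(x)
}

#' Excitatory / inhibitory synaptic density ratio
#'
#' Ratio of excitatory (PSD-95-like) to inhibitory (gephyrin-like) puncta
#' densities; a shift above control marks an excitation-inhibition
#' imbalance.
#'
#' @param excitatory_density,inhibitory_density Densities in per-um^2 (or
#'   `PunctaResult` objects).
#' @return Dimensionless ratio.
#' @export
synaptic_ratio <- function(excitatory_density, inhibitory_density) {
  e <- if (inherits(excitatory_density, "PunctaResult"))
    excitatory_density$density_per_um2 else excitatory_density
  i <- if (inherits(inhibitory_density, "PunctaResult"))
    inhibitory_density$density_per_um2 else inhibitory_density
  if (!is.numeric(i) || i <= 0)
    stop("inhibitory density must be > 0", call. = FALSE)
  e / i
}
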