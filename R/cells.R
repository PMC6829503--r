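#' Multi-channel confocal volume
#'
#' @param voxels 4-D numeric array `[x, y, z, channel]` (a 3-D array is
#'   treated as single-channel).
#' @param voxel_size_um Voxel pitch `c(x, y, z)` in micrometres;
#'   z-anisotropy is honored in all physical distances.
#' @param channels Optional channel names.
#' @return An object of class `CellVolume`.
#' @export
cell_volume <- function(voxels, voxel_size_um, channels = NULL) {
  if (length(dim(voxels)) == 3)
    dim(voxels) <- c(dim(voxels), 1L)
  stopifnot(length(dim(voxels)) == 4, length(voxel_size_um) == 3,
            all(voxel_size_um > 0))
  if (is.null(channels))
    channels <- paste0("ch", seq_len(dim(voxels)[4]))
  structure(list(voxels = voxels, voxel_size_um = as.numeric(voxel_size_um),
                 channels = channels),
            class = "CellVolume")
}

#' @export
print.CellVolume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("CellVolume: %d x %d x %d voxels, %d channel(s), voxel %s um\n",
              d[1], d[2], d[3], d[4],
              paste(x$voxel_size_um, collapse = " x ")))
  invisible(x)
}

# separable Gaussian smoothing of a 3-D array, per-axis sigma in voxels;
# replicate padding at the borders (kernel renormalized by convolving a
# ones array).
.gauss_smooth3 <- function(a, sigma_vox) {
  conv_axis <- function(a, k, axis) {
    h <- (length(k) - 1L) %/% 2L
    d <- dim(a)
    out <- array(0, d)
    for (j in seq_along(k)) {
      off <- j - h - 1L
      n <- d[axis]
      src <- pmin(pmax(seq_len(n) + off, 1L), n) # replicate edges
      out <- out + k[j] * switch(axis,
                                 a[src, , , drop = FALSE],
                                 a[, src, , drop = FALSE],
                                 a[, , src, drop = FALSE])
    }
    out
  }
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    h <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(-h:h, sd = s)
    k <- k / sum(k)
    a <- conv_axis(a, k, axis)
  }
  a
}

# grey dilation (running max) with half-widths r (voxels) per axis
.dilate3 <- function(a, r) {
  d <- dim(a)
  for (axis in 1:3) {
    if (r[axis] < 1) next
    out <- a
    for (off in c(-seq_len(r[axis]), seq_len(r[axis]))) {
      n <- d[axis]
      src <- seq_len(n) + off
      ok <- src >= 1L & src <= n
      dst <- which(ok); src <- src[ok]
      if (axis == 1) out[dst, , ] <- pmax(out[dst, , ], a[src, , ])
      else if (axis == 2) out[, dst, ] <- pmax(out[, dst, ], a[, src, ])
      else out[, , dst] <- pmax(out[, , dst], a[, , src])
    }
    a <- out
  }
  a
}

#' Detect cell-sized blobs in one channel of a 3-D volume
#'
#' Scale-matched blob detection for roughly spherical somata: the channel
#' is smoothed with an anisotropy-corrected Gaussian at the blob scale
#' (`sigma = diameter / (2 * sqrt(3))` per axis, converted to voxels with
#' the per-axis pitch), local maxima of the smoothed response within a
#' half-diameter neighborhood become candidates, candidates below the
#' intensity threshold are dropped, and remaining candidates closer than
#' half a diameter (physical distance, z-anisotropy honored) are merged
#' greedily in order of descending response — so near-touching somata
#' resolve deterministically. The threshold is relative to the response
#' maximum, making counts invariant under global gain changes.
#'
#' @param volume A [cell_volume()].
#' @param channel Channel index or name to detect in.
#' @param diameter_um Expected cell diameter in micrometres (default 7);
#'   must span at least 2 voxels on every axis.
#' @param intensity_threshold Fraction of the maximum smoothed response a
#'   candidate must reach (default 0.5).
#' @return A `CellDetections` data frame: centers in um (`x_um`, `y_um`,
#'   `z_um`), `response`, per-channel mean intensities inside the sphere
#'   (`mean_<channel>`), and a `class` column initialized to
#'   `"unclassified"`. Attributes `diameter_um` and `voxel_size_um`.
#' @export
detect_cells <- function(volume, channel = 1, diameter_um = 7,
                         intensity_threshold = 0.5) {
  stopifnot(inherits(volume, "CellVolume"))
  if (is.character(channel)) channel <- match(channel, volume$channels)
  vs <- volume$voxel_size_um
  if (any(diameter_um / vs < 2))
    stop("diameter spans fewer than 2 voxels on some axis; ",
         "voxel size too coarse", call. = FALSE)
  a <- volume$voxels[, , , channel, drop = TRUE]
  dim(a) <- dim(volume$voxels)[1:3]
  sigma_um <- diameter_um / (2 * sqrt(3))
  resp <- .gauss_smooth3(a, sigma_um / vs)
  r_vox <- pmax(1L, as.integer(round(diameter_um / 2 / vs)))
  peaks <- which(resp == .dilate3(resp, r_vox) &
                   resp > intensity_threshold * max(resp), arr.ind = TRUE)
  empty <- {
    z <- data.frame(x_um = numeric(), y_um = numeric(), z_um = numeric(),
                    response = numeric(), class = character())
    for (ch in volume$channels) z[[paste0("mean_", ch)]] <- numeric()
    z
  }
  if (max(resp) <= 0 || nrow(peaks) == 0) {
    out <- empty
  } else {
    pk_resp <- resp[peaks]
    o <- order(pk_resp, decreasing = TRUE)
    peaks <- peaks[o, , drop = FALSE]; pk_resp <- pk_resp[o]
    cen <- sweep(peaks - 0.5, 2, vs, "*")
    keep <- integer(0)
    for (i in seq_len(nrow(cen))) {
      if (length(keep) == 0 ||
          min(sqrt(colSums((t(cen[keep, , drop = FALSE]) - cen[i, ])^2))) >=
            diameter_um / 2)
        keep <- c(keep, i)
    }
    cen <- cen[keep, , drop = FALSE]; pk_resp <- pk_resp[keep]
    means <- .sphere_means(volume, cen, diameter_um / 2)
    out <- data.frame(x_um = cen[, 1], y_um = cen[, 2], z_um = cen[, 3],
                      response = pk_resp,
                      class = rep("unclassified", nrow(cen)))
    for (j in seq_along(volume$channels))
      out[[paste0("mean_", volume$channels[j])]] <- means[, j]
    out <- out[order(out$x_um, out$y_um, out$z_um), ]
    rownames(out) <- NULL
  }
  attr(out, "diameter_um") <- diameter_um
  attr(out, "voxel_size_um") <- vs
  class(out) <- c("CellDetections", "data.frame")
  out
}

# per-channel mean intensity within radius of each center (physical um)
.sphere_means <- function(volume, centers, radius_um) {
  vs <- volume$voxel_size_um
  d <- dim(volume$voxels)
  vx <- (seq_len(d[1]) - 0.5) * vs[1]
  vy <- (seq_len(d[2]) - 0.5) * vs[2]
  vz <- (seq_len(d[3]) - 0.5) * vs[3]
  out <- matrix(NA_real_, nrow(centers), d[4])
  for (i in seq_len(nrow(centers))) {
    p <- centers[i, ]
    ix <- which(abs(vx - p[1]) <= radius_um)
    iy <- which(abs(vy - p[2]) <= radius_um)
    iz <- which(abs(vz - p[3]) <= radius_um)
    d2 <- outer(outer((vx[ix] - p[1])^2, (vy[iy] - p[2])^2, "+"),
                (vz[iz] - p[3])^2, "+")
    inside <- d2 <= radius_um^2
    for (ch in seq_len(d[4])) {
      sub <- volume$voxels[ix, iy, iz, ch]
      out[i, ch] <- mean(sub[inside])
    }
  }
  out
}

#' Assign class labels to detected cells from channel intensities
#'
#' Each detection's per-channel sphere-mean intensities are normalized by
#' that channel's volume-wide maximum; the detection takes the role of the
#' brightest normalized channel if that channel exceeds its threshold,
#' otherwise it stays `"unclassified"`.
#'
#' @param detections A `CellDetections` from [detect_cells()].
#' @param volume The `CellVolume` the detections came from (for
#'   normalization).
#' @param channel_roles Named character vector mapping channel name to
#'   role, e.g. `c(inhibitory = "inhibitory", excitatory = "excitatory")`;
#'   defaults to the volume's channel names as their own roles.
#' @param threshold Normalized-intensity floor for a positive call
#'   (default 0.3).
#' @return The detections with the `class` column filled in.
#' @export
classify_cells <- function(detections, volume, channel_roles = NULL,
                           threshold = 0.3) {
  stopifnot(inherits(detections, "CellDetections"),
            inherits(volume, "CellVolume"))
  if (is.null(channel_roles)) {
    channel_roles <- stats::setNames(volume$channels, volume$channels)
  }
  chans <- names(channel_roles)
  if (is.null(chans) || !all(chans %in% volume$channels))
    stop("channel_roles must be named by the volume's channels", call. = FALSE)
  if (nrow(detections) == 0) return(detections)
  ch_max <- vapply(match(chans, volume$channels),
                   function(j) max(volume$voxels[, , , j]), numeric(1))
  ch_max[ch_max <= 0] <- Inf
  norm <- sapply(seq_along(chans), function(j)
    detections[[paste0("mean_", chans[j])]] / ch_max[j])
  norm <- matrix(norm, nrow = nrow(detections))
  best <- max.col(norm, ties.method = "first")
  pass <- norm[cbind(seq_len(nrow(norm)), best)] >= threshold
  detections$class <- ifelse(pass, unname(channel_roles[best]),
                             "unclassified")
  detections
}

#' Count dying (acridine-orange or caspase-3 positive) cells
#'
#' The cell detector restricted to one marker channel; the relative
#' intensity threshold makes the count invariant to image gain.
#'
#' @inheritParams detect_cells
#' @return Integer count of detected marker-positive cells.
#' @export
count_dying_cells <- function(volume, channel = 1, diameter_um = 7,
                              intensity_threshold = 0.5) {
  nrow(detect_cells(volume, channel, diameter_um, intensity_threshold))
}

#' Colocalize two detection sets
#'
#' Greedy nearest-neighbour one-to-one pairing between two sets of 3-D
#' detections in the same physical coordinate frame: candidate pairs
#' within `max_dist_um` are accepted in order of ascending distance, each
#' detection pairing at most once.
#'
#' @param detections_a,detections_b `CellDetections` data frames (e.g.
#'   apoptotic markers and classified neurons).
#' @param max_dist_um Maximum center distance in um (default 3.5, half
#'   the 7 um cell diameter).
#' @return List with `pairs` (data frame `idx_a`, `idx_b`, `dist_um`,
#'   `class_a`, `class_b`) and `counts_by_class_b`, a table of pair counts
#'   keyed by the class of the `b` partner.
#' @export
colocalize <- function(detections_a, detections_b, max_dist_um = 3.5) {
  na <- nrow(detections_a); nb <- nrow(detections_b)
  pairs <- data.frame(idx_a = integer(), idx_b = integer(),
                      dist_um = numeric(), class_a = character(),
                      class_b = character())
  if (na > 0 && nb > 0) {
    pa <- as.matrix(detections_a[, c("x_um", "y_um", "z_um")])
    pb <- as.matrix(detections_b[, c("x_um", "y_um", "z_um")])
    d2 <- outer(rowSums(pa^2), rep(1, nb)) +
      outer(rep(1, na), rowSums(pb^2)) - 2 * pa %*% t(pb)
    d2[d2 < 0] <- 0 # expanded form can go epsilon-negative at zero distance
    dmat <- sqrt(d2)
    cand <- which(dmat <= max_dist_um, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      cand <- cand[order(dmat[cand]), , drop = FALSE]
      used_a <- logical(na); used_b <- logical(nb)
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!used_a[i] && !used_b[j]) {
          used_a[i] <- TRUE; used_b[j] <- TRUE
          pairs <- rbind(pairs, data.frame(
            idx_a = i, idx_b = j, dist_um = dmat[i, j],
            class_a = detections_a$class[i],
            class_b = detections_b$class[j]))
        }
      }
    }
  }
  counts <- table(factor(pairs$class_b,
                         levels = sort(unique(detections_b$class))))
  list(pairs = pairs, counts_by_class_b = counts)
}

#' Quantify movement from a frame sequence
#'
#' Larval movement as "acting units": for each consecutive frame pair,
#' the number of pixels whose absolute intensity change exceeds the
#' threshold; the total is the sum over all pairs.
#'
#' @param frames A list of equally sized 2-D matrices, or a 3-D array
#'   `[x, y, frame]`.
#' @param intensity_change_threshold Minimum |delta intensity| for a pixel
#'   to count as changed (strict).
#' @return List with `per_frame` (changed-pixel counts, one per
#'   consecutive pair) and `total` acting units.
#' @export
quantify_movement <- function(frames, intensity_change_threshold) {
  if (is.array(frames) && length(dim(frames)) == 3)
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  if (!is.list(frames) || length(frames) < 2)
    stop("need at least 2 frames", call. = FALSE)
  d <- dim(frames[[1]])
  per <- vapply(seq_len(length(frames) - 1L), function(i) {
    if (!identical(dim(frames[[i + 1L]]), d))
      stop("frame ", i + 1L, " has a different shape", call. = FALSE)
    sum(abs(frames[[i + 1L]] - frames[[i]]) > intensity_change_threshold)
  }, numeric(1))
  list(per_frame = per, total = sum(per))
}
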