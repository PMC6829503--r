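#' Simulate a synaptic-puncta section image with planted ground truth
#'
#' Plants bright spots on a dark background in three area bands relative
#' to the punctum size filter (0.018-3.14 um^2): `n_below` sub-threshold
#' clusters of 1-4 pixels, `n_in_range` discs whose rasterized area falls
#' inside the band, and `n_above` discs larger than the band. Spots are
#' placed by rejection sampling with a hard retry cap and kept at least
#' 2 pixels apart so 8-connected components never merge. Truth areas are
#' the exact rasterized pixel counts times `pixel_size_um^2`.
#'
#' @param n_in_range,n_below,n_above Spot counts per area band (>= 0).
#' @param pixel_size_um Pixel side in micrometres (default 0.063).
#' @param noise_sd Gaussian background noise SD on the unit intensity
#'   scale (default 0).
#' @param seed RNG seed.
#' @param size_px Image side length in pixels (default 256).
#' @return List with `image` (a [puncta_image()]) and `truth` (a
#'   `GroundTruth` whose `puncta` data frame has centroid, pixel count,
#'   area and band per spot).
#' @export
simulate_puncta_image <- function(n_in_range, n_below = 0, n_above = 0,
                                  pixel_size_um = 0.063, noise_sd = 0,
                                  seed = 1L, size_px = 256L) {
  stopifnot(n_in_range >= 0, n_below >= 0, n_above >= 0, pixel_size_um > 0)
  set.seed(seed)
  px_area <- pixel_size_um^2
  img <- matrix(0, size_px, size_px)
  occupied <- matrix(FALSE, size_px, size_px)
  max_tries <- 10000L

  # compact offset patterns for sub-threshold clusters of k pixels
  below_patterns <- list(
    cbind(0L, 0L),
    cbind(c(0L, 1L), c(0L, 0L)),
    cbind(c(0L, 1L, 0L), c(0L, 0L, 1L)),
    cbind(c(0L, 1L, 0L, 1L), c(0L, 0L, 1L, 1L)))

  disc_pixels <- function(cx, cy, r) {
    ix <- max(1L, floor(cx - r)):min(size_px, ceiling(cx + r))
    iy <- max(1L, floor(cy - r)):min(size_px, ceiling(cy + r))
    g <- expand.grid(x = ix, y = iy)
    g <- g[(g$x - cx)^2 + (g$y - cy)^2 <= r^2, , drop = FALSE]
    as.matrix(g)
  }

  blocked <- function(px) {
    # 2-pixel Chebyshev margin around the candidate spot
    for (dx in -2:2) for (dy in -2:2) {
      x <- px[, 1] + dx; y <- px[, 2] + dy
      ok <- x >= 1 & x <= size_px & y >= 1 & y <= size_px
      if (any(occupied[cbind(x[ok], y[ok])])) return(TRUE)
    }
    FALSE
  }

  place_spot <- function(kind) {
    for (i in seq_len(max_tries)) {
      if (kind == "below") {
        k <- sample(4L, 1L)
        c0 <- sample.int(size_px - 4L, 2L) + 1L
        px <- cbind(c0[1] + below_patterns[[k]][, 1],
                    c0[2] + below_patterns[[k]][, 2])
      } else {
        target_px <- if (kind == "in_range")
          exp(stats::runif(1, log(8), log(600))) else stats::runif(1, 950, 1300)
        r <- sqrt(target_px / pi)
        cx <- stats::runif(1, r + 3, size_px - r - 3)
        cy <- stats::runif(1, r + 3, size_px - r - 3)
        px <- disc_pixels(cx, cy, r)
        n_px <- nrow(px)
        ok_band <- if (kind == "in_range")
          n_px * px_area >= 0.018 && n_px * px_area <= 3.1 else
          n_px * px_area > 3.14
        if (!ok_band) next
      }
      if (!blocked(px)) {
        occupied[px] <<- TRUE
        val <- stats::runif(1, 0.7, 1.0)
        img[px] <<- val
        return(data.frame(x_px = mean(px[, 1]), y_px = mean(px[, 2]),
                          n_pixels = nrow(px),
                          area_um2 = nrow(px) * px_area, band = kind,
                          intensity = val))
      }
    }
    stop("could not place a ", kind,
         " spot without overlap; field too small", call. = FALSE)
  }

  specs <- c(rep("above", n_above), rep("in_range", n_in_range),
             rep("below", n_below)) # big spots first: easier packing
  truth <- do.call(rbind, lapply(specs, place_spot))
  if (is.null(truth))
    truth <- data.frame(x_px = numeric(), y_px = numeric(),
                        n_pixels = integer(), area_um2 = numeric(),
                        band = character(), intensity = numeric())
  truth$centroid_x_um <- (truth$x_px - 0.5) * pixel_size_um
  truth$centroid_y_um <- (truth$y_px - 0.5) * pixel_size_um
  if (noise_sd > 0)
    img <- img + matrix(stats::rnorm(size_px^2, 0, noise_sd),
                        size_px, size_px)
  list(image = puncta_image(img, pixel_size_um),
       truth = .ground_truth(puncta = truth))
}

#' Simulate a multi-channel confocal volume of labeled cells
#'
#' Plants bright 7-um spheres in a three-channel anisotropic volume:
#' channel 1 inhibitory (Gad1b-like), channel 2 excitatory (Vglut2a-like),
#' channel 3 apoptotic (caspase-3 / acridine-orange-like). Apoptotic
#' markers are either placed at their own random positions or, via
#' `apoptotic_on`, directly on centers of one neuron class to plant
#' colocalization. Neuron centers keep a pairwise separation of at least
#' one diameter (rejection sampling, hard retry cap).
#'
#' @param n_inhibitory,n_excitatory,n_apoptotic Cell counts (>= 0).
#' @param diameter_um Cell diameter in micrometres (default 7).
#' @param size_um Volume extent `c(x, y, z)` in micrometres
#'   (default 80 x 80 x 40).
#' @param voxel_size_um Voxel pitch `c(x, y, z)` in micrometres (default
#'   0.8 x 0.8 x 2.0, the 20x acquisition regime of whole-tectum counting).
#' @param noise_sd Gaussian noise SD on the unit intensity scale
#'   (default 0.02).
#' @param apoptotic_on `NULL`, `"inhibitory"` or `"excitatory"`: place the
#'   apoptotic markers on centers of that class (requires enough cells).
#' @param seed RNG seed.
#' @return List with `volume` (a [cell_volume()]) and `truth` (a
#'   `GroundTruth` whose `cells` data frame has center, class and channel).
#' @export
simulate_cell_volume <- function(n_inhibitory, n_excitatory,
                                 n_apoptotic = 0, diameter_um = 7,
                                 size_um = c(80, 80, 40),
                                 voxel_size_um = c(0.8, 0.8, 2.0),
                                 noise_sd = 0.02, apoptotic_on = NULL,
                                 seed = 1L) {
  stopifnot(n_inhibitory >= 0, n_excitatory >= 0, n_apoptotic >= 0,
            diameter_um > 0, length(size_um) == 3,
            length(voxel_size_um) == 3)
  set.seed(seed)
  r <- diameter_um / 2
  n_neurons <- n_inhibitory + n_excitatory
  max_tries <- 10000L

  centers <- matrix(numeric(0), 0, 3)
  for (k in seq_len(n_neurons)) {
    placed <- FALSE
    for (i in seq_len(max_tries)) {
      p <- stats::runif(3, r, size_um - r)
      if (nrow(centers) == 0 ||
          min(sqrt(colSums((t(centers) - p)^2))) >= diameter_um) {
        centers <- rbind(centers, p)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("volume too crowded: could not place cell ", k,
           " with separation >= one diameter", call. = FALSE)
  }
  cls <- c(rep("inhibitory", n_inhibitory), rep("excitatory", n_excitatory))

  if (is.null(apoptotic_on)) {
    apo <- matrix(numeric(0), 0, 3)
    for (k in seq_len(n_apoptotic)) {
      placed <- FALSE
      for (i in seq_len(max_tries)) {
        p <- stats::runif(3, r, size_um - r)
        if (nrow(apo) == 0 ||
            min(sqrt(colSums((t(apo) - p)^2))) >= diameter_um) {
          apo <- rbind(apo, p); placed <- TRUE; break
        }
      }
      if (!placed)
        stop("volume too crowded for apoptotic markers", call. = FALSE)
    }
  } else {
    apoptotic_on <- match.arg(apoptotic_on, c("inhibitory", "excitatory"))
    host <- which(cls == apoptotic_on)
    if (length(host) < n_apoptotic)
      stop("not enough ", apoptotic_on, " cells to host ", n_apoptotic,
           " apoptotic markers", call. = FALSE)
    apo <- centers[host[seq_len(n_apoptotic)], , drop = FALSE]
  }

  dims <- pmax(2L, as.integer(round(size_um / voxel_size_um)))
  vol <- array(0, dim = c(dims, 3L))
  vx <- ((seq_len(dims[1]) - 0.5) * voxel_size_um[1])
  vy <- ((seq_len(dims[2]) - 0.5) * voxel_size_um[2])
  vz <- ((seq_len(dims[3]) - 0.5) * voxel_size_um[3])

  paint <- function(vol, ch, p, val) {
    ix <- which(abs(vx - p[1]) <= r)
    iy <- which(abs(vy - p[2]) <= r)
    iz <- which(abs(vz - p[3]) <= r)
    for (k in iz) {
      dz2 <- (vz[k] - p[3])^2
      d2 <- outer((vx[ix] - p[1])^2, (vy[iy] - p[2])^2, "+") + dz2
      sub <- vol[ix, iy, k, ch]
      sub[d2 <= r^2] <- pmax(sub[d2 <= r^2], val)
      vol[ix, iy, k, ch] <- sub
    }
    vol
  }

  rows <- list()
  all_centers <- rbind(centers, apo)
  all_cls <- c(cls, rep("apoptotic", nrow(apo)))
  all_ch <- c(ifelse(cls == "inhibitory", 1L, 2L),
              rep(3L, nrow(apo)))
  for (k in seq_along(all_cls)) {
    val <- stats::runif(1, 0.85, 1.0)
    vol <- paint(vol, all_ch[k], all_centers[k, ], val)
    rows[[k]] <- data.frame(x_um = all_centers[k, 1],
                            y_um = all_centers[k, 2],
                            z_um = all_centers[k, 3],
                            class = all_cls[k], channel = all_ch[k],
                            intensity = val)
  }
  cells <- if (length(rows)) do.call(rbind, rows) else
    data.frame(x_um = numeric(), y_um = numeric(), z_um = numeric(),
               class = character(), channel = integer(),
               intensity = numeric())
  if (noise_sd > 0)
    vol <- vol + array(stats::rnorm(length(vol), 0, noise_sd), dim = dim(vol))
  list(volume = cell_volume(vol, voxel_size_um,
                            channels = c("inhibitory", "excitatory",
                                         "apoptotic")),
       truth = .ground_truth(cells = cells))
}
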