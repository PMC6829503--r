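test_that("an empty volume yields no detections", {
  vol <- cell_volume(array(0, c(30, 30, 10, 1)), c(0.8, 0.8, 2))
  expect_equal(nrow(detect_cells(vol)), 0)
  expect_equal(count_dying_cells(vol), 0)
})

test_that("planted spheres are recovered with centers within one voxel", {
  sim <- simulate_cell_volume(10, 0, 0, seed = 51)
  det <- detect_cells(sim$volume, "inhibitory")
  expect_equal(nrow(det), 10)
  tr <- sim$truth$cells
  for (i in seq_len(nrow(det))) {
    d <- sqrt((tr$x_um - det$x_um[i])^2 + (tr$y_um - det$y_um[i])^2 +
                (tr$z_um - det$z_um[i])^2)
    expect_lt(min(d), max(attr(det, "voxel_size_um")))
  }
})

test_that("detection rejects volumes where the sphere spans < 2 voxels", {
  vol <- cell_volume(array(0, c(20, 20, 4, 1)), c(0.8, 0.8, 5))
  expect_error(detect_cells(vol, diameter_um = 7), "2 voxels")
})

test_that("counts are invariant to global gain and whole-voxel translation", {
  sim <- simulate_cell_volume(0, 0, 12, seed = 52)
  n0 <- count_dying_cells(sim$volume, channel = "apoptotic")
  expect_equal(n0, 12)

  gained <- cell_volume(sim$volume$voxels * 2, sim$volume$voxel_size_um,
                        sim$volume$channels)
  expect_equal(count_dying_cells(gained, channel = "apoptotic"), n0)

  v <- sim$volume$voxels
  shifted <- array(0, dim(v))
  shifted[4:dim(v)[1], , , ] <- v[1:(dim(v)[1] - 3), , , ]
  trans <- cell_volume(shifted, sim$volume$voxel_size_um,
                       sim$volume$channels)
  expect_equal(count_dying_cells(trans, channel = "apoptotic"), n0)
})

test_that("near-touching somata resolve to a stable deterministic count", {
  vol <- array(0, c(40, 40, 15, 1))
  vs <- c(0.8, 0.8, 2)
  paint_sphere <- function(vol, center) {
    for (i in 1:40) for (j in 1:40) for (k in 1:15) {
      p <- (c(i, j, k) - 0.5) * vs
      if (sum((p - center)^2) <= 3.5^2) vol[i, j, k, 1] <- 1
    }
    vol
  }
  vol <- paint_sphere(vol, c(12, 16, 14))
  vol <- paint_sphere(vol, c(15, 16, 14)) # centers 3 um apart
  cv <- cell_volume(vol, vs)
  counts <- replicate(3, nrow(detect_cells(cv)))
  expect_true(all(counts == counts[1]))
  expect_lte(counts[1], 2)
})

test_that("classification by channel role recovers planted class counts", {
  sim <- simulate_cell_volume(10, 15, 0, seed = 53)
  det_i <- detect_cells(sim$volume, "inhibitory")
  det_e <- detect_cells(sim$volume, "excitatory")
  both <- rbind(det_i, det_e)
  class(both) <- class(det_i)
  cls <- classify_cells(both, sim$volume,
                        channel_roles = c(inhibitory = "inhibitory",
                                          excitatory = "excitatory"))
  expect_equal(sum(cls$class == "inhibitory"), 10)
  expect_equal(sum(cls$class == "excitatory"), 15)
})

test_that("detections below every channel threshold stay unclassified", {
  sim <- simulate_cell_volume(2, 0, 0, noise_sd = 0, seed = 54)
  det <- detect_cells(sim$volume, "inhibitory")
  # dim marker channel: nothing reaches the 0.3 normalized floor there
  cls <- classify_cells(det, sim$volume,
                        channel_roles = c(excitatory = "excitatory"))
  expect_true(all(cls$class == "unclassified"))
})

test_that("colocalization pairs greedily, one-to-one and symmetrically", {
  mk <- function(x, cls) {
    d <- data.frame(x_um = x, y_um = rep(10, length(x)),
                    z_um = rep(10, length(x)), response = 1,
                    class = cls)
    class(d) <- c("CellDetections", "data.frame")
    d
  }
  far <- colocalize(mk(c(0, 5), "apoptotic"), mk(c(50, 60), "excitatory"))
  expect_equal(nrow(far$pairs), 0)

  same <- colocalize(mk(c(1, 2, 3), "apoptotic"), mk(c(1, 2, 3), "neuron"))
  expect_equal(nrow(same$pairs), 3)
  expect_equal(same$pairs$dist_um, rep(0, 3))

  a <- mk(c(0, 4, 9), "apoptotic"); b <- mk(c(1, 5, 30), "neuron")
  expect_equal(nrow(colocalize(a, b)$pairs), nrow(colocalize(b, a)$pairs))
})

test_that("planted apoptotic overlap is attributed to the right class", {
  sim <- simulate_cell_volume(10, 15, 5, apoptotic_on = "excitatory",
                              seed = 55)
  det_i <- detect_cells(sim$volume, "inhibitory")
  det_e <- detect_cells(sim$volume, "excitatory")
  neurons <- rbind(det_i, det_e)
  class(neurons) <- class(det_i)
  neurons <- classify_cells(neurons, sim$volume,
                            channel_roles = c(inhibitory = "inhibitory",
                                              excitatory = "excitatory"))
  apo <- detect_cells(sim$volume, "apoptotic")
  co <- colocalize(apo, neurons)
  counts <- co$counts_by_class_b
  expect_equal(unname(counts[["excitatory"]]), 5)
  expect_equal(unname(counts[["inhibitory"]]), 0)
})

test_that("movement counts changed pixels per frame pair", {
  f <- matrix(0, 20, 20)
  expect_equal(quantify_movement(list(f, f), 0.5)$total, 0)

  f1 <- f; f1[5:6, 5:9] <- 1
  f2 <- f; f2[5:6, 10:14] <- 1
  mv <- quantify_movement(list(f1, f2), 0.5)
  expect_equal(mv$per_frame, 20) # 10 px vacated + 10 px occupied
  expect_equal(quantify_movement(list(f1, f2), 2)$total, 0)

  expect_error(quantify_movement(list(f1, matrix(0, 10, 10)), 0.5), "shape")
  expect_error(quantify_movement(list(f1), 0.5), "2 frames")
})
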