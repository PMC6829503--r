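test_that("segmentation labels 8-connected components like a flood fill", {
  img <- matrix(0, 12, 12)
  img[3:4, 3:4] <- 1
  img[8:9, 8:10] <- 1
  seg <- segment_puncta(puncta_image(img, 0.063), "fixed", threshold = 0.5)
  expect_equal(nrow(seg$components), 2)
  expect_equal(sort(seg$components$n_pixels), c(4L, 6L))

  diag_img <- matrix(0, 8, 8)
  diag_img[2, 2] <- 1; diag_img[3, 3] <- 1; diag_img[4, 4] <- 1
  segd <- segment_puncta(puncta_image(diag_img, 0.063), "fixed", 0.5)
  expect_equal(nrow(segd$components), 1) # diagonal touch joins under 8-conn

  blank <- segment_puncta(puncta_image(matrix(c(0, rep(0, 62), 1e-6), 8, 8),
                                       0.063), "fixed", 0.5)
  expect_equal(nrow(blank$components), 0)
})

test_that("otsu requires a non-constant image", {
  expect_error(segment_puncta(puncta_image(matrix(0.5, 8, 8), 0.063)),
               "fixed")
})

test_that("component labeling agrees with the flood-fill oracle on random masks", {
  set.seed(33)
  for (rep in 1:8) {
    m <- matrix(runif(48 * 48) < 0.35, 48, 48)
    seg <- segment_puncta(puncta_image(m + 0, 0.1), "fixed", 0.5)
    orc <- oracle_flood_fill8(m)
    expect_equal(max(seg$labels), max(orc))
    expect_equal(component_sizes(seg$labels), component_sizes(orc))
  }
})

test_that("area filter applies the inclusive physical-area band", {
  comps <- data.frame(label = 1:3, n_pixels = c(1L, 5L, 800L),
                      area_um2 = c(1, 5, 800) * 0.063^2,
                      centroid_x_um = c(1, 2, 3),
                      centroid_y_um = c(1, 2, 3),
                      mean_intensity = c(1, 1, 1))
  kept <- filter_puncta(comps, pixel_size_um = 0.063)
  # 1 px = 0.003969 < 0.018 excluded; 5 px = 0.019845 kept;
  # 800 px = 3.1752 > 3.14 excluded
  expect_equal(nrow(kept), 1)
  expect_equal(kept$n_pixels, 5L)
  expect_equal(kept$area_um2, 0.019845, tolerance = 1e-12)
  expect_error(filter_puncta(comps, pixel_size_um = 0.063,
                             min_area_um2 = 2, max_area_um2 = 1), "below")
})

test_that("widening the area band never loses puncta, any label order", {
  sim <- simulate_puncta_image(n_in_range = 12, n_below = 6, n_above = 3,
                               seed = 17)
  seg <- segment_puncta(sim$image)
  n_narrow <- nrow(filter_puncta(seg, min_area_um2 = 0.05, max_area_um2 = 1))
  n_default <- nrow(filter_puncta(seg))
  n_wide <- nrow(filter_puncta(seg, min_area_um2 = 0.001, max_area_um2 = 10))
  expect_true(n_narrow <= n_default && n_default <= n_wide)

  shuffled <- seg$components[sample(nrow(seg$components)), ]
  expect_equal(nrow(filter_puncta(shuffled, pixel_size_um = 0.063)),
               n_default)
})

test_that("the puncta pipeline is exact on planted noiseless images", {
  for (seed in c(1, 5, 9)) {
    sim <- simulate_puncta_image(n_in_range = 20, n_below = 10, n_above = 5,
                                 seed = seed)
    pts <- filter_puncta(segment_puncta(sim$image))
    expect_equal(nrow(pts), 20)
  }
})

test_that("density and synaptic ratio are simple exact arithmetic", {
  expect_equal(puncta_density(data.frame()[0, ], 100)$density_per_um2, 0)
  pts <- data.frame(area_um2 = rep(0.1, 50))
  d <- puncta_density(pts, 100)
  expect_equal(d$density_per_um2, 0.5)
  expect_error(puncta_density(pts, 0), "> 0")

  expect_equal(synaptic_ratio(0.2, 0.2), 1)
  expect_equal(synaptic_ratio(0.4, 0.2), 2)
  expect_error(synaptic_ratio(0.4, 0), "> 0")
})

test_that("paired simulations with a planted 2x excess give ratio near 2", {
  ratios <- vapply(1:4, function(seed) {
    exc <- simulate_puncta_image(n_in_range = 40, seed = seed)
    inh <- simulate_puncta_image(n_in_range = 20, seed = seed + 100)
    roi <- prod(dim(exc$image$pixels)) * 0.063^2
    synaptic_ratio(
      puncta_density(filter_puncta(segment_puncta(exc$image)), roi),
      puncta_density(filter_puncta(segment_puncta(inh$image)), roi))
  }, numeric(1))
  expect_equal(mean(ratios), 2, tolerance = 0.05)
})
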