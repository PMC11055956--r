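test_that("an unbranched spec grows exactly one centreline per root", {
  spec <- phantom_spec(spheroid_radius = 60, voxel_spacing = c(2, 2, 2),
                       margin = 8, seed = 3,
                       vessel_params = list(n_roots = 1, branch_prob = 0,
                                            radius_range = c(4, 8),
                                            step_length = 6, max_depth = 3))
  truth <- generate_vessel_network(spec)
  expect_length(truth$centerlines, 1)
  expect_equal(truth$centerlines[[1]]$network, 1L)
  expect_equal(truth$centerlines[[1]]$depth, 0L)
})

test_that("network generation is bitwise deterministic for a fixed seed", {
  spec <- phantom_spec(seed = 12)
  t1 <- generate_vessel_network(spec)
  t2 <- generate_vessel_network(spec)
  expect_identical(t1$centerlines, t2$centerlines)
})

test_that("total centreline length matches an independent summation pass", {
  spec <- phantom_spec(spheroid_radius = 80, voxel_spacing = c(2, 2, 2),
                       margin = 8, seed = 5,
                       vessel_params = list(n_roots = 3, branch_prob = 0.2,
                                            radius_range = c(4, 8),
                                            step_length = 6, max_depth = 4))
  truth <- generate_vessel_network(spec)
  manual <- 0
  for (b in truth$centerlines)
    for (i in seq_len(nrow(b$points) - 1))
      manual <- manual + sqrt(sum((b$points[i + 1, ] - b$points[i, ])^2))
  expect_equal(centerline_length(truth), manual, tolerance = 1e-12)
})

test_that("radii taper monotonically from root to tip along each branch", {
  spec <- phantom_spec(seed = 21)
  truth <- generate_vessel_network(spec)
  for (b in truth$centerlines)
    expect_true(all(diff(b$radius) <= 1e-12))
})

test_that("an empty network renders only background in the CD31 channel", {
  spec <- phantom_spec(spheroid_radius = 40, voxel_spacing = c(2, 2, 2),
                       margin = 6, seed = 4, channel_set = "cd31",
                       vessel_params = list(n_roots = 0, branch_prob = 0,
                                            radius_range = c(4, 8),
                                            step_length = 6, max_depth = 1),
                       cell_params = list(),
                       noise_params = list(photon_scale = 0, gaussian_sd = 0,
                                           background_level = 10))
  truth <- generate_vessel_network(spec)
  out <- rasterize_phantom(spec, truth)
  bg <- spec$noise_params$background_level
  expect_lte(max(get_channel(out$stack, "cd31")), bg + 5 * 3)
  expect_false(any(out$truth$masks$cd31))
})

test_that("a straight rendered tube has near-analytic cylinder volume", {
  spec <- phantom_spec(spheroid_radius = 70, voxel_spacing = c(1, 0.5, 0.5),
                       margin = 5, seed = 2, channel_set = "cd31",
                       cell_params = list(),
                       noise_params = list(photon_scale = 0, gaussian_sd = 0,
                                           background_level = 0),
                       psf_sigma = 0)
  g <- vtsquant:::phantom_grid(spec)
  ctr <- g$center
  truth <- structure(list(
    centerlines = list(list(points = cbind(z = ctr[1], y = ctr[2],
                                           x = ctr[3] + seq(-50, 50, by = 1)),
                            radius = rep(4, 101), network = 1L, depth = 0L)),
    spheroid_center = ctr, spheroid_radius = 70, dims = g$dims,
    spacing = spec$voxel_spacing, cell_centroids = list(), masks = list()),
    class = c("phantom_truth", "list"))
  out <- rasterize_phantom(spec, truth)
  vol <- sum(out$truth$masks$cd31) * voxel_volume(spec$voxel_spacing)
  expect_lt(abs(vol / (pi * 16 * 100) - 1), 0.15)
})

test_that("requested orb counts are conserved in the ground truth", {
  spec <- phantom_spec(spheroid_radius = 60, voxel_spacing = c(2, 2, 2),
                       margin = 6, seed = 8, channel_set = c("cd11b"),
                       vessel_params = list(n_roots = 0, branch_prob = 0,
                                            radius_range = c(4, 8),
                                            step_length = 6, max_depth = 1),
                       cell_params = list(cd11b = list(count = 20,
                                                       orb_diameter = 10,
                                                       placement = "uniform")))
  out <- generate_phantom(spec)
  expect_equal(nrow(out$truth$cell_centroids$cd11b), 20)
  # all centroids strictly inside the spheroid
  ctr <- out$truth$spheroid_center
  d <- sqrt(rowSums(sweep(out$truth$cell_centroids$cd11b, 2, ctr)^2))
  expect_true(all(d <= 60 - 5))
})

test_that("rasterization is reproducible and masks match the noiseless render", {
  mini <- function() phantom_spec(
    spheroid_radius = 45, voxel_spacing = c(2, 2, 2), margin = 6, seed = 31,
    cell_params = list(tumor = list(render = "compartment"),
                       fibroblast = list(render = "compartment"),
                       cd11b = list(count = 8, orb_diameter = 10,
                                    placement = "uniform"),
                       hif1a = list(count = 8, orb_diameter = 10,
                                    placement = "uniform")))
  a <- generate_phantom(mini())
  b <- generate_phantom(mini())
  expect_identical(a$stack$channels, b$stack$channels)
  expect_identical(a$truth$masks, b$truth$masks)
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(spheroid_radius = -1), "positive")
  expect_error(phantom_spec(voxel_spacing = c(1, 0, 1)), "positive")
  expect_error(phantom_spec(vessel_params = list(n_roots = 1, branch_prob = 2,
                                                 radius_range = c(4, 8),
                                                 step_length = 6, max_depth = 1)),
               "branch_prob")
  expect_error(phantom_spec(spheroid_radius = 20,
                            vessel_params = list(n_roots = 1, branch_prob = 0,
                                                 radius_range = c(4, 8),
                                                 step_length = 6, max_depth = 1)),
               "radius_range")
})

test_that("ranking dataset equals the model VEI row-wise when noiseless", {
  tab <- generate_ranking_dataset(40, noise_sd = 0, seed = 6)
  expect_equal(tab$os, pmin(pmax(compute_vei(tab), -1), 1), tolerance = 1e-12)
  tab1 <- generate_ranking_dataset(40, noise_sd = 0, seed = 6)
  expect_identical(tab, tab1)
})

test_that("ranking noise is centred (CLT bound) and the design size is guarded", {
  n <- 200; nsd <- 0.05
  noisy <- generate_ranking_dataset(n, noise_sd = nsd, seed = 10)
  clean <- generate_ranking_dataset(n, noise_sd = 0, seed = 10)
  keep <- abs(noisy$os) < 1 & abs(clean$os) < 1  # unclipped rows only
  expect_lt(abs(mean(noisy$os[keep] - clean$os[keep])), 3 * nsd / sqrt(sum(keep)))
  expect_error(generate_ranking_dataset(5), "6")
})
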