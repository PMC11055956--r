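test_that("distance field obeys the domain rules and face-step distances", {
  dims <- c(8, 8, 8); sp <- c(1, 0.5, 0.5)
  cd31 <- array(FALSE, dims); cd31[4, 4, 4] <- TRUE
  vts <- array(TRUE, dims)
  df <- pv_distance_field(cd31, vts, sp)
  expect_true(is.na(df$field[4, 4, 4]))          # PV voxel excluded
  expect_equal(df$field[5, 4, 4], 1.0)           # one z step = dz
  expect_equal(df$field[4, 5, 4], 0.5)           # one y step = dy
  vts[1, , ] <- FALSE
  df2 <- pv_distance_field(cd31, vts, sp)
  expect_true(all(is.na(df2$field[1, , ])))      # out-of-VTS sentinel
})

test_that("distance field equals the brute-force nearest-PV search", {
  set.seed(31)
  for (seed in 1:5) {
    set.seed(seed)
    dims <- c(12, 13, 11); sp <- c(1.5, 0.8, 1.1)
    cd31 <- array(runif(prod(dims)) < 0.04, dims)
    if (!any(cd31)) cd31[3, 3, 3] <- TRUE
    vts <- array(runif(prod(dims)) < 0.8, dims)
    df <- pv_distance_field(cd31, vts, sp)
    oracle <- brute_edt(cd31, sp)
    dom <- vts & !cd31
    expect_equal(df$field[dom], oracle[dom], tolerance = 1e-9)
    expect_true(all(is.na(df$field[!dom])))
  }
})

test_that("distance histogram conserves the voxel count and summary stats", {
  pp <- small_phantom_prepped()
  cd31 <- pp$truth$masks$cd31
  vts <- pp$truth$masks$spheroid
  df <- pv_distance_field(cd31, vts, small_phantom()$stack$spacing)
  h <- distance_histogram(df, bin_width = 5)
  expect_equal(sum(h$histogram$count), sum(vts) - sum(cd31 & vts))
  v <- df$field[!is.na(df$field)]
  expect_equal(h$median_um, median(v))
  expect_equal(h$mean_um, mean(v))
})

test_that("axial PV in a cylindrical VTS gives the closed-form radial median", {
  # distance to the axis of a disk of radius R has median R/sqrt(2)
  sp <- c(2, 0.5, 0.5); R <- 20
  dims <- c(30, 101, 101)
  ctr <- c(50, 50)
  yy <- (seq_len(dims[2]) - 1 - ctr[1]) * sp[2]
  xx <- (seq_len(dims[3]) - 1 - ctr[2]) * sp[3]
  r2 <- outer(yy^2, xx^2, "+")
  vts <- array(rep(r2 <= R^2, each = dims[1]), dim = dims)
  cd31 <- array(FALSE, dims); cd31[, ctr[1] + 1, ctr[2] + 1] <- TRUE
  df <- pv_distance_field(cd31, vts, sp)
  h <- distance_histogram(df, bin_width = 1)
  expect_lt(abs(h$median_um - R / sqrt(2)), 0.5)
})

test_that("an empty PV mask yields the sentinel, with a warning", {
  dims <- c(8, 8, 8)
  vts <- array(TRUE, dims)
  expect_warning(df <- pv_distance_field(array(FALSE, dims), vts, c(1, 1, 1)),
                 "empty CD31")
  h <- distance_histogram(df, 5)
  expect_equal(nrow(h$histogram), 0)
  expect_identical(h$median_um, Inf)
})

test_that("supply index is the volume-over-distance ratio with guarded domain", {
  expect_equal(supply_index(10, 10), 1.0)
  expect_equal(supply_index(10, 20), supply_index(10, 10) / 2)
  expect_error(supply_index(0, 10), "relative CD31")
  expect_error(supply_index(150, 10), "relative CD31")
  expect_error(supply_index(10, 0), "median")
  expect_error(supply_index(10, Inf), "median")
})

test_that("supply index from the pipeline equals an independent recomputation", {
  sp <- c(1, 1, 1); dims <- c(40, 60, 60)
  vts <- ball_mask(dims, sp, c(20, 30, 30), 25)
  cd31 <- make_tube_mask(dims, sp, radius = 3, z0 = 20, y0 = 30,
                         x_from = 10, x_to = 50) & vts
  df <- pv_distance_field(cd31, vts, sp)
  h <- distance_histogram(df, 5)
  si <- supply_index(100 * sum(cd31 & vts) / sum(vts), h$median_um)
  # independent: brute-force distances over in-VTS non-PV voxels
  oracle <- brute_edt(cd31, sp)
  med <- median(oracle[vts & !cd31])
  si_oracle <- (100 * sum(cd31 & vts) / sum(vts)) / med
  expect_equal(si, si_oracle, tolerance = 1e-9)
})

test_that("cell distances: exact zero on target, analytic at sphere centre, brute force", {
  sp <- c(1, 0.8, 0.8); dims <- c(30, 40, 40)
  vts <- ball_mask(dims, sp, c(15, 14.4, 14.4), 12)
  cells <- data.frame(z = 15, y = 14.4, x = 14.4)  # exactly a voxel centre
  expect_equal(cell_distances(cells, vts, sp, "mask")$distances$distance_um, 0)
  surf <- cell_distances(cells, vts, sp, "surface")
  expect_lt(abs(surf$distances$distance_um - 12), 0.5 + max(sp) / 2)

  set.seed(9)
  tgt <- array(runif(prod(dims)) < 0.01, dims)
  pts <- data.frame(z = runif(6, 0, 29), y = runif(6, 0, 30), x = runif(6, 0, 30))
  got <- cell_distances(pts, tgt, sp, "mask")$distances$distance_um
  co <- coords_um <- vtsquant:::coords_to_um(arrayInd(which(tgt), dims), sp)
  want <- vapply(seq_len(6), function(i)
    sqrt(min((co[, 1] - pts$z[i])^2 + (co[, 2] - pts$y[i])^2 +
               (co[, 3] - pts$x[i])^2)), numeric(1))
  expect_equal(got, want, tolerance = 1e-9)
  # empty target: sentinel
  none <- cell_distances(pts, array(FALSE, dims), sp, "mask")
  expect_true(all(is.infinite(none$distances$distance_um)))
})

test_that("Col IV association partitions match direct voxel counting", {
  sp <- c(1, 1, 1); dims <- c(30, 40, 40)
  vts <- ball_mask(dims, sp, c(15, 20, 20), 16)
  cd31 <- make_tube_mask(dims, sp, radius = 3, z0 = 15, y0 = 20,
                         x_from = 8, x_to = 32) & vts
  d <- brute_edt(cd31, sp)
  sheath <- d > 0 & d <= 2.5 & vts                       # all within d_assoc=3
  # blob inside the VTS but > d_assoc away from the vessel axis
  far <- array(FALSE, dims); far[14:16, 29:31, 19:21] <- TRUE
  far <- far & vts & !sheath & d > 3
  expect_gt(sum(far), 0)
  ca <- coliv_association(sheath, cd31, vts, sp, d_assoc = 3)
  expect_equal(ca$associated_fraction, 1)
  ca2 <- coliv_association(sheath | far, cd31, vts, sp, d_assoc = 3)
  n_total <- sum(sheath | far)
  expect_equal(ca2$associated_fraction, sum(sheath) / n_total)
  expect_equal(ca2$associated_fraction + ca2$frac_in_vts_nonassociated +
                 ca2$frac_outside_vts, 1)
  # blob farther than d_assoc only
  ca3 <- coliv_association(far, cd31, vts, sp, d_assoc = 3)
  expect_equal(ca3$associated_fraction, 0)
  expect_warning(coliv_association(sheath, array(FALSE, dims), vts, sp), "empty")
})

test_that("distance field is 1-Lipschitz and contracts when PV grows", {
  set.seed(12)
  dims <- c(14, 14, 14); sp <- c(1, 1, 1)
  cd31 <- array(runif(prod(dims)) < 0.03, dims); cd31[7, 7, 7] <- TRUE
  vts <- array(TRUE, dims)
  f <- pv_distance_field(cd31, vts, sp)$field
  # adjacent in-domain voxels differ by at most the step length, per axis
  for (ax in 1:3) {
    n <- dims[ax]
    a <- switch(ax, f[-n, , ], f[, -n, ], f[, , -n])
    b <- switch(ax, f[-1, , ], f[, -1, ], f[, , -1])
    ok <- !is.na(a) & !is.na(b)
    expect_true(all(abs(a[ok] - b[ok]) <= sp[ax] + 1e-9))
  }
  more <- cd31; more[3, 10, 10] <- TRUE
  f2 <- pv_distance_field(more, vts, sp)$field
  both <- !is.na(f) & !is.na(f2)
  expect_true(all(f2[both] <= f[both] + 1e-9))
})

test_that("8-bit export quantizes within one step and flags out-of-domain as 255", {
  pp <- small_phantom_prepped()
  df <- pv_distance_field(pp$truth$masks$cd31, pp$truth$masks$spheroid,
                          small_phantom()$stack$spacing)
  q <- distance_field_8bit(df, max_um = 100)
  inb <- !is.na(df$field) & df$field <= 100
  expect_true(all(abs(q[inb] / 254 * 100 - df$field[inb]) <= 100 / 254 + 1e-9))
  expect_true(all(q[is.na(df$field)] == 255L))
})
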