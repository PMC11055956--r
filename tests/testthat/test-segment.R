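test_that("phantom CD31 segmentation overlaps ground truth (Dice >= 0.8)", {
  pp <- small_phantom_prepped()
  seg <- segment_channel(pp$stack, "cd31", pp$config, pp$vts$mask)
  tm <- pp$truth$masks$cd31
  dice <- 2 * sum(seg$mask & tm) / (sum(seg$mask) + sum(tm))
  expect_gte(dice, 0.8)
  # object bookkeeping: object volumes sum to the mask volume
  expect_equal(sum(seg$objects$volume_um3),
               sum(seg$mask) * voxel_volume(pp$stack))
})

test_that("a uniform supra-threshold channel yields one object filling the VTS", {
  sp <- c(2, 2, 2); dims <- c(50, 50, 50)
  vts <- ball_mask(dims, sp, c(49, 49, 49), 35)
  ch <- array(200, dim = dims)
  st <- vts_stack(list(cd31 = ch), sp)
  cfg <- pipeline_config(default_threshold = list(method = "absolute", value = 100),
                         surface_detail_channel = 0)
  seg <- segment_channel(st, "cd31", cfg, vts)
  expect_equal(nrow(seg$objects), 1)
  expect_equal(seg$objects$volume_um3, sum(vts) * prod(sp))
})

test_that("objects below min_object_volume are dropped", {
  sp <- c(1, 1, 1); dims <- c(20, 20, 20)
  ch <- array(0, dim = dims); ch[5:6, 5:10, 5:9] <- 200  # 60 um^3 blob
  st <- vts_stack(list(cd31 = ch), sp)
  cfg <- pipeline_config(default_threshold = list(method = "absolute", value = 100),
                         surface_detail_channel = 0, min_object_volume = 100)
  seg <- segment_channel(st, "cd31", cfg)
  expect_equal(nrow(seg$objects), 0)
  expect_false(any(seg$mask))
  cfg$min_object_volume <- 50
  expect_equal(nrow(segment_channel(st, "cd31", cfg)$objects), 1)
})

test_that("raising the threshold never grows the mask", {
  set.seed(17)
  ch <- array(runif(20^3, 0, 255), dim = c(20, 20, 20))
  st <- vts_stack(list(cd31 = ch), c(1, 1, 1))
  masks <- lapply(c(60, 120, 180), function(v)
    segment_channel(st, "cd31", pipeline_config(
      default_threshold = list(method = "absolute", value = v),
      min_object_volume = 0))$mask)
  expect_true(all(masks[[1]][masks[[2]]]))
  expect_true(all(masks[[2]][masks[[3]]]))
})

test_that("orb populations are detected completely and precisely", {
  pp <- small_phantom_prepped()
  for (role in c("cd11b", "hif1a")) {
    cs <- detect_cells(pp$stack, role, pp$config, pp$vts$mask)
    truth <- pp$truth$cell_centroids[[role]]
    expect_equal(nrow(cs$cells), nrow(truth))
    err <- vapply(seq_len(nrow(truth)), function(i)
      min(sqrt(colSums((t(as.matrix(cs$cells[, c("z", "y", "x")])) -
                          truth[i, ])^2))), numeric(1))
    expect_lt(max(err), 2)
  }
})

test_that("cell detection is deterministic and empty channels yield no cells", {
  pp <- small_phantom_prepped()
  a <- detect_cells(pp$stack, "cd11b", pp$config, pp$vts$mask)
  b <- detect_cells(pp$stack, "cd11b", pp$config, pp$vts$mask)
  expect_identical(a$cells, b$cells)

  flat <- vts_stack(list(cd11b = array(10, dim = c(16, 16, 16))), c(1, 1, 1))
  expect_equal(nrow(detect_cells(flat, "cd11b", pp$config)$cells), 0)
  expect_error(detect_cells(flat, "hif1a", pp$config), "not present")
})

test_that("object volume distribution preserves volume ratios and totals", {
  sp <- c(1, 1, 1); dims <- c(40, 40, 40)
  ch <- array(0, dim = dims)
  ch[2:11, 2:11, 2:11] <- 200          # 10^3 cube
  ch[20:39, 20:39, 20:39] <- 200       # 20^3 cube
  st <- vts_stack(list(cd11b = ch), sp)
  cfg <- pipeline_config(default_threshold = list(method = "absolute", value = 100),
                         surface_detail_channel = 0, min_object_volume = 0)
  seg <- segment_channel(st, "cd11b", cfg)
  ov <- object_volume_distribution(seg)
  expect_equal(nrow(ov$table), 2)
  expect_equal(ov$table$volume_um3[1] / ov$table$volume_um3[2], 8)
  expect_equal(sum(ov$table$volume_um3), sum(seg$mask) * prod(sp))

  empty <- segment_channel(vts_stack(list(cd11b = array(0, dims)), sp),
                           "cd11b", cfg)
  expect_equal(nrow(object_volume_distribution(empty)$table), 0)
})
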