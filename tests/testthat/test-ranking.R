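test_that("observer score aggregation is the plain mean with audit trail", {
  all_plus <- data.frame(observer = rep(1:4, each = 9),
                         treated_id = "t1", control_id = rep(c("c1", "c2", "c3"), 12),
                         grade = 1)
  expect_equal(aggregate_observer_score(all_plus)$os, 1)
  balanced <- data.frame(observer = 1:4, treated_id = "t", control_id = "c",
                         grade = c(0.5, -0.5, 0.5, -0.5))
  agg <- aggregate_observer_score(balanced)
  expect_equal(agg$os, 0)
  expect_equal(agg$n_ratings, 4)
  set.seed(2)
  mixed <- data.frame(observer = sample(1:4, 30, TRUE), treated_id = "t",
                      control_id = "c",
                      grade = sample(c(-1, -0.5, 0, 0.5, 1), 30, TRUE))
  expect_equal(aggregate_observer_score(mixed)$os, mean(mixed$grade))
  # Methods-style +-2 files are rescaled on import
  two <- data.frame(observer = 1, treated_id = "t", control_id = "c",
                    grade = c(2, -1, 0))
  expect_equal(aggregate_observer_score(two, scale = "two")$os, mean(c(1, -0.5, 0)))
  expect_error(aggregate_observer_score(two), "grades")
  expect_error(aggregate_observer_score(data.frame(observer = 1, treated_id = "a",
                                                   control_id = "a", grade = 0)),
               "itself")
})

test_that("OS correlations match the closed-form Pearson r and p from sums", {
  set.seed(77)
  n <- 17
  os <- runif(n, -1, 1)
  params <- data.frame(lin = 2 * os + 1, noisy = os + rnorm(n, 0, 0.4),
                       flat = rep(3, n))
  tab <- correlate_os_parameters(os, params)
  expect_equal(tab$r[tab$parameter == "lin"], 1, tolerance = 1e-12)
  expect_equal(tab$ci_hi[tab$parameter == "lin"], 1, tolerance = 1e-9)
  expect_identical(tab$flag[tab$parameter == "flat"], "undefined")
  # closed form from raw sums
  x <- params$noisy
  r_man <- (n * sum(x * os) - sum(x) * sum(os)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(os^2) - sum(os)^2))
  t_man <- r_man * sqrt((n - 2) / (1 - r_man^2))
  p_man <- 2 * pt(-abs(t_man), n - 2)
  expect_equal(tab$r[tab$parameter == "noisy"], r_man, tolerance = 1e-12)
  expect_equal(tab$p[tab$parameter == "noisy"], p_man, tolerance = 1e-12)
})

test_that("the published calibration gives 0.93 at identity ratios", {
  expect_equal(compute_vei(c(1, 1, 1)), 0.93, tolerance = 1e-12)
  # small-ratio limit is dominated by the negative SI term
  lim <- compute_vei(data.frame(rV = 1e-9, rSI = 1, rSN = 1e-9))
  expect_equal(lim, -0.11, tolerance = 1e-5)
  # independent power-sum evaluation at (2, 1, 1)
  expect_equal(compute_vei(c(2, 1, 1)),
               0.6 * 2^0.65 - 0.11 + 0.44, tolerance = 1e-12)
  expect_error(compute_vei(c(-1, 1, 1)), "positive")
  expect_error(vei_model(y2 = 0), "exponents")
})

test_that("VEI is monotone in each ratio with the published signs", {
  r <- seq(0.3, 3, length.out = 20)
  up_v <- compute_vei(data.frame(rV = r, rSI = 1, rSN = 1))
  dn_si <- compute_vei(data.frame(rV = 1, rSI = r, rSN = 1))
  up_sn <- compute_vei(data.frame(rV = 1, rSI = 1, rSN = r))
  expect_true(all(diff(up_v) > 0))
  expect_true(all(diff(dn_si) < 0))
  expect_true(all(diff(up_sn) > 0))
})

test_that("noiseless self-generated data is recovered exactly by the fit", {
  truth <- vei_model(x1 = 0.5, x2 = -0.2, x3 = 0.3,
                     y1 = 0.8, y2 = 1.2, y3 = 2)
  tab <- generate_ranking_dataset(60, truth, noise_sd = 0, seed = 14)
  fit <- suppressMessages(fit_vei_model(tab))
  expect_lt(max(abs(unlist(fit$model) - unlist(truth))), 1e-3)
  expect_lt(fit$residual_rms, 1e-6)
})

test_that("a ratio table without variation is a degenerate design", {
  tab <- data.frame(rV = rep(1, 10), rSI = rep(1, 10), rSN = rep(1, 10),
                    os = rep(0.93, 10))
  expect_error(fit_vei_model(tab), "degenerate")
  expect_error(fit_vei_model(generate_ranking_dataset(8, noise_sd = 0, seed = 1)[1:4, ]),
               "6")
})

test_that("effect indices are bounded, antisymmetric and zero at no change", {
  base <- c(cd31_volume_rel = 0.05, pv_total_length_um = 900,
            tumor_cell_density_mm3 = 4e5, tumor_volume_rel = 0.5,
            fibroblast_cell_density_mm3 = 5e5, fibroblast_volume_rel = 0.45)
  same <- effect_indices(base, base)
  expect_equal(unlist(same), c(anti_angiogenic = 0, vascular_disruptive = 0,
                               tumor_cell = 0, fibroblast = 0))
  # asymptotes of the bounded map
  expect_equal(bounded_ratio_index(1e12), 1, tolerance = 1e-9)
  expect_equal(bounded_ratio_index(1e-12), -1, tolerance = 1e-9)
  for (r in c(0.2, 0.5, 2, 7))
    expect_equal(bounded_ratio_index(r), -bounded_ratio_index(1 / r),
                 tolerance = 1e-12)
  # sign conventions: shrinking vasculature scores positive
  shrunk <- base; shrunk["cd31_volume_rel"] <- 0.02
  shrunk["pv_total_length_um"] <- 300
  ei <- effect_indices(shrunk, base)
  expect_gt(ei$anti_angiogenic, 0)
  expect_gt(ei$vascular_disruptive, 0)
  # growing tumor compartment scores positive
  grown <- base; grown["tumor_cell_density_mm3"] <- 8e5
  grown["tumor_volume_rel"] <- 0.7
  expect_gt(effect_indices(grown, base)$tumor_cell, 0)
  expect_error(effect_indices(base, replace(base, 1, 0)), "positive")
  bad <- base[-1]
  expect_error(effect_indices(bad, base), "need entries")
})
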