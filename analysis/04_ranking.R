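#!/usr/bin/env Rscript
# Stage 4 - observer-score calibration of the Vascular Effect Index.
#
# On the synthetic observer-score dataset from stage 1: correlate the
# score with the three pseudovessel ratios, run the stepwise calibration
# (OLS weights, then bounded nonlinear least squares), compare recovered
# coefficients with the generating model, score held-out groups, and
# derive compartmental effect indices for an example treated/control
# contrast.

suppressPackageStartupMessages(library(vtsquant))
dir.create("results", showWarnings = FALSE)

tab <- if (file.exists("results/ranking_dataset.csv")) {
  read.csv("results/ranking_dataset.csv")
} else {
  generate_ranking_dataset(200, vei_model(), noise_sd = 0.02, seed = 1L)
}

ct <- correlate_os_parameters(tab$os, tab[c("rV", "rSI", "rSN")])
write.csv(ct, "results/os_correlations.csv", row.names = FALSE)
message("OS correlations (Pearson r, 95% CI):")
for (i in seq_len(nrow(ct)))
  message(sprintf("  %-4s r = %+.3f [%.3f, %.3f], p = %.2g",
                  ct$parameter[i], ct$r[i], ct$ci_lo[i], ct$ci_hi[i], ct$p[i]))

train <- tab[1:150, ]; holdout <- tab[151:200, ]
fit <- fit_vei_model(train)
m <- fit$model
gen <- vei_model()
message(sprintf("Stage-1 OLS weights: x1=%.3f x2=%.3f x3=%.3f",
                fit$stage1["x1"], fit$stage1["x2"], fit$stage1["x3"]))
message(sprintf("Stage-2 fit:  x1=%.3f y1=%.3f x2=%.3f y2=%.3f x3=%.3f y3=%.3f",
                m$x1, m$y1, m$x2, m$y2, m$x3, m$y3))
message(sprintf("Generating model: x1=%.3f y1=%.3f x2=%.3f y2=%.3f x3=%.3f y3=%.3f",
                gen$x1, gen$y1, gen$x2, gen$y2, gen$x3, gen$y3))
jsonlite::write_json(unclass(m), "results/vei_model.json", auto_unbox = TRUE,
                     digits = NA)

pred <- compute_vei(holdout, m)
held <- abs(holdout$os) < 1
message(sprintf("Held-out VEI vs OS: Pearson r = %.3f (%d uncensored groups)",
                cor(pred[held], holdout$os[held]), sum(held)))
write.csv(data.frame(group = holdout$group, os = holdout$os, vei = pred),
          "results/vei_holdout.csv", row.names = FALSE)

# example compartmental effect indices: an anti-angiogenic-like contrast
control <- c(cd31_volume_rel = 0.050, pv_total_length_um = 1800,
             tumor_cell_density_mm3 = 4.2e5, tumor_volume_rel = 0.50,
             fibroblast_cell_density_mm3 = 4.6e5, fibroblast_volume_rel = 0.45)
treated <- c(cd31_volume_rel = 0.021, pv_total_length_um = 700,
             tumor_cell_density_mm3 = 3.9e5, tumor_volume_rel = 0.46,
             fibroblast_cell_density_mm3 = 5.1e5, fibroblast_volume_rel = 0.49)
ei <- effect_indices(treated, control)
message(sprintf(paste0("Example effect indices: anti-angiogenic %+.2f, ",
                       "vascular-disruptive %+.2f, tumor-cell %+.2f, fibroblast %+.2f"),
                ei$anti_angiogenic, ei$vascular_disruptive, ei$tumor_cell,
                ei$fibroblast))
write.csv(as.data.frame(ei), "results/effect_indices_example.csv",
          row.names = FALSE)
message("Wrote results/os_correlations.csv, vei_model.json, vei_holdout.csv, effect_indices_example.csv")
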