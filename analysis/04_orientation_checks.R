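#!/usr/bin/env Rscript
# Step 4 — molecular-orientation controls.
#
# The 1130 cm^-1 band strengthens under wear, but it is also sensitive to
# molecular chain orientation, which would bias the all-trans and
# ortho-trans results. Two controls mirror the experimental protocol:
#   1. the A1130/A1065 area ratio before vs after wear (stable ratio =>
#      isotropic surface);
#   2. coincidence of spectra recorded under parallel X(YY)X and crossed
#      X(ZY)X polarizations, judged against a noise-only null simulation.
#
# Outputs: results/tables/orientation_ratio.csv, polarization_null.csv.

library(ramanpe)
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)

# 1. orientation ratio across the simulated cohort
scenario <- default_study_scenario(seed = 20260930L)
rep <- run_analysis(simulate_study(scenario))
orat <- aggregate(ratio_1130_1065 ~ material + state, rep$per_spectrum,
                  function(v) c(mean = mean(v), sd = sd(v)))
cat("A1130/A1065 ratio by group and state (conformation changes move it;\n")
cat("the polarization control below distinguishes orientation):\n")
print(orat, digits = 3)
write.csv(do.call(data.frame, orat), "results/tables/orientation_ratio.csv",
          row.names = FALSE)

# 2. polarization coincidence: noise-only null vs a synthetic oriented case
areas <- invert_composition(phase_targets(0.59, 0.25, 0.70), 20000)
null_metric <- vapply(1:100, function(i) {
  yy <- render_spectrum(areas, baseline = c(50, -10),
                        noise = noise_spec(scale = 1), seed = i)
  zy <- render_spectrum(areas, baseline = c(50, -10),
                        noise = noise_spec(scale = 1), seed = 10000 + i)
  compare_polarizations(yy, zy)$metric
}, 1.0)
oriented <- band_areas(areas$A_1416, areas$A_1085, areas$A_1295_1305,
                       1.5 * areas$A_1130, areas$A_1065)
m_orient <- compare_polarizations(
  render_spectrum(areas, baseline = c(50, -10), noise = noise_spec(scale = 1),
                  seed = 1),
  render_spectrum(oriented, baseline = c(50, -10), noise = noise_spec(scale = 1),
                  seed = 10001))$metric

cat(sprintf("\nNoise-only coincidence metric: median %.4f, 99th pct %.4f (threshold 0.05)\n",
            median(null_metric), quantile(null_metric, 0.99)))
cat(sprintf("Metric with a 1.5x stronger 1130 cm^-1 band in one geometry: %.4f\n",
            m_orient))
write.csv(data.frame(replicate = seq_along(null_metric), metric = null_metric),
          "results/tables/polarization_null.csv", row.names = FALSE)
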