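#!/usr/bin/env Rscript

# Step 2: measure every phantom.
#
# Runs the per-patient measurement procedure over the simulated cohort: on
# the slice with the largest lesion extent, measure the maximum diameter a
# and the maximal orthogonal diameter b, count lesion-bearing slices, and
# derive the od-value, the od-based volume, the ABC/2 volume, the
# gold-standard voxel volume, and all four threshold classifications.
# Requires analysis/01_simulate_cohort.R to have been run first.

suppressPackageStartupMessages(library(strokevol))

catalog_path <- "scratch/cohort/catalog.csv"
if (!file.exists(catalog_path))
  stop("run analysis/01_simulate_cohort.R first (missing ", catalog_path, ")")

run <- run_cohort(catalog_path)
write.csv(run$results, "results/per_patient_results.csv", row.names = FALSE)

r <- run$results[!run$results$excluded, ]
cat(sprintf("Measured %d patients (%d excluded)\n",
            run$manifest$n_evaluated, run$manifest$n_excluded))
cat(sprintf("Median a = %.1f cm, b = %.1f cm, od-value = %.1f\n",
            median(r$a_cm), median(r$b_cm), median(r$od_value)))
cat(sprintf(
  "Median volumes: manual %.1f ml | od-based %.1f ml | ABC/2 %.1f ml\n",
  median(r$manual_volume_ml), median(r$od_volume_ml),
  median(r$abc2_volume_ml)))
cat(sprintf("Manual volumetry: %d lesions >70 ml, %d >100 ml\n",
            sum(r$truth_70), sum(r$truth_100)))
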