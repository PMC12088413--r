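#!/usr/bin/env Rscript
# Step 5 — end-to-end pipeline run and headline summary.
#
# Repeats the whole analysis through the single orchestration entry point
# (run_pipeline) so the staged scripts and the pipeline agree, writes the
# full report under results/report/, and prints the headline quantities,
# including the per-chromosome-pair crossover rates.

library(meioclock)

tab <- read.csv("results/cells_truth.csv")
controls <- read.csv("results/controls.csv")
cfg <- pipeline_config(
  input_mode = "table",
  cells = truth_to_measurements(tab),
  control_levels = controls$accumulation_pct,
  diploid_label = "DIP-2X",
  diakinesis_means = c(`DIP-2X` = 10, `NEO-4X` = 22, `HYB-4X` = 18,
                       `EST-4X` = 17),
  seed = 20250925L,
  output_dir = "results/report")
rep <- run_pipeline(cfg)

message(sprintf("cells: %d analyzed, %d excluded (partition of %d)",
                nrow(rep$cells_analyzed), nrow(rep$exclusions),
                nrow(rep$measurements)))
message(sprintf("decay model: R2c = %.3f, sigma_u = %.3f",
                rep$fits$decay$r2_conditional, rep$fits$decay$sigma_u))
on <- rep$predictions$onset_asynapsis
message("onset asynapsis (um): ",
        paste(sprintf("%s %.0f", on$genotype, on$mean_um), collapse = ", "))
message(sprintf("plateau cutoff: %s%%; late-pachytene cutoffs: %s",
                rep$cutoffs$plateau$cutoff_pct,
                paste(sprintf("%s>%d", names(rep$cutoffs$late_pachytene),
                              vapply(rep$cutoffs$late_pachytene, `[[`, 0,
                                     "cutoff_pct")), collapse = ", ")))
message(sprintf("crossovers per chromosome pair: EST-4X %.2f, 2X %.2f",
                crossovers_per_pair(17, chromosome_pairs(8, 4)),
                crossovers_per_pair(10, chromosome_pairs(8, 2))))
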