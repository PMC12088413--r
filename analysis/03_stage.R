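#!/usr/bin/env Rscript
# Step 3 — calibrate the accumulation-level staging cutoffs.
#
# Background cutoff from the control cells (the maximum level a cell with
# no true signal can register), filtering of the analysis set with the
# exclusion ledger, diploid axis doubling, and the per-genotype
# late-pachytene cutoffs against diakinesis crossover means. Outputs:
# results/cells_staged.csv, results/exclusions.csv, results/cutoffs.csv.

library(meioclock)

tab <- read.csv("results/cells_truth.csv")
controls <- read.csv("results/controls.csv")
cells <- truth_to_measurements(tab)

bg <- background_cutoff(controls$accumulation_pct)
message(sprintf("background cutoff: %.1f%% (control mean %.1f%%)",
                bg$cutoff_pct,
                bg$trace$value[bg$trace$statistic == "mean"]))

flt <- filter_by_cutoff(cells, bg$cutoff_pct)
message(sprintf("retained %d of %d cells (%d below cutoff)",
                nrow(flt$retained), nrow(cells), nrow(flt$excluded)))
staged <- normalize_diploid(flt$retained, "DIP-2X")
write.csv(staged, "results/cells_staged.csv", row.names = FALSE)
write.csv(flt$excluded, "results/exclusions.csv", row.names = FALSE)

diak <- c(`DIP-2X` = 10, `NEO-4X` = 22, `HYB-4X` = 18, `EST-4X` = 17)
lp <- late_pachytene_cutoffs(staged, diak)
cut_tab <- data.frame(
  genotype = c("all", names(lp)),
  rule = c("background", rep("late_pachytene", length(lp))),
  cutoff_pct = c(bg$cutoff_pct, vapply(lp, `[[`, 0, "cutoff_pct")))
write.csv(cut_tab, "results/cutoffs.csv", row.names = FALSE)
message("late-pachytene cutoffs (%):")
for (g in names(lp)) message(sprintf("  %-8s > %d", g, lp[[g]]$cutoff_pct))
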