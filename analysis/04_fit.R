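#!/usr/bin/env Rscript
# Step 4 — fit the genotype-comparison models.
#
# The exponential-decay Gamma-GLMM of asynapsis against the HEI10
# accumulation clock (plant random intercepts), onset predictions and
# decay-exponent contrasts, the synapsis-plateau search, the coalignment
# and elongation count models, and the crossover-vs-asynapsis model on the
# late-pachytene subset. Outputs under results/: decay_fit.json,
# onset_predictions.csv, decay_contrasts.csv, plateau_trace.csv,
# count_models.json.

library(meioclock)

staged <- read.csv("results/cells_staged.csv")
attr(staged, "ploidy_normalized") <- TRUE
cuts <- read.csv("results/cutoffs.csv")
bg_cut <- cuts$cutoff_pct[cuts$rule == "background"][1]

fit <- fit_gamma_decay(staged)
print(fit)
jsonlite::write_json(
  list(beta0 = as.list(fit$beta0), beta1 = as.list(fit$beta1),
       sigma_u = fit$sigma_u, gamma_shape = fit$gamma_shape,
       loglik = fit$loglik, r2_marginal = fit$r2_marginal,
       r2_conditional = fit$r2_conditional,
       n_cells = fit$n_cells, n_plants = fit$n_plants),
  "results/decay_fit.json", auto_unbox = TRUE, digits = NA)

onset <- predict_asynapsis(fit, bg_cut)
write.csv(onset, "results/onset_predictions.csv", row.names = FALSE)
message("predicted asynapsis at the onset of accumulation (um):")
for (i in seq_len(nrow(onset)))
  message(sprintf("  %-8s %6.1f [%5.1f, %6.1f]", onset$genotype[i],
                  onset$mean_um[i], onset$lo_um[i], onset$hi_um[i]))

ctr <- list()
for (g in fit$genotypes) {
  cv <- setNames(rep(0, length(fit$coefficients)), names(fit$coefficients))
  cv[fit$coef_idx$slope[[g]]] <- 1
  ctr[[paste0(g, "_decay_vs_0")]] <- cv
}
ct <- wald_contrasts(fit, ctr)
write.csv(ct, "results/decay_contrasts.csv", row.names = FALSE)
message("decay-exponent Wald tests (Holm-adjusted):")
for (i in seq_len(nrow(ct)))
  message(sprintf("  %-20s beta1 = %+.4f  p = %.3g", ct$label[i],
                  ct$estimate[i], ct$p_holm[i]))

plat <- plateau_cutoff(staged)
write.csv(plat$trace, "results/plateau_trace.csv", row.names = FALSE)
message(sprintf("synapsis plateau cutoff: %s%%",
                ifelse(is.na(plat$cutoff_pct), "none found",
                       plat$cutoff_pct)))

# count models: coalignment in the assessable window, elongation in
# zygotene, crossovers vs asynapsis in late pachytene
win <- staged[staged$asy1_length_um >= 30 & staged$asy1_length_um <= 150, ]
par_fit <- fit_count_model(win, "n_parallel", covariate = "asy1_length_um",
                           family = "nbinom", random_intercept = "plant",
                           covariate_scale = 100)
lp_cut <- setNames(cuts$cutoff_pct[cuts$rule == "late_pachytene"],
                   cuts$genotype[cuts$rule == "late_pachytene"])
late <- do.call(rbind, lapply(names(lp_cut), function(g)
  staged[staged$genotype == g & staged$accumulation_pct > lp_cut[[g]], ]))
co_fit <- fit_co_asynapsis(late)
message(sprintf("coalignment model: R2 = %.2f; crossover~asynapsis: slope %.4g (p = %.3g, R2 = %.2f)",
                par_fit$r2_conditional, co_fit$coefficients[2],
                co_fit$slope_p, co_fit$r2_marginal))
jsonlite::write_json(
  list(parallels = list(coefficients = as.list(par_fit$coefficients),
                        theta = par_fit$theta, sigma_u = par_fit$sigma_u,
                        r2 = par_fit$r2_conditional),
       co_asynapsis = list(coefficients = as.list(co_fit$coefficients),
                           slope_p = co_fit$slope_p,
                           r2 = co_fit$r2_marginal, n = co_fit$n)),
  "results/count_models.json", auto_unbox = TRUE, digits = NA)
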