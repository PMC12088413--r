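# Shared fixtures: small rendering volumes and parameter sets keep the unit
# tests fast; the acceptance suite uses the full-size defaults.

small_spec <- function(seed = 1L, noise = FALSE) {
  render_spec(shape = c(48L, 160L, 160L),
              shot_noise = noise, read_noise_sd = if (noise) 3 else 0,
              seed = as.integer(seed))
}

small_truth <- function(cell_id = "t", H = 60, asyn = 30, zyp = 40,
                        n_prom = 8L, n_par = 1L, n_irr = 2L,
                        n_pun = 2L, n_elo = 4L) {
  data.frame(cell_id = cell_id, plant_id = "p1", genotype = "G1",
             H_true = H, asynapsis_true = asyn, zyp1_total_true = zyp,
             n_prominent_true = n_prom, n_parallel_true = n_par,
             n_irregular_true = n_irr, n_punctate_true = n_pun,
             n_elongated_true = n_elo,
             dispersed_fraction_true = 1 - H / 100,
             stringsAsFactors = FALSE)
}

two_genotypes <- function(beta1 = c(-0.03, 0), plant_sd = 0.15,
                          gamma_shape = 3) {
  list(genotype_params("GA", beta0 = log(40) - beta1[1] * 12,
                       beta1 = beta1[1], plant_sd = plant_sd,
                       gamma_shape = gamma_shape),
       genotype_params("GB", beta0 = log(150), beta1 = beta1[2],
                       plant_sd = plant_sd, gamma_shape = gamma_shape))
}

# change-point population with a known synapsis plateau at h_star
plateau_params <- function() {
  list(genotype_params("P1", beta0 = log(5) + 0.15 * 50, beta1 = -0.15,
                       plant_sd = 0.1, gamma_shape = 6),
       genotype_params("P2", beta0 = log(8) + 0.15 * 50, beta1 = -0.15,
                       plant_sd = 0.1, gamma_shape = 6))
}

# paint a thin tube into an empty ASY1 channel and finish it like a render
painted_tube_stack <- function(pts, spec, radius_um = 0.08) {
  ns <- asNamespace("meioclock")
  arr <- array(0, spec$shape)
  arr[ns$tube_voxels(pts, radius_um, spec$shape, spec$voxel_size)] <- 1500
  ns$finish_channel(arr, spec)
}
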