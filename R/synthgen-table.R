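#' Simulate a tabular cell population with known ground truth
#'
#' Draws per-cell ground truth with exactly the statistical structure the
#' inference layer assumes: the HEI10 accumulation level `H_true` is uniform
#' over `h_range`; asynapsis is Gamma-distributed around
#' `exp(beta0 + beta1 * H + u_plant)` with per-plant random intercepts
#' `u_plant ~ N(0, plant_sd^2)` and shape `gamma_shape`; count variables
#' (crossover foci, prominent foci, coaligned parallels, irregulars, punctate
#' and elongated ZYP1 segments, quadrivalents, univalents) are drawn from
#' Poisson / negative-binomial models with the link functions documented in
#' [genotype_params()].
#'
#' One master seed is split into per-plant and per-cell substreams, so any
#' cell is reproducible independently of how many cells precede it.
#'
#' @param params list of [genotype_params()] objects (one per genotype).
#' @param plants_per_genotype number of plants per genotype (>= 1).
#' @param cells_per_plant number of cells per plant (>= 1).
#' @param h_range accumulation-level interval to sample `H_true` from
#'   (subset of `[0, 100]`).
#' @param seed master integer seed.
#' @param h_plateau optional change point (accumulation %); when given, the
#'   decay acts on `min(H, h_plateau)` so the mean asynapsis flattens above
#'   it (used to construct populations with a known synapsis plateau).
#' @return `data.frame` with one row per cell: identifiers (`cell_id`,
#'   `plant_id`, `genotype`) and ground-truth fields (`H_true`,
#'   `asynapsis_true`, `zyp1_total_true`, `n_prominent_true`,
#'   `dispersed_fraction_true`, `n_parallel_true`, `n_irregular_true`,
#'   `n_punctate_true`, `n_elongated_true`, `n_quadrivalent_true`,
#'   `n_univalent_true`, `n_co_true`).
#' @examples
#' tab <- simulate_cell_table(default_genotype_params()[1:2],
#'                            plants_per_genotype = 2, cells_per_plant = 5,
#'                            seed = 7)
#' head(tab)
#' @export
simulate_cell_table <- function(params, plants_per_genotype, cells_per_plant,
                                h_range = c(0, 100), seed = 1L,
                                h_plateau = NULL) {
  if (inherits(params, "genotype_params")) params <- list(params)
  for (p in params) {
    if (!inherits(p, "genotype_params"))
      stop("simulate_cell_table: 'params' must be genotype_params objects")
  }
  if (plants_per_genotype < 1 || cells_per_plant < 1)
    stop("simulate_cell_table: counts must be >= 1")
  if (length(h_range) != 2 || h_range[1] < 0 || h_range[2] > 100 ||
      h_range[1] > h_range[2])
    stop("simulate_cell_table: 'h_range' must lie within [0, 100]")
  if (!is.null(h_plateau) && (!is.finite(h_plateau) || h_plateau < 0))
    stop("simulate_cell_table: 'h_plateau' must be a nonnegative number")

  rows <- vector("list", length(params) * plants_per_genotype * cells_per_plant)
  ri <- 0L
  plant_global <- 0L
  cell_global <- 0L
  for (p in params) {
    for (pl in seq_len(plants_per_genotype)) {
      plant_global <- plant_global + 1L
      plant_id <- sprintf("%s_p%d", p$name, pl)
      set.seed(substream_seed(seed * 7L + 1L, plant_global))
      u <- rnorm(1, 0, p$plant_sd)
      for (cl in seq_len(cells_per_plant)) {
        cell_global <- cell_global + 1L
        set.seed(substream_seed(seed, cell_global))
        H <- runif(1, h_range[1], h_range[2])
        Heff <- if (is.null(h_plateau)) H else min(H, h_plateau)
        mu <- exp(p$beta0 + p$beta1 * Heff + u)
        asyn <- rgamma(1, shape = p$gamma_shape, rate = p$gamma_shape / mu)
        # respect the physical axis budget; resampling keeps truncation rare
        tries <- 0L
        while (asyn > p$total_axis_um && tries < 50L) {
          asyn <- rgamma(1, shape = p$gamma_shape, rate = p$gamma_shape / mu)
          tries <- tries + 1L
        }
        asyn <- min(asyn, p$total_axis_um)
        zyp1 <- (p$total_axis_um - asyn) / 2
        n_co <- rpois(1, exp(p$co_intercept + p$co_slope * asyn))
        n_prom <- n_co + rpois(1, 15 * exp(-H / 25))
        n_par <- rcount(1, exp(p$parallel_intercept +
                                 p$parallel_slope * asyn / 100), p$nb_theta)
        n_irr <- rpois(1, 0.5 + asyn / 60)
        n_pun <- rpois(1, p$punctate_mean)
        n_elo <- rpois(1, max(p$elong_intercept + p$elong_slope * zyp1, 0))
        n_quad <- rcount(1, p$quad_mean, p$nb_theta)
        n_uni <- rcount(1, p$uni_mean, p$nb_theta)
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          cell_id = sprintf("%s_c%d", plant_id, cl),
          plant_id = plant_id, genotype = p$name,
          H_true = H, asynapsis_true = asyn, zyp1_total_true = zyp1,
          n_prominent_true = n_prom,
          dispersed_fraction_true = 1 - H / 100,
          n_parallel_true = n_par, n_irregular_true = n_irr,
          n_punctate_true = n_pun, n_elongated_true = n_elo,
          n_quadrivalent_true = n_quad, n_univalent_true = n_uni,
          n_co_true = n_co,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Negative-binomial count draw with mean mu and dispersion theta;
# theta = Inf is the Poisson limit.
rcount <- function(n, mu, theta) {
  if (mu <= 0) return(rep(0L, n))
  if (!is.finite(theta)) rpois(n, mu) else rnbinom(n, size = theta, mu = mu)
}
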