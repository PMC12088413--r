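#' Genotype-level simulation parameters
#'
#' Bundles the parameters that govern one genotype's synthetic cell
#' population: the exponential decay of asynapsis against HEI10 accumulation
#' (`asynapsis ~ Gamma(mean = exp(beta0 + beta1 * H + u_plant))`), the
#' per-plant random intercept, and the count-variable models (crossover foci,
#' coaligned parallels, elongated ZYP1 segments, quadrivalents, univalents).
#'
#' @param name genotype label.
#' @param beta0 log-micrometre asynapsis at accumulation level 0 (intercept of
#'   the log-link decay model, on the raw measured scale for the genotype).
#' @param beta1 decay exponent per accumulation percentage point (<= 0 in the
#'   decaying regime; exactly 0 for a stalled genotype).
#' @param plant_sd standard deviation of the per-plant random intercept on the
#'   log scale (>= 0).
#' @param gamma_shape Gamma shape of the asynapsis noise (> 0; larger = less
#'   dispersed around the mean curve).
#' @param co_intercept,co_slope crossover-focus count model, log link:
#'   `n_co ~ Poisson(exp(co_intercept + co_slope * asynapsis_um))`.
#' @param parallel_intercept,parallel_slope coaligned-parallel count model,
#'   log link on ASY1 length in units of 100 um:
#'   `n_parallel ~ NB(exp(parallel_intercept + parallel_slope * asy1/100))`.
#' @param elong_intercept,elong_slope elongated-ZYP1-segment count model,
#'   identity link on total ZYP1 length:
#'   `n_elongated ~ Poisson(elong_intercept + elong_slope * zyp1_um)` (the
#'   intercept is the initial number of elongated stretches at zero ZYP1, the
#'   slope the increase per micrometre of synaptonemal complex).
#' @param quad_mean,uni_mean expected quadrivalents / univalents per metaphase
#'   I cell (negative binomial with dispersion `nb_theta`).
#' @param punctate_mean expected punctate (initiation-site) ZYP1 signals per
#'   early-zygotene cell.
#' @param nb_theta negative-binomial dispersion for the overdispersed counts
#'   (`Inf` recovers Poisson).
#' @param total_axis_um total ASY1-stainable axis length per nucleus at zero
#'   synapsis, in micrometres (upper bound for asynapsis).
#'
#' @return a `genotype_params` list.
#' @seealso [default_genotype_params()], [simulate_cell_table()]
#' @export
genotype_params <- function(name,
                            beta0, beta1,
                            plant_sd = 0.15,
                            gamma_shape = 3,
                            co_intercept = log(15), co_slope = 0.0015,
                            parallel_intercept = 0.7, parallel_slope = 0.69,
                            elong_intercept = 1.5, elong_slope = 0.10,
                            quad_mean = 0, uni_mean = 0,
                            punctate_mean = 8,
                            nb_theta = 5,
                            total_axis_um = 320) {
  p <- list(name = as.character(name), beta0 = beta0, beta1 = beta1,
            plant_sd = plant_sd, gamma_shape = gamma_shape,
            co_intercept = co_intercept, co_slope = co_slope,
            parallel_intercept = parallel_intercept,
            parallel_slope = parallel_slope,
            elong_intercept = elong_intercept, elong_slope = elong_slope,
            quad_mean = quad_mean, uni_mean = uni_mean,
            punctate_mean = punctate_mean, nb_theta = nb_theta,
            total_axis_um = total_axis_um)
  for (nm in setdiff(names(p), "name")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) ||
        (!is.finite(v) && nm != "nb_theta"))
      stop("genotype_params: parameter '", nm, "' must be a finite number")
  }
  if (p$gamma_shape <= 0) stop("genotype_params: 'gamma_shape' must be > 0")
  if (p$plant_sd < 0) stop("genotype_params: 'plant_sd' must be >= 0")
  if (p$total_axis_um <= 0) stop("genotype_params: 'total_axis_um' must be > 0")
  if (p$quad_mean < 0 || p$uni_mean < 0)
    stop("genotype_params: 'quad_mean'/'uni_mean' must be >= 0")
  class(p) <- "genotype_params"
  p
}

#' Default genotype parameter sets
#'
#' Four parameter bundles emulating the study system: a diploid (`DIP-2X`), a
#' first-generation colchicine-induced neo-tetraploid (`NEO-4X`) whose
#' synapsis is stalled (zero decay exponent, ~200 um asynapsis throughout), an
#' established tetraploid (`EST-4X`) with efficient synapsis (low onset
#' asynapsis, steepest decay), and their F1 hybrid (`HYB-4X`) with
#' intermediate values. Decay exponents are (-0.030, 0, -0.020, -0.035) per
#' accumulation point for 2X/NEO/HYB/EST with a plant random-intercept SD of
#' 0.15; intercepts are set so the mean asynapsis at the 12% accumulation
#' onset is ~25 um (2X, raw diploid scale: ~50 um after ploidy doubling),
#' ~200 um (NEO), ~30 um (HYB) and ~8 um (EST). Crossover-focus intercepts
#' reproduce mean counts near 10/22/18/17 at stage-typical asynapsis.
#'
#' @return named list of four [genotype_params()] objects.
#' @export
default_genotype_params <- function() {
  list(
    `DIP-2X` = genotype_params(
      "DIP-2X", beta0 = log(25) + 0.030 * 12, beta1 = -0.030,
      co_intercept = log(10) - 0.0015 * 6,
      parallel_intercept = log(4) - 0.69,
      elong_intercept = 1.5, elong_slope = 0.10,
      quad_mean = 0, uni_mean = 0, total_axis_um = 160),
    `NEO-4X` = genotype_params(
      "NEO-4X", beta0 = log(200), beta1 = 0,
      co_intercept = log(22) - 0.0015 * 200,
      parallel_intercept = log(2) - 0.69,
      elong_intercept = 3, elong_slope = 0.05,
      quad_mean = 3.0, uni_mean = 0.9, total_axis_um = 320),
    `HYB-4X` = genotype_params(
      "HYB-4X", beta0 = log(30) + 0.020 * 12, beta1 = -0.020,
      co_intercept = log(18) - 0.0015 * 12,
      parallel_intercept = log(4) - 0.69,
      elong_intercept = 2, elong_slope = 0.08,
      quad_mean = 1.8, uni_mean = 0.1, total_axis_um = 320),
    `EST-4X` = genotype_params(
      "EST-4X", beta0 = log(8) + 0.035 * 12, beta1 = -0.035,
      co_intercept = log(17) - 0.0015 * 2,
      parallel_intercept = log(4) - 0.69,
      elong_intercept = 1, elong_slope = 0.12,
      quad_mean = 0.8, uni_mean = 0.1, total_axis_um = 320)
  )
}

#' Rendering specification for synthetic stacks
#'
#' Geometry, optics and noise of the synthetic microscope. The default volume
#' is 64 x 256 x 256 voxels at (0.125, 0.04, 0.04) um (z, y, x): 0.125 um
#' optical sectioning with typical structured-illumination lateral sampling.
#'
#' @param shape integer triplet of voxel counts (z, y, x).
#' @param voxel_size physical voxel size in um (z, y, x); z-anisotropy
#'   expected (z >= xy).
#' @param psf_sigma Gaussian point-spread sigma in um (z, y, x).
#' @param n_axes number of axis paths used when a phantom or ad hoc render
#'   needs a path count not implied by ground truth.
#' @param background flat intensity offset (camera units).
#' @param shot_noise logical; apply Poisson shot noise.
#' @param read_noise_sd Gaussian read noise SD (camera units).
#' @param dispersed_focus_amp,prominent_focus_amp peak intensities of the two
#'   HEI10 focus classes before the accumulation-level rescaling (default
#'   ratio 10:1).
#' @param n_dispersed baseline count of dispersed dim HEI10 foci per nucleus.
#' @param focus_sigma_um Gaussian sigma of a painted HEI10 focus, um (z,y,x);
#'   foci are truncated at 2.5 sigma so they are compact blobs rather than
#'   infinite-tailed Gaussians.
#' @param tube_radius_um radius of painted axis/SC tubes in um.
#' @param seed integer seed for the renderer's randomness.
#' @return a `render_spec` list.
#' @export
render_spec <- function(shape = c(64L, 256L, 256L),
                        voxel_size = c(0.125, 0.04, 0.04),
                        psf_sigma = c(0.15, 0.06, 0.06),
                        n_axes = 8L,
                        background = 20,
                        shot_noise = TRUE,
                        read_noise_sd = 3,
                        dispersed_focus_amp = 400,
                        prominent_focus_amp = 4000,
                        n_dispersed = 150L,
                        focus_sigma_um = c(0.12, 0.08, 0.08),
                        tube_radius_um = 0.08,
                        seed = 1L) {
  if (length(shape) != 3 || any(shape <= 0))
    stop("render_spec: 'shape' must be three positive voxel counts")
  if (length(voxel_size) != 3 || any(voxel_size <= 0))
    stop("render_spec: 'voxel_size' must be three positive sizes (um)")
  if (length(psf_sigma) != 3 || any(psf_sigma < 0))
    stop("render_spec: 'psf_sigma' must be three nonnegative sigmas (um)")
  if (prominent_focus_amp <= dispersed_focus_amp)
    stop("render_spec: 'prominent_focus_amp' must exceed 'dispersed_focus_amp'")
  if (background < 0 || read_noise_sd < 0)
    stop("render_spec: noise parameters must be >= 0")
  structure(list(shape = as.integer(shape), voxel_size = as.numeric(voxel_size),
                 psf_sigma = as.numeric(psf_sigma), n_axes = as.integer(n_axes),
                 background = background, shot_noise = isTRUE(shot_noise),
                 read_noise_sd = read_noise_sd,
                 dispersed_focus_amp = dispersed_focus_amp,
                 prominent_focus_amp = prominent_focus_amp,
                 n_dispersed = as.integer(n_dispersed),
                 focus_sigma_um = as.numeric(focus_sigma_um),
                 tube_radius_um = tube_radius_um,
                 seed = as.integer(seed)),
            class = "render_spec")
}

# Derive a reproducible 32-bit substream seed from a master seed and index.
substream_seed <- function(master, index) {
  as.integer((as.numeric(master) * 48271 + as.numeric(index) * 8191) %% 2147483647)
}
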