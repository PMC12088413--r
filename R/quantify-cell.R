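# Composition of the per-cell quantification operators.

#' Quantification configuration
#'
#' Tunable parameters of the image-quantification layer, with the defaults
#' used throughout: Triangle for the permissive total-signal threshold, Otsu
#' within the total mask for the stringent prominent threshold, 26-connected
#' particle analysis with a 4-voxel speck filter, 0.999 normalization
#' quantile, a 0.4 um punctate/elongated ZYP1 cutoff, coalignment separation
#' 0.1-0.8 um over at least 0.5 um, and the linear-HEI10 exclusion rule
#' (centerline > 1.5 um with half the voxels within 0.2 um of ASY1).
#'
#' @param total_method,prominent_method histogram threshold methods for
#'   the HEI10 dual thresholds.
#' @param axis_method histogram method for the ASY1/ZYP1 signal masks (Otsu:
#'   axis channels have a strong foreground mode that Otsu splits cleanly,
#'   where the permissive Triangle would keep a wide blur halo).
#' @param min_voxels speck filter for particle analysis.
#' @param norm_quantile high quantile mapped to 1 by [normalize_channel()].
#' @param elong_cutoff_um ZYP1 punctate/elongated cutoff (um).
#' @param sep_range_um,min_len_um,sep_sd_max coalignment detection
#'   parameters (see [detect_parallel_axes()]).
#' @param linear_len_um,linear_dist_um,linear_frac linear-HEI10 flag
#'   parameters (see [flag_linear_hei10()]).
#' @param detect_geometry logical; run coalignment detection (it is the
#'   costliest operator and can be bypassed when geometry counts are supplied
#'   in a table).
#' @return list of class `quantify_config`.
#' @export
quantify_config <- function(total_method = "triangle",
                            prominent_method = "otsu2",
                            axis_method = "otsu",
                            min_voxels = 4L, norm_quantile = 0.9999,
                            elong_cutoff_um = 0.4,
                            sep_range_um = c(0.1, 0.8), min_len_um = 0.5,
                            sep_sd_max = 0.15,
                            linear_len_um = 1.5, linear_dist_um = 0.2,
                            linear_frac = 0.5, detect_geometry = TRUE) {
  structure(list(total_method = total_method,
                 prominent_method = prominent_method,
                 axis_method = axis_method,
                 min_voxels = as.integer(min_voxels),
                 norm_quantile = norm_quantile,
                 elong_cutoff_um = elong_cutoff_um,
                 sep_range_um = sep_range_um, min_len_um = min_len_um,
                 sep_sd_max = sep_sd_max, linear_len_um = linear_len_um,
                 linear_dist_um = linear_dist_um, linear_frac = linear_frac,
                 detect_geometry = isTRUE(detect_geometry)),
            class = "quantify_config")
}

#' Quantify one meiocyte stack
#'
#' Runs the full per-cell measurement battery on a `stack3c`: dual-threshold
#' HEI10 quantification and accumulation level, prominent-focus count,
#' ASY1 3D skeleton length (asynapsis), ZYP1 punctate/elongated
#' classification and total length, coalignment geometry, the linear-HEI10
#' exclusion flag, and quality control (a cell fails QC when the HEI10 total
#' mask is empty, or when both axis channels are empty).
#'
#' @param stack a `stack3c` (see [render_cell()] / [read_stacks()]).
#' @param config a [quantify_config()].
#' @return one-row `data.frame` of cell measurements: `cell_id`, `plant_id`,
#'   `genotype`, `accumulation_pct`, `n_prominent`, `total_hei10_intensity`,
#'   `prominent_hei10_intensity`, `asy1_length_um`, `zyp1_length_um`,
#'   `n_punctate`, `n_elongated`, `n_parallel`, `n_irregular`,
#'   `has_linear_hei10`, `qc_pass`.
#' @export
quantify_cell <- function(stack, config = quantify_config()) {
  stopifnot(inherits(stack, "stack3c"))
  vox <- stack$voxel_size
  shape <- dim(stack$hei10)
  res <- list(cell_id = stack$cell_id, plant_id = stack$plant_id,
              genotype = stack$genotype,
              accumulation_pct = 0, n_prominent = 0L,
              total_hei10_intensity = 0, prominent_hei10_intensity = 0,
              asy1_length_um = 0, zyp1_length_um = 0,
              n_punctate = 0L, n_elongated = 0L,
              n_parallel = 0L, n_irregular = 0L,
              has_linear_hei10 = FALSE, qc_pass = TRUE)

  with_ctx <- function(expr) tryCatch(expr, error = function(e)
    stop("quantify_cell [", stack$cell_id, "]: ", conditionMessage(e)))

  # ASY1: mask + skeleton length
  asy_norm <- tryCatch(normalize_channel(stack$asy1, config$norm_quantile),
                       error = function(e) NULL)
  asy_mask <- array(FALSE, shape)
  if (!is.null(asy_norm)) {
    asy_mask <- asy_norm > hist_threshold(asy_norm, config$axis_method)
    # drop specks so noise does not add length
    if (any(asy_mask)) {
      lab <- .label3d(asy_mask, shape)
      keep <- tabulate(lab[lab > 0L]) >= config$min_voxels
      m <- array(FALSE, shape)
      pos <- which(lab > 0L)
      m[pos] <- keep[lab[pos]]
      asy_mask <- m
    }
    res$asy1_length_um <- with_ctx(skeleton_length(asy_mask, vox,
                                                   config$min_voxels))
  }

  # ZYP1: punctate / elongated classes
  zy <- with_ctx(classify_zyp1(stack$zyp1, vox, config$elong_cutoff_um,
                               config$axis_method, config$min_voxels))
  res$n_punctate <- zy$n_punctate
  res$n_elongated <- zy$n_elongated
  res$zyp1_length_um <- zy$total_length_um

  # HEI10: dual thresholds, prominent components, accumulation
  hei_norm <- tryCatch(normalize_channel(stack$hei10, config$norm_quantile),
                       error = function(e) NULL)
  if (is.null(hei_norm)) {
    res$qc_pass <- FALSE
  } else {
    dt <- with_ctx(dual_threshold_hei10(hei_norm, config$total_method,
                                        config$prominent_method))
    if (!any(dt$total_mask)) {
      res$qc_pass <- FALSE
    } else {
      foci <- with_ctx(prominent_components(dt$total_mask, dt$prominent_mask,
                                            stack$hei10, config$min_voxels,
                                            vox))
      res$n_prominent <- nrow(foci)
      res$total_hei10_intensity <- sum(as.numeric(stack$hei10[dt$total_mask]))
      res$prominent_hei10_intensity <-
        if (nrow(foci)) sum(foci$integrated_intensity) else 0
      res$accumulation_pct <- with_ctx(
        hei10_accumulation(dt$total_mask, foci, stack$hei10))
      res$has_linear_hei10 <- with_ctx(
        flag_linear_hei10(foci, asy_mask, shape, vox, config$linear_len_um,
                          config$linear_dist_um, config$linear_frac))
    }
  }

  # coalignment geometry
  if (config$detect_geometry && any(asy_mask)) {
    geo <- with_ctx(detect_parallel_axes(asy_mask, vox, config$sep_range_um,
                                         config$min_len_um,
                                         config$sep_sd_max))
    res$n_parallel <- geo$n_parallel
    res$n_irregular <- geo$n_irregular
  }

  if (res$asy1_length_um == 0 && res$zyp1_length_um == 0)
    res$qc_pass <- FALSE
  as.data.frame(res, stringsAsFactors = FALSE)
}
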