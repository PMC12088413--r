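# 3D particle analysis of focus masks.

#' 3D particle analysis
#'
#' Decomposes a mask into 26-connected 3D components, drops specks smaller
#' than `min_voxels` (sub-PSF fragments are noise), and reports each
#' surviving focus with its voxel count, integrated raw intensity and
#' physical centroid.
#'
#' @param mask logical 3D array.
#' @param intensities raw intensity array of the same shape.
#' @param min_voxels minimum component size in voxels.
#' @param voxel_size um triplet (z, y, x).
#' @return a `focus_set`: `data.frame` with columns `voxel_count`,
#'   `integrated_intensity`, `centroid_z`, `centroid_y`, `centroid_x` (um);
#'   attribute `voxel_idx` holds each focus's linear voxel indices.
#' @export
particle_analysis <- function(mask, intensities, min_voxels = 4L,
                              voxel_size = c(0.125, 0.04, 0.04)) {
  stopifnot(all(dim(mask) == dim(intensities)))
  empty <- data.frame(voxel_count = integer(0),
                      integrated_intensity = numeric(0),
                      centroid_z = numeric(0), centroid_y = numeric(0),
                      centroid_x = numeric(0))
  attr(empty, "voxel_idx") <- list()
  class(empty) <- c("focus_set", "data.frame")
  if (!any(mask)) return(empty)
  lab <- .label3d(mask, dim(mask))
  idx <- which(lab > 0L)
  comp <- lab[idx]
  sizes <- tabulate(comp)
  keep <- which(sizes >= min_voxels)
  if (!length(keep)) return(empty)
  nz <- dim(mask)[1]; ny <- dim(mask)[2]
  iz <- (idx - 1L) %% nz
  iy <- ((idx - 1L) %/% nz) %% ny
  ix <- (idx - 1L) %/% (nz * ny)
  inten <- as.numeric(intensities[idx])
  sum_i <- rowsum(inten, comp)[, 1]
  cz <- rowsum(inten * (iz + 0.5) * voxel_size[1], comp)[, 1] / sum_i
  cy <- rowsum(inten * (iy + 0.5) * voxel_size[2], comp)[, 1] / sum_i
  cx <- rowsum(inten * (ix + 0.5) * voxel_size[3], comp)[, 1] / sum_i
  labs_present <- sort(unique(comp))
  ord <- match(keep, labs_present)
  out <- data.frame(voxel_count = sizes[keep],
                    integrated_intensity = sum_i[ord],
                    centroid_z = cz[ord], centroid_y = cy[ord],
                    centroid_x = cx[ord])
  attr(out, "voxel_idx") <- lapply(keep, function(k) idx[comp == k])
  class(out) <- c("focus_set", "data.frame")
  out
}

#' Prominent foci from the stringent core mask
#'
#' Detects prominent HEI10 foci as 26-connected components of the stringent
#' (prominent) mask with at least `min_voxels` voxels, and quantifies each
#' focus the way spot intensities are conventionally measured: the core is
#' dilated by `margin_um` (intersected with the total mask) to capture the
#' below-threshold shoulder of the focus, and the local background — the
#' median intensity of total-mask voxels outside all focus regions, i.e. the
#' dispersed/coating signal level — is subtracted voxelwise. The reported
#' `integrated_intensity` is therefore the focus's excess mass over the
#' dispersed signal it sits on.
#'
#' @param total_mask,prominent_mask logical arrays from
#'   [dual_threshold_hei10()] (`prominent_mask` a subset of `total_mask`).
#' @param intensities raw intensity array.
#' @param margin_um dilation margin around each core, um; a (z, y, x)
#'   triplet or a scalar. The default is wider axially because the axial
#'   PSF spreads focus tails ~2x further in z, and a margin that stops
#'   inside the tail would both lose focus mass and contaminate the
#'   background annulus. The annulus statistic is a lower quartile-ish
#'   quantile (`annulus_quantile`, default 0.60), robust to residual tail
#'   voxels.
#' @param annulus_quantile quantile of the annulus intensities used as the
#'   local background.
#' @param min_core_frac cores smaller than this fraction of the median core
#'   size are dropped (relative-prominence filter).
#' @inheritParams particle_analysis
#' @return a `focus_set` (one row per core; see [particle_analysis()]) whose
#'   `voxel_idx` attribute holds the dilated focus regions; attributes
#'   `local_bg` (dispersed-signal level) and `numerator_mass` (total
#'   background-corrected prominent mass) support the accumulation level.
#' @export
prominent_components <- function(total_mask, prominent_mask, intensities,
                                 min_voxels = 4L,
                                 voxel_size = c(0.125, 0.04, 0.04),
                                 margin_um = c(0.40, 0.22, 0.22),
                                 annulus_quantile = 0.60,
                                 min_core_frac = 0.4) {
  if (length(margin_um) == 1) margin_um <- rep(margin_um, 3)
  if (any(prominent_mask & !total_mask))
    stop("prominent_components: prominent mask not a subset of total mask")
  cores <- particle_analysis(prominent_mask, intensities,
                             min_voxels = min_voxels, voxel_size = voxel_size)
  if (!nrow(cores)) return(cores)
  # relative prominence: drop cores much smaller than the cell's typical
  # focus core (shoulders of the dispersed signal poking over the stringent
  # threshold are a fraction of a real focus core)
  big <- cores$voxel_count >= min_core_frac * median(cores$voxel_count)
  if (any(big) && !all(big)) {
    vi <- attr(cores, "voxel_idx")[big]
    cores <- cores[big, , drop = FALSE]
    attr(cores, "voxel_idx") <- vi
    class(cores) <- c("focus_set", "data.frame")
  }
  shape <- dim(total_mask)
  core_idx <- attr(cores, "voxel_idx")
  core_mask <- array(FALSE, shape)
  core_mask[unlist(core_idx)] <- TRUE
  regions <- .dilate3d(core_mask, shape, margin_um / voxel_size) & total_mask
  # local background from a thin annulus just outside the focus regions:
  # approximates the dispersed/coating level the foci sit on (or the camera
  # baseline when there is none), without being inflated by focus shoulders
  annulus <- (.dilate3d(regions, shape, pmax(0.12 / voxel_size, 1)) &
                !regions) & total_mask
  base <- if (all(total_mask)) 0
  else median(as.numeric(intensities[!total_mask]))
  t_floor <- min(as.numeric(intensities[total_mask]))
  ann_q <- if (sum(annulus) >= 20)
    quantile(as.numeric(intensities[annulus]), annulus_quantile, names = FALSE)
  else if (any(total_mask & !regions))
    median(as.numeric(intensities[total_mask & !regions]))
  else base
  # the annulus lies inside the total mask, so its values are floored at the
  # mask threshold; the excess over that floor measures genuine local signal
  # (dispersed coating) while the floor itself is not background
  local_bg <- base + max(ann_q - t_floor, 0)
  rlab <- .label3d(regions, shape)
  # assign each core to its region; split region mass among its cores
  core_region <- vapply(core_idx, function(ii) rlab[ii[1]], 0L)
  reg_ids <- sort(unique(core_region))
  reg_mass <- vapply(reg_ids, function(r) {
    ii <- which(rlab == r)
    sum(pmax(as.numeric(intensities[ii]) - local_bg, 0))
  }, 0)
  cores_per_reg <- tabulate(match(core_region, reg_ids), length(reg_ids))
  out <- cores
  out$integrated_intensity <-
    reg_mass[match(core_region, reg_ids)] / cores_per_reg[match(core_region, reg_ids)]
  attr(out, "voxel_idx") <- lapply(core_region, function(r) which(rlab == r))
  attr(out, "local_bg") <- local_bg
  attr(out, "numerator_mass") <- sum(reg_mass)
  class(out) <- c("focus_set", "data.frame")
  out
}

#' HEI10 accumulation level
#'
#' The percentage of HEI10 signal intensity residing in the prominent foci
#' relative to the total thresholded signal. The numerator is the summed
#' background-corrected focus mass from [prominent_components()] (each focus
#' integrated over its dilated region minus the local dispersed-signal
#' level); the denominator is the camera-baseline-corrected intensity over
#' the total mask (baseline = median intensity outside the total mask).
#' Returns 0 when the total mask or the focus set is empty. Errors if any
#' focus voxel lies outside the total mask (a threshold-ordering bug
#' upstream).
#'
#' @param total_mask logical array of total HEI10 signal.
#' @param prominent_foci `focus_set` from [prominent_components()].
#' @param intensities raw intensity array.
#' @param baseline camera baseline; `"auto"` (default) uses the median
#'   outside the total mask.
#' @return accumulation level in `[0, 100]`.
#' @export
hei10_accumulation <- function(total_mask, prominent_foci, intensities,
                               baseline = "auto") {
  b <- if (identical(baseline, "auto")) {
    if (all(total_mask)) 0 else median(as.numeric(intensities[!total_mask]))
  } else as.numeric(baseline)
  tot <- sum(pmax(as.numeric(intensities[total_mask]) - b, 0))
  if (tot <= 0) return(0)
  vidx <- attr(prominent_foci, "voxel_idx")
  if (is.null(vidx) || !length(vidx)) return(0)
  if (any(!total_mask[unlist(vidx)]))
    stop("hei10_accumulation: prominent focus voxels outside the total mask")
  num <- attr(prominent_foci, "numerator_mass")
  if (is.null(num)) num <- sum(prominent_foci$integrated_intensity)
  min(100 * num / tot, 100)
}
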