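# Skeleton (medial-curve) extraction and physical length measurement.
#
# Masks are reduced to centerline paths per 26-connected component: the
# component's geodesic diameter (double-sweep Dijkstra with physical-unit
# edge weights) gives the main path; voxels not explained by it are
# decomposed recursively into branch paths. Length is the sum of edge
# lengths sqrt(dz^2 + dy^2 + dx^2) in micrometres, so anisotropic voxels are
# honored without resampling.

# Bounding-box crop of a component's voxels (linear indices) with 1-voxel pad.
crop_component <- function(idx, shape) {
  nz <- shape[1]; ny <- shape[2]
  iz <- (idx - 1L) %% nz
  iy <- ((idx - 1L) %/% nz) %% ny
  ix <- (idx - 1L) %/% (nz * ny)
  z0 <- max(min(iz) - 1L, 0L); z1 <- min(max(iz) + 1L, shape[1] - 1L)
  y0 <- max(min(iy) - 1L, 0L); y1 <- min(max(iy) + 1L, shape[2] - 1L)
  x0 <- max(min(ix) - 1L, 0L); x1 <- min(max(ix) + 1L, shape[3] - 1L)
  cdim <- c(z1 - z0 + 1L, y1 - y0 + 1L, x1 - x0 + 1L)
  cidx <- (iz - z0) + cdim[1] * (iy - y0) + cdim[1] * cdim[2] * (ix - x0) + 1L
  list(dim = cdim, idx = cidx, origin = c(z0, y0, x0))
}

# Geodesic diameter path over a voxel set (0-based linear indices into a
# dim-shaped array); returns 0-based (z,y,x) voxel rows of the path plus its
# physical length.
diameter_path_idx <- function(idx0, cdim, vox) {
  d1 <- .dijkstra_sparse(idx0, cdim, vox, 0L)
  f1 <- d1$dist
  f1[!is.finite(f1)] <- -1
  e1 <- which.max(f1) - 1L
  d2 <- .dijkstra_sparse(idx0, cdim, vox, e1)
  f2 <- d2$dist
  f2[!is.finite(f2)] <- -1
  e2 <- which.max(f2) - 1L
  path <- integer(0)
  cur <- e2
  repeat {
    path <- c(path, cur)
    nxt <- d2$parent[cur + 1L]
    if (nxt < 0) break
    cur <- nxt
  }
  lin <- idx0[path + 1L]
  nz <- cdim[1]; ny <- cdim[2]
  coords <- cbind(lin %% nz, (lin %/% nz) %% ny, lin %/% (nz * ny))
  list(coords = coords, length = max(f2), idx = lin + 1L)
}

# Back-compatible wrapper taking a logical mask.
diameter_path <- function(mask, cdim, vox) {
  diameter_path_idx(which(mask) - 1L, cdim, vox)
}

# Refine a raw voxel path: uniform resampling, moving-average smoothing
# (removes the lattice zigzag that inflates 26-connected path lengths), and
# a small end trim compensating the cap the blur+threshold adds beyond the
# true structure end. Returns physical coordinates plus arc length.
refine_path <- function(coords_um, ds = 0.05, w = 5L, end_trim_um = 0.12) {
  if (nrow(coords_um) < 3) {
    out <- coords_um
    attr(out, "length_um") <- curve_length(coords_um)
    return(out)
  }
  rp <- resample_path(coords_um, ds)
  n <- nrow(rp)
  if (n > w) {
    sm <- sapply(1:3, function(a) stats::filter(rp[, a], rep(1 / w, w),
                                                sides = 2))
    h <- (w - 1L) / 2L
    sm[1:h, ] <- rp[1:h, ]
    sm[(n - h + 1):n, ] <- rp[(n - h + 1):n, ]
    rp <- sm
  }
  seg <- sqrt(rowSums(diff(rp)^2))
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  if (L > 2 * end_trim_um) {
    keep <- cum >= end_trim_um & cum <= L - end_trim_um
    if (sum(keep) >= 2) rp <- rp[keep, , drop = FALSE]
  }
  out <- rp
  attr(out, "length_um") <- curve_length(rp)
  out
}

#' Extract centerline paths from a binary mask
#'
#' Per 26-connected component: the geodesic diameter path is extracted, the
#' voxels within `claim_radius_um` of it are claimed, and remaining voxel
#' clusters are decomposed recursively into branch paths until no residual
#' path of at least `min_branch_um` remains. Suited to the curvilinear
#' (axis/synaptonemal-complex) signals this package measures.
#'
#' @param mask logical 3D array.
#' @param voxel_size um triplet (z, y, x).
#' @param min_voxels ignore components smaller than this.
#' @param min_branch_um discard residual branch paths shorter than this.
#' @param claim_radius_um tube radius within which mask voxels are considered
#'   explained by an extracted path.
#' @return list of paths; each is a matrix of physical (z, y, x) coordinates
#'   (um) with attribute `length_um`.
#' @export
skeleton_paths <- function(mask, voxel_size = c(0.125, 0.04, 0.04),
                           min_voxels = 4L, min_branch_um = 0.5,
                           claim_radius_um = 0.25) {
  if (!any(mask)) return(list())
  shape <- dim(mask)
  lab <- .label3d(mask, shape)
  idx <- which(lab > 0L)
  comp <- lab[idx]
  sizes <- tabulate(comp)
  paths <- list()
  for (k in which(sizes >= min_voxels)) {
    cur <- idx[comp == k]  # 1-based global linear indices, re-cropped per pass
    first <- TRUE
    repeat {
      if (!length(cur)) break
      cr <- crop_component(cur, shape)
      sublab_arr <- array(FALSE, cr$dim)
      sublab_arr[cr$idx] <- TRUE
      sublab <- .label3d(sublab_arr, cr$dim)
      comp_loc <- sublab[cr$idx]
      ss <- tabulate(comp_loc)
      big <- which.max(ss)
      in_big <- comp_loc == big
      dp <- diameter_path_idx(cr$idx[in_big] - 1L, cr$dim, voxel_size)
      if (!first && dp$length < min_branch_um) {
        cur <- cur[!in_big]  # too short to count
        next
      }
      coords_um <- sweep(dp$coords, 2, cr$origin, "+")
      coords_um <- sweep(coords_um + 0.5, 2, voxel_size, "*")
      paths <- c(paths, list(refine_path(coords_um)))
      pm <- array(FALSE, cr$dim)
      pm[dp$idx] <- TRUE
      claimed <- .dilate3d(pm, cr$dim,
                           pmax(claim_radius_um / voxel_size, 1), box = TRUE)
      cur <- cur[!claimed[cr$idx]]
      first <- FALSE
    }
  }
  paths
}

#' Skeleton length of a mask in micrometres
#'
#' Total physical length of the mask's centerline paths (see
#' [skeleton_paths()]); 0 for an empty mask.
#'
#' @inheritParams skeleton_paths
#' @return length in um.
#' @export
skeleton_length <- function(mask, voxel_size = c(0.125, 0.04, 0.04),
                            min_voxels = 4L) {
  p <- skeleton_paths(mask, voxel_size, min_voxels = min_voxels)
  if (!length(p)) return(0)
  sum(vapply(p, function(x) attr(x, "length_um"), 0))
}

#' Classify ZYP1 signals into punctate and elongated segments
#'
#' Thresholds the (normalized) ZYP1 channel, decomposes the mask into
#' 26-connected components, measures each component's centerline length, and
#' classifies components shorter than `elong_cutoff_um` as punctate
#' (synapsis-initiation sites) and the rest as elongated (elongating
#' synaptonemal-complex stretches).
#'
#' @param zyp1 raw ZYP1 3D array.
#' @param voxel_size um triplet (z, y, x).
#' @param elong_cutoff_um punctate/elongated length cutoff.
#' @param threshold histogram method for the signal mask.
#' @param min_voxels speck filter.
#' @return list with `n_punctate`, `n_elongated`, `total_length_um`, and the
#'   per-component `lengths_um`.
#' @export
classify_zyp1 <- function(zyp1, voxel_size = c(0.125, 0.04, 0.04),
                          elong_cutoff_um = 0.4, threshold = "triangle",
                          min_voxels = 4L) {
  norm <- tryCatch(normalize_channel(zyp1),
                   error = function(e) NULL)
  if (is.null(norm))
    return(list(n_punctate = 0L, n_elongated = 0L, total_length_um = 0,
                lengths_um = numeric(0)))
  mask <- norm > hist_threshold(norm, threshold)
  if (!any(mask))
    return(list(n_punctate = 0L, n_elongated = 0L, total_length_um = 0,
                lengths_um = numeric(0)))
  shape <- dim(mask)
  lab <- .label3d(mask, shape)
  idx <- which(lab > 0L)
  comp <- lab[idx]
  sizes <- tabulate(comp)
  lens <- numeric(0)
  for (k in which(sizes >= min_voxels)) {
    cidx <- idx[comp == k]
    cr <- crop_component(cidx, shape)
    dp <- diameter_path_idx(cr$idx - 1L, cr$dim, voxel_size)
    coords_um <- sweep(dp$coords, 2, cr$origin, "+")
    coords_um <- sweep(coords_um + 0.5, 2, voxel_size, "*")
    lens <- c(lens, attr(refine_path(coords_um), "length_um"))
  }
  # total length from the full skeleton (branches included): components that
  # merge at crossings would otherwise be undercounted by their diameter
  total_len <- skeleton_length(mask, voxel_size, min_voxels)
  list(n_punctate = sum(lens < elong_cutoff_um),
       n_elongated = sum(lens >= elong_cutoff_um),
       total_length_um = total_len,
       lengths_um = lens)
}
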