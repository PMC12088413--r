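# Coalignment geometry: parallel vs irregular asynaptic structures, and the
# linear-HEI10 exclusion flag.

# Resample a path matrix at roughly `ds` um spacing.
resample_path <- function(p, ds = 0.1) {
  if (nrow(p) < 2) return(p)
  seg <- sqrt(rowSums(diff(p)^2))
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  if (L <= ds) return(p[c(1, nrow(p)), , drop = FALSE])
  s <- seq(0, L, by = ds)
  sapply(1:3, function(a) approx_noties(cum, p[, a], s))
}

#' Detect parallel vs irregular asynaptic structures
#'
#' Automated surrogate for by-eye coalignment scoring. The ASY1 mask is
#' decomposed into centerline paths ([skeleton_paths()]); a parallel
#' structure is a pair of distinct paths, each at least `min_len_um` long,
#' whose mutual nearest-point separation stays within `sep_range_um` over at
#' least `min_len_um` of contiguous arc length with a low separation spread
#' (SD below `sep_sd_max`). Overlapping pairs are merged into one structure;
#' qualifying paths not in any parallel structure are counted irregular.
#'
#' @param asy1_mask logical 3D array of asynaptic (ASY1) signal.
#' @param voxel_size um triplet (z, y, x).
#' @param sep_range_um admissible coalignment separation (um).
#' @param min_len_um minimum structure (and coaligned-run) length.
#' @param sep_sd_max maximum SD of the separation over the coaligned run.
#' @return list with `n_parallel`, `n_irregular`, and the `paths` used.
#' @export
detect_parallel_axes <- function(asy1_mask, voxel_size = c(0.125, 0.04, 0.04),
                                 sep_range_um = c(0.1, 0.8),
                                 min_len_um = 0.5, sep_sd_max = 0.15) {
  paths <- skeleton_paths(asy1_mask, voxel_size)
  lens <- vapply(paths, function(p) attr(p, "length_um"), 0)
  qual <- which(lens >= min_len_um)
  if (!length(qual))
    return(list(n_parallel = 0L, n_irregular = 0L, paths = paths))
  rs <- lapply(paths[qual], resample_path, ds = 0.08)
  nq <- length(qual)
  # union-find over qualifying paths; edges = coaligned pairs
  parent <- seq_len(nq)
  findp <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  paired <- rep(FALSE, nq)
  if (nq >= 2) {
    for (i in 1:(nq - 1)) {
      for (j in (i + 1):nq) {
        a <- rs[[i]]; b <- rs[[j]]
        # cheap bounding-box rejection
        if (any(apply(a, 2, min) > apply(b, 2, max) + sep_range_um[2]) ||
            any(apply(b, 2, min) > apply(a, 2, max) + sep_range_um[2])) next
        small <- if (nrow(a) <= nrow(b)) a else b
        large <- if (nrow(a) <= nrow(b)) b else a
        d2 <- outer(rowSums(small^2), rowSums(large^2), "+") -
          2 * small %*% t(large)
        dmin <- sqrt(pmax(apply(d2, 1, min), 0))
        inr <- dmin >= sep_range_um[1] & dmin <= sep_range_um[2]
        # longest contiguous coaligned run
        r <- rle(inr)
        ends <- cumsum(r$lengths)
        best <- 0; best_run <- NULL
        for (k in seq_along(r$lengths)) {
          if (r$values[k] && r$lengths[k] > best) {
            best <- r$lengths[k]
            best_run <- (ends[k] - r$lengths[k] + 1):ends[k]
          }
        }
        if (is.null(best_run)) next
        run_len <- (best - 1) * 0.08
        if (run_len >= min_len_um && sd(dmin[best_run]) <= sep_sd_max) {
          pi_ <- findp(i); pj <- findp(j)
          parent[pi_] <- pj
          paired[i] <- paired[j] <- TRUE
        }
      }
    }
  }
  roots <- vapply(seq_len(nq), findp, 0L)
  n_parallel <- length(unique(roots[paired]))
  n_irregular <- sum(!paired)
  list(n_parallel = as.integer(n_parallel),
       n_irregular = as.integer(n_irregular), paths = paths)
}

#' Flag linear HEI10 signal on unsynapsed axes
#'
#' Rare cells show HEI10 as a linear signal coating unsynapsed (ASY1)
#' chromosomes rather than discrete foci; these cells are excluded from
#' accumulation analyses. The flag is raised when any prominent HEI10
#' component has a centerline longer than `len_um` and at least `frac` of
#' its voxels within `dist_um` of the ASY1 mask.
#'
#' @param prominent_foci `focus_set` of prominent HEI10 components.
#' @param asy1_mask logical ASY1 mask (same shape as the stack).
#' @param shape stack dimensions c(nz, ny, nx).
#' @param voxel_size um triplet (z, y, x).
#' @param len_um minimum centerline length of a "linear" component.
#' @param dist_um overlap distance to the ASY1 mask.
#' @param frac minimum overlapping voxel fraction.
#' @return logical flag.
#' @export
flag_linear_hei10 <- function(prominent_foci, asy1_mask, shape,
                              voxel_size = c(0.125, 0.04, 0.04),
                              len_um = 1.5, dist_um = 0.2, frac = 0.5) {
  vidx <- attr(prominent_foci, "voxel_idx")
  if (is.null(vidx) || !length(vidx)) return(FALSE)
  near_asy <- if (any(asy1_mask))
    .dilate3d(asy1_mask, dim(asy1_mask), dist_um / voxel_size)
  else asy1_mask
  for (ii in vidx) {
    cr <- crop_component(ii, shape)
    sub <- array(FALSE, cr$dim)
    sub[cr$idx] <- TRUE
    len <- diameter_path(sub, cr$dim, voxel_size)$length
    if (len > len_um && mean(near_asy[ii]) >= frac) return(TRUE)
  }
  FALSE
}
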