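# Rendering of synthetic three-channel meiocyte stacks.
#
# Geometry convention: arrays are dim = c(nz, ny, nx); physical coordinates
# are voxel centers, coord = (index - 0.5) * voxel_size for 1-based indices;
# all lengths in micrometres, ordered (z, y, x).

# --- curve machinery ---------------------------------------------------------

# Smooth random space curve of a given arc length inside a box.
# Cubic splines through control points of a bounded random walk; the curve is
# arc-length resampled at `ds` spacing and cut at `length_um` exactly.
# `wiggle` scales the walk step (smaller = straighter curve).
random_space_curve <- function(length_um, lo, hi, ds = 0.02, wiggle = 1) {
  n_ctrl <- max(4L, min(12L, as.integer(round(length_um / 1.5)) + 3L))
  step <- 1.3 * length_um / (n_ctrl - 1) * wiggle
  pts <- matrix(0, n_ctrl, 3)
  pts[1, ] <- runif(3, lo + 0.15 * (hi - lo), hi - 0.15 * (hi - lo))
  dir <- rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  for (i in 2:n_ctrl) {
    turn <- rnorm(3, sd = 0.45 * wiggle)
    dir <- dir + turn
    dir <- dir / sqrt(sum(dir^2))
    cand <- pts[i - 1, ] + dir * step
    # reflect off the box walls
    for (a in 1:3) {
      if (cand[a] < lo[a]) { cand[a] <- 2 * lo[a] - cand[a]; dir[a] <- -dir[a] }
      if (cand[a] > hi[a]) { cand[a] <- 2 * hi[a] - cand[a]; dir[a] <- -dir[a] }
      cand[a] <- min(max(cand[a], lo[a]), hi[a])
    }
    pts[i, ] <- cand
  }
  # keep walking until the spline is long enough to cut inside the box
  for (rep in 1:8) {
    dense <- spline_through(pts, n_per_seg = 24L)
    if (curve_length(dense) >= length_um) break
    extra <- pts[nrow(pts), ]
    for (k in 1:2) {
      turn <- rnorm(3, sd = 0.45 * wiggle)
      dir <- dir + turn
      dir <- dir / sqrt(sum(dir^2))
      cand <- extra + dir * step
      for (a in 1:3) {
        if (cand[a] < lo[a]) { cand[a] <- 2 * lo[a] - cand[a]; dir[a] <- -dir[a] }
        if (cand[a] > hi[a]) { cand[a] <- 2 * hi[a] - cand[a]; dir[a] <- -dir[a] }
        cand[a] <- min(max(cand[a], lo[a]), hi[a])
      }
      pts <- rbind(pts, cand)
      extra <- cand
    }
  }
  cut_curve(dense, length_um, ds = ds)
}

# Natural cubic spline through control points, densely sampled.
spline_through <- function(pts, n_per_seg = 24L) {
  n <- nrow(pts)
  t0 <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  if (t0[n] == 0) return(pts)
  tt <- seq(0, t0[n], length.out = (n - 1L) * n_per_seg + 1L)
  out <- sapply(1:3, function(a) splinefun(t0, pts[, a], method = "natural")(tt))
  out
}

# Arc-length resample a polyline at spacing ds, cut to total length L.
# Extends by repeating the generator's tail direction if the polyline is
# shorter than L (rare; the walk overshoots by design).
cut_curve <- function(pts, L, ds = 0.02) {
  seg <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total < L) {
    # extend straight along the final tangent
    tangent <- pts[nrow(pts), ] - pts[nrow(pts) - 1, ]
    tangent <- tangent / sqrt(sum(tangent^2))
    extra <- L - total
    pts <- rbind(pts, pts[nrow(pts), ] + tangent * extra)
    seg <- sqrt(rowSums(diff(pts)^2))
    cum <- c(0, cumsum(seg))
    total <- cum[length(cum)]
  }
  s <- seq(0, L, by = ds)
  if (s[length(s)] < L) s <- c(s, L)
  out <- sapply(1:3, function(a) approx_noties(cum, pts[, a], s))
  out
}

approx_noties <- function(x, y, xout) {
  keep <- c(TRUE, diff(x) > 0)
  stats::approx(x[keep], y[keep], xout = xout, rule = 2)$y
}

curve_length <- function(pts) sum(sqrt(rowSums(diff(pts)^2)))

# Offset a curve by constant separation s along a propagated normal,
# giving the second track of a coaligned parallel pair.
offset_curve <- function(pts, s) {
  n <- nrow(pts)
  tang <- rbind(pts[2, ] - pts[1, ], pts[3:n, ] - pts[1:(n - 2), ],
                pts[n, ] - pts[n - 1, ])
  tang <- tang / pmax(sqrt(rowSums(tang^2)), 1e-12)
  ref <- c(0, 1, 0)
  if (abs(sum(ref * tang[1, ])) > 0.9) ref <- c(0, 0, 1)
  nrm <- matrix(0, n, 3)
  v <- ref - sum(ref * tang[1, ]) * tang[1, ]
  nrm[1, ] <- v / sqrt(sum(v^2))
  for (i in 2:n) {
    v <- nrm[i - 1, ] - sum(nrm[i - 1, ] * tang[i, ]) * tang[i, ]
    if (sum(v^2) < 1e-12) v <- nrm[i - 1, ]
    nrm[i, ] <- v / sqrt(sum(v^2))
  }
  pts + s * nrm
}

# --- painting ----------------------------------------------------------------

# Voxel indices (1-based linear) covered by a tube of radius r around a curve.
tube_voxels <- function(pts, radius_um, shape, vox) {
  rad_vox <- radius_um / vox
  h <- floor(rad_vox)
  offs <- as.matrix(expand.grid(dz = -h[1]:h[1], dy = -h[2]:h[2], dx = -h[3]:h[3]))
  q <- rep(0, nrow(offs))
  for (a in 1:3) {
    if (rad_vox[a] > 0) q <- q + (offs[, a] / rad_vox[a])^2
    else q <- q + ifelse(offs[, a] != 0, Inf, 0)
  }
  offs <- offs[q <= 1, , drop = FALSE]
  ctr <- cbind(floor(pts[, 1] / vox[1]), floor(pts[, 2] / vox[2]),
               floor(pts[, 3] / vox[3])) + 1L  # 1-based voxel indices
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  iz <- rep(ctr[, 1], each = nrow(offs)) + rep(offs[, 1], nrow(ctr))
  iy <- rep(ctr[, 2], each = nrow(offs)) + rep(offs[, 2], nrow(ctr))
  ix <- rep(ctr[, 3], each = nrow(offs)) + rep(offs[, 3], nrow(ctr))
  ok <- iz >= 1 & iz <= nz & iy >= 1 & iy <= ny & ix >= 1 & ix <= nx
  unique(iz[ok] + nz * (iy[ok] - 1) + nz * ny * (ix[ok] - 1))
}

# Additive compact Gaussian blob (truncated at `trunc` sigma).
# Returns list(idx, val) to be accumulated into a channel.
focus_blob <- function(center_um, sigma_um, amp, shape, vox, trunc = 2.5) {
  h <- ceiling(trunc * sigma_um / vox)
  ctr <- floor(center_um / vox) + 1L
  rng <- lapply(1:3, function(a) {
    a0 <- max(1L, ctr[a] - h[a]); a1 <- min(shape[a], ctr[a] + h[a])
    if (a0 > a1) integer(0) else a0:a1
  })
  if (any(lengths(rng) == 0)) return(list(idx = integer(0), val = numeric(0)))
  g <- expand.grid(iz = rng[[1]], iy = rng[[2]], ix = rng[[3]])
  d2 <- ((g$iz - 0.5) * vox[1] - center_um[1])^2 / sigma_um[1]^2 +
        ((g$iy - 0.5) * vox[2] - center_um[2])^2 / sigma_um[2]^2 +
        ((g$ix - 0.5) * vox[3] - center_um[3])^2 / sigma_um[3]^2
  keep <- d2 <= trunc^2
  idx <- g$iz[keep] + shape[1] * (g$iy[keep] - 1) +
    shape[1] * shape[2] * (g$ix[keep] - 1)
  list(idx = idx, val = amp * exp(-0.5 * d2[keep]))
}

add_blobs <- function(arr, blobs) {
  for (b in blobs) if (length(b$idx)) arr[b$idx] <- arr[b$idx] + b$val
  arr
}

# Apply PSF blur + noise + 16-bit digitisation to a raw painted channel.
finish_channel <- function(arr, spec) {
  sig_vox <- spec$psf_sigma / spec$voxel_size
  # painted scenes are sparse (<~2% nonzero): scatter-add blur is much
  # cheaper than the dense separable pass, which remains the fallback
  nnz <- sum(arr != 0)
  arr <- if (nnz < 0.05 * length(arr))
    .blur3d_sparse(arr, dim(arr), sig_vox)
  else .blur3d(arr, dim(arr), sig_vox)
  arr <- arr + spec$background
  if (spec$shot_noise) {
    v <- rpois(length(arr), lambda = pmax(as.numeric(arr), 0))
    arr <- array(v, dim = dim(arr))
  }
  if (spec$read_noise_sd > 0)
    arr <- arr + array(rnorm(length(arr), 0, spec$read_noise_sd), dim(arr))
  array(pmin(pmax(round(arr), 0), 65535), dim(arr))
}

new_stack3c <- function(hei10, asy1, zyp1, voxel_size, cell_id = "cell",
                        plant_id = "plant", genotype = "NA") {
  structure(list(hei10 = hei10, asy1 = asy1, zyp1 = zyp1,
                 voxel_size = voxel_size, cell_id = cell_id,
                 plant_id = plant_id, genotype = genotype),
            class = "stack3c")
}

# --- render_cell -------------------------------------------------------------

#' Render one synthetic meiocyte as a three-channel 3D stack
#'
#' Draws the cell described by a ground-truth row as curvilinear axis
#' structures inside the imaging volume: asynaptic regions (ASY1 channel) as
#' coaligned parallel pairs and irregular single tracks, synapsed regions
#' (ZYP1 channel) as elongated stretches plus punctate initiation dots, and
#' the HEI10 channel as `n_prominent_true` bright compact foci on synapsed
#' stretches plus dispersed dim foci scaled so that the bright-focus share of
#' total pre-blur HEI10 intensity equals `H_true` exactly. The painted scene
#' is convolved with an anisotropic Gaussian PSF, then optional shot and read
#' noise are applied and intensities are digitised to 16-bit counts.
#'
#' @param truth one-row `data.frame` (or list) with the ground-truth fields of
#'   [simulate_cell_table()].
#' @param spec a [render_spec()].
#' @return a `stack3c` object (channels `hei10`, `asy1`, `zyp1`, plus
#'   `voxel_size` and identifiers) with attributes:
#'   `truth_masks` (logical arrays `prominent`, `asy1`, `zyp1` marking the
#'   pre-blur painted support), `h_pre` (pre-blur accumulation %),
#'   `asy1_track_um` / `zyp1_track_um` (summed painted arc lengths), and
#'   `truth` (the input row).
#' @export
render_cell <- function(truth, spec = render_spec()) {
  truth <- as.list(truth)
  need <- c("H_true", "asynapsis_true", "zyp1_total_true", "n_prominent_true",
            "n_parallel_true", "n_irregular_true", "n_punctate_true",
            "n_elongated_true")
  for (nm in need)
    if (is.null(truth[[nm]]) || !is.finite(truth[[nm]]))
      stop("render_cell: truth field '", nm, "' missing or non-finite")
  shape <- spec$shape; vox <- spec$voxel_size
  extent <- shape * vox
  # axis budget feasibility: painted tube voxels must not exceed ~30% volume
  vox_per_um <- max(length(tube_voxels(matrix(extent / 2, 1, 3),
                                       spec$tube_radius_um, shape, vox)), 1) /
    mean(vox)  # rough voxels per um of painted tube
  track_total <- truth$asynapsis_true + truth$zyp1_total_true
  if (track_total * vox_per_um > 0.3 * prod(shape))
    stop("render_cell: axis budget infeasible within the volume (",
         round(track_total), " um of track in ", paste(shape, collapse = "x"),
         " voxels)")
  cid <- if (!is.null(truth$cell_id)) truth$cell_id else "cell"
  set.seed(substream_seed(spec$seed, sum(utf8ToInt(as.character(cid)))))

  lo <- 0.08 * extent; hi <- 0.92 * extent
  asy1 <- array(0, shape); zyp1 <- array(0, shape)
  tube_amp <- 1500

  # -- asynaptic structures: parallel pairs + irregular singles
  n_par <- truth$n_parallel_true; n_irr <- truth$n_irregular_true
  asy_budget <- truth$asynapsis_true
  asy_len <- 0
  asy_curves <- list()
  if (asy_budget > 0.2) {
    if (n_par + n_irr == 0) n_irr <- 1
    w <- runif(n_par + n_irr, 0.5, 1.5)
    cons <- c(rep(2, n_par), rep(1, n_irr))  # pairs consume two tracks
    lens <- w * asy_budget / sum(w * cons)
    lens <- pmax(lens, 0.3)
    lens <- lens * asy_budget / sum(lens * cons)
    for (k in seq_along(lens)) {
      if (k <= n_par) {
        a <- random_space_curve(lens[k], lo, hi, wiggle = 0.45)
        b <- offset_curve(a, 0.3)
        b[, 1] <- pmin(pmax(b[, 1], lo[1]), hi[1])
        b[, 2] <- pmin(pmax(b[, 2], lo[2]), hi[2])
        b[, 3] <- pmin(pmax(b[, 3], lo[3]), hi[3])
        asy_curves <- c(asy_curves, list(a, b))
      } else {
        asy_curves <- c(asy_curves, list(random_space_curve(lens[k], lo, hi)))
      }
    }
    drawn <- sum(vapply(asy_curves, curve_length, 0))
    # trim/extend the longest curve so the painted total matches the budget
    excess <- drawn - asy_budget
    if (abs(excess) / asy_budget > 0.002) {
      li <- which.max(vapply(asy_curves, curve_length, 0))
      tgt <- curve_length(asy_curves[[li]]) - excess
      if (tgt > 0.25)
        asy_curves[[li]] <- cut_curve(asy_curves[[li]], tgt)
    }
    asy_len <- sum(vapply(asy_curves, curve_length, 0))
    for (cv in asy_curves)
      asy1[tube_voxels(cv, spec$tube_radius_um, shape, vox)] <- tube_amp
  }

  # -- synapsed structures: elongated stretches + punctate dots
  n_elo <- truth$n_elongated_true; n_pun <- truth$n_punctate_true
  zyp_curves <- list()
  pun_centers <- list()
  zyp_len <- 0
  if (truth$zyp1_total_true > 0.05) {
    pun_len <- 0.15
    elo_budget <- max(truth$zyp1_total_true - pun_len * n_pun, 0)
    if (n_elo > 0 && elo_budget > 0.3) {
      w <- runif(n_elo, 0.5, 1.5)
      lens <- pmax(w * elo_budget / sum(w), 0.6)
      lens <- lens * elo_budget / sum(lens)
      for (k in seq_len(n_elo))
        zyp_curves <- c(zyp_curves, list(random_space_curve(lens[k], lo, hi)))
      drawn <- sum(vapply(zyp_curves, curve_length, 0))
      excess <- drawn - elo_budget
      if (abs(excess) > 0.002 * elo_budget) {
        li <- which.max(vapply(zyp_curves, curve_length, 0))
        tgt <- curve_length(zyp_curves[[li]]) - excess
        if (tgt > 0.25) zyp_curves[[li]] <- cut_curve(zyp_curves[[li]], tgt)
      }
      for (cv in zyp_curves)
        zyp1[tube_voxels(cv, spec$tube_radius_um, shape, vox)] <- tube_amp
    }
    if (n_pun > 0) {
      for (k in seq_len(n_pun)) {
        ctr <- runif(3, lo, hi)
        pun_centers <- c(pun_centers, list(ctr))
        seg <- rbind(ctr - c(0, 0, pun_len / 2), ctr + c(0, 0, pun_len / 2))
        zyp1[tube_voxels(seg, spec$tube_radius_um, shape, vox)] <- tube_amp
      }
    }
    zyp_len <- sum(vapply(zyp_curves, curve_length, 0)) + pun_len * n_pun
  }

  # -- HEI10: bright prominent foci + dispersed dim foci
  hei10 <- array(0, shape)
  n_prom <- truth$n_prominent_true
  H <- truth$H_true
  prom_centers <- place_on_curves(
    if (length(zyp_curves)) zyp_curves else asy_curves,
    n_prom, min_sep = 1.2)
  prom_blobs <- lapply(prom_centers, function(ct)
    focus_blob(ct, spec$focus_sigma_um, spec$prominent_focus_amp, shape, vox))
  P <- array(0, shape); P <- add_blobs(P, prom_blobs)
  sumP <- sum(P)

  D <- array(0, shape)
  if (H < 100) {
    all_curves <- c(asy_curves, zyp_curves)
    # dispersed signal budget: share (100 - H) of the pre-blur intensity,
    # realised as discrete dim foci at the nominal 10:1 amplitude ratio plus
    # a faint coating along the axes (early stages: mostly coating; late
    # stages: a few dim foci, no coating), mirroring coarsening kinetics
    D_target <- if (sumP > 0 && H > 0) sumP * (100 - H) / H else NA
    unit <- focus_blob(extent / 2, spec$focus_sigma_um,
                       spec$dispersed_focus_amp, shape, vox)
    unit_mass <- sum(unit$val)
    n_disp <- if (is.finite(D_target))
      min(spec$n_dispersed, max(3L, round(D_target / unit_mass)))
    else spec$n_dispersed
    disp_centers <- if (length(all_curves))
      place_on_curves(all_curves, n_disp, min_sep = 0.3,
                      avoid = prom_centers, avoid_dist = 0.6)
    else lapply(seq_len(n_disp), function(i) runif(3, lo, hi))
    disp_blobs <- lapply(disp_centers, function(ct)
      focus_blob(ct, spec$focus_sigma_um, spec$dispersed_focus_amp, shape, vox))
    D <- add_blobs(D, disp_blobs)
    if (is.finite(D_target) && D_target > sum(D) && length(all_curves)) {
      coat_idx <- unique(unlist(lapply(all_curves, tube_voxels,
                                       radius_um = spec$tube_radius_um,
                                       shape = shape, vox = vox)))
      D[coat_idx] <- D[coat_idx] + (D_target - sum(D)) / length(coat_idx)
    }
    if (is.finite(D_target) && sum(D) > 0)
      D <- D * D_target / sum(D)  # exact pre-blur share
  }
  hei10 <- P + D
  sumD <- sum(D)
  h_pre <- if (sumP + sumD > 0) 100 * sumP / (sumP + sumD) else 0

  # ground-truth masks (pre-blur support; prominent at 2.6 sigma)
  prom_mask <- array(FALSE, shape)
  for (ct in prom_centers) {
    b <- focus_blob(ct, spec$focus_sigma_um, 1, shape, vox, trunc = 2.6)
    prom_mask[b$idx] <- TRUE
  }
  masks <- list(prominent = prom_mask, asy1 = asy1 > 0, zyp1 = zyp1 > 0)

  out <- new_stack3c(finish_channel(hei10, spec), finish_channel(asy1, spec),
                     finish_channel(zyp1, spec), vox,
                     cell_id = as.character(cid),
                     plant_id = if (!is.null(truth$plant_id)) truth$plant_id else "plant",
                     genotype = if (!is.null(truth$genotype)) truth$genotype else "NA")
  attr(out, "truth_masks") <- masks
  attr(out, "h_pre") <- h_pre
  attr(out, "hei10_preblur") <- hei10
  attr(out, "asy1_track_um") <- asy_len
  attr(out, "zyp1_track_um") <- zyp_len
  attr(out, "truth") <- truth
  out
}

# Place n points on a set of curves with a minimum arc separation within each
# curve (a nod to crossover interference; also keeps foci resolvable).
place_on_curves <- function(curves, n, min_sep = 1.2, avoid = list(),
                            avoid_dist = 0) {
  if (n <= 0 || !length(curves)) return(list())
  lens <- vapply(curves, curve_length, 0)
  av <- if (length(avoid)) do.call(rbind, avoid) else NULL
  centers <- vector("list", n)
  taken <- lapply(curves, function(x) numeric(0))
  for (i in seq_len(n)) {
    placed <- FALSE
    for (tries in 1:60) {
      ci <- sample.int(length(curves), 1, prob = pmax(lens, 1e-6))
      s <- runif(1, 0, lens[ci])
      if (!is.null(av) && avoid_dist > 0) {
        pts <- curves[[ci]]
        cum <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
        cand <- sapply(1:3, function(a) approx_noties(cum, pts[, a], s))
        if (min(sqrt(rowSums(sweep(av, 2, cand)^2))) < avoid_dist) next
      }
      if (!length(taken[[ci]]) || min(abs(taken[[ci]] - s)) >= min_sep) {
        pts <- curves[[ci]]
        cum <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
        centers[[i]] <- sapply(1:3, function(a) approx_noties(cum, pts[, a], s))
        taken[[ci]] <- c(taken[[ci]], s)
        placed <- TRUE
        break
      }
    }
    if (!placed) {  # crowded: accept the last candidate without the spacing
      pts <- curves[[ci]]
      cum <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
      centers[[i]] <- sapply(1:3, function(a) approx_noties(cum, pts[, a], s))
    }
  }
  centers
}

# --- phantoms ----------------------------------------------------------------

#' Analytic phantoms for the length and geometry operators
#'
#' Draws a structure of known analytic arc length / separation into a stack:
#' `line` (straight line along x), `helix` (circular helix), `parallel_pair`
#' (two straight tracks at constant separation, one coaligned structure), or
#' `bubble` (an interstitial asynaptic bubble between two synapsed
#' stretches). Lines, helices and pairs are painted into the ASY1 channel;
#' the bubble paints ASY1 (asynaptic arcs) and ZYP1 (flanking synapsed
#' stretches).
#'
#' @param kind one of `"line"`, `"helix"`, `"parallel_pair"`, `"bubble"`.
#' @param spec a [render_spec()]; phantom geometry must fit its volume.
#' @param n_voxels line phantom: number of voxels spanned along x.
#' @param radius_um,pitch_um,turns helix parameters.
#' @param sep_um,length_um parallel-pair separation and track length; for
#'   `bubble`, `length_um` is the bubble's axial extent.
#' @param thin logical; paint single-voxel-thin structures (default uses the
#'   spec's tube radius).
#' @return a `stack3c` with attribute `truth`: a list carrying the analytic
#'   `length_um` of the drawn structure (per track where relevant) and the
#'   structure class.
#' @export
make_phantom <- function(kind = c("line", "helix", "parallel_pair", "bubble"),
                         spec = render_spec(), n_voxels = 101L,
                         radius_um = 1, pitch_um = 1, turns = 3,
                         sep_um = 0.3, length_um = 5, thin = FALSE) {
  kind <- match.arg(kind)
  shape <- spec$shape; vox <- spec$voxel_size
  extent <- shape * vox
  ctr <- extent / 2
  rad <- if (thin) 0 else spec$tube_radius_um
  set.seed(spec$seed)
  asy1 <- array(0, shape); zyp1 <- array(0, shape)
  tube_amp <- 1500
  truth <- list(kind = kind)

  if (kind == "line") {
    L <- (n_voxels - 1) * vox[3]
    if (L > 0.9 * extent[3]) stop("make_phantom: line does not fit the volume")
    x <- seq(ctr[3] - L / 2, ctr[3] + L / 2, by = vox[3] / 2)
    pts <- cbind(ctr[1], ctr[2], x)
    asy1[tube_voxels(pts, rad, shape, vox)] <- tube_amp
    truth$length_um <- L
  } else if (kind == "helix") {
    L <- turns * sqrt((2 * pi * radius_um)^2 + pitch_um^2)
    if (2 * radius_um > 0.85 * min(extent[2:3]) ||
        turns * pitch_um > 0.85 * extent[1])
      stop("make_phantom: helix does not fit the volume")
    th <- seq(0, 2 * pi * turns, length.out = max(200, round(L / 0.02)))
    pts <- cbind(ctr[1] - turns * pitch_um / 2 + th / (2 * pi) * pitch_um,
                 ctr[2] + radius_um * cos(th),
                 ctr[3] + radius_um * sin(th))
    asy1[tube_voxels(pts, rad, shape, vox)] <- tube_amp
    truth$length_um <- L
  } else if (kind == "parallel_pair") {
    if (length_um > 0.9 * extent[3] || sep_um > 0.5 * extent[2])
      stop("make_phantom: pair does not fit the volume")
    x <- seq(ctr[3] - length_um / 2, ctr[3] + length_um / 2, by = vox[3] / 2)
    a <- cbind(ctr[1], ctr[2] - sep_um / 2, x)
    b <- cbind(ctr[1], ctr[2] + sep_um / 2, x)
    asy1[tube_voxels(a, rad, shape, vox)] <- tube_amp
    asy1[tube_voxels(b, rad, shape, vox)] <- tube_amp
    truth$length_um <- length_um
    truth$separation_um <- sep_um
    truth$n_parallel <- 1L
  } else {  # bubble: ZYP1 -- ASY1 arcs -- ZYP1 along x
    Lb <- length_um
    flank <- min(2, (0.9 * extent[3] - Lb) / 2)
    if (flank <= 0.2) stop("make_phantom: bubble does not fit the volume")
    x0 <- ctr[3] - Lb / 2
    xs <- seq(ctr[3] - Lb / 2 - flank, ctr[3] - Lb / 2, by = vox[3] / 2)
    zyp1[tube_voxels(cbind(ctr[1], ctr[2], xs), rad, shape, vox)] <- tube_amp
    xs <- seq(ctr[3] + Lb / 2, ctr[3] + Lb / 2 + flank, by = vox[3] / 2)
    zyp1[tube_voxels(cbind(ctr[1], ctr[2], xs), rad, shape, vox)] <- tube_amp
    # two elliptical arcs bulging +/- in y between the stretches
    t <- seq(0, pi, length.out = 400)
    bulge <- min(0.8, 0.25 * Lb)
    arc_len <- 0
    for (sgn in c(-1, 1)) {
      pts <- cbind(ctr[1], ctr[2] + sgn * bulge * sin(t),
                   x0 + Lb * (1 - cos(t)) / 2)
      asy1[tube_voxels(pts, rad, shape, vox)] <- tube_amp
      arc_len <- arc_len + curve_length(pts)
    }
    truth$length_um <- arc_len  # total asynaptic track length (both arcs)
    truth$bubble_extent_um <- Lb
  }
  hei10 <- array(0, shape)
  out <- new_stack3c(finish_channel(hei10, spec), finish_channel(asy1, spec),
                     finish_channel(zyp1, spec), vox, cell_id = kind)
  attr(out, "truth") <- truth
  out
}
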