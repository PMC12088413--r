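# Histogram thresholding and channel normalization.

#' Normalize a channel to [0, 1]
#'
#' Affine rescaling based on the channel's own intensity distribution: the
#' minimum maps to 0 and a high quantile (default 0.9999, which tolerates
#' hundreds of hot voxels yet stays above the bright-focus cores, which
#' occupy well under 0.01% of a stack) maps to 1; values above the quantile are clipped. Relative
#' ordering is preserved, and the result is invariant to affine changes of
#' the raw intensities, so downstream thresholds act on relative rather than
#' absolute intensity.
#'
#' @param channel 3D (or any) numeric array of finite nonnegative intensities.
#' @param hi_quantile quantile mapped to 1.
#' @return array of the same shape with values in `[0, 1]`.
#' @export
normalize_channel <- function(channel, hi_quantile = 0.9999) {
  if (!all(is.finite(channel))) stop("normalize_channel: non-finite intensities")
  lo <- min(channel)
  hi <- quantile(channel, hi_quantile, names = FALSE)
  if (hi <= lo) {
    if (max(channel) > lo) hi <- max(channel)
    else stop("normalize_channel: no dynamic range (constant channel)")
  }
  out <- (channel - lo) / (hi - lo)
  out[out > 1] <- 1
  out
}

#' Triangle threshold of an intensity sample
#'
#' Classical geometric histogram method: a line is drawn from the histogram
#' peak to the far end of the longer tail, and the threshold is placed at the
#' bin whose count is farthest (perpendicular distance) below that line.
#' Permissive on images dominated by background, which is why it serves as
#' the default "total signal" threshold.
#'
#' @param x numeric vector (or array) of intensities in `[0, 1]`.
#' @param n_bins histogram resolution.
#' @return scalar threshold.
#' @export
threshold_triangle <- function(x, n_bins = 256L) {
  h <- tabulate(pmin(pmax(floor(as.numeric(x) * n_bins) + 1L, 1L), n_bins),
                nbins = n_bins)
  peak <- which.max(h)
  nz <- which(h > 0)
  lo <- nz[1]; hi <- nz[length(nz)]
  # pick the longer tail side
  if ((hi - peak) >= (peak - lo)) { a <- peak; b <- hi } else { a <- peak; b <- lo }
  if (a == b) return((peak - 0.5) / n_bins)
  idx <- seq(min(a, b), max(a, b))
  # distance from (i, h[i]) to the line through (a, h[a]) and (b, h[b])
  x1 <- a; y1 <- h[a]; x2 <- b; y2 <- h[b]
  d <- abs((y2 - y1) * idx - (x2 - x1) * h[idx] + x2 * y1 - y2 * x1)
  t_bin <- idx[which.max(d)]
  (t_bin - 0.5) / n_bins
}

#' Otsu threshold of an intensity sample
#'
#' Maximizes between-class variance of the two-class split of the intensity
#' histogram; stringent on focus-plus-background images, which is why it
#' serves as the default "prominent foci" threshold (computed within the
#' total-signal mask).
#'
#' @inheritParams threshold_triangle
#' @return scalar threshold.
#' @export
threshold_otsu <- function(x, n_bins = 256L) {
  h <- tabulate(pmin(pmax(floor(as.numeric(x) * n_bins) + 1L, 1L), n_bins),
                nbins = n_bins)
  p <- h / sum(h)
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

hist_threshold <- function(x, method) {
  switch(method,
         triangle = threshold_triangle(x),
         otsu = threshold_otsu(x),
         otsu2 = threshold_otsu2(x),
         stop("unknown threshold method '", method, "'"))
}

#' Two-stage Otsu threshold
#'
#' Hierarchical Otsu for trimodal focus images: a first Otsu split separates
#' the dominant low-intensity class (background and blur shoulders), and a
#' second Otsu on the upper class separates dim from bright foci; the upper
#' split is returned, unless it would cut a single tight mode in half
#' (upper/lower class means within 1.5x), in which case the first split
#' already isolated the foci and is kept. A single Otsu applied to a mask dominated by
#' near-threshold shoulder voxels lands between background and signal rather
#' than between the two focus classes.
#'
#' @inheritParams threshold_triangle
#' @return scalar threshold.
#' @export
threshold_otsu2 <- function(x, n_bins = 256L) {
  t1 <- threshold_otsu(x, n_bins)
  up <- x[x > t1]
  if (length(up) < 50) return(t1)
  t2 <- max(threshold_otsu(up, n_bins), t1)
  # accept the second split only if it separates genuinely distinct
  # amplitude classes; splitting a single tight mode down the middle
  # (mean ratio near 1) means the first split already isolated the foci
  lo <- up[up <= t2]; hi <- up[up > t2]
  if (!length(lo) || !length(hi)) return(t1)
  if (mean(hi) < 1.5 * mean(lo)) return(t1)
  t2
}

#' Dual-threshold segmentation of the HEI10 channel
#'
#' Applies two automated histogram thresholds to a normalized HEI10 channel:
#' a permissive one (default Triangle) defining the total-signal mask, and a
#' stringent one (default Otsu, computed over voxels inside the total mask)
#' defining the prominent-focus core mask. The stringent threshold is forced
#' to be at least the permissive one, so the prominent mask is a subset of
#' the total mask by construction.
#'
#' @param channel normalized 3D array (see [normalize_channel()]).
#' @param total_method,prominent_method histogram methods (`"triangle"`,
#'   `"otsu"` or `"otsu2"`; the two-stage Otsu is the stringent default
#'   because a single Otsu within a permissive mask separates background
#'   shoulders from signal rather than dim from bright foci).
#' @return list with logical arrays `total_mask`, `prominent_mask`, and the
#'   numeric `thresholds` (total, prominent).
#' @export
dual_threshold_hei10 <- function(channel, total_method = "triangle",
                                 prominent_method = "otsu2") {
  t_tot <- hist_threshold(channel, total_method)
  total_mask <- channel > t_tot
  if (!any(total_mask)) {
    return(list(total_mask = total_mask, prominent_mask = total_mask,
                thresholds = c(total = t_tot, prominent = t_tot)))
  }
  t_prom <- hist_threshold(channel[total_mask], prominent_method)
  t_prom <- max(t_prom, t_tot)
  prominent_mask <- channel > t_prom
  stopifnot(!any(prominent_mask & !total_mask))
  list(total_mask = total_mask, prominent_mask = prominent_mask,
       thresholds = c(total = t_tot, prominent = t_prom))
}
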