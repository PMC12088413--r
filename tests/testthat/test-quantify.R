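test_that("channel normalization is an affine-invariant [0,1] map", {
  x <- array(c(0, 50, 100, rep(0, 24)), c(3, 3, 3))
  n <- normalize_channel(x, hi_quantile = 1)
  expect_equal(sort(unique(as.numeric(n))), c(0, 0.5, 1))
  expect_equal(normalize_channel(x + 17, hi_quantile = 1),
               normalize_channel(x, hi_quantile = 1))
  expect_equal(normalize_channel(x * 3, hi_quantile = 1),
               normalize_channel(x, hi_quantile = 1))
  expect_error(normalize_channel(array(5, c(2, 2, 2))), "no dynamic range")
})

test_that("dual thresholds split a bimodal histogram with the subset relation", {
  set.seed(101)
  n_bg <- 26000; n_fg <- 1000
  v <- c(pmax(rnorm(n_bg, 0.05, 0.01), 0), rnorm(n_fg, 0.8, 0.02))
  x <- array(v, c(30, 30, 30))
  dt <- dual_threshold_hei10(x)
  expect_true(all(x[dt$prominent_mask] > 0.5))       # bright mode captured
  expect_gt(sum(dt$prominent_mask), 0.95 * n_fg)
  expect_false(any(dt$prominent_mask & !dt$total_mask))
  expect_gte(dt$thresholds["prominent"], dt$thresholds["total"])
  # brute-force Otsu oracle: sweep all bin edges, maximize between-class var
  sweep_otsu <- function(v, nb = 256) {
    cand <- (1:(nb - 1)) / nb
    bc <- vapply(cand, function(t) {
      a <- v[v <= t]; b <- v[v > t]
      if (!length(a) || !length(b)) return(0)
      length(a) * length(b) * (mean(a) - mean(b))^2
    }, 0)
    cand[which.max(bc)]
  }
  expect_lt(abs(threshold_otsu(v) - sweep_otsu(v)), 1 / 256 + 1e-9)
})

test_that("particle analysis reports 26-connected components with size filter", {
  x <- array(0, c(10, 12, 14))
  x[2:4, 2:4, 2:4] <- 5       # blob A: 27 voxels, sum 135
  x[7:9, 8:10, 10:12] <- 2    # blob B: 27 voxels, sum 54
  fs <- particle_analysis(x > 0, x, min_voxels = 4,
                          voxel_size = c(0.125, 0.04, 0.04))
  expect_equal(nrow(fs), 2)
  expect_equal(sort(fs$integrated_intensity), c(54, 135))
  expect_equal(fs$voxel_count, c(27L, 27L))
  # centroid of blob A: voxels 2:4 centered at index 3 -> (3-0.5)*size
  expect_equal(fs$centroid_z[1], 2.5 * 0.125)
  expect_equal(fs$centroid_y[1], 2.5 * 0.04)
  # 2-voxel speck excluded by min_voxels = 4
  y <- array(FALSE, c(6, 6, 6)); y[2, 2, 2:3] <- TRUE
  expect_equal(nrow(particle_analysis(y, array(1, dim(y)), 4)), 0)
  expect_equal(nrow(particle_analysis(array(FALSE, c(4, 4, 4)),
                                      array(0, c(4, 4, 4)))), 0)
})

test_that("accumulation level handles the trivial and error cases", {
  x <- array(0, c(8, 20, 20))
  x[3:5, 3:5, 3:5] <- 100
  x[3:5, 12:14, 12:14] <- 100
  total <- x > 0
  foci <- particle_analysis(total, x, 4)
  expect_equal(hei10_accumulation(total, foci, x, baseline = 0), 100)
  empty <- particle_analysis(array(FALSE, dim(x)), x, 4)
  expect_equal(hei10_accumulation(total, empty, x), 0)
  expect_equal(hei10_accumulation(array(FALSE, dim(x)), foci, x), 0)
  # subset violation indicates a threshold-ordering bug
  bad_total <- total; bad_total[3, 3, 3] <- FALSE
  expect_error(hei10_accumulation(bad_total, foci, x), "outside the total")
})

test_that("raising the prominent threshold never raises the accumulation", {
  set.seed(102)
  x <- array(1, c(16, 40, 40))
  ctrs <- list(c(5, 8, 8), c(9, 20, 30), c(12, 32, 12), c(6, 30, 30))
  amps <- c(40, 80, 160, 320)
  for (i in seq_along(ctrs)) {
    cz <- ctrs[[i]]
    x[cz[1] + (-1:1), cz[2] + (-2:2), cz[3] + (-2:2)] <- amps[i]
  }
  total <- x > 10
  accs <- vapply(c(30, 70, 150, 300), function(t) {
    f <- prominent_components(total, x > t, x, min_voxels = 4,
                              min_core_frac = 0)
    hei10_accumulation(total, f, x)
  }, 0)
  expect_true(all(diff(accs) <= 1e-9))
})

test_that("skeleton length matches analytic arc length on painted tubes", {
  spec <- small_spec(seed = 14)
  vox <- spec$voxel_size
  expect_equal(skeleton_length(array(FALSE, c(8, 8, 8)), vox), 0)
  t <- seq(0, 1, by = 0.002)
  # axis-aligned and diagonal tubes: within 10% of analytic length
  lines <- list(
    list(pts = cbind(3, 3, 1 + 4 * t), truth = 4),
    list(pts = cbind(3, 1 + 4 * t, 3), truth = 4),
    list(pts = cbind(3, 1 + 3.5 * t, 1 + 3.5 * t), truth = 3.5 * sqrt(2)),
    list(pts = cbind(2 + 2 * t, 1 + 3.5 * t, 1 + 3.5 * t),
         truth = sqrt(4 + 2 * 3.5^2)))
  for (ln in lines) {
    st <- painted_tube_stack(ln$pts, spec)
    nrm <- normalize_channel(st)
    m <- nrm > threshold_otsu(nrm)
    expect_lt(abs(skeleton_length(m, vox) / ln$truth - 1), 0.10)
  }
})

test_that("ZYP1 signals classify into punctate and elongated segments", {
  spec <- small_spec(seed = 15)
  vox <- spec$voxel_size
  ns <- asNamespace("meioclock")
  arr <- array(0, spec$shape)
  # three point-like blobs
  for (ct in list(c(2, 1.0, 1.0), c(3, 1.0, 5.0), c(4, 5.0, 1.0))) {
    seg <- rbind(ct - c(0, 0, 0.05), ct + c(0, 0, 0.05))
    arr[ns$tube_voxels(seg, 0.08, spec$shape, vox)] <- 1500
  }
  # one drawn 5-um stretch
  t <- seq(0, 1, by = 0.002)
  arr[ns$tube_voxels(cbind(3, 3.5, 0.7 + 5 * t), 0.08, spec$shape, vox)] <- 1500
  arr <- ns$finish_channel(arr, spec)
  z <- classify_zyp1(arr, vox, threshold = "otsu")
  expect_equal(z$n_punctate, 3L)
  expect_equal(z$n_elongated, 1L)
  expect_lt(abs(z$total_length_um - 5) / 5, 0.25)
  blank <- classify_zyp1(array(0, c(6, 6, 6)), vox)
  expect_equal(blank, list(n_punctate = 0L, n_elongated = 0L,
                           total_length_um = 0, lengths_um = numeric(0)))
})

test_that("coalignment detection separates parallel from irregular", {
  spec <- small_spec(seed = 16)
  vox <- spec$voxel_size
  ph <- make_phantom("parallel_pair", spec, sep_um = 0.3, length_um = 5)
  nrm <- normalize_channel(ph$asy1)
  m <- nrm > threshold_otsu(nrm)
  g <- detect_parallel_axes(m, vox)
  expect_equal(g$n_parallel, 1L)
  expect_equal(g$n_irregular, 0L)
  # far-apart tracks are not coaligned: two irregulars
  ph <- make_phantom("parallel_pair", spec, sep_um = 3, length_um = 5)
  nrm <- normalize_channel(ph$asy1)
  m <- nrm > threshold_otsu(nrm)
  g <- detect_parallel_axes(m, vox)
  expect_equal(g$n_parallel, 0L)
  expect_equal(g$n_irregular, 2L)
})

test_that("coalignment counts recover rendered ground truth", {
  cfg <- quantify_config()
  hits <- 0L
  for (s in 1:8) {
    tr <- small_truth(cell_id = paste0("par", s), H = 30, asyn = 28,
                      zyp = 10, n_prom = 4L, n_par = 3L, n_irr = 1L,
                      n_pun = 2L, n_elo = 2L)
    st <- render_cell(tr, small_spec(seed = 100 + s))
    m <- quantify_cell(st, cfg)
    if (abs(m$n_parallel - 3) <= 1) hits <- hits + 1L
  }
  expect_gte(hits, 6L)
})

test_that("linear HEI10 on unsynapsed axes is flagged, compact foci are not", {
  spec <- small_spec(seed = 18)
  vox <- spec$voxel_size
  shape <- spec$shape
  ns <- asNamespace("meioclock")
  t <- seq(0, 1, by = 0.002)
  line_pts <- cbind(3, 3, 1.5 + 3 * t)           # 3-um line
  asy <- array(FALSE, shape)
  asy[ns$tube_voxels(line_pts, 0.08, shape, vox)] <- TRUE
  hei <- array(0, shape)
  hei[ns$tube_voxels(line_pts, 0.08, shape, vox)] <- 500
  foci <- particle_analysis(hei > 100, hei, 4, vox)
  expect_true(flag_linear_hei10(foci, asy, shape, vox))
  # same line far from any ASY1 signal
  far_asy <- array(FALSE, shape)
  far_asy[ns$tube_voxels(cbind(1, 5.5, 1.5 + 3 * t), 0.08, shape, vox)] <- TRUE
  expect_false(flag_linear_hei10(foci, far_asy, shape, vox))
  # compact focus on ASY1: too short to be linear
  blob <- array(0, shape)
  b <- ns$focus_blob(c(3, 3, 3), c(0.12, 0.08, 0.08), 500, shape, vox)
  blob[b$idx] <- b$val
  bf <- particle_analysis(blob > 100, blob, 4, vox)
  expect_false(flag_linear_hei10(bf, asy, shape, vox))
})

test_that("whole-cell quantification is intensity-scale invariant", {
  tr <- small_truth(H = 55, asyn = 20, zyp = 25, n_prom = 6L)
  st <- render_cell(tr, small_spec(seed = 19))
  cfg <- quantify_config(detect_geometry = FALSE)
  m1 <- quantify_cell(st, cfg)
  st3 <- st
  for (ch in c("hei10", "asy1", "zyp1")) st3[[ch]] <- st3[[ch]] * 3
  m3 <- quantify_cell(st3, cfg)
  inv <- c("accumulation_pct", "n_prominent", "asy1_length_um",
           "zyp1_length_um", "n_punctate", "n_elongated", "qc_pass")
  expect_equal(m1[inv], m3[inv], tolerance = 1e-6)
})

test_that("a blank stack fails quality control", {
  blank <- meioclock:::new_stack3c(array(0, c(8, 16, 16)),
                                   array(0, c(8, 16, 16)),
                                   array(0, c(8, 16, 16)),
                                   c(0.125, 0.04, 0.04), cell_id = "blank")
  m <- quantify_cell(blank)
  expect_false(m$qc_pass)
  expect_equal(m$accumulation_pct, 0)
})

test_that("noiseless rendered cells are measured within operator tolerances", {
  tr <- small_truth(H = 60, asyn = 24, zyp = 30, n_prom = 7L, n_par = 1L,
                    n_irr = 2L, n_pun = 2L, n_elo = 3L)
  st <- render_cell(tr, small_spec(seed = 20))
  m <- quantify_cell(st)
  expect_true(m$qc_pass)
  expect_lt(abs(m$accumulation_pct - 60), 3)
  expect_equal(m$n_prominent, 7L)
  expect_lt(abs(m$asy1_length_um - 24) / 24, 0.2)
  expect_false(m$has_linear_hei10)
  # fully synapsed cell: ASY1 skeleton below half a micrometre
  tr0 <- small_truth(H = 80, asyn = 0, zyp = 40, n_prom = 6L, n_par = 0L,
                     n_irr = 0L)
  st0 <- render_cell(tr0, small_spec(seed = 21))
  m0 <- quantify_cell(st0, quantify_config(detect_geometry = FALSE))
  expect_lt(m0$asy1_length_um, 0.5)
})
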