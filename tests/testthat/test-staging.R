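make_cells <- function(n, H, asy = NULL, foci = NULL, genotype = "G",
                       plant = "p1", qc = TRUE, linear = FALSE) {
  data.frame(cell_id = paste0(genotype, "_", seq_len(n)),
             plant_id = plant, genotype = genotype,
             accumulation_pct = H,
             asy1_length_um = if (is.null(asy)) rep(10, n) else asy,
             n_prominent = if (is.null(foci)) rep(10L, n) else foci,
             qc_pass = qc, has_linear_hei10 = linear,
             stringsAsFactors = FALSE)
}

test_that("background cutoff is the control maximum on the grid", {
  r <- background_cutoff(c(5.1, 7, 12))
  expect_equal(r$cutoff_pct, 12)
  expect_equal(r$trace$value[r$trace$statistic == "mean"], mean(c(5.1, 7, 12)))
  expect_equal(background_cutoff(c(0, 0, 0))$cutoff_pct, 0)
  expect_equal(background_cutoff(c(3.2, 8.9, 11.4))$cutoff_pct, 11.4)
  expect_equal(background_cutoff(c(3.2, 8.93))$cutoff_pct, 9)
  expect_error(background_cutoff(numeric(0)), "empty control set")
  # the choice is reproducible from the trace
  expect_equal(ceiling(r$trace$value[r$trace$statistic == "max"] / 0.1) * 0.1,
               r$cutoff_pct)
})

test_that("cutoff filtering partitions the input exactly", {
  cells <- rbind(make_cells(500, H = runif(500, 12, 100)),
                 make_cells(100, H = runif(100, 0, 11.9)))
  f <- filter_by_cutoff(cells, 12)
  expect_equal(nrow(f$retained), 500)
  expect_equal(nrow(f$excluded), 100)
  expect_equal(nrow(f$retained) + nrow(f$excluded), nrow(cells))
  # linear-HEI10 cells are always excluded, regardless of level
  lin <- make_cells(7, H = 80, linear = TRUE)
  mixed <- rbind(cells, lin)
  f2 <- filter_by_cutoff(mixed, 12)
  expect_equal(sum(f2$excluded$exclusion_reason == "linear_hei10"), 7)
  expect_false(any(f2$retained$has_linear_hei10))
  # cutoff 0: only QC exclusions apply
  bad <- make_cells(5, H = 50, qc = FALSE)
  f3 <- filter_by_cutoff(rbind(cells, bad), 0)
  expect_equal(nrow(f3$excluded), 5)
  expect_true(all(f3$excluded$exclusion_reason == "qc_fail"))
})

test_that("plateau search returns the smallest flat candidate", {
  # already-flat population: the first candidate passes
  flat <- list(genotype_params("F", beta0 = log(30), beta1 = 0,
                               plant_sd = 0.05, gamma_shape = 5))
  tab <- truth_to_measurements(
    simulate_cell_table(flat, 3, 60, h_range = c(13, 90), seed = 31))
  pc <- plateau_cutoff(tab, alpha = 0.01, grid = 13:90)
  expect_equal(pc$cutoff_pct, 13)
  expect_true(all(c("cutoff", "genotype", "p_decay") %in% names(pc$trace)))
  # strong decay over the full range: no candidate is ever flat
  steep <- list(genotype_params("S", beta0 = log(400), beta1 = -0.06,
                                plant_sd = 0.05, gamma_shape = 8,
                                total_axis_um = 500))
  tab <- truth_to_measurements(
    simulate_cell_table(steep, 3, 80, h_range = c(13, 90), seed = 32))
  pc <- plateau_cutoff(tab, alpha = 0.05, grid = seq(13, 60, by = 1))
  expect_true(is.na(pc$cutoff_pct))
  expect_gt(nrow(pc$trace), 0)
})

test_that("plateau cutoff is non-decreasing in alpha", {
  tab <- truth_to_measurements(
    simulate_cell_table(plateau_params(), 3, 60, h_range = c(13, 90),
                        seed = 33, h_plateau = 50))
  c_lo <- plateau_cutoff(tab, alpha = 0.01)$cutoff_pct
  c_hi <- plateau_cutoff(tab, alpha = 0.20)$cutoff_pct
  expect_false(is.na(c_lo) || is.na(c_hi))
  expect_gte(c_hi, c_lo)
})

test_that("late-pachytene calibration finds a constructed crossing point", {
  set.seed(34)
  n <- 400
  H <- runif(n, 13, 90)
  foci <- ifelse(H > 60, 17L, 30L)  # noiseless crossing at 60
  cells <- make_cells(n, H = H, foci = foci)
  lp <- late_pachytene_cutoffs(cells, c(G = 17), grid = 13:90)
  expect_lte(abs(lp$G$cutoff_pct - 60), 1)
  # the choice reproduces from the trace
  tr <- lp$G$trace
  ok <- which(!is.na(tr$distance))
  expect_equal(tr$cutoff[min(ok[tr$distance[ok] == min(tr$distance[ok])])],
               lp$G$cutoff_pct)
  # degenerate flat case: smallest candidate wins
  flat <- make_cells(200, H = runif(200, 13, 90), foci = 17L)
  lp2 <- late_pachytene_cutoffs(flat, c(G = 17), grid = 13:90)
  expect_equal(lp2$G$cutoff_pct, 13)
  # staggered crossing points resolve per genotype, in input order
  set.seed(35)
  mk <- function(g, h_star) {
    H <- runif(300, 13, 90)
    make_cells(300, H = H, foci = ifelse(H > h_star, 17L, 30L), genotype = g)
  }
  cells4 <- rbind(mk("A", 44), mk("B", 59), mk("C", 48), mk("D", 65))
  lp4 <- late_pachytene_cutoffs(cells4, c(A = 17, B = 17, C = 17, D = 17))
  got <- vapply(lp4, function(x) x$cutoff_pct, 0)
  expect_equal(names(got), c("A", "B", "C", "D"))
  expect_true(all(abs(got - c(44, 59, 48, 65)) <= 1))
  # insufficient cells above every candidate is an error naming the genotype
  tiny <- make_cells(12, H = runif(12, 1, 5), foci = 17L, genotype = "Z")
  expect_error(late_pachytene_cutoffs(tiny, c(Z = 17)), "Z")
})

test_that("diploid axis doubling applies exactly once", {
  cells <- rbind(make_cells(5, H = 50, asy = 25, genotype = "DIP"),
                 make_cells(5, H = 50, asy = 40, genotype = "TET"))
  out <- normalize_diploid(cells, "DIP")
  expect_equal(out$asy1_length_um[out$genotype == "DIP"], rep(50, 5))
  expect_equal(out$asy1_length_um[out$genotype == "TET"], rep(40, 5))
  expect_error(normalize_diploid(out, "DIP"), "already applied")
  expect_error(normalize_diploid(cells, "NOPE"), "NOPE")
})
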