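test_that("generator parameters are validated with named messages", {
  expect_error(genotype_params("X", beta0 = NA, beta1 = 0), "beta0")
  expect_error(genotype_params("X", beta0 = 1, beta1 = Inf), "beta1")
  expect_error(genotype_params("X", beta0 = 1, beta1 = 0, gamma_shape = 0),
               "gamma_shape")
  expect_error(genotype_params("X", beta0 = 1, beta1 = 0, plant_sd = -1),
               "plant_sd")
  expect_error(render_spec(prominent_focus_amp = 10, dispersed_focus_amp = 10),
               "prominent_focus_amp")
  expect_error(render_spec(voxel_size = c(0.1, 0)), "voxel_size")
  p <- two_genotypes()
  expect_error(simulate_cell_table(p, 2, 5, h_range = c(-5, 50)), "h_range")
  expect_error(simulate_cell_table(p, 0, 5), ">= 1")
})

test_that("cell tables are seed-deterministic and per-cell reproducible", {
  p <- two_genotypes()
  t1 <- simulate_cell_table(p, 3, 10, seed = 42)
  t2 <- simulate_cell_table(p, 3, 10, seed = 42)
  expect_identical(t1, t2)
  t3 <- simulate_cell_table(p, 3, 10, seed = 43)
  expect_false(identical(t1, t3))
  # substream design: the first plant's cells do not depend on later plants
  t4 <- simulate_cell_table(p, 3, 25, seed = 42)
  expect_equal(t1[t1$plant_id == "GA_p1", ]$asynapsis_true,
               t4[t4$plant_id == "GA_p1", ]$asynapsis_true[1:10])
})

test_that("tabular moments match the stated Gamma / count models", {
  # no decay, no plant effect: mean asynapsis independent of H (flat trend)
  flat <- list(genotype_params("F", beta0 = log(50), beta1 = 0, plant_sd = 0,
                               gamma_shape = 3))
  tab <- simulate_cell_table(flat, 1, 4000, seed = 7)
  lo <- tab$asynapsis_true[tab$H_true < 50]
  hi <- tab$asynapsis_true[tab$H_true >= 50]
  expect_lt(abs(mean(lo) - mean(hi)) / mean(tab$asynapsis_true), 0.06)

  # near-deterministic shape limit: empirical mean within 1% of closed form
  det <- list(genotype_params("D", beta0 = log(30), beta1 = -0.02,
                              plant_sd = 0, gamma_shape = 1e6))
  tab <- simulate_cell_table(det, 1, 8000, h_range = c(40, 40.0001), seed = 8)
  expect_lt(abs(mean(tab$asynapsis_true) / (30 * exp(-0.02 * 40)) - 1), 0.01)

  # closed-form decay means: stalled neo-like flat at 200 um while a
  # diploid-like genotype has decayed well below it at H = 49
  mix <- list(genotype_params("NEOish", beta0 = log(200), beta1 = 0,
                              plant_sd = 0, gamma_shape = 50,
                              total_axis_um = 500),
              genotype_params("DIPish", beta0 = log(50) + 0.36, beta1 = -0.03,
                              plant_sd = 0, gamma_shape = 50))
  tab <- simulate_cell_table(mix, 1, 3000, h_range = c(48.9, 49.1), seed = 9)
  m_neo <- mean(tab$asynapsis_true[tab$genotype == "NEOish"])
  m_dip <- mean(tab$asynapsis_true[tab$genotype == "DIPish"])
  expect_lt(abs(m_neo / 200 - 1), 0.05)
  expect_lt(abs(m_dip / (50 * exp(0.36) * exp(-0.03 * 49)) - 1), 0.05)
  expect_lt(m_dip, m_neo)

  # count moments: Poisson crossover model and NB quadrivalents
  cp <- list(genotype_params("C", beta0 = log(50), beta1 = 0, plant_sd = 0,
                             gamma_shape = 1e6, co_intercept = log(17),
                             co_slope = 0, quad_mean = 3, nb_theta = 5))
  tab <- simulate_cell_table(cp, 1, 5000, seed = 10)
  expect_lt(abs(mean(tab$n_co_true) - 17), 3 * sqrt(17 / 5000) * 2)
  expect_lt(abs(mean(tab$n_quadrivalent_true) - 3), 0.15)
  v_expect <- 3 + 9 / 5  # NB variance mu + mu^2/theta
  expect_lt(abs(var(tab$n_quadrivalent_true) / v_expect - 1), 0.15)
})

test_that("rendered cells conserve track lengths and pre-blur accumulation", {
  spec <- small_spec(seed = 11)
  tr <- small_truth(H = 60, asyn = 25, zyp = 30, n_prom = 6)
  st <- render_cell(tr, spec)
  expect_s3_class(st, "stack3c")
  expect_lt(abs(attr(st, "asy1_track_um") / 25 - 1), 0.02)
  expect_lt(abs(attr(st, "zyp1_track_um") / 30 - 1), 0.02)
  expect_equal(attr(st, "h_pre"), 60, tolerance = 1e-8)
  # oracle: integral of the pre-blur field over the truth focus mask
  pre <- attr(st, "hei10_preblur")
  pm <- attr(st, "truth_masks")$prominent
  expect_gt(100 * sum(pre[pm]) / sum(pre), 59)
  expect_lt(100 * sum(pre[pm]) / sum(pre), 61)
  # rendering is deterministic given truth + spec
  st2 <- render_cell(tr, spec)
  expect_identical(st$hei10, st2$hei10)
  expect_identical(st$asy1, st2$asy1)
})

test_that("degenerate focus configurations render consistently", {
  spec <- small_spec(seed = 12)
  # all signal in prominent foci
  tr <- small_truth(H = 100, asyn = 10, zyp = 25, n_prom = 5)
  tr$dispersed_fraction_true <- 0
  st <- render_cell(tr, spec)
  pre <- attr(st, "hei10_preblur")
  pm <- attr(st, "truth_masks")$prominent
  expect_equal(100 * sum(pre[pm]) / sum(pre), 100, tolerance = 1e-8)
  # no prominent foci: empty truth mask, zero accumulation
  tr0 <- small_truth(H = 0, asyn = 10, zyp = 25, n_prom = 0L)
  st0 <- render_cell(tr0, spec)
  expect_false(any(attr(st0, "truth_masks")$prominent))
  expect_equal(attr(st0, "h_pre"), 0)
})

test_that("infeasible axis budgets are rejected by name", {
  spec <- small_spec()
  tr <- small_truth(asyn = 5000, zyp = 5000)
  expect_error(render_cell(tr, spec), "axis budget infeasible")
  tr2 <- small_truth()
  tr2$H_true <- NA
  expect_error(render_cell(tr2, spec), "H_true")
})

test_that("phantoms carry analytic truth", {
  spec <- small_spec(seed = 13)
  ph <- make_phantom("line", spec, n_voxels = 101)
  expect_equal(attr(ph, "truth")$length_um, 100 * 0.04)
  ph <- make_phantom("helix", spec, radius_um = 1, pitch_um = 1, turns = 3)
  expect_equal(attr(ph, "truth")$length_um,
               3 * sqrt((2 * pi)^2 + 1), tolerance = 1e-8)
  ph <- make_phantom("parallel_pair", spec, sep_um = 0.3, length_um = 4)
  expect_equal(attr(ph, "truth")$n_parallel, 1L)
  expect_equal(attr(ph, "truth")$separation_um, 0.3)
  ph <- make_phantom("bubble", spec, length_um = 3)
  expect_gt(attr(ph, "truth")$length_um, 2 * 3)  # two arcs, each > extent
  expect_error(make_phantom("line", spec, n_voxels = 10000L), "fit")
  expect_error(make_phantom("helix", spec, radius_um = 50), "fit")
})
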