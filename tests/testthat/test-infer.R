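sim_cells <- function(params, plants = 4, cells = 40, seed = 1,
                      h_range = c(12, 100)) {
  truth_to_measurements(
    simulate_cell_table(params, plants, cells, h_range = h_range, seed = seed))
}

test_that("the Laplace objective reaches the Gamma-GLM limit as sigma_u -> 0", {
  cells <- sim_cells(two_genotypes(plant_sd = 0), plants = 2, cells = 80,
                     seed = 41)
  cells$genotype <- factor(cells$genotype)
  X <- model.matrix(~ 0 + genotype + genotype:accumulation_pct, cells)
  y <- cells$asy1_length_um
  g <- glm(y ~ 0 + X, family = stats::Gamma(link = "log"))
  mu <- fitted(g)
  # profile the Gamma shape at the GLM coefficients (beta ML is shape-free)
  prof <- function(nu) sum(dgamma(y, shape = nu, rate = nu / mu, log = TRUE))
  nu_hat <- optimize(prof, c(0.1, 100), maximum = TRUE)$maximum
  ll_glm <- prof(nu_hat)
  plant <- as.integer(factor(cells$plant_id))
  ll_laplace <- -meioclock:::laplace_nll(c(coef(g), -9, log(nu_hat)),
                                         X, y, plant, ncol(X))
  expect_lt(abs(ll_laplace - ll_glm) / abs(ll_glm), 1e-4)
})

test_that("sigma_u = 0 data recover plain GLM coefficients", {
  # with finitely many plants the fitted sigma_u absorbs plant-mean noise of
  # order resid_sd/sqrt(cells_per_plant); 100 cells/plant puts that near 0.06
  cells <- sim_cells(two_genotypes(plant_sd = 0), plants = 6, cells = 100,
                     seed = 42)
  fit <- fit_gamma_decay(cells)
  expect_lt(fit$sigma_u, 0.08)
  g <- glm(asy1_length_um ~ 0 + genotype + genotype:accumulation_pct,
           family = stats::Gamma(link = "log"),
           data = transform(cells, genotype = factor(genotype)))
  expect_lt(max(abs(fit$coefficients - coef(g)) /
                  pmax(abs(coef(g)), 0.01)), 0.01)
})

test_that("the decay GLMM agrees with an independent mixed-model fitter", {
  cells <- sim_cells(two_genotypes(beta1 = c(-0.03, -0.01)), plants = 4,
                     cells = 40, seed = 43)
  fit <- fit_gamma_decay(cells)
  tmb <- glmmTMB::glmmTMB(
    asy1_length_um ~ 0 + genotype + genotype:accumulation_pct +
      (1 | plant_id),
    family = stats::Gamma(link = "log"),
    data = transform(cells, genotype = factor(genotype)))
  b_tmb <- glmmTMB::fixef(tmb)$cond
  expect_lt(max(abs(fit$coefficients - b_tmb[names(fit$coefficients)]) /
                  pmax(abs(b_tmb[names(fit$coefficients)]), 0.005)), 0.02)
  expect_lt(abs(fit$loglik - as.numeric(logLik(tmb))), 0.5)
  sd_tmb <- sqrt(as.numeric(glmmTMB::VarCorr(tmb)$cond$plant_id[1, 1]))
  expect_lt(abs(fit$sigma_u - sd_tmb), 0.03)
})

test_that("zero asynapsis values are replaced and recorded", {
  cells <- sim_cells(two_genotypes(), plants = 2, cells = 30, seed = 44)
  cells$asy1_length_um[1:3] <- 0
  fit <- fit_gamma_decay(cells)
  expect_equal(fit$zero_replacement,
               min(cells$asy1_length_um[cells$asy1_length_um > 0]) / 2)
  expect_true(is.finite(fit$loglik))
})

test_that("single-plant-per-genotype data fall back to the GLM limit", {
  cells <- sim_cells(two_genotypes(), plants = 1, cells = 50, seed = 45)
  fit <- fit_gamma_decay(cells)
  expect_true(fit$glm_fallback)
  expect_equal(fit$sigma_u, 0)
})

test_that("asynapsis predictions follow the closed form with delta-method CIs", {
  cells <- sim_cells(two_genotypes(), plants = 4, cells = 40, seed = 46)
  fit <- fit_gamma_decay(cells)
  pr <- predict_asynapsis(fit, 20)
  for (g in fit$genotypes) {
    expect_equal(pr$mean_um[pr$genotype == g],
                 exp(fit$beta0[[g]] + fit$beta1[[g]] * 20), tolerance = 1e-10)
  }
  expect_true(all(pr$lo_um < pr$mean_um & pr$mean_um < pr$hi_um))
  expect_error(predict_asynapsis(fit, 120), "\\[0, 100\\]")
  # CI width shrinks with sample size
  wide <- predict_asynapsis(fit_gamma_decay(
    sim_cells(two_genotypes(), 2, 12, seed = 47)), 20)
  narrow <- predict_asynapsis(fit_gamma_decay(
    sim_cells(two_genotypes(), 4, 125, seed = 47)), 20)
  rel_w <- function(p) (p$hi_um - p$lo_um) / p$mean_um
  expect_true(all(rel_w(narrow) < rel_w(wide)))
})

test_that("Wald contrasts follow textbook Holm arithmetic", {
  z <- qnorm(1 - c(0.01, 0.02, 0.20) / 2)
  fake <- structure(list(coefficients = setNames(z, c("a", "b", "c")),
                         vcov = diag(3, ncol = 3, nrow = 3)^0),
                    class = "count_fit")
  fake$vcov <- diag(1, 3); dimnames(fake$vcov) <- list(c("a","b","c"),
                                                       c("a","b","c"))
  ct <- wald_contrasts(fake, list(A = c(a = 1), B = c(b = 1), C = c(c = 1)))
  expect_equal(ct$p_raw, c(0.01, 0.02, 0.20), tolerance = 1e-12)
  expect_equal(ct$p_holm, c(0.03, 0.04, 0.20), tolerance = 1e-12)
  # invariants: adjusted >= raw; single contrast unchanged; self-contrast p=1
  expect_true(all(ct$p_holm >= ct$p_raw))
  ct1 <- wald_contrasts(fake, list(A = c(a = 1)))
  expect_equal(ct1$p_holm, ct1$p_raw)
  self <- wald_contrasts(fake, list(S = c(a = 1, b = 0, c = 0) -
                                      c(a = 1, b = 0, c = 0)))
  expect_equal(self$estimate, 0)
  expect_equal(self$p_raw, 1)
  expect_error(wald_contrasts(fake, list(bad = c(zzz = 1))), "zzz")
})

test_that("count models recover their generators across families and links", {
  p <- list(genotype_params("A", beta0 = log(10), beta1 = 0, plant_sd = 0.05,
                            quad_mean = 3.0),
            genotype_params("B", beta0 = log(10), beta1 = 0, plant_sd = 0.05,
                            quad_mean = 0.9),
            genotype_params("C", beta0 = log(10), beta1 = 0, plant_sd = 0.05,
                            quad_mean = 0.3))
  cells <- sim_cells(p, plants = 2, cells = 100, seed = 48)
  fit <- fit_count_model(cells, "n_quadrivalent", family = "nbinom",
                         random_intercept = "plant")
  means <- exp(fit$coefficients[1:3])
  true <- c(3.0, 0.9, 0.3)
  se_mc <- sqrt((true + true^2 / 5) / 200)
  expect_true(all(abs(means - true) < 4 * se_mc))
  expect_s3_class(fit, "count_fit")
  # Poisson data fitted as negative binomial: dispersion diverges and the
  # coefficients match the Poisson fit
  cells$y <- rpois(nrow(cells), 6)
  f_nb <- fit_count_model(cells, "y", family = "nbinom",
                          random_intercept = "none")
  f_po <- fit_count_model(cells, "y", family = "poisson",
                          random_intercept = "none")
  expect_true(f_nb$poisson_limit)
  expect_lt(max(abs(f_nb$coefficients - f_po$coefficients) /
                  abs(f_po$coefficients)), 0.02)
  cells$z <- 0L
  expect_error(fit_count_model(cells, "z"), "all-zero")
})

test_that("the identity-link elongation model reads as initial count + rate", {
  set.seed(49)
  n <- 600
  L <- runif(n, 0, 40)
  geno <- rep(c("NEO", "EST"), each = n / 2)
  a <- ifelse(geno == "NEO", 3, 1); b <- ifelse(geno == "NEO", 0.05, 0.12)
  cells <- data.frame(genotype = geno, plant_id = "p",
                      zyp1_length_um = L,
                      n_elongated = rpois(n, a + b * L))
  fit <- fit_count_model(cells, "n_elongated", covariate = "zyp1_length_um",
                         family = "poisson", link = "identity",
                         random_intercept = "none")
  co <- fit$coefficients
  expect_lt(abs(co[["genotypeEST"]] - 1), 0.35)
  expect_lt(abs(co[["genotypeNEO"]] - 3), 0.75)
  expect_lt(abs(co[["genotypeEST:.x"]] - 0.12), 0.03)
  expect_lt(abs(co[["genotypeNEO:.x"]] - 0.05), 0.03)
  # EST slope exceeds NEO slope, NEO intercept exceeds EST intercept
  ct <- wald_contrasts(fit, list(
    slope_diff = c(`genotypeEST:.x` = 1, `genotypeNEO:.x` = -1),
    int_diff = c(genotypeNEO = 1, genotypeEST = -1)))
  expect_true(all(ct$p_holm < 0.05))
  expect_gt(ct$estimate[1], 0)
  expect_gt(ct$estimate[2], 0)
})

test_that("crossover-asynapsis coupling is detected and destroyed by shuffling", {
  set.seed(50)
  n <- 200
  asy <- runif(n, 0, 200)
  cells <- data.frame(asy1_length_um = asy,
                      n_prominent = rpois(n, exp(log(17) + 0.0015 * asy)))
  fit <- fit_co_asynapsis(cells)
  b <- fit$coefficients[2]
  se <- sqrt(fit$vcov[2, 2])
  expect_lt(abs(b - 0.0015), 4 * se)
  expect_lt(fit$slope_p, 0.05)
  expect_false(fit$small_sample)
  expect_true(fit_co_asynapsis(cells[1:10, ])$small_sample)
  # a log1p covariate is exposed as the alternative model
  expect_silent(fit_co_asynapsis(cells, covariate = "log1p"))
  # null slope stays non-significant at roughly the nominal rate
  rej <- 0
  for (r in 1:30) {
    set.seed(600 + r)
    nullc <- data.frame(asy1_length_um = runif(80, 0, 200),
                        n_prominent = rpois(80, 17))
    if (fit_co_asynapsis(nullc)$slope_p < 0.05) rej <- rej + 1
  }
  expect_lte(rej, 6)
  # within-genotype shuffle destroys a cross-genotype association
  set.seed(51)
  geno <- rep(c("A", "B", "C"), each = 100)
  asy_g <- c(A = 5, B = 60, C = 180)[geno] * runif(300, 0.8, 1.2)
  strong <- data.frame(genotype = geno, asy1_length_um = asy_g,
                       n_prominent = rpois(300, exp(log(12) + 0.004 * asy_g)))
  expect_gt(fit_co_asynapsis(strong)$r2_marginal, 0.3)
  shuffled <- do.call(rbind, lapply(split(strong, strong$genotype), function(d) {
    d$asy1_length_um <- sample(d$asy1_length_um)
    d
  }))
  r2_within <- vapply(split(shuffled, shuffled$genotype),
                      function(d) fit_co_asynapsis(d)$r2_marginal, 0)
  expect_true(all(r2_within < 0.15))
})

test_that("pseudo-R2 partitions variance as expected", {
  # no fixed-effect signal: marginal near zero; sigma_u = 0: conditional equal
  flat <- list(genotype_params("F", beta0 = log(30), beta1 = 0, plant_sd = 0,
                               gamma_shape = 3))
  fit0 <- fit_gamma_decay(sim_cells(flat, 2, 80, seed = 52))
  r2 <- pseudo_r2(fit0)
  expect_lt(r2[["marginal"]], 0.05)
  expect_equal(r2[["marginal"]], r2[["conditional"]], tolerance = 0.01)
  # paper-like regime: strong conditional explanatory power
  fit1 <- fit_gamma_decay(sim_cells(default_genotype_params(), 4, 40,
                                    seed = 53))
  expect_gte(pseudo_r2(fit1)[["conditional"]], 0.6)
  expect_true(all(pseudo_r2(fit1) >= 0 & pseudo_r2(fit1) <= 1))
})

test_that("family selection prefers the generator's dispersion regime", {
  set.seed(54)
  cells <- data.frame(genotype = rep(c("A", "B"), each = 200),
                      plant_id = "p")
  cells$over <- rnbinom(400, size = 2, mu = 8)   # strongly overdispersed
  cells$equi <- rpois(400, 8)
  over <- select_family(cells, list(
    poisson = list(response = "over", family = "poisson",
                   random_intercept = "none"),
    nbinom = list(response = "over", family = "nbinom",
                  random_intercept = "none")))
  expect_equal(over$chosen_name, "nbinom")
  expect_true(any(over$diagnostics$overdispersed[
    over$diagnostics$candidate == "poisson"]))
  equi <- select_family(cells, list(
    poisson = list(response = "equi", family = "poisson",
                   random_intercept = "none"),
    nbinom = list(response = "equi", family = "nbinom",
                  random_intercept = "none")))
  expect_equal(equi$chosen_name, "poisson")
  # identical candidates: first by declaration order, tie logged
  same <- select_family(cells, list(
    first = list(response = "equi", family = "poisson",
                 random_intercept = "none"),
    second = list(response = "equi", family = "poisson",
                  random_intercept = "none")))
  expect_equal(same$chosen_name, "first")
  expect_true(same$tie)
})
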