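# Exponential-decay Gamma-GLMM of asynapsis against HEI10 accumulation.
#
# Model: asy1_length ~ Gamma(shape nu, mean mu), log mu = beta0_g +
# beta1_g * H + u_plant, u_plant ~ N(0, sigma_u^2). The marginal likelihood
# integrates the plant random intercepts by a Laplace approximation; with a
# single scalar intercept per plant the inner mode has a closed-form Newton
# update, so each likelihood evaluation reduces to per-plant scalar
# iterations over sufficient statistics.

# Per-plant Laplace contribution machinery. For plant j with offset
# eta0_i = x_i' beta: A_j = sum y_i exp(-eta0_i), B_j = sum eta0_i,
# C_j = sum log y_i, n_j = #cells. The inner objective is
#   h(u) = nu * (n_j log nu - B_j - n_j u) + (nu - 1) C_j - n_j lgamma(nu)
#          - nu * A_j * exp(-u) - u^2 / (2 s2) - 0.5 log(2 pi s2)
laplace_nll <- function(theta, X, y, plant, n_beta) {
  beta <- theta[seq_len(n_beta)]
  sigma <- exp(theta[n_beta + 1])
  nu <- exp(theta[n_beta + 2])
  eta0 <- pmin(pmax(drop(X %*% beta), -30), 30)  # guard optimizer excursions
  w <- y * exp(-eta0)
  A <- rowsum(w, plant)[, 1]
  B <- rowsum(eta0, plant)[, 1]
  Cs <- rowsum(log(y), plant)[, 1]
  nj <- tabulate(plant)[sort(unique(plant))]
  s2 <- sigma^2
  # Newton for the inner mode u_j
  u <- rep(0, length(A))
  for (it in 1:25) {
    e <- exp(-u)
    g <- nu * (A * e - nj) - u / s2
    hess <- -nu * A * e - 1 / s2
    step <- g / hess
    u <- u - step
    if (max(abs(step)) < 1e-12) break
  }
  e <- exp(-u)
  h <- nu * (nj * log(nu) - B - nj * u) + (nu - 1) * Cs - nj * lgamma(nu) -
    nu * A * e - u^2 / (2 * s2) - 0.5 * log(2 * pi * s2)
  hpp <- -nu * A * e - 1 / s2
  ll <- sum(h + 0.5 * log(2 * pi) - 0.5 * log(-hpp))
  if (!is.finite(ll)) return(1e10)
  -ll
}

#' Fit the exponential-decay Gamma-GLMM
#'
#' Maximizes the Laplace-approximated marginal Gamma likelihood with log
#' link, per-genotype intercept and decay exponent
#' (`log mean = beta0_g + beta1_g * H + u_plant`), a shared plant
#' random-intercept SD `sigma_u`, and a shared Gamma shape. Optimization is
#' L-BFGS-B over (fixed effects, log sigma_u, log shape), started from a
#' plain Gamma-GLM. Exactly-zero asynapsis values (fully synapsed cells) are
#' incompatible with the Gamma likelihood and are replaced by half the
#' smallest positive measured length, recorded in the fit. With a single
#' plant per genotype the random intercept is unidentifiable from the
#' genotype intercepts; the fit then falls back to the GLM limit
#' (`sigma_u` pinned at ~0) and is flagged.
#'
#' @param cells table with `genotype`, `plant_id`, `accumulation_pct`, and
#'   `asy1_length_um`.
#' @param start optional previous `decay_fit` used as a warm start.
#' @param compute_vcov logical; compute the fixed-effect covariance
#'   (observed information at the optimum, conditional on the variance
#'   parameters, as mixed-model software conventionally reports).
#' @return a `decay_fit`: per-genotype `beta0`/`beta1`, `vcov`, `sigma_u`,
#'   `gamma_shape`, `loglik`, `aic`, Nakagawa `r2_marginal` /
#'   `r2_conditional`, sizes, convergence and provenance fields.
#' @export
fit_gamma_decay <- function(cells, start = NULL, compute_vcov = TRUE) {
  need <- c("genotype", "plant_id", "accumulation_pct", "asy1_length_um")
  miss <- setdiff(need, names(cells))
  if (length(miss))
    stop("fit_gamma_decay: missing columns: ", paste(miss, collapse = ", "))
  cells$genotype <- factor(cells$genotype)
  y <- cells$asy1_length_um
  if (any(!is.finite(y)) || any(y < 0))
    stop("fit_gamma_decay: asy1_length_um must be finite and >= 0")
  zero_repl <- NA_real_
  if (any(y == 0)) {
    pos <- y[y > 0]
    if (!length(pos)) stop("fit_gamma_decay: all asynapsis values are zero")
    zero_repl <- min(pos) / 2
    y[y == 0] <- zero_repl
  }
  H <- cells$accumulation_pct
  genos <- levels(cells$genotype)
  if (length(genos) == 1) {
    # interaction contrasts need >= 2 levels; build the design directly
    X <- cbind(1, H)
    colnames(X) <- c(paste0("genotype", genos),
                     paste0("genotype", genos, ":accumulation_pct"))
  } else {
    X <- model.matrix(~ 0 + genotype + genotype:accumulation_pct,
                      data = transform(cells, accumulation_pct = H))
  }
  n_beta <- ncol(X)
  plant <- as.integer(factor(cells$plant_id))
  n_plants <- length(unique(plant))
  glm_fallback <- n_plants <= length(genos)

  # starting values: Gamma-GLM + moment shape
  if (!is.null(start) && inherits(start, "decay_fit") &&
      identical(start$genotypes, genos)) {
    # column order of X is (intercepts..., slopes...)
    th0 <- c(start$beta0, start$beta1)
    theta0 <- c(th0, log(max(start$sigma_u, 1e-3)), log(start$gamma_shape))
  } else {
    g0 <- tryCatch(glm(y ~ 0 + X, family = stats::Gamma(link = "log")),
                   error = function(e) NULL)
    if (is.null(g0) || any(!is.finite(coef(g0)))) {
      b0 <- rep(0, n_beta)
      b0[seq_along(genos)] <- log(pmax(tapply(y, cells$genotype, mean), 1e-3))
    } else b0 <- coef(g0)
    mu0 <- exp(pmin(pmax(drop(X %*% b0), -20), 20))
    r <- y / mu0
    shp0 <- max(0.5, min(50, 1 / max(var(r), 1e-3)))
    theta0 <- c(b0, log(0.1), log(shp0))
  }
  # parameter scaling: slope coefficients live on a ~0.01 scale while the
  # intercepts and variance parameters are O(1); without it the numeric
  # gradient in the slope directions drowns the variance-parameter signal
  n_g <- length(genos)
  pscale_beta <- c(rep(1, n_g), rep(0.01, n_g))
  if (glm_fallback) {
    # sigma_u unidentifiable: pin it at the GLM limit, optimize the rest
    obj <- function(th) laplace_nll(c(th[seq_len(n_beta)], -8,
                                      th[n_beta + 1]), X, y, plant, n_beta)
    opt <- optim(theta0[-(n_beta + 1)], obj, method = "L-BFGS-B",
                 lower = c(rep(-Inf, n_beta), -3),
                 upper = c(rep(Inf, n_beta), 6),
                 control = list(maxit = 400, factr = 1e8,
                                parscale = c(pscale_beta, 0.5)))
    opt$par <- c(opt$par[seq_len(n_beta)], -8, opt$par[n_beta + 1])
  } else {
    lower <- c(rep(-Inf, n_beta), -8, -3)
    upper <- c(rep(Inf, n_beta), 3, 6)
    ctl <- list(maxit = 400, factr = 1e8,
                parscale = c(pscale_beta, 1, 0.5))
    opt <- optim(theta0, laplace_nll, X = X, y = y, plant = plant,
                 n_beta = n_beta, method = "L-BFGS-B", lower = lower,
                 upper = upper, control = ctl)
    # guard against line-search aborts: restart from the incumbent
    for (rs in 1:2) {
      opt2 <- optim(opt$par, laplace_nll, X = X, y = y, plant = plant,
                    n_beta = n_beta, method = "L-BFGS-B", lower = lower,
                    upper = upper, control = ctl)
      improved <- opt$value - opt2$value
      if (opt2$value <= opt$value) opt <- opt2
      if (improved < 1e-6) break
    }
  }
  if (opt$convergence != 0 && opt$convergence != 52)
    stop("fit_gamma_decay: optimizer failed to converge (code ",
         opt$convergence, "): ", opt$message)
  th <- opt$par
  beta <- th[seq_len(n_beta)]
  names(beta) <- colnames(X)
  sigma_u <- exp(th[n_beta + 1])
  if (sigma_u < 2e-3) sigma_u <- 0  # boundary: effectively no plant effect
  nu <- exp(th[n_beta + 2])

  V <- NULL
  if (compute_vcov) {
    f_beta <- function(b) laplace_nll(c(b, th[n_beta + 1], th[n_beta + 2]),
                                      X, y, plant, n_beta)
    Hb <- pracma::hessian(f_beta, beta)
    V <- tryCatch(solve((Hb + t(Hb)) / 2), error = function(e)
      MASS::ginv((Hb + t(Hb)) / 2))
    dimnames(V) <- list(colnames(X), colnames(X))
  }

  idx0 <- seq_along(genos)
  idx1 <- n_beta - length(genos) + seq_along(genos)
  var_f <- var(drop(X %*% beta))
  var_e <- trigamma(nu)
  r2m <- var_f / (var_f + sigma_u^2 + var_e)
  r2c <- (var_f + sigma_u^2) / (var_f + sigma_u^2 + var_e)

  structure(list(
    genotypes = genos,
    beta0 = setNames(beta[idx0], genos),
    beta1 = setNames(beta[idx1], genos),
    coefficients = beta, vcov = V,
    coef_idx = list(intercept = setNames(idx0, genos),
                    slope = setNames(idx1, genos)),
    sigma_u = sigma_u, gamma_shape = nu,
    loglik = -opt$value, aic = 2 * (n_beta + 2) + 2 * opt$value,
    r2_marginal = unname(r2m), r2_conditional = unname(r2c),
    n_cells = nrow(cells), n_plants = n_plants,
    glm_fallback = glm_fallback, zero_replacement = zero_repl,
    optim = opt[c("convergence", "counts", "message")]),
    class = "decay_fit")
}

#' @export
coef.decay_fit <- function(object, ...) object$coefficients

#' @export
vcov.decay_fit <- function(object, ...) object$vcov

#' @export
print.decay_fit <- function(x, ...) {
  cat("<decay_fit> Gamma-GLMM, log link,", x$n_cells, "cells /", x$n_plants,
      "plants\n")
  tab <- data.frame(beta0 = x$beta0, beta1 = x$beta1)
  print(round(tab, 4))
  cat(sprintf("sigma_u = %.3f, shape = %.2f, logLik = %.1f, R2m = %.3f, R2c = %.3f\n",
              x$sigma_u, x$gamma_shape, x$loglik, x$r2_marginal,
              x$r2_conditional))
  if (x$glm_fallback) cat("note: GLM fallback (single plant per genotype)\n")
  invisible(x)
}

#' Wald p-values for the per-genotype decay exponents
#'
#' Two-sided normal-reference p-values for `beta1_g = 0`, from the fit's
#' fixed-effect covariance.
#'
#' @param fit a `decay_fit`.
#' @return named numeric vector of p-values per genotype.
#' @export
decay_p_values <- function(fit) {
  idx <- fit$coef_idx$slope
  est <- fit$coefficients[idx]
  se <- sqrt(pmax(diag(fit$vcov)[idx], 0))
  p <- 2 * pnorm(-abs(est / se))
  p[se == 0] <- 1
  setNames(p, fit$genotypes)
}

#' Predict asynapsis at a given accumulation level
#'
#' Population-level prediction (random effect at zero):
#' `mean = exp(beta0_g + beta1_g * H)` per genotype, with a 95% CI obtained
#' by the delta method on the linear predictor and exponentiated.
#'
#' @param fit a `decay_fit`.
#' @param H accumulation level in `[0, 100]` (e.g. the onset cutoff).
#' @param level confidence level.
#' @return `data.frame` with `genotype`, `mean_um`, `lo_um`, `hi_um`.
#' @export
predict_asynapsis <- function(fit, H, level = 0.95) {
  if (!is.finite(H) || H < 0 || H > 100)
    stop("predict_asynapsis: H must lie in [0, 100]")
  z <- qnorm(1 - (1 - level) / 2)
  out <- lapply(fit$genotypes, function(g) {
    cvec <- rep(0, length(fit$coefficients))
    cvec[fit$coef_idx$intercept[[g]]] <- 1
    cvec[fit$coef_idx$slope[[g]]] <- H
    est <- sum(cvec * fit$coefficients)
    se <- if (is.null(fit$vcov)) NA_real_
    else sqrt(max(drop(t(cvec) %*% fit$vcov %*% cvec), 0))
    data.frame(genotype = g, mean_um = exp(est),
               lo_um = exp(est - z * se), hi_um = exp(est + z * se))
  })
  do.call(rbind, out)
}

#' Nakagawa-style pseudo-R2
#'
#' Variance-partition R2 on the linear-predictor (latent) scale:
#' marginal = fixed / (fixed + random + residual); conditional adds the
#' random-intercept variance to the numerator. The residual variance is the
#' distribution-specific latent variance: `trigamma(shape)` for the
#' log-link Gamma, `log(1 + 1/mean)` for log-link Poisson,
#' `log(1 + 1/mean + 1/theta)` for log-link negative binomial, and the mean
#' response-scale variance for identity-link count models (where all three
#' components live on the response scale).
#'
#' @param fit a `decay_fit` or `count_fit`.
#' @return named numeric vector `c(marginal, conditional)`.
#' @export
pseudo_r2 <- function(fit) {
  if (inherits(fit, "decay_fit"))
    return(c(marginal = fit$r2_marginal, conditional = fit$r2_conditional))
  if (inherits(fit, "count_fit"))
    return(c(marginal = fit$r2_marginal, conditional = fit$r2_conditional))
  stop("pseudo_r2: unsupported fit class '", class(fit)[1], "'")
}
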