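# Count regressions (Poisson / negative binomial, GLM or plant-random-
# intercept GLMM) behind a uniform surface, fitted with glmmTMB.

#' Fit a count model for a cell-level response
#'
#' Poisson or negative-binomial regression of a count response on genotype,
#' optionally with a continuous covariate (per-genotype slopes), a
#' scorability-class fixed effect (spread quality of metaphase images), and
#' a per-plant random intercept. Used for quadrivalent and univalent counts,
#' coaligned parallels vs ASY1 length, elongated ZYP1 segments vs total ZYP1
#' length, and crossover foci vs asynapsis.
#'
#' @param cells cell table; must contain `genotype`, the response, and any
#'   requested covariate / scorability / `plant_id` columns.
#' @param response name of the count column.
#' @param covariate optional name of a continuous covariate (fitted with
#'   per-genotype slopes when more than one genotype is present).
#' @param family `"poisson"` or `"nbinom"` (negative binomial, NB2).
#' @param link `"log"` or `"identity"`.
#' @param random_intercept `"plant"` or `"none"`.
#' @param scorability optional name of a scorability-class column (fixed
#'   effect).
#' @param covariate_scale divide the covariate by this before fitting (e.g.
#'   100 to express slopes per 100 um).
#' @return a `count_fit`: coefficients, covariance, family/link, dispersion
#'   `theta` (Inf for Poisson), `sigma_u`, `aic`, Nakagawa `r2_marginal` /
#'   `r2_conditional`, a `poisson_limit` flag (NB dispersion diverging), and
#'   the underlying glmmTMB fit.
#' @export
fit_count_model <- function(cells, response, covariate = NULL,
                            family = c("nbinom", "poisson"),
                            link = c("log", "identity"),
                            random_intercept = c("plant", "none"),
                            scorability = NULL, covariate_scale = 1) {
  family <- match.arg(family)
  link <- match.arg(link)
  random_intercept <- match.arg(random_intercept)
  y <- cells[[response]]
  if (is.null(y)) stop("fit_count_model: no column '", response, "'")
  if (any(!is.finite(y)) || any(y < 0) || any(y != round(y)))
    stop("fit_count_model: response must be nonnegative integers")
  if (all(y == 0)) stop("fit_count_model: all-zero response")
  dat <- cells
  dat$.y <- y
  dat$genotype <- factor(dat$genotype)
  multi_geno <- nlevels(dat$genotype) > 1
  rhs <- if (multi_geno) "0 + genotype" else "1"
  if (!is.null(covariate)) {
    dat$.x <- cells[[covariate]] / covariate_scale
    rhs <- paste(rhs, if (multi_geno) "+ genotype:.x" else "+ .x")
  }
  if (!is.null(scorability)) {
    dat$.score <- factor(cells[[scorability]])
    if (nlevels(dat$.score) > 1) rhs <- paste(rhs, "+ .score")
  }
  if (random_intercept == "plant") rhs <- paste(rhs, "+ (1 | plant_id)")
  form <- stats::as.formula(paste(".y ~", rhs))
  fam <- if (family == "poisson") stats::poisson(link = link)
  else glmmTMB::nbinom2(link = link)
  ctrl <- glmmTMB::glmmTMBControl(
    optCtrl = list(iter.max = 500, eval.max = 500))
  fit <- suppressWarnings(glmmTMB::glmmTMB(form, data = dat, family = fam,
                                           control = ctrl))
  co <- glmmTMB::fixef(fit)$cond
  V <- as.matrix(stats::vcov(fit)$cond)
  theta <- if (family == "nbinom") stats::sigma(fit) else Inf
  poisson_limit <- is.finite(theta) && theta > 1e3
  sigma_u <- 0
  if (random_intercept == "plant") {
    vc <- glmmTMB::VarCorr(fit)$cond
    if (length(vc)) sigma_u <- sqrt(as.numeric(vc$plant_id[1, 1]))
  }
  # Nakagawa-style R2
  Xf <- model.matrix(stats::as.formula(paste("~", gsub("\\+ \\(1 \\| plant_id\\)", "", rhs))), dat)
  Xf <- Xf[, names(co), drop = FALSE]
  eta_f <- drop(Xf %*% co)
  var_f <- var(eta_f)
  if (link == "log") {
    lam <- mean(exp(eta_f))
    var_e <- if (family == "poisson") log1p(1 / lam)
    else log1p(1 / lam + 1 / theta)
    var_u <- sigma_u^2
  } else {
    lam <- mean(eta_f)
    var_e <- if (family == "poisson") max(lam, 1e-8)
    else max(lam + lam^2 / theta, 1e-8)
    var_u <- sigma_u^2
  }
  r2m <- var_f / (var_f + var_u + var_e)
  r2c <- (var_f + var_u) / (var_f + var_u + var_e)

  structure(list(coefficients = co, vcov = V, family = family, link = link,
                 theta = theta, sigma_u = sigma_u,
                 aic = stats::AIC(fit), loglik = as.numeric(stats::logLik(fit)),
                 r2_marginal = unname(r2m), r2_conditional = unname(r2c),
                 poisson_limit = poisson_limit,
                 response = response, covariate = covariate,
                 n = nrow(dat), model = fit),
            class = "count_fit")
}

#' @export
coef.count_fit <- function(object, ...) object$coefficients

#' @export
vcov.count_fit <- function(object, ...) object$vcov

#' @export
print.count_fit <- function(x, ...) {
  cat(sprintf("<count_fit> %s (%s link), n = %d, AIC = %.1f, R2m = %.3f\n",
              x$family, x$link, x$n, x$aic, x$r2_marginal))
  print(round(x$coefficients, 4))
  if (is.finite(x$theta)) cat("theta =", round(x$theta, 2),
                              if (x$poisson_limit) "(Poisson limit)\n" else "\n")
  invisible(x)
}

#' Crossover count vs extent of asynapsis (late pachytene)
#'
#' Poisson GLM with log link for the prominent-focus (crossover) count of
#' late-pachytene cells, with the extent of asynapsis as the explanatory
#' variable: `log E[n] = a + b * asy1_length_um` (default), or
#' `log E[n] = a + b * log(asy1_length_um + 1)` with
#' `covariate = "log1p"`.
#'
#' @param cells late-pachytene cell table (`n_prominent`, `asy1_length_um`).
#' @param covariate `"linear"` or `"log1p"` transform of asynapsis.
#' @return a `count_fit` with extra fields `slope_p` (Wald p for `b`) and
#'   `small_sample` flag (fewer than 20 cells).
#' @export
fit_co_asynapsis <- function(cells, covariate = c("linear", "log1p")) {
  covariate <- match.arg(covariate)
  x <- if (covariate == "linear") cells$asy1_length_um
  else log1p(cells$asy1_length_um)
  dat <- data.frame(.y = cells$n_prominent, .x = x)
  fit <- glm(.y ~ .x, data = dat, family = stats::poisson())
  co <- coef(fit)
  V <- stats::vcov(fit)
  eta_f <- drop(model.matrix(fit) %*% co)
  var_f <- var(eta_f)
  var_e <- log1p(1 / mean(exp(eta_f)))
  r2 <- var_f / (var_f + var_e)
  z <- co[2] / sqrt(V[2, 2])
  structure(list(coefficients = co, vcov = V, family = "poisson",
                 link = "log", theta = Inf, sigma_u = 0,
                 aic = stats::AIC(fit), loglik = as.numeric(stats::logLik(fit)),
                 r2_marginal = unname(r2), r2_conditional = unname(r2),
                 poisson_limit = FALSE, response = "n_prominent",
                 covariate = covariate, n = nrow(cells), model = fit,
                 slope_p = unname(2 * pnorm(-abs(z))),
                 small_sample = nrow(cells) < 20),
            class = "count_fit")
}

#' Rank candidate count-model specifications
#'
#' Fits each candidate specification (argument lists for
#' [fit_count_model()]), ranks by AIC, and flags overdispersion via the
#' Pearson chi-squared / df statistic (> 1.5). When the top candidates are
#' within 2 AIC units the simpler family (Poisson over negative binomial,
#' then declaration order) wins, and the tie is logged.
#'
#' @param cells cell table passed to every candidate.
#' @param candidates named list of argument lists.
#' @return list with `chosen` (a `count_fit`), `chosen_name`, and a
#'   `diagnostics` table (AIC, dispersion, status per candidate).
#' @export
select_family <- function(cells, candidates) {
  if (length(candidates) < 2)
    stop("select_family: need at least 2 candidate specifications")
  nm <- names(candidates)
  if (is.null(nm)) nm <- paste0("cand", seq_along(candidates))
  fits <- vector("list", length(candidates))
  diag_rows <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    fits[[i]] <- tryCatch(do.call(fit_count_model, c(list(cells), candidates[[i]])),
                          error = function(e) e)
    if (inherits(fits[[i]], "error")) {
      diag_rows[[i]] <- data.frame(candidate = nm[i], aic = NA, dispersion = NA,
                                   overdispersed = NA,
                                   status = conditionMessage(fits[[i]]))
    } else {
      f <- fits[[i]]
      mu <- stats::fitted(f$model)
      y <- f$model$frame$.y
      vfun <- if (f$family == "poisson") mu else mu + mu^2 / f$theta
      disp <- sum((y - mu)^2 / vfun) / (length(y) - length(f$coefficients))
      diag_rows[[i]] <- data.frame(candidate = nm[i], aic = f$aic,
                                   dispersion = disp,
                                   overdispersed = disp > 1.5, status = "ok")
    }
  }
  diagnostics <- do.call(rbind, diag_rows)
  ok <- which(diagnostics$status == "ok" & is.finite(diagnostics$aic))
  if (!length(ok))
    stop("select_family: all candidates failed: ",
         paste(sprintf("%s (%s)", diagnostics$candidate, diagnostics$status),
               collapse = "; "))
  aic <- diagnostics$aic[ok]
  best_aic <- min(aic)
  near <- ok[aic <= best_aic + 2]
  fam_rank <- vapply(fits[near], function(f) f$family == "poisson", FALSE)
  tie <- length(near) > 1
  pick <- if (any(fam_rank)) near[which(fam_rank)[1]] else near[1]
  list(chosen = fits[[pick]], chosen_name = nm[pick],
       diagnostics = diagnostics, tie = tie)
}
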