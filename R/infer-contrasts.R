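# Wald contrasts with Holm correction.

#' Wald contrasts on fitted coefficients, Holm-adjusted
#'
#' Evaluates linear combinations of a fit's coefficients: estimate `c'b`,
#' `SE = sqrt(c' V c)`, Wald `z = estimate / SE`, two-sided p from the
#' normal reference, and Holm-adjusted p within the requested family of
#' contrasts. A contrast of a coefficient with itself has estimate 0 and
#' p = 1.
#'
#' @param fit a `decay_fit` or `count_fit` (anything with `coef()` and
#'   `vcov()` methods).
#' @param contrasts named list; each element is either a numeric vector of
#'   length `length(coef(fit))`, or a named numeric vector of weights on
#'   coefficient names (unnamed coefficients weight 0).
#' @return `data.frame` (`contrast_table`): `label`, `estimate`, `se`, `z`,
#'   `p_raw`, `p_holm`.
#' @export
wald_contrasts <- function(fit, contrasts) {
  b <- coef(fit)
  V <- vcov(fit)
  if (is.null(V)) stop("wald_contrasts: fit carries no covariance")
  labs <- names(contrasts)
  if (is.null(labs)) labs <- paste0("contrast", seq_along(contrasts))
  rows <- lapply(seq_along(contrasts), function(i) {
    cv <- contrasts[[i]]
    if (!is.null(names(cv)) && length(cv) != length(b)) {
      bad <- setdiff(names(cv), names(b))
      if (length(bad))
        stop("wald_contrasts: non-estimable contrast '", labs[i],
             "' (unknown coefficient ", paste(bad, collapse = ", "), ")")
      full <- setNames(rep(0, length(b)), names(b))
      full[names(cv)] <- cv
      cv <- full
    }
    if (length(cv) != length(b))
      stop("wald_contrasts: contrast '", labs[i], "' has wrong length")
    est <- sum(cv * b)
    se <- sqrt(max(drop(t(cv) %*% V %*% cv), 0))
    z <- if (se > 0) est / se else 0
    data.frame(label = labs[i], estimate = est, se = se, z = z,
               p_raw = if (se > 0) 2 * pnorm(-abs(z)) else as.numeric(est == 0))
  })
  out <- do.call(rbind, rows)
  # a self-contrast (estimate 0, se 0) is "no difference": p = 1
  out$p_raw[out$se == 0 & out$estimate == 0] <- 1
  out$p_holm <- p.adjust(out$p_raw, method = "holm")
  class(out) <- c("contrast_table", "data.frame")
  out
}
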