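# Calibration of HEI10 accumulation-level cutoffs that convert raw
# accumulation measurements into analyzable developmental windows.

new_cutoff_result <- function(cutoff_pct, rule, trace, genotype = "all") {
  structure(list(cutoff_pct = cutoff_pct, rule = rule, trace = trace,
                 genotype = genotype),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("<cutoff_result> rule=%s genotype=%s cutoff=%s%%\n",
              x$rule, x$genotype,
              if (is.na(x$cutoff_pct)) "none" else format(x$cutoff_pct)))
  invisible(x)
}

#' Background cutoff from control cells
#'
#' Somatic and leptotene cells carry no true HEI10 accumulation, yet the
#' relative-intensity measurement registers a nonzero level on them; the
#' background cutoff is the maximum level observed among such control cells
#' (rounded up to the grid step), below which accumulation levels are
#' indistinguishable from background.
#'
#' @param control_levels accumulation percentages of control
#'   (somatic/leptotene) cells; at least one required.
#' @param grid_step rounding step for the cutoff (percent).
#' @return a `cutoff_result` (rule `"background"`) whose trace records the
#'   control mean and maximum.
#' @export
background_cutoff <- function(control_levels, grid_step = 0.1) {
  if (!length(control_levels)) stop("background_cutoff: empty control set")
  if (any(!is.finite(control_levels)))
    stop("background_cutoff: non-finite control levels")
  mx <- max(control_levels)
  cutoff <- ceiling(mx / grid_step) * grid_step
  trace <- data.frame(statistic = c("mean", "max", "n"),
                      value = c(mean(control_levels), mx,
                                length(control_levels)))
  new_cutoff_result(cutoff, "background", trace)
}

#' Filter a cell table by accumulation cutoff and QC
#'
#' Retains cells with `accumulation_pct >= cutoff`, passing QC, and without
#' the linear-HEI10 flag; the retained and excluded sets partition the input.
#'
#' @param cells `data.frame` with `accumulation_pct` and (optionally)
#'   `qc_pass`, `has_linear_hei10`, `genotype`.
#' @param cutoff accumulation percentage cutoff.
#' @return list with `retained` (data.frame), `excluded` (data.frame with an
#'   `exclusion_reason` column), and `n_excluded` per genotype.
#' @export
filter_by_cutoff <- function(cells, cutoff) {
  qc <- if ("qc_pass" %in% names(cells)) cells$qc_pass else TRUE
  lin <- if ("has_linear_hei10" %in% names(cells)) cells$has_linear_hei10 else FALSE
  reason <- rep(NA_character_, nrow(cells))
  reason[!qc] <- "qc_fail"
  reason[qc & lin] <- "linear_hei10"
  reason[qc & !lin & cells$accumulation_pct < cutoff] <- "below_cutoff"
  keep <- is.na(reason)
  geno <- if ("genotype" %in% names(cells)) cells$genotype else
    rep("all", nrow(cells))
  excl <- cells[!keep, , drop = FALSE]
  excl$exclusion_reason <- reason[!keep]
  list(retained = cells[keep, , drop = FALSE],
       excluded = excl,
       n_excluded = table(genotype = geno[!keep]))
}

#' Synapsis-plateau cutoff by decay-exponent flattening
#'
#' Finds the lowest accumulation level above which asynapsis no longer
#' declines: for each candidate cutoff `c` (ascending grid) the exponential
#' decay model ([fit_gamma_decay()]) is refit on cells with
#' `accumulation_pct > c`, and the smallest `c` at which every genotype's
#' decay-exponent Wald p-value is at least `alpha` is returned. The trace
#' stores all per-genotype p-values per candidate; candidates whose fit
#' fails are skipped and logged in the trace.
#'
#' @param cells filtered cell table (needs `genotype`, `plant_id`,
#'   `accumulation_pct`, `asy1_length_um`).
#' @param alpha significance level of the flatness rule.
#' @param grid candidate cutoffs in ascending order (percent).
#' @param min_cells minimum cells above a candidate for a fit attempt.
#' @return a `cutoff_result` (rule `"plateau"`); `cutoff_pct` is `NA` when no
#'   candidate satisfies the rule.
#' @export
plateau_cutoff <- function(cells, alpha = 0.05, grid = 13:90,
                           min_cells = 30L) {
  grid <- sort(grid)
  trace <- list()
  found <- NA_real_
  fit_prev <- NULL
  for (cc in grid) {
    sub <- cells[cells$accumulation_pct > cc, , drop = FALSE]
    genos <- unique(sub$genotype)
    if (nrow(sub) < min_cells || length(genos) < length(unique(cells$genotype))) {
      trace[[length(trace) + 1]] <- data.frame(cutoff = cc, genotype = NA,
                                               p_decay = NA,
                                               status = "insufficient_cells")
      next
    }
    fit <- tryCatch(fit_gamma_decay(sub, start = fit_prev),
                    error = function(e) NULL)
    if (is.null(fit)) {
      trace[[length(trace) + 1]] <- data.frame(cutoff = cc, genotype = NA,
                                               p_decay = NA,
                                               status = "fit_failed")
      next
    }
    fit_prev <- fit
    pv <- decay_p_values(fit)
    trace[[length(trace) + 1]] <- data.frame(cutoff = cc,
                                             genotype = names(pv),
                                             p_decay = unname(pv),
                                             status = "ok")
    if (all(pv >= alpha)) { found <- cc; break }
  }
  new_cutoff_result(found, "plateau", do.call(rbind, trace))
}

#' Late-pachytene cutoffs from diakinesis crossover counts
#'
#' Calibrates, per genotype, the accumulation level above which prominent
#' HEI10 foci can be read as crossovers: the candidate cutoff whose mean
#' prominent-focus count (over cells above it) is closest to the genotype's
#' diakinesis crossover mean. Exact ties break toward the smallest
#' candidate (the crossing point itself); a candidate needs at least
#' `min_cells` cells above it.
#'
#' @param cells cell table with `genotype`, `accumulation_pct`,
#'   `n_prominent`.
#' @param diakinesis_means named numeric vector of per-genotype diakinesis
#'   crossover means.
#' @param grid candidate cutoffs (percent).
#' @param min_cells minimum cells above a candidate.
#' @return named list of `cutoff_result` (rule `"late_pachytene"`), one per
#'   genotype, in the order of `diakinesis_means`.
#' @export
late_pachytene_cutoffs <- function(cells, diakinesis_means, grid = 13:90,
                                   min_cells = 5L) {
  grid <- sort(grid)
  out <- list()
  for (g in names(diakinesis_means)) {
    sub <- cells[cells$genotype == g, , drop = FALSE]
    if (nrow(sub) < 10)
      stop("late_pachytene_cutoffs: fewer than 10 cells for genotype ", g)
    cand <- data.frame(cutoff = grid, mean_foci = NA_real_, n = NA_integer_)
    for (i in seq_along(grid)) {
      above <- sub$n_prominent[sub$accumulation_pct > grid[i]]
      cand$n[i] <- length(above)
      if (length(above) >= min_cells) cand$mean_foci[i] <- mean(above)
    }
    cand$distance <- abs(cand$mean_foci - diakinesis_means[[g]])
    ok <- which(!is.na(cand$distance))
    if (!length(ok))
      stop("late_pachytene_cutoffs: no candidate with >= ", min_cells,
           " cells for genotype ", g)
    dmin <- min(cand$distance[ok])
    best <- ok[cand$distance[ok] == dmin]
    # exact ties resolve to the earliest candidate: a constructed population
    # whose focus mean equals the diakinesis mean everywhere above a crossing
    # point should be cut at the crossing, not at the top of the grid
    pick <- min(best)
    out[[g]] <- new_cutoff_result(grid[pick], "late_pachytene", cand,
                                  genotype = g)
  }
  out
}

#' Double diploid axis lengths onto the tetraploid scale
#'
#' Multiplies `asy1_length_um` of the designated diploid genotype by
#' `factor` (default 2) so diploid asynapsis is directly comparable with
#' tetraploids, which carry twice the axis content. Guarded by a provenance
#' flag so it can only be applied once.
#'
#' @param cells cell table with `genotype` and `asy1_length_um`.
#' @param diploid_label genotype label of the diploid.
#' @param factor ploidy scaling factor.
#' @return the table with scaled diploid lengths and attribute
#'   `ploidy_normalized = TRUE`.
#' @export
normalize_diploid <- function(cells, diploid_label, factor = 2) {
  if (isTRUE(attr(cells, "ploidy_normalized")))
    stop("normalize_diploid: ploidy normalization already applied")
  if (!diploid_label %in% cells$genotype)
    stop("normalize_diploid: no cells with genotype '", diploid_label, "'")
  sel <- cells$genotype == diploid_label
  cells$asy1_length_um[sel] <- cells$asy1_length_um[sel] * factor
  attr(cells, "ploidy_normalized") <- TRUE
  cells
}
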