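# End-to-end orchestration: stacks or tables -> measurements -> staging ->
# models -> report.

#' Pipeline configuration
#'
#' @param input_mode `"table"` (precomputed or simulated measurements) or
#'   `"stacks"` (image directories quantified with [quantify_cell()]).
#' @param cells measurement table (table mode).
#' @param stacks_path directory of cell directories (stacks mode).
#' @param channels channel-name map for [read_stacks()].
#' @param control_levels accumulation levels of somatic/leptotene control
#'   cells; when given, the background cutoff is calibrated from them,
#'   otherwise `background_cutoff_pct` is used directly.
#' @param background_cutoff_pct fallback background cutoff (percent).
#' @param diploid_label genotype whose ASY1 lengths are doubled onto the
#'   tetraploid scale (`NULL` to skip).
#' @param doubling_factor ploidy scaling factor.
#' @param diakinesis_means named per-genotype diakinesis crossover means for
#'   the late-pachytene calibration (`NULL` to skip).
#' @param grid cutoff candidate grid (percent).
#' @param alpha significance level of the plateau rule.
#' @param parallel_window_um ASY1 window for the coalignment model (the
#'   geometry is only assessable at intermediate asynapsis).
#' @param zygotene_max_pct accumulation level bounding the early/mid
#'   zygotene subset used by the elongation model.
#' @param quantify a [quantify_config()] (stacks mode).
#' @param seed seed for any stochastic step.
#' @param output_dir directory for report tables (`NULL`: no files written).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_mode = c("table", "stacks"),
                            cells = NULL, stacks_path = NULL,
                            channels = c(hei10 = "hei10", asy1 = "asy1",
                                         zyp1 = "zyp1"),
                            control_levels = NULL,
                            background_cutoff_pct = 12,
                            diploid_label = NULL, doubling_factor = 2,
                            diakinesis_means = NULL,
                            grid = 13:90, alpha = 0.05,
                            parallel_window_um = c(30, 150),
                            zygotene_max_pct = 24,
                            quantify = quantify_config(),
                            seed = 1L, output_dir = NULL) {
  input_mode <- match.arg(input_mode)
  if (input_mode == "table" && (is.null(cells) || !nrow(cells)))
    stop("pipeline_config: table mode requires a non-empty 'cells' table")
  if (input_mode == "stacks") {
    if (is.null(stacks_path) || !dir.exists(stacks_path))
      stop("pipeline_config: stacks mode requires an existing 'stacks_path'")
  }
  if (!is.null(diploid_label) && input_mode == "table" &&
      !diploid_label %in% cells$genotype)
    stop("pipeline_config: diploid label '", diploid_label,
         "' absent from the cell table")
  structure(list(input_mode = input_mode, cells = cells,
                 stacks_path = stacks_path, channels = channels,
                 control_levels = control_levels,
                 background_cutoff_pct = background_cutoff_pct,
                 diploid_label = diploid_label,
                 doubling_factor = doubling_factor,
                 diakinesis_means = diakinesis_means,
                 grid = grid, alpha = alpha,
                 parallel_window_um = parallel_window_um,
                 zygotene_max_pct = zygotene_max_pct,
                 quantify = quantify, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: quantification (stacks mode) or table ingestion;
#' background-cutoff calibration (from control cells when provided);
#' filtering with the exclusion ledger; diploid axis-length doubling; the
#' exponential-decay Gamma-GLMM with onset predictions and decay-exponent
#' contrasts; the synapsis-plateau search and final asynapsis per genotype;
#' the coalignment (parallels) model on the intermediate-asynapsis window;
#' the ZYP1 elongation model on the early/mid-zygotene subset; multivalent /
#' univalent count models when those columns are present; late-pachytene
#' calibration and the crossover-vs-asynapsis model when diakinesis means
#' are provided. Every input cell appears exactly once in the measurements
#' or the exclusion ledger.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_report` list: `measurements`, `exclusions`, `cutoffs`,
#'   `fits`, `predictions`, `contrasts`, `final_asynapsis`, and a `config`
#'   fingerprint. Tables are also written as CSV/JSON under
#'   `config$output_dir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  report <- list(config = config[setdiff(names(config), "cells")])

  # --- measurements
  if (config$input_mode == "stacks") {
    stacks <- read_stacks(config$stacks_path, config$channels)
    if (inherits(stacks, "stack3c")) stacks <- list(stacks)
    meas <- do.call(rbind, lapply(stacks, quantify_cell,
                                  config = config$quantify))
  } else {
    meas <- config$cells
    need <- c("genotype", "plant_id", "accumulation_pct", "asy1_length_um")
    miss <- setdiff(need, names(meas))
    if (length(miss))
      stop("run_pipeline: cell table lacks columns: ",
           paste(miss, collapse = ", "))
  }
  if (!nrow(meas)) stop("run_pipeline: no cells to analyze")

  # --- staging: background cutoff + filtering
  bg <- if (!is.null(config$control_levels))
    background_cutoff(config$control_levels)
  else new_cutoff_result(config$background_cutoff_pct, "background",
                         data.frame(statistic = "configured",
                                    value = config$background_cutoff_pct))
  flt <- filter_by_cutoff(meas, bg$cutoff_pct)
  cells <- flt$retained
  report$measurements <- meas
  report$exclusions <- flt$excluded
  report$cutoffs <- list(background = bg)
  if (!nrow(cells)) stop("run_pipeline: no cells retained after filtering")

  if (!is.null(config$diploid_label) &&
      config$diploid_label %in% cells$genotype)
    cells <- normalize_diploid(cells, config$diploid_label,
                               config$doubling_factor)
  report$cells_analyzed <- cells

  # --- decay model, onset predictions, decay contrasts
  fit <- fit_gamma_decay(cells)
  report$fits <- list(decay = fit)
  report$predictions <- list(
    onset_asynapsis = predict_asynapsis(fit, bg$cutoff_pct))
  genos <- fit$genotypes
  ctr <- list()
  for (g in genos) {
    cv <- setNames(rep(0, length(fit$coefficients)),
                   names(fit$coefficients))
    cv[fit$coef_idx$slope[[g]]] <- 1
    ctr[[paste0("decay_", g, "_vs_0")]] <- cv
  }
  if (length(genos) > 1) {
    for (i in 1:(length(genos) - 1)) for (j in (i + 1):length(genos)) {
      cv <- setNames(rep(0, length(fit$coefficients)),
                     names(fit$coefficients))
      cv[fit$coef_idx$slope[[genos[i]]]] <- 1
      cv[fit$coef_idx$slope[[genos[j]]]] <- -1
      ctr[[paste0("decay_", genos[i], "_vs_", genos[j])]] <- cv
    }
  }
  report$contrasts <- list(decay = wald_contrasts(fit, ctr))

  # --- plateau search + final asynapsis
  plat <- plateau_cutoff(cells, alpha = config$alpha, grid = config$grid)
  report$cutoffs$plateau <- plat
  if (!is.na(plat$cutoff_pct)) {
    fin <- cells[cells$accumulation_pct > plat$cutoff_pct, , drop = FALSE]
    report$final_asynapsis <- do.call(rbind, lapply(split(fin, fin$genotype),
      function(d) data.frame(genotype = d$genotype[1],
                             mean_um = mean(d$asy1_length_um),
                             se_um = sd(d$asy1_length_um) / sqrt(nrow(d)),
                             n = nrow(d))))
  }

  # --- coalignment (parallels) model on the assessable ASY1 window
  win <- config$parallel_window_um
  par_cells <- cells[cells$asy1_length_um >= win[1] &
                       cells$asy1_length_um <= win[2], , drop = FALSE]
  if ("n_parallel" %in% names(par_cells) &&
      nrow(par_cells) >= 20 && sum(par_cells$n_parallel) > 0) {
    report$fits$parallels <- tryCatch(
      fit_count_model(par_cells, "n_parallel", covariate = "asy1_length_um",
                      family = "nbinom", link = "log",
                      random_intercept = "plant", covariate_scale = 100),
      error = function(e) e)
  }

  # --- elongation model on the early/mid-zygotene subset
  zy_cells <- meas[meas$accumulation_pct <= config$zygotene_max_pct, ,
                   drop = FALSE]
  if ("n_elongated" %in% names(zy_cells) && nrow(zy_cells) >= 20 &&
      sum(zy_cells$n_elongated, na.rm = TRUE) > 0) {
    report$fits$elongation <- tryCatch(
      fit_count_model(zy_cells, "n_elongated", covariate = "zyp1_length_um",
                      family = "nbinom", link = "identity",
                      random_intercept = "none"),
      error = function(e) e)
  }

  # --- multivalent / univalent models
  for (resp in c("n_quadrivalent", "n_univalent")) {
    if (resp %in% names(meas) && sum(meas[[resp]], na.rm = TRUE) > 0) {
      report$fits[[resp]] <- tryCatch(
        fit_count_model(meas, resp, family = "nbinom",
                        random_intercept = "plant",
                        scorability = if ("scorability" %in% names(meas))
                          "scorability" else NULL),
        error = function(e) e)
    }
  }

  # --- late-pachytene calibration + crossover model
  if (!is.null(config$diakinesis_means)) {
    lp <- late_pachytene_cutoffs(cells, config$diakinesis_means,
                                 grid = config$grid)
    report$cutoffs$late_pachytene <- lp
    late <- do.call(rbind, lapply(names(lp), function(g)
      cells[cells$genotype == g &
              cells$accumulation_pct > lp[[g]]$cutoff_pct, , drop = FALSE]))
    if (nrow(late) >= 10)
      report$fits$co_asynapsis <- fit_co_asynapsis(late)
  }

  class(report) <- "pipeline_report"
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' Write report tables to disk
#'
#' CSV tables (measurements, exclusions, analyzed cells, predictions, final
#' asynapsis, contrast tables) plus a JSON summary of cutoffs and model
#' coefficients.
#'
#' @param report a `pipeline_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(d, f) if (!is.null(d) && nrow(d))
    write.csv(d, file.path(dir, f), row.names = FALSE)
  wr(report$measurements, "measurements.csv")
  wr(report$exclusions, "exclusions.csv")
  wr(report$cells_analyzed, "cells_analyzed.csv")
  wr(report$predictions$onset_asynapsis, "onset_asynapsis.csv")
  wr(report$final_asynapsis, "final_asynapsis.csv")
  wr(report$contrasts$decay, "decay_contrasts.csv")
  summ <- list(
    cutoffs = lapply(report$cutoffs, function(cr) {
      if (inherits(cr, "cutoff_result"))
        list(rule = cr$rule, genotype = cr$genotype,
             cutoff_pct = cr$cutoff_pct)
      else lapply(cr, function(x) list(rule = x$rule, genotype = x$genotype,
                                       cutoff_pct = x$cutoff_pct))
    }),
    fits = lapply(report$fits, function(f) {
      if (inherits(f, "decay_fit"))
        list(class = "decay_fit", beta0 = as.list(f$beta0),
             beta1 = as.list(f$beta1), sigma_u = f$sigma_u,
             gamma_shape = f$gamma_shape, loglik = f$loglik, aic = f$aic,
             r2_marginal = f$r2_marginal, r2_conditional = f$r2_conditional,
             n_cells = f$n_cells, n_plants = f$n_plants)
      else if (inherits(f, "count_fit"))
        list(class = "count_fit", family = f$family, link = f$link,
             coefficients = as.list(f$coefficients),
             theta = if (is.finite(f$theta)) f$theta else NULL,
             sigma_u = f$sigma_u, aic = f$aic, r2_marginal = f$r2_marginal)
      else list(class = "error", message = conditionMessage(f))
    }))
  jsonlite::write_json(summ, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
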