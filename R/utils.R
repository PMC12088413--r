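# Small domain helpers.

#' Chromosome pairs per meiocyte
#'
#' Number of chromosome pairs formed at meiosis for a given base chromosome
#' number and ploidy: `base_number * ploidy / 2` (e.g. base number 8: 8
#' pairs in a diploid, 16 in a tetraploid).
#'
#' @param base_number haploid base chromosome number (x; 8 for
#'   *Arabidopsis arenosa*).
#' @param ploidy ploidy level (2 = diploid, 4 = tetraploid).
#' @return number of chromosome pairs.
#' @export
chromosome_pairs <- function(base_number = 8, ploidy = 2) {
  if (ploidy %% 2 != 0) stop("chromosome_pairs: ploidy must be even")
  base_number * ploidy / 2
}

#' Crossovers per chromosome pair
#'
#' Mean crossover (HEI10 focus) count per cell divided by the number of
#' chromosome pairs, the per-pair crossover rate used to compare cytotypes
#' of different ploidy.
#'
#' @param mean_foci mean crossover-focus count per cell (diakinesis stage).
#' @param n_pairs number of chromosome pairs (see [chromosome_pairs()]).
#' @return crossovers per chromosome pair.
#' @export
crossovers_per_pair <- function(mean_foci, n_pairs) {
  if (n_pairs <= 0) stop("crossovers_per_pair: n_pairs must be positive")
  mean_foci / n_pairs
}

#' Rename ground-truth columns to measurement columns
#'
#' Maps a [simulate_cell_table()] ground-truth table onto the measurement
#' schema produced by [quantify_cell()], so the statistical layer can run on
#' tabular populations without rendering ("table mode"). QC fields are set
#' to pass.
#'
#' @param truth ground-truth table.
#' @return measurement-schema `data.frame`.
#' @export
truth_to_measurements <- function(truth) {
  data.frame(cell_id = truth$cell_id, plant_id = truth$plant_id,
             genotype = truth$genotype,
             accumulation_pct = truth$H_true,
             n_prominent = truth$n_prominent_true,
             total_hei10_intensity = NA_real_,
             prominent_hei10_intensity = NA_real_,
             asy1_length_um = truth$asynapsis_true,
             zyp1_length_um = truth$zyp1_total_true,
             n_punctate = truth$n_punctate_true,
             n_elongated = truth$n_elongated_true,
             n_parallel = truth$n_parallel_true,
             n_irregular = truth$n_irregular_true,
             n_quadrivalent = truth$n_quadrivalent_true,
             n_univalent = truth$n_univalent_true,
             has_linear_hei10 = FALSE, qc_pass = TRUE,
             stringsAsFactors = FALSE)
}
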