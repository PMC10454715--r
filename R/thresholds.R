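#' Numeric thresholds of the rule engine
#'
#' Houses every numeric constant used by the criterion engine. Defaults are
#' the published calibration values: REVEL 0.644/0.29 and CADD-phred
#' 25.3/22.7 pathogenic/benign cutoffs (ClinGen computational-predictor
#' calibration), the same 0.644/0.29 cutoffs applied to the fifteen dbNSFP
#' rank scores with an 8-of-15 majority, dbscSNV AdaBoost 0.708 and random
#' forest 0.515 splice cutoffs, the 33.1% benign-missense fraction and 2.99
#' missense-Z thresholds for BP1, and the 3% decision-MAF pre-filter.
#'
#' @param revel_path,revel_benign REVEL cutoffs (pathogenic `>=`, benign `<=`).
#' @param cadd_path,cadd_benign CADD-phred cutoffs.
#' @param rank_cutoff_path,rank_cutoff_benign Rank-score cutoffs applied to
#'   the 15 functional predictors.
#' @param n_rank_required,n_rank_total Majority rule for the rank scores
#'   (8 of 15).
#' @param ada_cutoff,rf_cutoff dbscSNV AdaBoost / random-forest cutoffs.
#' @param bp1_benign_fraction_pct BP1 benign non-VUS missense fraction
#'   threshold, percent (strictly greater fires).
#' @param bp1_missense_z BP1 missense-Z threshold (strictly less fires; the
#'   sub-rule is enabled per gene, see [gene_info]).
#' @param decision_maf_pct Decision-MAF pre-filter, percent (strictly below
#'   passes).
#' @return A list of class `acmg_thresholds`.
#' @export
acmg_thresholds <- function(revel_path = 0.644, revel_benign = 0.29,
                            cadd_path = 25.3, cadd_benign = 22.7,
                            rank_cutoff_path = 0.644,
                            rank_cutoff_benign = 0.29,
                            n_rank_required = 8L, n_rank_total = 15L,
                            ada_cutoff = 0.708, rf_cutoff = 0.515,
                            bp1_benign_fraction_pct = 33.1,
                            bp1_missense_z = 2.99,
                            decision_maf_pct = 3.0) {
  cfg <- list(
    revel_path = revel_path, revel_benign = revel_benign,
    cadd_path = cadd_path, cadd_benign = cadd_benign,
    rank_cutoff_path = rank_cutoff_path,
    rank_cutoff_benign = rank_cutoff_benign,
    n_rank_required = as.integer(n_rank_required),
    n_rank_total = as.integer(n_rank_total),
    ada_cutoff = ada_cutoff, rf_cutoff = rf_cutoff,
    bp1_benign_fraction_pct = bp1_benign_fraction_pct,
    bp1_missense_z = bp1_missense_z,
    decision_maf_pct = decision_maf_pct
  )
  stopifnot(all(vapply(cfg, is.numeric, TRUE)),
            all(unlist(cfg) > 0),
            cfg$revel_benign < cfg$revel_path,
            cfg$cadd_benign < cfg$cadd_path,
            cfg$n_rank_required <= cfg$n_rank_total)
  structure(cfg, class = "acmg_thresholds")
}

#' Load thresholds from a JSON config file
#'
#' Keys are the argument names of [acmg_thresholds]; absent keys keep their
#' defaults.
#'
#' @param path Path to a JSON file.
#' @return An `acmg_thresholds` object.
#' @export
read_thresholds <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(acmg_thresholds))
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    stop("unknown threshold key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  do.call(acmg_thresholds, raw)
}
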