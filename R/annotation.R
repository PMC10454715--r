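#' @title Variant annotation records
#' @description Constructors and validators for the structured annotation a
#'   variant arrives with: in-silico predictor scores, population
#'   frequencies, gene-level statistics, the loss-of-function block that
#'   drives PVS1, a ClinVar summary and any upstream evidence calls.
#' @name annotation-model
NULL

#' The fifteen rank-score predictor names
#' @format Character vector of length 15.
#' @export
rank_score_predictors <- c(
  "DANN", "EigenPC", "FATHMM", "LRT", "MCAP", "MetaLR", "MetaSVM",
  "MutPred", "MutationAssessor", "MutationTaster", "PROVEAN",
  "Polyphen2HDIV", "Polyphen2HVAR", "SIFT", "VEST3"
)

#' Consequence classes understood by the engine
#' @format Character vector.
#' @export
consequence_classes <- c(
  "missense", "missense_splice", "synonymous_splice", "splice_region",
  "intronic_within_5", "frameshift", "nonsense", "canonical_splice",
  "start_loss", "other"
)

.lof_consequences <- c("frameshift", "nonsense", "canonical_splice",
                       "start_loss")

.chk_unit <- function(x, name) {
  if (!is.null(x)) {
    stopifnot(is.numeric(x), length(x) == 1L)
    if (is.na(x) || x < 0 || x > 1) stop(name, " must lie in [0,1]", call. = FALSE)
  }
  x
}

#' In-silico predictor scores
#'
#' All entries optional; a missing score simply leaves the corresponding
#' rule condition unmet (never an error).
#'
#' @param revel REVEL score in `[0,1]`.
#' @param cadd_phred CADD-phred score (`>= 0`).
#' @param rank_scores Named numeric vector/list, names a subset of
#'   [rank_score_predictors], values in `[0,1]`.
#' @param ada_boost,rf dbscSNV AdaBoost and random-forest scores in `[0,1]`.
#' @return A list of class `predictor_scores`.
#' @export
predictor_scores <- function(revel = NULL, cadd_phred = NULL,
                             rank_scores = NULL, ada_boost = NULL,
                             rf = NULL) {
  .chk_unit(revel, "revel")
  if (!is.null(cadd_phred)) stopifnot(is.numeric(cadd_phred), cadd_phred >= 0)
  if (!is.null(rank_scores)) {
    rank_scores <- unlist(rank_scores)
    bad <- setdiff(names(rank_scores), rank_score_predictors)
    if (length(bad)) {
      stop("unknown rank-score predictor(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    stopifnot(all(rank_scores >= 0 & rank_scores <= 1, na.rm = TRUE))
  }
  .chk_unit(ada_boost, "ada_boost")
  .chk_unit(rf, "rf")
  structure(list(revel = revel, cadd_phred = cadd_phred,
                 rank_scores = rank_scores, ada_boost = ada_boost, rf = rf),
            class = "predictor_scores")
}

#' Population frequency data
#'
#' @param maf_by_source Named numeric vector/list of minor-allele
#'   frequencies in `[0,1]`; names among `dbNSFP`, `VEP`, `gnomAD`.
#' @param gnomad_allele_count,gnomad_hom_count Optional gnomAD allele /
#'   homozygote counts.
#' @param coverage_ok Optional logical: was gnomAD coverage adequate?
#' @return A list of class `population_data`.
#' @export
population_data <- function(maf_by_source = NULL, gnomad_allele_count = NULL,
                            gnomad_hom_count = NULL, coverage_ok = NULL) {
  if (!is.null(maf_by_source)) {
    maf_by_source <- unlist(maf_by_source)
    bad <- setdiff(names(maf_by_source), c("dbNSFP", "VEP", "gnomAD"))
    if (length(bad)) {
      stop("unknown frequency source(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    stopifnot(all(maf_by_source >= 0 & maf_by_source <= 1))
  }
  structure(list(maf_by_source = maf_by_source,
                 gnomad_allele_count = gnomad_allele_count,
                 gnomad_hom_count = gnomad_hom_count,
                 coverage_ok = coverage_ok),
            class = "population_data")
}

#' Gene-level information
#'
#' @param symbol Gene symbol.
#' @param inheritance Character subset of `AD`, `AR`, `XL`.
#' @param missense_z Optional gnomAD missense Z-score.
#' @param benign_nonvus_missense,total_nonvus_missense Optional counts for
#'   the BP1 benign-fraction sub-rule.
#' @param lof_mechanism Optional logical: is loss of function an established
#'   disease mechanism for this gene (required by PVS1)?
#' @param bp1_z_rule Enable the BP1 missense-Z sub-rule for this gene
#'   (default off: as printed the `< 2.99` rule would fire for almost every
#'   gene, so it is opt-in per gene).
#' @return A list of class `gene_info`.
#' @export
gene_info <- function(symbol, inheritance = character(), missense_z = NULL,
                      benign_nonvus_missense = NULL,
                      total_nonvus_missense = NULL, lof_mechanism = NULL,
                      bp1_z_rule = FALSE) {
  stopifnot(is.character(symbol), nzchar(symbol),
            all(inheritance %in% c("AD", "AR", "XL")))
  if (!is.null(benign_nonvus_missense) && !is.null(total_nonvus_missense)) {
    stopifnot(benign_nonvus_missense <= total_nonvus_missense)
  }
  structure(list(symbol = symbol, inheritance = inheritance,
                 missense_z = missense_z,
                 benign_nonvus_missense = benign_nonvus_missense,
                 total_nonvus_missense = total_nonvus_missense,
                 lof_mechanism = lof_mechanism,
                 bp1_z_rule = isTRUE(bp1_z_rule)),
            class = "gene_info")
}

#' Structured loss-of-function annotation
#'
#' Pre-computed facts about a truncating variant that the PVS1 decision tree
#' consumes (the engine does not predict NMD or transcript relevance itself).
#'
#' @param lof_type One of `frameshift`, `nonsense`, `canonical_splice`,
#'   `start_loss`, `exon_deletion`.
#' @param nmd_predicted Is the transcript predicted to undergo
#'   nonsense-mediated decay?
#' @param exon_in_relevant_transcript Is the affected exon present in
#'   biologically relevant transcript(s)?
#' @param lof_frequent_in_population Are LoF variants in this exon frequent
#'   in the general population?
#' @param fraction_protein_removed Fraction of the protein removed by the
#'   truncation, in `[0,1]`.
#' @param truncated_region_critical Optional: is the truncated region
#'   critical to protein function?
#' @param pathogenic_variants_in_truncated_region Optional count of known
#'   pathogenic variants in the removed region.
#' @param splice_rescue_possible Optional (canonical splice only): could
#'   exon skipping or a cryptic site preserve the reading frame?
#' @return A list of class `lof_annotation`.
#' @export
lof_annotation <- function(lof_type, nmd_predicted,
                           exon_in_relevant_transcript,
                           lof_frequent_in_population,
                           fraction_protein_removed,
                           truncated_region_critical = NULL,
                           pathogenic_variants_in_truncated_region = NULL,
                           splice_rescue_possible = NULL) {
  stopifnot(lof_type %in% c("frameshift", "nonsense", "canonical_splice",
                            "start_loss", "exon_deletion"),
            is.logical(nmd_predicted),
            is.logical(exon_in_relevant_transcript),
            is.logical(lof_frequent_in_population))
  .chk_unit(fraction_protein_removed, "fraction_protein_removed")
  structure(list(
    lof_type = lof_type, nmd_predicted = nmd_predicted,
    exon_in_relevant_transcript = exon_in_relevant_transcript,
    lof_frequent_in_population = lof_frequent_in_population,
    fraction_protein_removed = fraction_protein_removed,
    truncated_region_critical = truncated_region_critical,
    pathogenic_variants_in_truncated_region =
      pathogenic_variants_in_truncated_region,
    splice_rescue_possible = splice_rescue_possible
  ), class = "lof_annotation")
}

#' ClinVar summary
#'
#' @param classification One of `P`, `LP`, `VUS`, `LB`, `B`, `conflicting`,
#'   `none`.
#' @param stars Review status, 0-4 stars.
#' @param n_submissions Number of submissions.
#' @return A list of class `clinvar_summary`.
#' @export
clinvar_summary <- function(classification = "none", stars = 0L,
                            n_submissions = 0L) {
  stopifnot(classification %in% c("P", "LP", "VUS", "LB", "B",
                                  "conflicting", "none"),
            stars >= 0, stars <= 4, n_submissions >= 0)
  structure(list(classification = classification, stars = as.integer(stars),
                 n_submissions = as.integer(n_submissions)),
            class = "clinvar_summary")
}

#' A fully annotated variant in one sample
#'
#' The unit record of the engine: everything known upstream about one
#' variant observed in one individual.
#'
#' @param sample_id Sample identifier.
#' @param gene A [gene_info].
#' @param transcript RefSeq `NM_` accession.
#' @param hgvs_c Coding-sequence HGVS change (non-empty).
#' @param hgvs_p Optional protein HGVS change.
#' @param consequence One of [consequence_classes].
#' @param zygosity `het`, `hom` or `hemi`.
#' @param scores A [predictor_scores].
#' @param population A [population_data].
#' @param lof A [lof_annotation]; required exactly when `consequence` is a
#'   loss-of-function class (frameshift, nonsense, canonical splice, start
#'   loss).
#' @param clinvar Optional [clinvar_summary].
#' @param upstream_calls List of [evidence_call] objects the engine does not
#'   compute itself (e.g. PM1, PS1, PP4, BS1), accepted verbatim.
#' @param panel Opaque panel label carried through to reports.
#' @return A list of class `variant_annotation`.
#' @export
variant_annotation <- function(sample_id, gene, transcript, hgvs_c,
                               hgvs_p = NULL, consequence = "other",
                               zygosity = "het",
                               scores = predictor_scores(),
                               population = population_data(),
                               lof = NULL, clinvar = NULL,
                               upstream_calls = list(), panel = "") {
  stopifnot(is.character(sample_id), nzchar(sample_id),
            inherits(gene, "gene_info"),
            is.character(hgvs_c), nzchar(hgvs_c),
            consequence %in% consequence_classes,
            zygosity %in% c("het", "hom", "hemi"),
            inherits(scores, "predictor_scores"),
            inherits(population, "population_data"))
  if (consequence %in% .lof_consequences) {
    if (is.null(lof)) {
      stop("consequence '", consequence,
           "' requires a loss-of-function annotation block", call. = FALSE)
    }
    stopifnot(inherits(lof, "lof_annotation"))
  } else if (!is.null(lof)) {
    stop("lof block supplied for non-LoF consequence '", consequence, "'",
         call. = FALSE)
  }
  if (!is.null(clinvar)) stopifnot(inherits(clinvar, "clinvar_summary"))
  stopifnot(all(vapply(upstream_calls, inherits, TRUE, "acmg_call")))
  up_codes <- vapply(upstream_calls, `[[`, "", "criterion")
  if (anyDuplicated(up_codes)) {
    stop("duplicate upstream call(s) for: ",
         paste(unique(up_codes[duplicated(up_codes)]), collapse = ", "),
         call. = FALSE)
  }
  for (uc in upstream_calls) {
    if (uc$criterion == "PPOT") {
      stop("PPOT is engine-assigned and cannot arrive upstream", call. = FALSE)
    }
  }
  structure(list(sample_id = sample_id, gene = gene, transcript = transcript,
                 hgvs_c = hgvs_c, hgvs_p = hgvs_p, consequence = consequence,
                 zygosity = zygosity, scores = scores,
                 population = population, lof = lof, clinvar = clinvar,
                 upstream_calls = upstream_calls, panel = panel),
            class = "variant_annotation")
}

#' Canonical GENE:transcript:c-change label of a variant
#' @param variant A [variant_annotation].
#' @return Character scalar.
#' @export
variant_label <- function(variant) {
  paste(variant$gene$symbol, variant$transcript, variant$hgvs_c, sep = ":")
}
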