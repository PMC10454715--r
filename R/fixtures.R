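#' @title Worked-example fixtures and synthetic generator
#' @description Four curated fixture cases reproducing the published worked
#'   examples end to end, a seeded generator of synthetic annotation
#'   records covering every rule branch, and the exhaustive count
#'   enumeration used to check the combiner against a brute-force oracle.
#' @name fixtures
NULL

# Synthesize a named 15-vector of rank scores with exactly n_damaging
# entries >= 0.644 (the aggregates, not the individual scores, drive every
# rule; the synthesized values are fixed and documented here: damaging
# entries at 0.90, the rest at 0.40).
.synth_rank_scores <- function(n_damaging, hi = 0.90, lo = 0.40) {
  vals <- c(rep(hi, n_damaging), rep(lo, 15L - n_damaging))
  stats::setNames(vals, rank_score_predictors)
}

#' Gene table used by the builtin fixture cases
#'
#' @return A named list of [gene_info] objects (SERPINA6, TYR, USH2A,
#'   CELSR1).
#' @export
fixture_genes <- function() {
  list(
    # corticosteroid-binding globulin deficiency: recessive; the missense-Z
    # sub-rule of BP1 is enabled for this gene (Z = -0.662 < 2.99)
    SERPINA6 = gene_info("SERPINA6", inheritance = "AR",
                         missense_z = -0.662, bp1_z_rule = TRUE),
    # oculocutaneous albinism type 1: recessive, LoF mechanism established
    TYR = gene_info("TYR", inheritance = "AR", lof_mechanism = TRUE),
    # Usher syndrome type 2A: recessive; 196/529 non-VUS missense benign
    USH2A = gene_info("USH2A", inheritance = "AR",
                      benign_nonvus_missense = 196L,
                      total_nonvus_missense = 529L,
                      lof_mechanism = TRUE),
    # lymphatic malformation 9: dominant; 33/33 non-VUS missense benign
    CELSR1 = gene_info("CELSR1", inheritance = "AD",
                       benign_nonvus_missense = 33L,
                       total_nonvus_missense = 33L)
  )
}

#' The four builtin worked-example cases
#'
#' Each case carries the annotation(s) of one sample (the USH2A case
#' includes its pathogenic frameshift partner), the expected met evidence
#' (criterion -> strength), the expected final class/subclass and
#' reportability, and a citation note.
#'
#' @return Named list of fixture cases.
#' @export
builtin_cases <- function() {
  genes <- fixture_genes()

  serpina6 <- variant_annotation(
    sample_id = "S_SERPINA6", panel = "ENDO",
    gene = genes$SERPINA6, transcript = "NM_001756.4",
    hgvs_c = "c.1165G>A", hgvs_p = "p.(Asp389Asn)",
    consequence = "missense", zygosity = "het",
    scores = predictor_scores(revel = 0.518, cadd_phred = 24.78,
                              rank_scores = .synth_rank_scores(11L)),
    population = population_data(gnomad_hom_count = 0L, coverage_ok = TRUE,
                                 maf_by_source = c(gnomAD = 1e-05)),
    clinvar = clinvar_summary("VUS", stars = 2L, n_submissions = 5L),
    upstream_calls = list(
      evidence_call("BP4", strength = "Strong", source = "upstream",
                    rationale = "upstream meta-predictor call"),
      evidence_call("PM2", strength = "Supporting", source = "upstream",
                    rationale = paste0("GnomAD genomes homozygous allele ",
                                       "count = 0 is less than 2")),
      evidence_call("PP5", strength = "Supporting", source = "upstream",
                    rationale = paste0("ClinVar classifies this variant as ",
                                       "Uncertain Significance, 2 stars"))))

  tyr <- variant_annotation(
    sample_id = "S_TYR", panel = "ALBINISM",
    gene = genes$TYR, transcript = "NM_000372.5",
    hgvs_c = "c.1586del", hgvs_p = "p.(Leu529Tyrfs*7)",
    consequence = "frameshift", zygosity = "het",
    population = population_data(coverage_ok = TRUE),
    lof = lof_annotation(
      lof_type = "frameshift", nmd_predicted = FALSE,
      exon_in_relevant_transcript = TRUE,
      lof_frequent_in_population = FALSE,
      fraction_protein_removed = 0.0019,  # removes 0.19% of the protein
      truncated_region_critical = FALSE,
      pathogenic_variants_in_truncated_region = 0L))

  ush2a <- variant_annotation(
    sample_id = "S_USH2A", panel = "USHER",
    gene = genes$USH2A, transcript = "NM_206933.4",
    hgvs_c = "c.5213T>C", hgvs_p = "p.(Phe1738Ser)",
    consequence = "missense", zygosity = "het",
    scores = predictor_scores(revel = 0.767, cadd_phred = 28.30,
                              rank_scores = .synth_rank_scores(14L)),
    population = population_data(coverage_ok = TRUE),
    upstream_calls = list(
      evidence_call("PP4", strength = "Supporting", source = "upstream",
                    rationale = paste0("phenotype (Usher syndrome) highly ",
                                       "specific for the gene"))))

  # the pathogenic partner in the same individual, unknown phase
  ush2a_partner <- variant_annotation(
    sample_id = "S_USH2A", panel = "USHER",
    gene = genes$USH2A, transcript = "NM_206933.4",
    hgvs_c = "c.2299del", hgvs_p = "p.(Glu767Serfs*21)",
    consequence = "frameshift", zygosity = "het",
    population = population_data(maf_by_source = c(gnomAD = 0.0008),
                                 coverage_ok = TRUE),
    lof = lof_annotation(
      lof_type = "frameshift", nmd_predicted = TRUE,
      exon_in_relevant_transcript = TRUE,
      lof_frequent_in_population = FALSE,
      fraction_protein_removed = 0.85),
    upstream_calls = list(
      evidence_call("PM2", strength = "Supporting", source = "upstream",
                    rationale = "extremely low frequency for recessive gene"),
      evidence_call("PS4", strength = "Strong", source = "upstream",
                    rationale = paste0("established founder variant with ",
                                       "greatly increased prevalence in ",
                                       "affected individuals"))))

  celsr1 <- variant_annotation(
    sample_id = "S_CELSR1", panel = "LYMPH",
    gene = genes$CELSR1, transcript = "NM_014246.4",
    hgvs_c = "c.5165G>A", hgvs_p = "p.(Arg1722Gln)",
    consequence = "missense", zygosity = "het",
    scores = predictor_scores(revel = 0.723, cadd_phred = 29.1,
                              rank_scores = .synth_rank_scores(13L)),
    population = population_data(gnomad_allele_count = 2L,
                                 coverage_ok = TRUE,
                                 maf_by_source = c(gnomAD = 8e-06)),
    upstream_calls = list(
      evidence_call("PM2", strength = "Supporting", source = "upstream",
                    rationale = paste0("GnomAD genomes allele count = 2 is ",
                                       "less than 5 for AD gene CELSR1"))))

  list(
    SERPINA6 = list(
      name = "SERPINA6", annotation = serpina6, sample = list(serpina6),
      expected_evidence = c(BP1 = "Supporting", PM2 = "Moderate",
                            PP5 = "Supporting"),
      expected_class = "VUS", expected_subclass = "Middle",
      expected_reportable = FALSE, expected_ppot = NULL,
      citation = "worked example 1: BP4/PP3 both not applicable"),
    TYR = list(
      name = "TYR", annotation = tyr, sample = list(tyr),
      expected_evidence = c(PVS1 = "Moderate", PM2 = "Moderate"),
      expected_class = "VUS", expected_subclass = "Middle",
      expected_reportable = FALSE, expected_ppot = NULL,
      expected_pvs1_path = "NP6",
      citation = "worked example 2: graded PVS1 via the LoF tree"),
    USH2A = list(
      name = "USH2A", annotation = ush2a,
      sample = list(ush2a, ush2a_partner),
      expected_evidence = c(PP3 = "Supporting", BP1 = "Supporting",
                            PM2 = "Moderate", PP4 = "Supporting"),
      expected_class = "VUS", expected_subclass = "Hot",
      expected_reportable = TRUE, expected_ppot = "Supporting",
      citation = "worked example 3: P_POT for possible in-trans phase"),
    CELSR1 = list(
      name = "CELSR1", annotation = celsr1, sample = list(celsr1),
      expected_evidence = c(PP3 = "Supporting", BP1 = "Supporting",
                            PM2 = "Moderate"),
      expected_class = "VUS", expected_subclass = "Hot",
      expected_reportable = TRUE, expected_ppot = "Moderate",
      citation = "worked example 4: P_POT for possible de novo occurrence")
  )
}

#' Run one fixture case end to end
#'
#' @param case An element of [builtin_cases].
#' @param cfg An [acmg_thresholds].
#' @return The `acmg_verdict_result` of the case's index variant (the
#'   whole classified [sample_context] is attached as
#'   `attr(, "context")`).
#' @export
run_fixture <- function(case, cfg = acmg_thresholds()) {
  contexts <- classify_annotations(case$sample, cfg)
  ctx <- contexts[[case$annotation$sample_id]]
  label <- variant_label(case$annotation)
  for (entry in ctx$variants) {
    if (identical(variant_label(entry$annotation), label)) {
      return(structure(entry$verdict, context = ctx))
    }
  }
  stop("fixture variant not found in classified context", call. = FALSE)
}

#' Generate synthetic annotation records
#'
#' Reproducible (same seed, same output) generator used by the property
#' tests. The first records of each profile are deterministic boundary
#' cases (scores exactly at each cutoff, every loss-of-function branch);
#' the remainder draw scores uniformly, inheritance over AD/AR/XL, and
#' zygosity consistent with inheritance (hemizygous only in X-linked
#' genes).
#'
#' @param seed Integer seed.
#' @param n Number of records (`> 0`).
#' @param profile `missense`, `splice`, `lof` or `mixed`.
#' @return List of `n` [variant_annotation] objects.
#' @export
generate_annotations <- function(seed, n, profile = c("mixed", "missense",
                                                      "splice", "lof")) {
  profile <- match.arg(profile)
  stopifnot(n > 0)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  cfg <- acmg_thresholds()
  inh_pool <- list("AD", "AR", "XL", c("AD", "AR"))

  one <- function(i, kind) {
    inh <- inh_pool[[sample.int(4L, 1L)]]
    zyg <- if (identical(inh, "XL")) {
      sample(c("het", "hemi"), 1L)
    } else {
      sample(c("het", "hom"), 1L, prob = c(0.8, 0.2))
    }
    gene <- gene_info(sprintf("GENE%03d", sample.int(40L, 1L)),
                      inheritance = inh,
                      benign_nonvus_missense = sample.int(50L, 1L) - 1L,
                      total_nonvus_missense = 50L,
                      lof_mechanism = stats::runif(1) < 0.7)
    pop <- population_data(
      maf_by_source = if (stats::runif(1) < 0.5) NULL else
        c(gnomAD = stats::runif(1, 0, 0.05)),
      coverage_ok = TRUE)
    boundary <- i <= 8L
    if (kind == "missense") {
      # boundary records sit exactly at the cutoffs to pin inclusivity
      revel <- if (boundary && i %% 2L == 0L) cfg$revel_path else
        stats::runif(1)
      cadd <- if (boundary && i %% 3L == 0L) cfg$cadd_path else
        stats::runif(1, 0, 40)
      n_dmg <- sample.int(16L, 1L) - 1L
      variant_annotation(
        sample_id = sprintf("SYN%04d", i), gene = gene,
        transcript = "NM_000000.1",
        hgvs_c = sprintf("c.%dA>G", 100L + i),
        consequence = sample(c("missense", "missense_splice"), 1L,
                             prob = c(0.8, 0.2)),
        zygosity = zyg,
        scores = predictor_scores(revel = revel, cadd_phred = cadd,
                                  rank_scores = .synth_rank_scores(n_dmg)),
        population = pop)
    } else if (kind == "splice") {
      ada <- if (boundary && i %% 2L == 0L) cfg$ada_cutoff else stats::runif(1)
      rf <- if (boundary && i %% 3L == 0L) cfg$rf_cutoff else stats::runif(1)
      variant_annotation(
        sample_id = sprintf("SYN%04d", i), gene = gene,
        transcript = "NM_000000.1",
        hgvs_c = sprintf("c.%d+3A>G", 100L + i),
        consequence = sample(c("synonymous_splice", "splice_region",
                               "intronic_within_5"), 1L),
        zygosity = zyg,
        scores = predictor_scores(ada_boost = ada, rf = rf),
        population = pop)
    } else {  # lof
      types <- c("frameshift", "nonsense", "canonical_splice", "start_loss")
      lt <- types[1L + (i - 1L) %% 4L]
      variant_annotation(
        sample_id = sprintf("SYN%04d", i), gene = gene,
        transcript = "NM_000000.1",
        hgvs_c = sprintf("c.%ddel", 100L + i),
        consequence = lt, zygosity = zyg,
        lof = lof_annotation(
          lof_type = lt,
          nmd_predicted = stats::runif(1) < 0.5,
          exon_in_relevant_transcript = stats::runif(1) < 0.8,
          lof_frequent_in_population = stats::runif(1) < 0.2,
          fraction_protein_removed = if (i %% 5L == 0L) 0.10 else
            stats::runif(1),
          truncated_region_critical = stats::runif(1) < 0.3,
          pathogenic_variants_in_truncated_region = sample(0:3, 1L),
          splice_rescue_possible = stats::runif(1) < 0.5),
        population = pop)
    }
  }

  kinds <- switch(profile,
    missense = rep("missense", n),
    splice = rep("splice", n),
    lof = rep("lof", n),
    mixed = c("missense", "splice", "lof")[1L + (seq_len(n) - 1L) %% 3L])
  lapply(seq_len(n), function(i) one(i, kinds[i]))
}

#' Exhaustively enumerate strength-count tuples
#'
#' Full Cartesian enumeration up to per-bucket maxima; oracle support for
#' the combiner equivalence check.
#'
#' @param limits Named integer vector with entries `pvs, ps, pm, pp, ba,
#'   bs, bp`.
#' @return Data frame, one row per tuple.
#' @export
enumerate_counts <- function(limits = c(pvs = 1L, ps = 2L, pm = 4L,
                                        pp = 5L, ba = 1L, bs = 2L,
                                        bp = 3L)) {
  need <- c("pvs", "ps", "pm", "pp", "ba", "bs", "bp")
  stopifnot(setequal(names(limits), need), all(is.finite(limits)))
  grid <- expand.grid(lapply(limits[need], function(k) 0L:k),
                      KEEP.OUT.ATTRS = FALSE)
  names(grid) <- need
  grid
}
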