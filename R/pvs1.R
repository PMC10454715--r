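#' Graded PVS1 assignment from a structured loss-of-function block
#'
#' Walks a decision tree over pre-computed loss-of-function facts,
#' emulating the outcome labels of the ClinGen PVS1 specification as
#' applied by automated tools. The engine consumes booleans and fractions
#' ([lof_annotation]) rather than raw transcript structure; each outcome
#' carries a `path_code` naming the branch taken.
#'
#' Frameshift / nonsense (and whole-exon deletion):
#' * NMD predicted and exon in relevant transcript(s): VeryStrong (`NF1`).
#' * NMD predicted, exon not in relevant transcript(s): not met (`NF0`).
#' * No NMD, truncated region critical to function: Strong (`NP4`).
#' * No NMD, LoF not frequent in population and exon relevant:
#'   removes `>=` 10% of protein: Strong (`NP5`); `<` 10%: Moderate
#'   (`NP6`).
#' * No NMD, LoF frequent or exon not relevant: not met (`NP0`).
#'
#' Canonical splice: when no splice rescue (exon skipping / cryptic site)
#' can preserve the frame, the variant behaves like a truncation and the
#' same NMD-led logic applies (`SS1`/`SS0`/`SS4`-`SS6`); with a possible
#' in-frame rescue the preserved-protein logic applies one notch down
#' (`SS7`-`SS10`).
#'
#' Start loss caps at Moderate: Moderate when pathogenic variant(s) exist
#' upstream of the closest in-frame start (`IC1`), else Supporting (`IC2`).
#'
#' Any type: not met when loss of function is not an established disease
#' mechanism for the gene.
#'
#' @param lof A [lof_annotation].
#' @param gene A [gene_info] with `lof_mechanism` known.
#' @return List of class `pvs1_result`: `met`, `strength` (or `NULL`),
#'   `path_code`, `rationale`.
#' @export
classify_pvs1 <- function(lof, gene) {
  if (is.null(lof)) stop("lof annotation block is required", call. = FALSE)
  stopifnot(inherits(lof, "lof_annotation"), inherits(gene, "gene_info"))

  res <- function(met, strength = NULL, path_code, rationale) {
    structure(list(met = met, strength = strength, path_code = path_code,
                   rationale = rationale), class = "pvs1_result")
  }
  if (!isTRUE(gene$lof_mechanism)) {
    return(res(FALSE, path_code = "LOF0",
               rationale = sprintf(
                 "loss of function is not an established disease mechanism for gene %s",
                 gene$symbol)))
  }

  frac <- lof$fraction_protein_removed
  pct <- format(round_half_away(100 * frac, 2L))

  truncating <- function(prefix) {
    nmd_code <- paste0(prefix, "1"); nmd_na <- paste0(prefix, "0")
    if (lof$nmd_predicted) {
      if (lof$exon_in_relevant_transcript) {
        return(res(TRUE, "VeryStrong", nmd_code, paste0(
          nmd_code, "-Predicted to undergo NMD and exon is present in ",
          "biologically relevant transcript(s)")))
      }
      return(res(FALSE, path_code = nmd_na, rationale = paste0(
        nmd_na, "-Predicted to undergo NMD but exon is absent from ",
        "biologically relevant transcripts")))
    }
    # escapes NMD
    if (isTRUE(lof$truncated_region_critical)) {
      code <- if (prefix == "NF") "NP4" else paste0(prefix, "4")
      return(res(TRUE, "Strong", code, paste0(
        code, "-Truncated/altered region is critical to protein function")))
    }
    if (!lof$lof_frequent_in_population && lof$exon_in_relevant_transcript) {
      if (frac >= 0.10) {
        code <- if (prefix == "NF") "NP5" else paste0(prefix, "5")
        return(res(TRUE, "Strong", code, paste0(
          code, "-LoF variants in this exon are not frequent in the ",
          "general population and exon is present in biologically ",
          "relevant transcript(s)-Variants remove >=10% of protein (",
          pct, "%)")))
      }
      code <- if (prefix == "NF") "NP6" else paste0(prefix, "6")
      return(res(TRUE, "Moderate", code, paste0(
        code, "-LoF variants in this exon are not frequent in the general ",
        "population and exon is present in biologically relevant ",
        "transcript(s)-Variants remove <10% of protein")))
    }
    code <- if (prefix == "NF") "NP0" else paste0(prefix, "0")
    res(FALSE, path_code = code, rationale = paste0(
      code, "-LoF variants in this exon are frequent in the general ",
      "population and/or exon is absent from biologically relevant ",
      "transcripts"))
  }

  switch(lof$lof_type,
    frameshift = ,
    nonsense = truncating("NF"),
    exon_deletion = truncating("DL"),
    canonical_splice = {
      if (isTRUE(lof$splice_rescue_possible)) {
        # in-frame rescue preserves part of the protein: one notch down
        if (isTRUE(lof$truncated_region_critical)) {
          return(res(TRUE, "Strong", "SS7", paste0(
            "SS7-In-frame rescue possible but the altered region is ",
            "critical to protein function")))
        }
        if (!lof$lof_frequent_in_population &&
            lof$exon_in_relevant_transcript) {
          if (frac >= 0.10) {
            return(res(TRUE, "Moderate", "SS9", paste0(
              "SS9-In-frame rescue removes >=10% of protein (", pct, "%)")))
          }
          return(res(TRUE, "Supporting", "SS10", paste0(
            "SS10-In-frame rescue removes <10% of protein")))
        }
        return(res(FALSE, path_code = "SS8", rationale = paste0(
          "SS8-In-frame rescue; LoF variants frequent in the general ",
          "population and/or exon absent from relevant transcripts")))
      }
      truncating("SS")
    },
    start_loss = {
      n_up <- lof$pathogenic_variants_in_truncated_region
      if (!is.null(n_up) && n_up > 0) {
        return(res(TRUE, "Moderate", "IC1", sprintf(
          "IC1-%d pathogenic variant(s) upstream of closest potential in-frame start codon",
          n_up)))
      }
      res(TRUE, "Supporting", "IC2", paste0(
        "IC2-No pathogenic variants upstream of closest potential ",
        "in-frame start codon"))
    },
    res(FALSE, path_code = "UNK", rationale = paste0(
      "unknown loss-of-function type '", lof$lof_type, "'"))
  )
}

#' @export
print.pvs1_result <- function(x, ...) {
  if (x$met) {
    cat(sprintf("PVS1 %s: %s\n", x$strength, x$rationale))
  } else {
    cat(sprintf("PVS1 not met: %s\n", x$rationale))
  }
  invisible(x)
}
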