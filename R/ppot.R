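#' @title Pathogenicity-potential (P_POT) logic
#' @description Sample-aware triage of Middle VUS: eligibility over the
#'   four inheritance conditions, the Moderate-with-downgrade strength
#'   rule, attachment and promotion to Hot, and substitution by the real
#'   segregation criterion once family testing results arrive.
#' @name ppot-engine
NULL

#' Per-sample collection of classified variants
#'
#' @param sample_id Sample identifier.
#' @param variants List of entries, each a list with elements `annotation`
#'   (a [variant_annotation]) and `verdict` (an `acmg_verdict_result`).
#' @return A list of class `sample_context`.
#' @export
sample_context <- function(sample_id, variants = list()) {
  stopifnot(is.character(sample_id), nzchar(sample_id))
  for (v in variants) {
    stopifnot(inherits(v$annotation, "variant_annotation"),
              inherits(v$verdict, "acmg_verdict_result"))
    if (!identical(v$annotation$sample_id, sample_id)) {
      stop("all variants in a sample context must share sample_id",
           call. = FALSE)
    }
  }
  structure(list(sample_id = sample_id, variants = variants),
            class = "sample_context")
}

# does a P_POT-free verdict qualify a partner variant for condition 1?
.qualifying_partner <- function(verdict) {
  verdict$acmg_class %in% c("P", "LP") ||
    (verdict$acmg_class == "VUS" &&
       verdict$vus_subclass %in% c("Hot", "Middle"))
}

.class_text <- function(verdict) {
  switch(verdict$acmg_class,
         P = "pathogenic", LP = "likely pathogenic",
         VUS = paste0(verdict$vus_subclass, " VUS"), verdict$acmg_class)
}

#' P_POT eligibility of one variant
#'
#' A `PPOT` call may be attached only to a Middle VUS, when at least one
#' of four conditions holds: (1) the same individual carries another
#' pathogenic / likely pathogenic / Hot / Middle VUS variant in the same
#' gene and the gene is autosomal recessive; (2) the variant is homozygous
#' in an autosomal recessive gene; (3) heterozygous in an autosomal
#' dominant gene; (4) hemizygous in an X-linked gene. Partner eligibility
#' (condition 1) is judged on P_POT-free verdicts in a single pass, so two
#' Middle VUS in one recessive gene each qualify the other.
#'
#' @param variant A [variant_annotation].
#' @param verdict Its P_POT-free `acmg_verdict_result`.
#' @param context The [sample_context] the variant belongs to.
#' @return List with `eligible` (logical), `condition` (1-4 or `NA`) and
#'   `rationale`.
#' @export
ppot_eligible <- function(variant, verdict, context) {
  stopifnot(inherits(variant, "variant_annotation"),
            inherits(verdict, "acmg_verdict_result"),
            inherits(context, "sample_context"))
  not_eligible <- function(why) {
    list(eligible = FALSE, condition = NA_integer_, rationale = why)
  }
  if (verdict$acmg_class != "VUS" || verdict$vus_subclass != "Middle") {
    return(not_eligible("P_POT applies to Middle VUS only"))
  }
  inh <- variant$gene$inheritance
  if (length(inh) == 0L) {
    warning("gene ", variant$gene$symbol,
            " has no recorded inheritance mode; P_POT not assessable",
            call. = FALSE)
    return(not_eligible("inheritance mode unknown"))
  }
  # condition 1: another qualifying variant in the same recessive gene
  if ("AR" %in% inh) {
    self <- variant_label(variant)
    for (entry in context$variants) {
      other <- entry$annotation
      if (!identical(other$gene$symbol, variant$gene$symbol)) next
      if (identical(variant_label(other), self)) next
      if (.qualifying_partner(entry$verdict)) {
        return(list(
          eligible = TRUE, condition = 1L,
          rationale = sprintf(
            "possible in-trans configuration with the %s %s variant",
            .class_text(entry$verdict), variant_label(other))))
      }
    }
  }
  if (variant$zygosity == "hom" && "AR" %in% inh) {
    return(list(eligible = TRUE, condition = 2L,
                rationale = "homozygous variant in autosomal recessive gene"))
  }
  if (variant$zygosity == "het" && "AD" %in% inh) {
    return(list(eligible = TRUE, condition = 3L,
                rationale = "possible de novo variant"))
  }
  if (variant$zygosity == "hemi" && "XL" %in% inh) {
    return(list(eligible = TRUE, condition = 4L,
                rationale = "hemizygous variant in X-linked gene"))
  }
  not_eligible("no eligibility condition satisfied")
}

#' P_POT strength with downgrade
#'
#' `PPOT` is assigned at Moderate, downgraded to Supporting when the
#' Middle VUS carries exactly the combinations 1 Moderate + 2 Supporting
#' pathogenic criteria, or 2 Moderate pathogenic criteria. Benign counts
#' are ignored.
#'
#' @param counts The variant's [strength_counts] *excluding* `PPOT`.
#' @return `"Moderate"` or `"Supporting"`.
#' @export
ppot_strength <- function(counts) {
  stopifnot(inherits(counts, "strength_counts"))
  pm <- counts["pm"]; pp <- counts["pp"]
  if ((pm == 1L && pp == 2L) || pm == 2L) "Supporting" else "Moderate"
}

#' Attach P_POT across a sample
#'
#' Single pass over the P_POT-free verdicts of a sample: every eligible
#' Middle VUS receives a `PPOT` call at [ppot_strength] and is
#' resubclassified with `PPOT` included; patterns absent from the printed
#' table fall back through the lookup reduction, and any remaining
#' non-Hot outcome is promoted directly, so a variant carrying a met
#' `PPOT` is always Hot (potential) and reportable. The ACMG class itself
#' never changes.
#'
#' @param context A [sample_context] of P_POT-free verdicts.
#' @return The updated [sample_context].
#' @export
apply_ppot <- function(context) {
  stopifnot(inherits(context, "sample_context"))
  out <- context
  for (i in seq_along(context$variants)) {
    entry <- context$variants[[i]]
    elig <- ppot_eligible(entry$annotation, entry$verdict, context)
    if (!elig$eligible) next
    base_counts <- effective_counts(entry$verdict$evidence,
                                    include_ppot = FALSE)
    ppot <- evidence_call("PPOT", strength = ppot_strength(base_counts),
                          rationale = elig$rationale, source = "auto")
    ev <- evidence_set(c(unclass(entry$verdict$evidence), list(ppot)))
    verdict <- classify_variant(ev)
    verdict$explanation <- c(verdict$explanation, "subclass: Hot (potential)")
    out$variants[[i]]$verdict <- verdict
  }
  out
}

#' A family-segregation result for one variant
#'
#' @param kind One of `de_novo_confirmed`, `de_novo_excluded`,
#'   `in_trans_confirmed`, `in_cis_or_refuted`, `cosegregation_confirmed`,
#'   `cosegregation_refuted`.
#' @param meioses Optional number of informative meioses.
#' @param parentage_confirmed For `de_novo_confirmed`: was parentage
#'   confirmed (PS2) or merely assumed (PM6)?
#' @param unaffected_carrier Optional: the genotype was also observed in a
#'   healthy adult relative (adds BS2).
#' @return A list of class `segregation_result`.
#' @export
segregation_result <- function(kind, meioses = NULL,
                               parentage_confirmed = FALSE,
                               unaffected_carrier = FALSE) {
  stopifnot(kind %in% c("de_novo_confirmed", "de_novo_excluded",
                        "in_trans_confirmed", "in_cis_or_refuted",
                        "cosegregation_confirmed", "cosegregation_refuted"))
  if (!is.null(meioses)) stopifnot(meioses >= 0)
  structure(list(kind = kind, meioses = meioses,
                 parentage_confirmed = isTRUE(parentage_confirmed),
                 unaffected_carrier = isTRUE(unaffected_carrier)),
            class = "segregation_result")
}

#' Substitute P_POT with the observed segregation criterion
#'
#' Once family testing is available, the proxy `PPOT` call is inactivated
#' and replaced by the criterion it stood for: confirmed de novo gives PS2
#' (Strong, parentage confirmed) or PM6 (Moderate); confirmed in-trans
#' phase gives PM3 (Moderate); confirmed cosegregation gives PP1
#' (Supporting). Refutations apply the opposite benign criteria: de novo
#' excluded or cosegregation refuted gives BS4 (Strong); in-cis phase
#' gives BP2 (Supporting); observation in an unaffected relative adds BS2
#' (Strong). The ACMG class and subclass are recomputed from scratch on
#' the updated evidence.
#'
#' @param variant A [variant_annotation].
#' @param verdict Its `acmg_verdict_result`, carrying a met `PPOT`.
#' @param result A [segregation_result].
#' @return A fresh `acmg_verdict_result` with no `PPOT` call.
#' @export
resolve_segregation <- function(variant, verdict, result) {
  stopifnot(inherits(verdict, "acmg_verdict_result"),
            inherits(result, "segregation_result"))
  ppot <- verdict$evidence[["PPOT"]]
  if (is.null(ppot) || !ppot$met) {
    stop("resolve_segregation requires a verdict carrying a met PPOT call",
         call. = FALSE)
  }
  sub <- switch(result$kind,
    de_novo_confirmed = if (result$parentage_confirmed) {
      evidence_call("PS2", strength = "Strong",
                    rationale = "de novo occurrence, parentage confirmed")
    } else {
      evidence_call("PM6", strength = "Moderate",
                    rationale = "assumed de novo, parentage not confirmed")
    },
    in_trans_confirmed = evidence_call(
      "PM3", strength = "Moderate",
      rationale = "in trans with a pathogenic variant (recessive disorder)"),
    cosegregation_confirmed = evidence_call(
      "PP1", strength = "Supporting",
      rationale = sprintf("cosegregation with disease in affected relatives%s",
                          if (is.null(result$meioses)) "" else
                            sprintf(" (%d meioses)", result$meioses))),
    de_novo_excluded = evidence_call(
      "BS4", strength = "Strong",
      rationale = "inherited from an unaffected parent (de novo excluded)"),
    cosegregation_refuted = evidence_call(
      "BS4", strength = "Strong",
      rationale = "lack of segregation in affected members of the family"),
    in_cis_or_refuted = evidence_call(
      "BP2", strength = "Supporting",
      rationale = "observed in cis with a pathogenic variant")
  )
  calls <- unclass(verdict$evidence)
  calls[["PPOT"]] <- NULL
  calls[[sub$criterion]] <- sub
  if (result$unaffected_carrier && !"BS2" %in% names(calls)) {
    calls[["BS2"]] <- evidence_call(
      "BS2", strength = "Strong",
      rationale = "genotype observed in a healthy adult relative")
  }
  classify_variant(evidence_set(calls))
}

#' Classify annotated variants end to end
#'
#' Runs the full pipeline: the decision-MAF pre-filter, criterion
#' assignment, ACMG combination and subclassification per variant, then
#' the sample-level P_POT pass, and finally any supplied segregation
#' substitutions.
#'
#' @param variants List of [variant_annotation] objects (any mix of
#'   samples).
#' @param cfg An [acmg_thresholds].
#' @param segregation Optional named list mapping `GENE:hgvs_c` keys
#'   (e.g. `"USH2A:c.5213T>C"`) to [segregation_result] objects.
#' @return Named list of [sample_context] objects, one per sample.
#' @export
classify_annotations <- function(variants, cfg = acmg_thresholds(),
                                 segregation = NULL) {
  stopifnot(all(vapply(variants, inherits, TRUE, "variant_annotation")))
  sample_ids <- vapply(variants, `[[`, "", "sample_id")
  contexts <- list()
  for (sid in unique(sample_ids)) {
    entries <- list()
    for (v in variants[sample_ids == sid]) {
      dm <- decision_maf(v$population, cfg)
      verdict <- if (!dm$passes) {
        .filtered_verdict(dm$maf)
      } else {
        classify_variant(assign_criteria(v, cfg))
      }
      entries[[length(entries) + 1L]] <- list(annotation = v,
                                              verdict = verdict)
    }
    ctx <- apply_ppot(sample_context(sid, entries))
    if (!is.null(segregation)) {
      for (i in seq_along(ctx$variants)) {
        entry <- ctx$variants[[i]]
        key <- paste(entry$annotation$gene$symbol, entry$annotation$hgvs_c,
                     sep = ":")
        seg <- segregation[[key]]
        if (!is.null(seg) && !is.null(entry$verdict$ppot)) {
          ctx$variants[[i]]$verdict <-
            resolve_segregation(entry$annotation, entry$verdict, seg)
        }
      }
    }
    contexts[[sid]] <- ctx
  }
  contexts
}
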