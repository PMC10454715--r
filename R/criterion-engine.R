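#' @title Automatic criterion assignment
#' @description The criteria the engine computes itself: the PP3/BP4
#'   computational-evidence rules per consequence class, the PM2 and BP6
#'   strength modifications, the BP1 benign-missense rule, and the
#'   decision-MAF pre-filter. Everything else is accepted as an upstream
#'   call and merged by [assign_criteria()].
#' @name criterion-engine
NULL

#' Count rank scores beyond a cutoff
#'
#' @param scores A [predictor_scores].
#' @param cutoff Cutoff in `[0,1]`.
#' @param direction `"ge"` (damaging, `>= cutoff`) or `"le"` (benign,
#'   `<= cutoff`). Both comparisons are inclusive.
#' @return List with `count` (scores satisfying the comparison) and
#'   `n_available` (non-missing rank scores).
#' @export
count_rank_scores <- function(scores, cutoff, direction = c("ge", "le")) {
  direction <- match.arg(direction)
  stopifnot(inherits(scores, "predictor_scores"),
            cutoff >= 0, cutoff <= 1)
  rs <- scores$rank_scores
  rs <- rs[!is.na(rs)]
  n <- length(rs)
  cnt <- if (n == 0L) 0L else if (direction == "ge") sum(rs >= cutoff)
         else sum(rs <= cutoff)
  list(count = as.integer(cnt), n_available = as.integer(n))
}

# Evaluate the three missense conditions for one side.
# A condition is evaluable iff its inputs are present; an inevaluable
# condition counts as unmet, never as absent, when >= 2 are evaluable.
.missense_conditions <- function(scores, cfg, side) {
  if (side == "path") {
    rv_cut <- cfg$revel_path; cd_cut <- cfg$cadd_path
    rk_cut <- cfg$rank_cutoff_path; dir <- "ge"
    rv_ok <- function(x) x >= rv_cut; cd_ok <- function(x) x >= cd_cut
  } else {
    rv_cut <- cfg$revel_benign; cd_cut <- cfg$cadd_benign
    rk_cut <- cfg$rank_cutoff_benign; dir <- "le"
    rv_ok <- function(x) x <= rv_cut; cd_ok <- function(x) x <= cd_cut
  }
  rk <- count_rank_scores(scores, rk_cut, dir)
  evaluable <- c(revel = !is.null(scores$revel),
                 cadd = !is.null(scores$cadd_phred),
                 rank_majority = rk$n_available > 0L)
  met <- c(revel = !is.null(scores$revel) && rv_ok(scores$revel),
           cadd = !is.null(scores$cadd_phred) && cd_ok(scores$cadd_phred),
           rank_majority = rk$count >= cfg$n_rank_required)
  list(met = met, evaluable = evaluable, rank = rk)
}

.splice_condition <- function(scores, cfg, side) {
  ada <- scores$ada_boost; rf <- scores$rf
  if (is.null(ada) || is.null(rf)) {
    return(list(met = FALSE, evaluable = FALSE))
  }
  met <- if (side == "path") ada >= cfg$ada_cutoff && rf >= cfg$rf_cutoff
         else                ada <= cfg$ada_cutoff && rf <= cfg$rf_cutoff
  list(met = met, evaluable = TRUE)
}

.insilico_decision <- function(consequence, scores, cfg, side) {
  crit <- if (side == "path") "PP3" else "BP4"
  verdict_met <- if (side == "path") "pp3_met" else "bp4_met"
  splice_classes <- c("synonymous_splice", "splice_region",
                      "intronic_within_5")
  res <- list(verdict = "not_applicable", conditions_met = logical(),
              branch = NA_character_, rationale = "", call = NULL)

  mk_call <- function(rationale) {
    evidence_call(crit, met = TRUE, strength = "Supporting",
                  rationale = rationale, source = "auto")
  }

  if (consequence %in% c("missense", "missense_splice")) {
    mc <- .missense_conditions(scores, cfg, side)
    use_missense <- consequence == "missense" || sum(mc$evaluable) >= 2L
    if (use_missense) {
      n_true <- sum(mc$met)
      res$branch <- "missense"
      res$conditions_met <- mc$met
      res$verdict <- if (n_true >= 2L) verdict_met else "neither"
      res$rationale <- sprintf(
        "%d/%d predictors are %s, REVEL score: %s and CADD score: %s (%d/3 %s conditions)",
        mc$rank$count, cfg$n_rank_total,
        if (side == "path") "damaging" else "benign",
        if (is.null(scores$revel)) "NA" else format(scores$revel),
        if (is.null(scores$cadd_phred)) "NA" else format(scores$cadd_phred),
        n_true, if (side == "path") "pathogenic" else "benign")
      if (res$verdict == verdict_met) res$call <- mk_call(res$rationale)
      return(res)
    }
    res$branch <- "missense_fallback_splice"
  } else if (consequence %in% splice_classes) {
    res$branch <- "splice_scores"
  } else {
    return(res)  # not_applicable
  }

  sp <- .splice_condition(scores, cfg, side)
  res$conditions_met <- c(ada_rf = sp$met)
  res$verdict <- if (sp$met) verdict_met else "neither"
  res$rationale <- sprintf(
    "AdaBoost: %s, RF: %s vs cutoffs %s/%s",
    if (is.null(scores$ada_boost)) "NA" else format(scores$ada_boost),
    if (is.null(scores$rf)) "NA" else format(scores$rf),
    format(cfg$ada_cutoff), format(cfg$rf_cutoff))
  if (res$verdict == verdict_met) res$call <- mk_call(res$rationale)
  res
}

# Boundary equality on the splice branch satisfies both the ">=" and "<="
# rules; neither criterion is assigned and a conflict is recorded.
.resolve_insilico_conflict <- function(pp3, bp4) {
  if (identical(pp3$verdict, "pp3_met") && identical(bp4$verdict, "bp4_met")) {
    msg <- "conflict: pathogenic and benign splice rules both satisfied at cutoff equality; neither assigned"
    pp3$verdict <- "neither"; pp3$call <- NULL
    pp3$rationale <- paste(msg, pp3$rationale, sep = " | ")
    bp4$verdict <- "neither"; bp4$call <- NULL
    bp4$rationale <- paste(msg, bp4$rationale, sep = " | ")
  }
  list(pp3 = pp3, bp4 = bp4)
}

#' Assign PP3 (computational evidence, pathogenic)
#'
#' Missense: met iff at least 2 of 3 conditions hold (REVEL `>=` 0.644,
#' CADD `>=` 25.3, at least 8/15 rank scores `>=` 0.644). Missense+splice:
#' the missense rule when at least two of its conditions are evaluable,
#' otherwise the splice rule. Synonymous-splice, splice-region and intronic
#' (+/-5): AdaBoost `>=` 0.708 AND RF `>=` 0.515. Other consequences: not
#' applicable. A met PP3 always carries Supporting strength. If the benign
#' mirror rule would fire on the same inputs (possible only at exact cutoff
#' equality on the splice branch) neither criterion is assigned.
#'
#' @param consequence One of [consequence_classes].
#' @param scores A [predictor_scores].
#' @param cfg An [acmg_thresholds].
#' @return List with `verdict` (`pp3_met`/`neither`/`not_applicable`),
#'   `conditions_met`, `branch`, `rationale`, and `call` (an
#'   [evidence_call] when met, else `NULL`).
#' @export
assign_pp3 <- function(consequence, scores, cfg = acmg_thresholds()) {
  stopifnot(consequence %in% consequence_classes)
  pp3 <- .insilico_decision(consequence, scores, cfg, "path")
  bp4 <- .insilico_decision(consequence, scores, cfg, "benign")
  .resolve_insilico_conflict(pp3, bp4)$pp3
}

#' Assign BP4 (computational evidence, benign)
#'
#' Mirror of [assign_pp3] with the benign cutoffs: missense met iff at
#' least 2 of (REVEL `<=` 0.29, CADD `<=` 22.7, at least 8/15 rank scores
#' `<=` 0.29); splice branches met iff AdaBoost `<=` 0.708 AND RF `<=`
#' 0.515. A met BP4 carries Supporting strength.
#'
#' @inheritParams assign_pp3
#' @return As [assign_pp3], with verdict `bp4_met`/`neither`/
#'   `not_applicable`.
#' @export
assign_bp4 <- function(consequence, scores, cfg = acmg_thresholds()) {
  stopifnot(consequence %in% consequence_classes)
  pp3 <- .insilico_decision(consequence, scores, cfg, "path")
  bp4 <- .insilico_decision(consequence, scores, cfg, "benign")
  .resolve_insilico_conflict(pp3, bp4)$bp4
}

#' PM2 strength modification
#'
#' When PM2 is triggered (upstream at any strength, or by the engine's
#' population-absence check) it is re-assigned the standard Moderate
#' intensity, regardless of the Supporting or Strong level it arrived at.
#'
#' @param triggered Was PM2 triggered?
#' @param upstream_strength Strength it arrived at (informational only).
#' @return An [evidence_call] for PM2.
#' @export
modify_pm2 <- function(triggered, upstream_strength = NULL) {
  if (!triggered) {
    return(evidence_call("PM2", met = FALSE,
                         rationale = "not triggered", source = "auto"))
  }
  note <- if (!is.null(upstream_strength) && upstream_strength != "Moderate") {
    sprintf(" (re-assigned from %s)", upstream_strength)
  } else ""
  evidence_call(
    "PM2", strength = "Moderate", source = "auto",
    rationale = paste0(
      "Absent from controls (or at extremely low frequency if recessive) ",
      "in Exome Sequencing Project, 1000 Genomes Project, or Exome ",
      "Aggregation Consortium", note))
}

#' BP6 strength modification
#'
#' A BP6 triggered at VeryStrong or Moderate is re-assigned Supporting
#' intensity (a geneticist may later confirm or upgrade it to Strong via
#' the `confirm` workflow); triggered at Strong or Supporting it is kept
#' as-is.
#'
#' @param triggered Was BP6 triggered upstream?
#' @param upstream_strength Benign strength it arrived at.
#' @return An [evidence_call] for BP6.
#' @export
modify_bp6 <- function(triggered, upstream_strength = NULL) {
  if (!triggered) {
    return(evidence_call("BP6", met = FALSE,
                         rationale = "not triggered", source = "auto"))
  }
  if (is.null(upstream_strength)) upstream_strength <- "Supporting"
  if (upstream_strength %in% c("Strong", "Supporting")) {
    return(evidence_call("BP6", strength = upstream_strength,
                         source = "upstream",
                         rationale = "reputable-source benign assertion"))
  }
  # VeryStrong / Moderate (and any other off-scale label an upstream
  # system emits) are re-assigned Supporting pending confirmation
  evidence_call(
    "BP6", strength = "Supporting", source = "auto",
    rationale = sprintf(
      "reputable-source benign assertion; re-assigned Supporting from %s pending geneticist confirmation",
      upstream_strength))
}

#' Assign BP1 (missense in a gene where missense is rarely pathogenic)
#'
#' Met at Supporting for missense variants when either sub-rule holds:
#' (a) the benign fraction rule, `100 * benign / total > 33.1` percent of
#' non-VUS missense variants in the gene are benign; or (b) the missense-Z
#' rule, gnomAD missense Z `< 2.99`. Sub-rule (b) is opt-in per gene
#' (`gene$bp1_z_rule`) because as printed it would fire genome-wide.
#'
#' @param gene A [gene_info].
#' @param consequence One of [consequence_classes].
#' @param cfg An [acmg_thresholds].
#' @return An [evidence_call] for BP1; when met via sub-rule (a) the
#'   one-decimal percentage is available as `attr(, "percent")`.
#' @export
assign_bp1 <- function(gene, consequence, cfg = acmg_thresholds()) {
  if (!consequence %in% c("missense", "missense_splice")) {
    return(evidence_call("BP1", met = FALSE, source = "auto",
                         rationale = "not a missense variant"))
  }
  b <- gene$benign_nonvus_missense
  t <- gene$total_nonvus_missense
  if (!is.null(b) && !is.null(t) && t > 0) {
    pct <- round_half_away(100 * b / t, 1L)
    if (100 * b / t > cfg$bp1_benign_fraction_pct) {
      call <- evidence_call(
        "BP1", strength = "Supporting", source = "auto",
        rationale = sprintf(
          "%d out of %d non-VUS missense variants in gene %s are benign = %.1f%%, which is more than threshold of %s%%",
          b, t, gene$symbol, pct, format(cfg$bp1_benign_fraction_pct)))
      attr(call, "percent") <- pct
      return(call)
    }
  }
  if (gene$bp1_z_rule && !is.null(gene$missense_z) &&
      gene$missense_z < cfg$bp1_missense_z) {
    return(evidence_call(
      "BP1", strength = "Supporting", source = "auto",
      rationale = sprintf(
        "GnomAD missense Z-score for gene %s is %s, which is less than %s",
        gene$symbol, format(gene$missense_z), format(cfg$bp1_missense_z))))
  }
  evidence_call("BP1", met = FALSE, source = "auto",
                rationale = "benign-missense sub-rules not satisfied")
}

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; the rationale percentages use
#' commercial rounding (196/529 prints as 37.1).
#'
#' @param x Numeric.
#' @param digits Decimal digits.
#' @return Numeric.
#' @export
round_half_away <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Decision-MAF pre-filter
#'
#' Integrates the per-source minor-allele frequencies (dbNSFP, VEP, gnomAD)
#' by maximum; only variants with a decision MAF strictly below 3% proceed
#' to criterion assignment, the rest are marked `filtered`.
#'
#' @param population A [population_data].
#' @param cfg An [acmg_thresholds].
#' @return List with `maf` (the integrated frequency, 0 when absent from
#'   all sources) and `passes` (logical).
#' @export
decision_maf <- function(population, cfg = acmg_thresholds()) {
  f <- population$maf_by_source
  maf <- if (is.null(f) || length(f) == 0L) 0 else max(f)
  list(maf = maf, passes = maf < cfg$decision_maf_pct / 100)
}

# Engine PM2 trigger when no upstream PM2 call is supplied: all present
# population fields show absence, or (AR gene) homozygote count < 2;
# requires coverage not known-bad.
.auto_pm2_trigger <- function(population, gene) {
  if (isFALSE(population$coverage_ok)) return(FALSE)
  f <- population$maf_by_source
  absent <- (is.null(f) || length(f) == 0L || all(f == 0)) &&
    (is.null(population$gnomad_allele_count) ||
       population$gnomad_allele_count == 0L)
  if (absent) return(TRUE)
  if ("AR" %in% gene$inheritance &&
      !is.null(population$gnomad_hom_count) &&
      population$gnomad_hom_count < 2L) {
    return(TRUE)
  }
  FALSE
}

.engine_owned <- c("PP3", "BP4", "PM2", "BP1", "PVS1")

#' Assign the full evidence set for one variant
#'
#' Merges (1) engine-computed calls -- PP3/BP4, PM2 (with strength
#' modification), BP1 and PVS1 via the loss-of-function tree -- which
#' override any upstream call for the same criterion, and (2) the remaining
#' upstream calls passed through verbatim, with the BP6 strength
#' modification applied and PP5 capped at Supporting. Only met calls enter
#' the set; overridden upstream calls are logged in `attr(, "overrides")`
#' and engine not-met decisions in `attr(, "notes")`.
#'
#' @param variant A [variant_annotation] that passed [decision_maf].
#' @param cfg An [acmg_thresholds].
#' @return An [evidence_set] with attributes `overrides` and `notes`.
#' @export
assign_criteria <- function(variant, cfg = acmg_thresholds()) {
  stopifnot(inherits(variant, "variant_annotation"))
  upstream <- variant$upstream_calls
  up_codes <- vapply(upstream, `[[`, "", "criterion")
  names(upstream) <- up_codes

  calls <- list()
  overrides <- character()
  notes <- character()
  add <- function(call) {
    if (call$met) calls[[call$criterion]] <<- call
  }

  # PP3 / BP4 (auto; exclusive by construction)
  pp3 <- assign_pp3(variant$consequence, variant$scores, cfg)
  bp4 <- assign_bp4(variant$consequence, variant$scores, cfg)
  if (!is.null(pp3$call)) add(pp3$call) else notes <- c(notes,
    paste0("PP3 ", pp3$verdict, ": ", pp3$rationale))
  if (!is.null(bp4$call)) add(bp4$call) else notes <- c(notes,
    paste0("BP4 ", bp4$verdict, ": ", bp4$rationale))

  # PM2: prefer an explicit upstream trigger, else the engine's check
  pm2_up <- upstream[["PM2"]]
  triggered <- if (!is.null(pm2_up)) pm2_up$met
               else .auto_pm2_trigger(variant$population, variant$gene)
  add(modify_pm2(triggered,
                 if (!is.null(pm2_up)) pm2_up$strength else NULL))

  # BP1
  add(assign_bp1(variant$gene, variant$consequence, cfg))

  # PVS1 via the LoF decision tree
  if (!is.null(variant$lof)) {
    pvs1 <- classify_pvs1(variant$lof, variant$gene)
    if (pvs1$met) {
      add(evidence_call("PVS1", strength = pvs1$strength,
                        rationale = pvs1$rationale, source = "auto"))
    } else {
      notes <- c(notes, paste0("PVS1 not met: ", pvs1$rationale))
    }
  }

  # upstream pass-through (user-sourced confirmations handled last)
  user_calls <- Filter(function(u) identical(u$source, "user"), upstream)
  upstream <- Filter(function(u) !identical(u$source, "user"), upstream)
  for (uc in upstream) {
    code <- uc$criterion
    if (code %in% .engine_owned) {
      if (uc$met && is.null(calls[[code]])) {
        overrides <- c(overrides, sprintf(
          "%s upstream %s overridden to not-met by engine", code,
          uc$strength))
      } else if (uc$met && !identical(calls[[code]]$strength, uc$strength)) {
        overrides <- c(overrides, sprintf(
          "%s upstream %s overridden to %s by engine", code, uc$strength,
          calls[[code]]$strength))
      }
      next
    }
    if (!uc$met) next
    if (code == "BP6") {
      add(modify_bp6(TRUE, uc$strength))
    } else if (code == "PP5" &&
               strength_rank(uc$strength, "pathogenic") >
                 strength_rank("Supporting", "pathogenic")) {
      # symmetric with the BP6 auto cap
      add(evidence_call("PP5", strength = "Supporting", source = "auto",
                        rationale = paste0(uc$rationale,
                                           " (capped at Supporting)")))
      overrides <- c(overrides,
                     sprintf("PP5 upstream %s capped at Supporting",
                             uc$strength))
    } else {
      uc$source <- "upstream"
      add(uc)
    }
  }

  # geneticist confirmations override any engine or upstream call
  for (uc in user_calls) {
    if (uc$met) {
      calls[[uc$criterion]] <- uc
    } else if (!is.null(calls[[uc$criterion]])) {
      overrides <- c(overrides, sprintf(
        "%s turned off by user confirmation", uc$criterion))
      calls[[uc$criterion]] <- NULL
    }
  }

  ev <- evidence_set(calls)
  attr(ev, "overrides") <- overrides
  attr(ev, "notes") <- notes
  ev
}
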