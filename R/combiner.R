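#' @title Evidence combination and VUS subclassification
#' @description Turns a strength-count tally into the five-tier ACMG 2015
#'   verdict and, for variants of uncertain significance, the Hot / Middle /
#'   Cold subclass via an exact lookup in the shipped 36-row pattern table
#'   with a deterministic reduction fallback.
#' @name combiner
NULL

.pkg_cache <- new.env(parent = emptyenv())

#' The VUS subclassification pattern table
#'
#' Thirty-six strength-multiset patterns (16 Hot, 10 Middle, 10 Cold),
#' shipped as a TSV under `extdata` so the mapping is auditable. Loading
#' asserts that no pattern is duplicated and that every pattern is
#' genuinely VUS under the combining rules.
#'
#' @param path Optional path to an alternative table (same columns:
#'   `pvs, ps, pm, pp, ba, bs, bp, subclass`).
#' @return A data frame with the seven count columns and `subclass`.
#' @export
vus_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.pkg_cache$vus_table)) return(.pkg_cache$vus_table)
    path <- system.file("extdata", "vus_subclass_table.tsv",
                        package = "acmgrules", mustWork = TRUE)
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pvs", "ps", "pm", "pp", "ba", "bs", "bp", "subclass")
  if (!identical(names(tab), need)) {
    stop("subclass table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(tab$subclass %in% c("Hot", "Middle", "Cold")))
  key <- do.call(paste, c(tab[need[1:7]], sep = ":"))
  if (anyDuplicated(key)) {
    stop("duplicate pattern(s) in subclass table", call. = FALSE)
  }
  for (i in seq_len(nrow(tab))) {
    cls <- acmg_verdict(do.call(strength_counts, as.list(tab[i, need[1:7]])))
    if (cls != "VUS") {
      stop("subclass table row ", i, " is ", cls, ", not VUS", call. = FALSE)
    }
  }
  tab$key <- key
  if (cache) .pkg_cache$vus_table <- tab
  tab
}

#' ACMG 2015 combining rules
#'
#' Combines a strength-count tally into Pathogenic, Likely pathogenic,
#' VUS, Likely benign or Benign per the 2015 ACMG/AMP scheme. Pathogenic:
#' 1 VeryStrong with (1 Strong, or 2 Moderate, or 1 Moderate + 1
#' Supporting, or 2 Supporting); or 2 Strong; or 1 Strong with (3
#' Moderate, or 2 Moderate + 2 Supporting, or 1 Moderate + 4 Supporting).
#' Likely pathogenic: 1 VeryStrong + 1 Moderate; 1 Strong + 1-2 Moderate;
#' 1 Strong + 2 Supporting; 3 Moderate; 2 Moderate + 2 Supporting; 1
#' Moderate + 4 Supporting. Benign: 1 StandAlone or 2 Strong benign.
#' Likely benign: 1 Strong benign + 1 Supporting benign, or 2 Supporting
#' benign. When a pathogenic-side and a benign-side rule both fire, or no
#' rule fires, the verdict is VUS. `PPOT` never contributes here: pass
#' counts from `effective_counts(evidence, include_ppot = FALSE)`.
#'
#' @param counts A [strength_counts].
#' @return One of `"P"`, `"LP"`, `"VUS"`, `"LB"`, `"B"`.
#' @export
acmg_verdict <- function(counts) {
  stopifnot(inherits(counts, "strength_counts"))
  pvs <- counts["pvs"]; ps <- counts["ps"]; pm <- counts["pm"]
  pp <- counts["pp"]; ba <- counts["ba"]; bs <- counts["bs"]
  bp <- counts["bp"]

  pathogenic <-
    (pvs >= 1 && (ps >= 1 || pm >= 2 || (pm >= 1 && pp >= 1) || pp >= 2)) ||
    ps >= 2 ||
    (ps >= 1 && (pm >= 3 || (pm >= 2 && pp >= 2) || (pm >= 1 && pp >= 4)))
  likely_path <-
    (pvs >= 1 && pm >= 1) ||
    (ps >= 1 && pm >= 1) ||
    (ps >= 1 && pp >= 2) ||
    pm >= 3 ||
    (pm >= 2 && pp >= 2) ||
    (pm >= 1 && pp >= 4)
  benign <- ba >= 1 || bs >= 2
  likely_benign <- (bs >= 1 && bp >= 1) || bp >= 2

  path_side <- pathogenic || likely_path
  benign_side <- benign || likely_benign
  if (path_side && benign_side) return("VUS")
  if (pathogenic) return("P")
  if (likely_path) return("LP")
  if (benign) return("B")
  if (likely_benign) return("LB")
  "VUS"
}

.counts_key <- function(counts) paste(counts, collapse = ":")

#' Subclassify a VUS as Hot, Middle or Cold
#'
#' Exact match of the full count tuple (benign counts included) against
#' the 36-row pattern table. Combinations outside the printed table are
#' reduced deterministically until a row matches: benign evidence is
#' dropped one unit at a time (Supporting-benign first, then
#' Strong-benign), then the weakest pathogenic unit (Supporting, then
#' Moderate, then Strong, then VeryStrong); if nothing ever matches the
#' result is Middle. Fallback use is flagged on the result.
#'
#' @param counts A [strength_counts] whose [acmg_verdict] is `"VUS"`.
#' @param table A table from [vus_table].
#' @return `"Hot"`, `"Middle"` or `"Cold"`, with attributes `fallback`
#'   (logical) and `trace` (character, the reduction steps taken).
#' @export
vus_subclass <- function(counts, table = vus_table()) {
  stopifnot(inherits(counts, "strength_counts"))
  if (acmg_verdict(counts) != "VUS") {
    stop("vus_subclass requires a VUS count pattern", call. = FALSE)
  }
  lookup <- function(x) {
    hit <- match(.counts_key(x), table$key)
    if (is.na(hit)) NULL else table$subclass[hit]
  }
  direct <- lookup(counts)
  if (!is.null(direct)) {
    return(structure(direct, fallback = FALSE, trace = character()))
  }
  trace <- character()
  work <- counts
  # benign reduction: BP first, then BS (and any BA, which no row carries)
  for (bucket in c("bp", "bs", "ba")) {
    while (work[bucket] > 0L) {
      work[bucket] <- work[bucket] - 1L
      trace <- c(trace, paste0("dropped one ", toupper(bucket)))
      hit <- lookup(work)
      if (!is.null(hit)) {
        return(structure(hit, fallback = TRUE, trace = trace))
      }
    }
  }
  # then the weakest pathogenic unit
  for (bucket in c("pp", "pm", "ps", "pvs")) {
    while (work[bucket] > 0L) {
      work[bucket] <- work[bucket] - 1L
      trace <- c(trace, paste0("dropped one ", toupper(bucket)))
      hit <- lookup(work)
      if (!is.null(hit)) {
        return(structure(hit, fallback = TRUE, trace = trace))
      }
    }
  }
  structure("Middle", fallback = TRUE,
            trace = c(trace, "no reduced pattern matched; defaulted Middle"))
}

#' Classify one variant from its evidence set
#'
#' Computes the ACMG class on the counts *without* `PPOT`; when the class
#' is VUS, subclassifies on the counts *with* a met `PPOT` included. The
#' variant is reportable iff Pathogenic, Likely pathogenic, or Hot VUS.
#'
#' @param evidence An [evidence_set].
#' @return A list of class `acmg_verdict_result`: `acmg_class`,
#'   `vus_subclass` (`"none"` unless VUS), `ppot` (the met `PPOT` call or
#'   `NULL`), `reportable`, `evidence`, `explanation` (character lines).
#' @export
classify_variant <- function(evidence) {
  stopifnot(inherits(evidence, "acmg_evidence"))
  counts <- effective_counts(evidence, include_ppot = FALSE)
  cls <- acmg_verdict(counts)
  ppot <- evidence[["PPOT"]]
  if (!is.null(ppot) && !ppot$met) ppot <- NULL
  sub <- "none"
  sub_attr <- NULL
  if (cls == "VUS") {
    if (!is.null(ppot)) {
      # subclassify WITH the met PPOT; a variant carrying P_POT is always
      # promoted to Hot, directly when its augmented pattern is outside
      # the printed table (e.g. the BS+PVS row, whose augmented counts
      # exceed the VUS combinations altogether)
      counts_sub <- effective_counts(evidence, include_ppot = TRUE)
      sub_attr <- if (acmg_verdict(counts_sub) == "VUS") {
        vus_subclass(counts_sub)
      } else {
        structure("Hot", fallback = TRUE, trace =
          "P_POT-augmented pattern exceeds the VUS combinations; promoted directly")
      }
      if (as.character(sub_attr) != "Hot") {
        sub_attr <- structure("Hot", fallback = TRUE, trace = c(
          attr(sub_attr, "trace"),
          "promoted directly to Hot by P_POT (augmented pattern unprinted)"))
      }
      sub <- "Hot"
    } else {
      sub_attr <- vus_subclass(counts)
      sub <- as.character(sub_attr)
    }
  } else {
    ppot <- NULL
  }
  reportable <- cls %in% c("P", "LP") || (cls == "VUS" && sub == "Hot")
  explanation <- character()
  for (call in evidence) {
    if (call$met && call$criterion != "PPOT") {
      explanation <- c(explanation, sprintf("%s %s: %s", call$criterion,
                                            call$strength, call$rationale))
    }
  }
  if (!is.null(ppot)) {
    explanation <- c(explanation, sprintf("P_POT %s: %s", ppot$strength,
                                          ppot$rationale))
  }
  if (!is.null(sub_attr) && isTRUE(attr(sub_attr, "fallback"))) {
    explanation <- c(explanation, paste0(
      "fallback: pattern outside the printed table (",
      paste(attr(sub_attr, "trace"), collapse = "; "), ")"))
  }
  explanation <- c(explanation, paste0(
    "Final: ", cls, if (cls == "VUS") paste0(" ", sub) else ""))
  structure(list(acmg_class = cls, vus_subclass = sub, ppot = ppot,
                 reportable = reportable, evidence = evidence,
                 explanation = explanation),
            class = "acmg_verdict_result")
}

#' @export
print.acmg_verdict_result <- function(x, ...) {
  cat(paste(x$explanation, collapse = "\n"), "\n")
  cat("Reportable:", if (x$reportable) "yes" else "no", "\n")
  invisible(x)
}

# verdict for a variant removed by the decision-MAF pre-filter
.filtered_verdict <- function(maf) {
  structure(list(acmg_class = "filtered", vus_subclass = "none",
                 ppot = NULL, reportable = FALSE,
                 evidence = evidence_set(),
                 explanation = sprintf(
                   "filtered: decision MAF %.4g is not below the 3%% threshold",
                   maf)),
            class = "acmg_verdict_result")
}
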