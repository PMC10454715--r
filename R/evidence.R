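#' @title Evidence criteria, strengths and evidence sets
#' @description Core domain vocabulary shared by every stage of the rule
#'   engine: the 28 ACMG/AMP criterion codes plus the pathogenicity-potential
#'   criterion (`PPOT`), evidence strengths on both polarities, single
#'   evidence calls, per-variant evidence sets, and the strength-count tally
#'   that the combiner consumes.
#' @name evidence-model
NULL

#' The 28 ACMG/AMP criterion codes plus PPOT
#'
#' PVS1; PS1-PS4; PM1-PM6; PP1-PP5; BA1; BS1-BS4; BP1-BP7; and `PPOT`,
#' the pathogenicity-potential criterion attached to Middle VUS.
#'
#' @format Character vector of length 29.
#' @export
acmg_criteria <- c(
  "PVS1",
  paste0("PS", 1:4),
  paste0("PM", 1:6),
  paste0("PP", 1:5),
  "BA1",
  paste0("BS", 1:4),
  paste0("BP", 1:7),
  "PPOT"
)

# strength vocabularies; order encodes the within-polarity ranking
.path_strengths   <- c(Supporting = 1, Moderate = 2, Strong = 3, VeryStrong = 4)
.benign_strengths <- c(Supporting = 1, Strong = 2, StandAlone = 3)

#' Polarity of a criterion code
#'
#' `P*` codes (and `PPOT`) are pathogenic evidence, `B*` codes benign.
#'
#' @param criterion Criterion code, e.g. `"PM2"`.
#' @return `"pathogenic"` or `"benign"`.
#' @export
criterion_polarity <- function(criterion) {
  stopifnot(criterion %in% acmg_criteria)
  if (startsWith(criterion, "B")) "benign" else "pathogenic"
}

.valid_strengths <- function(polarity) {
  if (polarity == "pathogenic") names(.path_strengths) else names(.benign_strengths)
}

#' Rank of a strength within its polarity
#'
#' @param strength Strength label.
#' @param polarity `"pathogenic"` or `"benign"`.
#' @return Integer rank (higher = stronger).
#' @export
strength_rank <- function(strength, polarity = "pathogenic") {
  tab <- if (polarity == "pathogenic") .path_strengths else .benign_strengths
  stopifnot(strength %in% names(tab))
  unname(tab[strength])
}

#' One evidence call
#'
#' A single ACMG/AMP criterion (or `PPOT`) with its met status, effective
#' strength, a human-readable rationale and the provenance of the call.
#'
#' @param criterion One of [acmg_criteria].
#' @param met Logical; is the criterion met?
#' @param strength Strength label; required when `met`, must be `NULL`
#'   otherwise. Pathogenic criteria take `VeryStrong`/`Strong`/`Moderate`/
#'   `Supporting`; benign criteria take `StandAlone`/`Strong`/`Supporting`.
#' @param rationale Free-text justification.
#' @param source `"auto"` (engine-computed), `"upstream"` (accepted from the
#'   input record) or `"user"` (interactive confirmation).
#' @return An object of class `acmg_call`.
#' @examples
#' evidence_call("PM2", strength = "Moderate", rationale = "Absent from controls")
#' @export
evidence_call <- function(criterion, met = TRUE, strength = NULL,
                          rationale = "", source = "auto") {
  stopifnot(is.character(criterion), length(criterion) == 1L,
            criterion %in% acmg_criteria,
            is.logical(met), length(met) == 1L, !is.na(met),
            source %in% c("auto", "upstream", "user"))
  pol <- criterion_polarity(criterion)
  if (met) {
    if (is.null(strength)) {
      stop("a met call for ", criterion, " requires a strength", call. = FALSE)
    }
    if (!strength %in% .valid_strengths(pol)) {
      stop("strength '", strength, "' is not valid for ", pol,
           " criterion ", criterion, call. = FALSE)
    }
  } else if (!is.null(strength)) {
    stop("an unmet call carries no strength", call. = FALSE)
  }
  structure(
    list(criterion = criterion, met = met, strength = strength,
         rationale = rationale, source = source),
    class = "acmg_call"
  )
}

#' @export
print.acmg_call <- function(x, ...) {
  if (x$met) {
    cat(sprintf("%s [%s, %s] %s\n", x$criterion, x$strength, x$source,
                x$rationale))
  } else {
    cat(sprintf("%s [not met] %s\n", x$criterion, x$rationale))
  }
  invisible(x)
}

#' A per-variant evidence set
#'
#' Container for the evidence checklist of one variant. Enforces at most one
#' call per criterion, and the mutual exclusions PP3/BP4 and PP5/BP6 (the
#' computational-evidence and assertion criteria can never both be met).
#'
#' @param calls List of [evidence_call] objects (or several calls given as
#'   `...`).
#' @return An object of class `acmg_evidence` (a named list of calls).
#' @export
evidence_set <- function(calls = list()) {
  if (inherits(calls, "acmg_call")) calls <- list(calls)
  stopifnot(is.list(calls), all(vapply(calls, inherits, TRUE, "acmg_call")))
  codes <- vapply(calls, `[[`, "", "criterion")
  if (anyDuplicated(codes)) {
    stop("duplicate evidence call(s) for: ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "),
         call. = FALSE)
  }
  names(calls) <- codes
  met <- vapply(calls, `[[`, TRUE, "met")
  for (pair in list(c("PP3", "BP4"), c("PP5", "BP6"))) {
    if (all(pair %in% codes) && all(met[pair])) {
      stop(pair[1], " and ", pair[2], " cannot both be met", call. = FALSE)
    }
  }
  structure(calls, class = "acmg_evidence")
}

#' @export
print.acmg_evidence <- function(x, ...) {
  if (length(x) == 0L) {
    cat("<empty evidence set>\n")
    return(invisible(x))
  }
  for (call in x) print(call)
  invisible(x)
}

#' Construct a strength-count tally
#'
#' The canonical multiset of met evidence by effective strength: counts of
#' pathogenic VeryStrong (`pvs`), Strong (`ps`), Moderate (`pm`), Supporting
#' (`pp`) and benign StandAlone (`ba`), Strong (`bs`), Supporting (`bp`)
#' evidence. This tuple is the sole input of the combiner.
#'
#' @param pvs,ps,pm,pp,ba,bs,bp Non-negative integer counts.
#' @return A named integer vector of class `strength_counts`.
#' @examples
#' strength_counts(pm = 2)  # the "PM PM" pattern
#' @export
strength_counts <- function(pvs = 0L, ps = 0L, pm = 0L, pp = 0L,
                            ba = 0L, bs = 0L, bp = 0L) {
  x <- c(pvs = pvs, ps = ps, pm = pm, pp = pp, ba = ba, bs = bs, bp = bp)
  stopifnot(all(!is.na(x)), all(x >= 0), all(x == as.integer(x)))
  structure(as.integer(x), names = names(x), class = "strength_counts")
}

#' @export
print.strength_counts <- function(x, ...) {
  pat <- c(rep("PVS", x["pvs"]), rep("PS", x["ps"]), rep("PM", x["pm"]),
           rep("PP", x["pp"]), rep("BA", x["ba"]), rep("BS", x["bs"]),
           rep("BP", x["bp"]))
  cat("strength counts:",
      if (length(pat)) paste(pat, collapse = " ") else "<none>", "\n")
  invisible(x)
}

# map one met call to its count bucket
.call_bucket <- function(call) {
  pol <- criterion_polarity(call$criterion)
  if (pol == "pathogenic") {
    switch(call$strength,
           VeryStrong = "pvs", Strong = "ps", Moderate = "pm",
           Supporting = "pp")
  } else {
    switch(call$strength,
           StandAlone = "ba", Strong = "bs", Supporting = "bp")
  }
}

#' Tally met evidence at effective strengths
#'
#' Counts every met call in the bucket of its *effective* strength: a PVS1
#' carried at Moderate counts among the PM evidence, which is what routes a
#' graded loss-of-function call through the "PM PM" pattern of the
#' subclassification table. `PPOT` participates only when `include_ppot` is
#' `TRUE`; the ACMG verdict itself is always computed without it.
#'
#' @param evidence An [evidence_set].
#' @param include_ppot Count a met `PPOT` call (at its strength) as
#'   pathogenic evidence?
#' @return A [strength_counts] tally.
#' @export
effective_counts <- function(evidence, include_ppot = FALSE) {
  stopifnot(inherits(evidence, "acmg_evidence"))
  out <- strength_counts()
  for (call in evidence) {
    if (!call$met) next
    if (call$criterion == "PPOT" && !include_ppot) next
    b <- .call_bucket(call)
    out[b] <- out[b] + 1L
  }
  out
}
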