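# Independent brute-force transcription of the ACMG 2015 combining rules,
# written directly from the published scheme and kept separate from the
# package's implementation.
oracle_acmg <- function(pvs, ps, pm, pp, ba, bs, bp) {
  p1 <- pvs >= 1 && (ps >= 1 || pm >= 2 || (pm == 1 && pp == 1) || pp >= 2)
  p2 <- ps >= 2
  p3 <- ps == 1 && (pm >= 3 || (pm == 2 && pp >= 2) || (pm == 1 && pp >= 4))
  pathogenic <- p1 || p2 || p3
  lp <- (pvs >= 1 && pm == 1) ||
    (ps == 1 && (pm == 1 || pm == 2)) ||
    (ps == 1 && pp >= 2) ||
    pm >= 3 ||
    (pm == 2 && pp >= 2) ||
    (pm == 1 && pp >= 4)
  benign <- ba >= 1 || bs >= 2
  lb <- (bs >= 1 && bp >= 1) || bp >= 2
  path_side <- pathogenic || lp
  benign_side <- benign || lb
  if (path_side && benign_side) return("VUS")
  if (pathogenic) return("P")
  if (lp) return("LP")
  if (benign) return("B")
  if (lb) return("LB")
  "VUS"
}

# Independent transcription of the printed 36-row subclassification table:
# each pattern as the multiset of criterion strengths it is made of.
subclass_patterns <- function() {
  spec <- c(
    "PVS" = "Hot", "BP PVS" = "Hot", "PP PVS" = "Hot",
    "PS" = "Hot", "PP PS" = "Hot", "BP PP PS" = "Hot", "BS PP PS" = "Hot",
    "BP PS" = "Hot",
    "PP PM PM" = "Hot", "BP PP PM PM" = "Hot", "BS PP PM PM" = "Hot",
    "PP PP PP PM" = "Hot", "BP PP PP PP PM" = "Hot",
    "BS PP PP PP PM" = "Hot",
    "PP PP PP PP" = "Hot", "BP PP PP PP PP" = "Hot",
    "PM PM" = "Middle", "BP PM PM" = "Middle",
    "PP PM" = "Middle", "BP PP PM" = "Middle",
    "PP PP PM" = "Middle", "BP PP PP PM" = "Middle",
    "BS PVS" = "Middle", "BS PS" = "Middle",
    "PP PP PP" = "Middle", "BP PP PP PP" = "Middle",
    "PM" = "Cold", "BP PM" = "Cold",
    "PP PP" = "Cold", "BP PP PP" = "Cold", "BS PP PP" = "Cold",
    "PP" = "Cold", "BP PP" = "Cold", "BS PP" = "Cold",
    "BP" = "Cold", "BS" = "Cold")
  rows <- lapply(names(spec), function(pat) {
    toks <- strsplit(pat, " ", fixed = TRUE)[[1]]
    data.frame(pvs = sum(toks == "PVS"), ps = sum(toks == "PS"),
               pm = sum(toks == "PM"), pp = sum(toks == "PP"),
               ba = 0L, bs = sum(toks == "BS"), bp = sum(toks == "BP"),
               subclass = unname(spec[pat]), pattern = pat)
  })
  do.call(rbind, rows)
}

counts_from_row <- function(row) {
  strength_counts(pvs = row$pvs, ps = row$ps, pm = row$pm, pp = row$pp,
                  ba = row$ba, bs = row$bs, bp = row$bp)
}

# Build an evidence set realizing a given strength-count tuple, using
# distinct generic criterion codes per bucket.
evidence_for_counts <- function(counts, ppot_strength = NULL) {
  pools <- list(
    pvs = list(c("PVS1"), "VeryStrong"),
    ps = list(c("PS1", "PS2"), "Strong"),
    pm = list(c("PM1", "PM3", "PM4", "PM5"), "Moderate"),
    pp = list(c("PP1", "PP2", "PP3", "PP4", "PP5"), "Supporting"),
    ba = list(c("BA1"), "StandAlone"),
    bs = list(c("BS1", "BS2"), "Strong"),
    bp = list(c("BP1", "BP2", "BP3"), "Supporting"))
  calls <- list()
  for (bucket in names(pools)) {
    n <- counts[bucket]
    if (n > length(pools[[bucket]][[1]])) {
      stop("counts exceed helper criterion pool for ", bucket)
    }
    for (code in utils::head(pools[[bucket]][[1]], n)) {
      calls[[length(calls) + 1L]] <- evidence_call(
        code, strength = pools[[bucket]][[2]], rationale = "synthetic")
    }
  }
  if (!is.null(ppot_strength)) {
    calls[[length(calls) + 1L]] <- evidence_call(
      "PPOT", strength = ppot_strength, rationale = "synthetic")
  }
  evidence_set(calls)
}

met_strengths <- function(evidence) {
  met <- Filter(function(x) x$met, unclass(evidence))
  vapply(met, `[[`, "", "strength")
}

# random predictor scores with optional missingness, for property tests
random_scores <- function(p_missing = 0.2) {
  maybe <- function(x) if (stats::runif(1) < p_missing) NULL else x
  n_rank <- sample(0:15, 1)
  rs <- if (n_rank == 0) NULL else
    stats::setNames(stats::runif(n_rank),
                    sample(rank_score_predictors, n_rank))
  predictor_scores(
    revel = maybe(stats::runif(1)),
    cadd_phred = maybe(stats::runif(1, 0, 40)),
    rank_scores = rs,
    ada_boost = maybe(stats::runif(1)),
    rf = maybe(stats::runif(1)))
}
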