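cfg <- acmg_thresholds()

scores15 <- function(n_hi, hi = 0.9, lo = 0.4) {
  predictor_scores(rank_scores = stats::setNames(
    c(rep(hi, n_hi), rep(lo, 15 - n_hi)), rank_score_predictors))
}

test_that("count_rank_scores counts inclusively over available scores", {
  r <- count_rank_scores(scores15(14), 0.644, "ge")
  expect_equal(r, list(count = 14L, n_available = 15L))
  expect_equal(count_rank_scores(predictor_scores(), 0.644, "ge"),
               list(count = 0L, n_available = 0L))
  # boundary is inclusive per the printed ">=" / "<="
  at_cut <- predictor_scores(rank_scores = stats::setNames(
    rep(0.644, 15), rank_score_predictors))
  expect_equal(count_rank_scores(at_cut, 0.644, "ge")$count, 15L)
  expect_equal(count_rank_scores(at_cut, 0.644, "le")$count, 15L)
  # partial availability
  part <- predictor_scores(rank_scores = c(SIFT = 0.7, DANN = 0.1))
  expect_equal(count_rank_scores(part, 0.644, "ge"),
               list(count = 1L, n_available = 2L))
})

test_that("assign_pp3 follows the 2-of-3 missense rule", {
  # worked example values: all three / one / all three conditions
  hot <- predictor_scores(revel = 0.767, cadd_phred = 28.30,
                          rank_scores = scores15(14)$rank_scores)
  d <- assign_pp3("missense", hot, cfg)
  expect_equal(d$verdict, "pp3_met")
  expect_equal(d$call$strength, "Supporting")
  expect_equal(sum(d$conditions_met), 3)

  lukewarm <- predictor_scores(revel = 0.518, cadd_phred = 24.78,
                               rank_scores = scores15(11)$rank_scores)
  d2 <- assign_pp3("missense", lukewarm, cfg)
  expect_equal(d2$verdict, "neither")
  expect_equal(sum(d2$conditions_met), 1)  # only the rank majority

  d3 <- assign_pp3("missense",
                   predictor_scores(revel = 0.723, cadd_phred = 29.1,
                                    rank_scores = scores15(13)$rank_scores),
                   cfg)
  expect_equal(d3$verdict, "pp3_met")

  # exactly two of three conditions also fires
  two <- predictor_scores(revel = 0.70, cadd_phred = 10,
                          rank_scores = scores15(9)$rank_scores)
  expect_equal(assign_pp3("missense", two, cfg)$verdict, "pp3_met")
})

test_that("splice branches use the AdaBoost/RF conjunction", {
  d <- assign_pp3("intronic_within_5",
                  predictor_scores(ada_boost = 0.9, rf = 0.6), cfg)
  expect_equal(d$verdict, "pp3_met")
  expect_equal(d$branch, "splice_scores")
  # one score below cutoff fails the conjunction
  expect_equal(assign_pp3("splice_region",
                          predictor_scores(ada_boost = 0.9, rf = 0.2),
                          cfg)$verdict, "neither")
  # benign side requires both at or below
  expect_equal(assign_bp4("synonymous_splice",
                          predictor_scores(ada_boost = 0.1, rf = 0.2),
                          cfg)$verdict, "bp4_met")
  # LoF consequences are out of scope for PP3/BP4
  expect_equal(assign_pp3("frameshift", predictor_scores(), cfg)$verdict,
               "not_applicable")
})

test_that("missense_splice falls back to splice scores only when fewer than two missense conditions are evaluable", {
  sc <- predictor_scores(revel = 0.9, ada_boost = 0.9, rf = 0.9)
  # one evaluable missense condition -> fallback to splice branch
  d <- assign_pp3("missense_splice", sc, cfg)
  expect_equal(d$branch, "missense_fallback_splice")
  expect_equal(d$verdict, "pp3_met")
  # two evaluable missense conditions -> stays on the missense branch
  sc2 <- predictor_scores(revel = 0.9, cadd_phred = 30,
                          ada_boost = 0.1, rf = 0.1)
  d2 <- assign_pp3("missense_splice", sc2, cfg)
  expect_equal(d2$branch, "missense")
  expect_equal(d2$verdict, "pp3_met")
})

test_that("exact splice-cutoff equality satisfies both rules and assigns neither", {
  sc <- predictor_scores(ada_boost = cfg$ada_cutoff, rf = cfg$rf_cutoff)
  p <- assign_pp3("splice_region", sc, cfg)
  b <- assign_bp4("splice_region", sc, cfg)
  expect_equal(p$verdict, "neither")
  expect_equal(b$verdict, "neither")
  expect_match(p$rationale, "conflict")
  expect_match(b$rationale, "conflict")
})

test_that("assign_bp4 mirrors with benign cutoffs", {
  d <- assign_bp4("missense",
                  predictor_scores(revel = 0.518, cadd_phred = 24.78,
                                   rank_scores = scores15(11)$rank_scores),
                  cfg)
  expect_equal(d$verdict, "neither")
  expect_equal(sum(d$conditions_met), 0)
  cold <- predictor_scores(revel = 0.05, cadd_phred = 3.0,
                           rank_scores = stats::setNames(
                             rep(0.05, 15), rank_score_predictors))
  d2 <- assign_bp4("missense", cold, cfg)
  expect_equal(d2$verdict, "bp4_met")
  expect_equal(d2$call$strength, "Supporting")
  expect_equal(sum(d2$conditions_met), 3)
})

test_that("PP3 and BP4 are mutually exclusive and monotone (seeded grid)", {
  set.seed(4242)
  classes <- c("missense", "missense_splice", "synonymous_splice",
               "splice_region", "intronic_within_5")
  for (i in 1:400) {
    sc <- random_scores()
    cls <- sample(classes, 1)
    p <- assign_pp3(cls, sc, cfg)
    b <- assign_bp4(cls, sc, cfg)
    expect_false(p$verdict == "pp3_met" && b$verdict == "bp4_met")
    if (p$verdict == "pp3_met") {
      # raising every present score never un-meets PP3
      up <- predictor_scores(
        revel = if (is.null(sc$revel)) NULL else min(1, sc$revel + 0.2),
        cadd_phred = if (is.null(sc$cadd_phred)) NULL else
          sc$cadd_phred + 5,
        rank_scores = if (is.null(sc$rank_scores)) NULL else
          pmin(1, sc$rank_scores + 0.2),
        ada_boost = if (is.null(sc$ada_boost)) NULL else
          min(1, sc$ada_boost + 0.2),
        rf = if (is.null(sc$rf)) NULL else min(1, sc$rf + 0.2))
      expect_equal(assign_pp3(cls, up, cfg)$verdict, "pp3_met")
    }
    if (b$verdict == "bp4_met") {
      down <- predictor_scores(
        revel = if (is.null(sc$revel)) NULL else max(0, sc$revel - 0.2),
        cadd_phred = if (is.null(sc$cadd_phred)) NULL else
          max(0, sc$cadd_phred - 5),
        rank_scores = if (is.null(sc$rank_scores)) NULL else
          pmax(0, sc$rank_scores - 0.2),
        ada_boost = if (is.null(sc$ada_boost)) NULL else
          max(0, sc$ada_boost - 0.2),
        rf = if (is.null(sc$rf)) NULL else max(0, sc$rf - 0.2))
      expect_equal(assign_bp4(cls, down, cfg)$verdict, "bp4_met")
    }
  }
})

test_that("modify_pm2 re-assigns Moderate whenever triggered", {
  expect_equal(modify_pm2(TRUE, "Supporting")$strength, "Moderate")
  expect_equal(modify_pm2(TRUE, "Strong")$strength, "Moderate")
  expect_equal(modify_pm2(TRUE, "Moderate")$strength, "Moderate")
  expect_false(modify_pm2(FALSE)$met)
})

test_that("modify_bp6 re-assigns Supporting from VeryStrong/Moderate and keeps Strong/Supporting", {
  expect_equal(modify_bp6(TRUE, "VeryStrong")$strength, "Supporting")
  expect_equal(modify_bp6(TRUE, "Moderate")$strength, "Supporting")
  expect_equal(modify_bp6(TRUE, "StandAlone")$strength, "Supporting")
  expect_equal(modify_bp6(TRUE, "Strong")$strength, "Strong")
  expect_equal(modify_bp6(TRUE, "Supporting")$strength, "Supporting")
  expect_false(modify_bp6(FALSE)$met)
})

test_that("assign_bp1 applies the benign-fraction and gated missense-Z sub-rules", {
  ush <- gene_info("USH2A", "AR", benign_nonvus_missense = 196L,
                   total_nonvus_missense = 529L)
  call <- assign_bp1(ush, "missense", cfg)
  expect_true(call$met)
  expect_equal(call$strength, "Supporting")
  expect_equal(attr(call, "percent"), 37.1)
  expect_match(call$rationale, "37.1%")

  all_benign <- gene_info("CELSR1", "AD", benign_nonvus_missense = 33L,
                          total_nonvus_missense = 33L)
  call2 <- assign_bp1(all_benign, "missense", cfg)
  expect_true(call2$met)
  expect_equal(attr(call2, "percent"), 100.0)

  none <- gene_info("G1", "AD", benign_nonvus_missense = 0L,
                    total_nonvus_missense = 529L)
  expect_false(assign_bp1(none, "missense", cfg)$met)

  # missense-Z sub-rule fires only when enabled for the gene
  z_off <- gene_info("SERPINA6", "AR", missense_z = -0.662)
  expect_false(assign_bp1(z_off, "missense", cfg)$met)
  z_on <- gene_info("SERPINA6", "AR", missense_z = -0.662,
                    bp1_z_rule = TRUE)
  expect_true(assign_bp1(z_on, "missense", cfg)$met)

  # non-missense consequences never receive BP1
  expect_false(assign_bp1(all_benign, "frameshift", cfg)$met)
  # empty denominator is not evaluable
  empty <- gene_info("G2", "AD", benign_nonvus_missense = 0L,
                     total_nonvus_missense = 0L)
  expect_false(assign_bp1(empty, "missense", cfg)$met)
})

test_that("decision_maf integrates sources by maximum and is monotone", {
  expect_equal(decision_maf(population_data(c(gnomAD = 0.05)), cfg),
               list(maf = 0.05, passes = FALSE))
  expect_equal(decision_maf(population_data(), cfg),
               list(maf = 0, passes = TRUE))
  r <- decision_maf(population_data(c(dbNSFP = 0.001, VEP = 0.002,
                                      gnomAD = 0.0)), cfg)
  expect_equal(r$maf, 0.002)
  expect_true(r$passes)
  # boundary: exactly 3% does not pass ("below 3%")
  expect_false(decision_maf(population_data(c(gnomAD = 0.03)), cfg)$passes)
  set.seed(5)
  for (i in 1:50) {
    f <- stats::runif(3, 0, 0.05)
    base <- decision_maf(population_data(
      c(dbNSFP = f[1], VEP = f[2], gnomAD = f[3])), cfg)$maf
    bumped <- decision_maf(population_data(
      c(dbNSFP = f[1] + 0.01, VEP = f[2], gnomAD = f[3])), cfg)$maf
    expect_gte(bumped, base)
  }
})

test_that("assign_criteria merges engine and upstream calls with overrides", {
  cases <- builtin_cases()
  ev <- assign_criteria(cases$SERPINA6$annotation, cfg)
  expect_setequal(names(ev), c("BP1", "PM2", "PP5"))
  expect_equal(met_strengths(ev),
               c(PM2 = "Moderate", BP1 = "Supporting", PP5 = "Supporting")[names(ev)])
  expect_true(any(grepl("BP4 upstream Strong overridden",
                        attr(ev, "overrides"))))

  ev_tyr <- assign_criteria(cases$TYR$annotation, cfg)
  expect_setequal(names(ev_tyr), c("PVS1", "PM2"))
  expect_equal(ev_tyr$PVS1$strength, "Moderate")

  # bare record absent from all sources: PM2 only
  bare <- variant_annotation("S1", gene_info("G1", "AD"), "NM_1.1",
                             "c.1A>G", consequence = "missense")
  ev_bare <- assign_criteria(bare, cfg)
  expect_equal(names(ev_bare), "PM2")
  expect_equal(ev_bare$PM2$strength, "Moderate")

  # PP5 above Supporting is capped
  pp5 <- variant_annotation(
    "S1", gene_info("G1", "AD"), "NM_1.1", "c.1A>G",
    consequence = "missense",
    upstream_calls = list(evidence_call("PP5", strength = "Strong",
                                        source = "upstream")))
  expect_equal(assign_criteria(pp5, cfg)$PP5$strength, "Supporting")

  # duplicate upstream calls are rejected at record construction
  expect_error(variant_annotation(
    "S1", gene_info("G1", "AD"), "NM_1.1", "c.1A>G",
    consequence = "missense",
    upstream_calls = list(evidence_call("PM1", strength = "Moderate"),
                          evidence_call("PM1", strength = "Supporting"))),
    "duplicate")
})
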