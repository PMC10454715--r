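middle_variant <- function(sample_id = "S1", gene, zygosity = "het",
                           hgvs_c = "c.100A>G") {
  # PM2 auto-triggers (absent from all sources), giving the Cold "PM" row;
  # add an upstream PP to land on the Middle "PP PM" row
  variant_annotation(
    sample_id = sample_id, gene = gene, transcript = "NM_1.1",
    hgvs_c = hgvs_c, consequence = "missense", zygosity = zygosity,
    population = population_data(coverage_ok = TRUE),
    upstream_calls = list(evidence_call("PP2", strength = "Supporting",
                                        source = "upstream")))
}

classified <- function(variant) {
  classify_variant(assign_criteria(variant))
}

ctx_of <- function(...) {
  variants <- list(...)
  sample_context(variants[[1]]$sample_id, lapply(variants, function(v) {
    list(annotation = v, verdict = classified(v))
  }))
}

test_that("ppot_eligible implements the four conditions in order", {
  ar <- gene_info("GAR", "AR")
  ad <- gene_info("GAD", "AD")
  xl <- gene_info("GXL", "XL")

  # condition 3: heterozygous Middle VUS in a dominant gene
  v_ad <- middle_variant(gene = ad)
  e <- ppot_eligible(v_ad, classified(v_ad), ctx_of(v_ad))
  expect_true(e$eligible)
  expect_equal(e$condition, 3L)
  expect_equal(e$rationale, "possible de novo variant")

  # condition 2: homozygous in a recessive gene
  v_hom <- middle_variant(gene = ar, zygosity = "hom")
  e2 <- ppot_eligible(v_hom, classified(v_hom), ctx_of(v_hom))
  expect_equal(e2$condition, 2L)

  # condition 4: hemizygous in an X-linked gene
  v_hemi <- middle_variant(gene = xl, zygosity = "hemi")
  e4 <- ppot_eligible(v_hemi, classified(v_hemi), ctx_of(v_hemi))
  expect_equal(e4$condition, 4L)

  # het in a recessive gene with no partner: not eligible
  v_ar <- middle_variant(gene = ar)
  expect_false(ppot_eligible(v_ar, classified(v_ar), ctx_of(v_ar))$eligible)

  # condition 1 beats condition 2 when both hold (lowest number wins)
  partner <- variant_annotation(
    "S1", ar, "NM_1.1", "c.200del", consequence = "frameshift",
    zygosity = "het", population = population_data(coverage_ok = TRUE),
    lof = lof_annotation("frameshift", nmd_predicted = TRUE,
                         exon_in_relevant_transcript = TRUE,
                         lof_frequent_in_population = FALSE,
                         fraction_protein_removed = 0.9),
    upstream_calls = list(evidence_call("PS4", strength = "Strong",
                                        source = "upstream")))
  ar_lof <- gene_info("GAR", "AR", lof_mechanism = TRUE)
  partner$gene <- ar_lof
  v_hom2 <- middle_variant(gene = ar_lof, zygosity = "hom")
  e1 <- ppot_eligible(v_hom2, classified(v_hom2), ctx_of(v_hom2, partner))
  expect_equal(e1$condition, 1L)
  expect_match(e1$rationale, "in-trans configuration")

  # Cold and Hot VUS are never eligible
  cold <- variant_annotation("S1", ar, "NM_1.1", "c.1A>G",
                             consequence = "missense",
                             population = population_data(coverage_ok = TRUE))
  cv <- classified(cold)  # PM2 only: the Cold "PM" row
  expect_equal(cv$vus_subclass, "Cold")
  expect_false(ppot_eligible(cold, cv, ctx_of(cold))$eligible)

  # unknown inheritance warns and declines
  noinh <- middle_variant(gene = gene_info("GX"))
  expect_warning(
    e5 <- ppot_eligible(noinh, classified(noinh), ctx_of(noinh)),
    "inheritance")
  expect_false(e5$eligible)
})

test_that("ppot_strength downgrades exactly the printed combinations", {
  expect_equal(ppot_strength(strength_counts(pm = 1, pp = 2, bp = 1)),
               "Supporting")
  expect_equal(ppot_strength(strength_counts(pm = 1, pp = 1, bp = 1)),
               "Moderate")
  expect_equal(ppot_strength(strength_counts(pm = 2)), "Supporting")
  expect_equal(ppot_strength(strength_counts(pm = 1, pp = 3)), "Moderate")
  # pure function of the pathogenic counts
  for (bs in 0:2) for (bp in 0:2) {
    expect_equal(ppot_strength(strength_counts(pm = 2, bs = bs, bp = bp)),
                 "Supporting")
    expect_equal(ppot_strength(strength_counts(pm = 1, pp = 1, bs = bs,
                                               bp = bp)), "Moderate")
  }
})

test_that("apply_ppot promotes eligible Middle VUS to reportable Hot only", {
  ad <- gene_info("GAD", "AD")
  v <- middle_variant(gene = ad)
  ctx <- apply_ppot(ctx_of(v))
  verdict <- ctx$variants[[1]]$verdict
  expect_equal(verdict$acmg_class, "VUS")
  expect_equal(verdict$vus_subclass, "Hot")
  expect_true(verdict$reportable)
  expect_equal(verdict$ppot$strength, "Moderate")
  expect_true(any(grepl("Hot \\(potential\\)", verdict$explanation)))

  # two Middle VUS in one recessive gene each qualify the other
  ar <- gene_info("GAR", "AR")
  a <- middle_variant(gene = ar, hgvs_c = "c.100A>G")
  b <- middle_variant(gene = ar, hgvs_c = "c.200A>G")
  ctx2 <- apply_ppot(ctx_of(a, b))
  for (entry in ctx2$variants) {
    expect_equal(entry$verdict$vus_subclass, "Hot")
    expect_equal(entry$verdict$ppot$strength, "Moderate")
  }

  # a lone Cold VUS is untouched
  cold <- variant_annotation("S1", ar, "NM_1.1", "c.1A>G",
                             consequence = "missense",
                             population = population_data(coverage_ok = TRUE))
  ctx3 <- apply_ppot(ctx_of(cold))
  expect_equal(ctx3$variants[[1]]$verdict$vus_subclass, "Cold")
  expect_null(ctx3$variants[[1]]$verdict$ppot)
})

test_that("apply_ppot never changes the ACMG class and met PPOT implies Hot", {
  variants <- generate_annotations(seed = 31, n = 60, profile = "mixed")
  # group all records into a handful of samples to exercise condition 1
  for (i in seq_along(variants)) {
    variants[[i]]$sample_id <- paste0("S", (i %% 5) + 1)
  }
  contexts <- classify_annotations(variants)
  for (ctx in contexts) {
    # re-derive the P_POT-free verdicts and compare classes
    for (entry in ctx$variants) {
      if (entry$verdict$acmg_class == "filtered") next
      base <- classified(entry$annotation)
      expect_equal(entry$verdict$acmg_class, base$acmg_class)
      if (!is.null(entry$verdict$ppot)) {
        expect_equal(entry$verdict$vus_subclass, "Hot")
        expect_true(entry$verdict$reportable)
      }
    }
  }
})

test_that("every Middle row of the table promotes to Hot under P_POT", {
  tab <- vus_table()
  for (i in which(tab$subclass == "Middle")) {
    base <- counts_from_row(tab[i, ])
    ev <- evidence_for_counts(base, ppot_strength = ppot_strength(base))
    v <- classify_variant(ev)
    expect_equal(v$acmg_class, "VUS")
    expect_equal(v$vus_subclass, "Hot")
    expect_true(v$reportable)
  }
})

test_that("resolve_segregation substitutes PPOT by the observed criterion", {
  ad <- gene_info("GAD", "AD")
  v <- middle_variant(gene = ad)
  ctx <- apply_ppot(ctx_of(v))
  entry <- ctx$variants[[1]]

  # confirmed de novo with parentage: PS2 Strong
  lp <- resolve_segregation(entry$annotation, entry$verdict,
                            segregation_result("de_novo_confirmed",
                                               parentage_confirmed = TRUE))
  expect_equal(lp$acmg_class, "LP")
  expect_null(lp$evidence[["PPOT"]])
  expect_equal(lp$evidence$PS2$strength, "Strong")

  # without parentage confirmation: PM6 Moderate
  pm6 <- resolve_segregation(entry$annotation, entry$verdict,
                             segregation_result("de_novo_confirmed"))
  expect_equal(pm6$evidence$PM6$strength, "Moderate")

  # de novo excluded: BS4 replaces PPOT, verdict recomputed
  bs4 <- resolve_segregation(entry$annotation, entry$verdict,
                             segregation_result("de_novo_excluded"))
  expect_null(bs4$evidence[["PPOT"]])
  expect_equal(bs4$evidence$BS4$strength, "Strong")

  # in-cis phase: BP2; unaffected carrier adds BS2
  bp2 <- resolve_segregation(
    entry$annotation, entry$verdict,
    segregation_result("in_cis_or_refuted", unaffected_carrier = TRUE))
  expect_equal(bp2$evidence$BP2$strength, "Supporting")
  expect_equal(bp2$evidence$BS2$strength, "Strong")

  # cosegregation: PP1 Supporting
  pp1 <- resolve_segregation(entry$annotation, entry$verdict,
                             segregation_result("cosegregation_confirmed",
                                                meioses = 4L))
  expect_equal(pp1$evidence$PP1$strength, "Supporting")

  # contract: verdict must carry a met PPOT
  expect_error(resolve_segregation(v, classified(v),
                                   segregation_result("de_novo_excluded")),
               "met PPOT")
})
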