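one_call_profile <- function(genotype, rsid = "rs100001", id = "M1") {
  calls <- if (is.null(genotype)) {
    data.frame(rsid = character(), chrom = character(), position = integer(),
               genotype = character())
  } else {
    data.frame(rsid = rsid, chrom = "1", position = 1000L,
               genotype = genotype, stringsAsFactors = FALSE)
  }
  genotype_profile(id, calls)
}

test_that("direct, mismatching and strand-flipped calls resolve correctly", {
  v_gt <- variant_row(effect_allele = "G", other_allele = "T")
  m <- match_variant(one_call_profile("GG"), v_gt)
  expect_equal(m$dosage, 2L)
  expect_false(m$strand_flipped)
  expect_equal(m$excluded_reason, "none")

  m <- match_variant(one_call_profile("GT"), v_gt)
  expect_equal(m$dosage, 1L)
  m <- match_variant(one_call_profile("TT"), v_gt)
  expect_equal(m$dosage, 0L)

  # irreconcilable alleles are a typed exclusion, not an error
  v_ga <- variant_row(effect_allele = "G", other_allele = "A")
  m <- match_variant(one_call_profile("AC"), v_ga)
  expect_true(is.na(m$dosage))
  expect_equal(m$excluded_reason, "allele_mismatch")
  # for a G/T site an A/C call sits fully on the complement strand
  m <- match_variant(one_call_profile("AC"), v_gt)
  expect_equal(m$dosage, 1L)  # complement of the G effect allele is C
  expect_true(m$strand_flipped)

  # CC against a G/A panel site matches on the complement strand
  m <- match_variant(one_call_profile("CC"), v_ga)
  expect_equal(m$dosage, 2L)
  expect_true(m$strand_flipped)
  # one complement copy
  m <- match_variant(one_call_profile("CT"), v_ga)
  expect_equal(m$dosage, 1L)
  expect_true(m$strand_flipped)
})

test_that("palindromic sites are excluded unless strand is trusted", {
  v_at <- variant_row(effect_allele = "A", other_allele = "T")
  m <- match_variant(one_call_profile("AA"), v_at)
  expect_true(m$ambiguous)
  expect_equal(m$excluded_reason, "ambiguous_site")
  expect_true(is.na(m$dosage))
  m <- match_variant(one_call_profile("AA"), v_at, trust_palindromic = TRUE)
  expect_equal(m$dosage, 2L)
  expect_equal(m$excluded_reason, "none")
  # C/G site likewise
  v_cg <- variant_row(effect_allele = "C", other_allele = "G")
  expect_equal(match_variant(one_call_profile("CG"), v_cg)$excluded_reason,
               "ambiguous_site")
})

test_that("missing, non-SNP and hemizygous calls are typed", {
  v <- variant_row(effect_allele = "G", other_allele = "T")
  expect_equal(match_variant(one_call_profile("--"), v)$excluded_reason,
               "missing_call")
  expect_equal(match_variant(one_call_profile(NULL), v)$excluded_reason,
               "missing_call")
  expect_equal(match_variant(one_call_profile("DD"), v)$excluded_reason,
               "non_snp")
  expect_equal(match_variant(one_call_profile("II"), v)$excluded_reason,
               "non_snp")
  # hemizygous: dosage counts the single allele once
  expect_equal(match_variant(one_call_profile("G"), v)$dosage, 1L)
  expect_equal(match_variant(one_call_profile("T"), v)$dosage, 0L)
})

test_that("dosage of the effect allele and of the other allele sum to 2", {
  set.seed(71)
  pairs <- list(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"))
  for (i in 1:20) {
    pr <- pairs[[sample(4, 1)]]
    v_eff <- variant_row(effect_allele = pr[1], other_allele = pr[2])
    v_oth <- variant_row(effect_allele = pr[2], other_allele = pr[1])
    d <- sample(0:2, 1)
    g <- paste(sort(c(rep(pr[1], d), rep(pr[2], 2 - d))), collapse = "")
    prof <- one_call_profile(g)
    expect_equal(match_variant(prof, v_eff)$dosage +
                   match_variant(prof, v_oth)$dosage, 2L)
  }
})

test_that("additive scores follow the hand-computed weighted sum", {
  v <- variant_block(3, weight = c(0.1, 0.2, 0.3), category = "ACL_rupture")
  panel <- injury_panel(v)
  prof <- profile_from_dosages(panel, c(2, 1, 0))
  s <- additive_score(prof, panel, "ACL_rupture")
  expect_s3_class(s, "category_score")
  expect_equal(s$raw_score, 0.1 * 2 + 0.2 * 1 + 0.3 * 0)
  expect_equal(s$risk_allele_count, 3L)
  expect_equal(s$coverage, 1)
  expect_false(s$rescaled)
})

test_that("heterozygosity at all seven osteoarthritis loci counts 7 risk alleles", {
  panel <- fixture_panel()
  prof <- profile_from_dosages(panel, 1)
  s <- additive_score(prof, panel, "osteoarthritis")
  expect_equal(s$n_panel, 7L)
  expect_equal(s$risk_allele_count, 7L)
})

test_that("empty and absent categories behave as specified", {
  panel <- fixture_panel()
  empty <- genotype_profile("E", data.frame(rsid = character(),
                                            chrom = character(),
                                            position = integer(),
                                            genotype = character()),
                            build = panel$build)
  s <- additive_score(empty, panel, "osteoarthritis")
  expect_equal(s$raw_score, 0)
  expect_equal(s$coverage, 0)
  expect_equal(s$n_matched, 0L)
  expect_error(additive_score(empty, panel, "sickle_cell_trait"),
               "no additive panel loci")
})

test_that("weight rescaling compensates for missing loci", {
  v <- variant_block(2, weight = c(0.1, 0.3), category = "ACL_rupture")
  panel <- injury_panel(v)
  # call only the first locus, homozygous for the effect allele
  prof <- genotype_profile("R1", data.frame(
    rsid = v$rsid[1], chrom = v$chrom[1], position = v$position[1],
    genotype = paste0(v$effect_allele[1], v$effect_allele[1]),
    stringsAsFactors = FALSE))
  plain <- additive_score(prof, panel, "ACL_rupture")
  expect_equal(plain$raw_score, 0.2)
  scaled <- additive_score(prof, panel, "ACL_rupture", rescale = TRUE)
  expect_true(scaled$rescaled)
  expect_equal(scaled$raw_score, 0.2 * (0.4 / 0.1))
  expect_equal(scaled$coverage, 0.5)
})

test_that("additive scores are invariant under strand complementation", {
  panel <- fixture_panel()
  for (d in list(0, 1, 2, c(0, 1, 2))) {
    fwd <- profile_from_dosages(panel, d)
    rev <- profile_from_dosages(panel, d, complement = TRUE)
    for (cat in c("ACL_rupture", "bone_mineral_density")) {
      sf <- additive_score(fwd, panel, cat)
      sr <- additive_score(rev, panel, cat)
      expect_equal(sr$raw_score, sf$raw_score)
      expect_equal(sr$risk_allele_count, sf$risk_allele_count)
    }
  }
})

test_that("zero-weight loci never change the score", {
  v <- variant_block(4, weight = c(0.2, 0, 0.5, 0), category = "ACL_rupture")
  panel_full <- injury_panel(v)
  panel_trim <- injury_panel(v[v$weight != 0, , drop = FALSE])
  prof <- profile_from_dosages(panel_full, c(2, 2, 1, 1))
  expect_equal(additive_score(prof, panel_full, "ACL_rupture")$raw_score,
               additive_score(prof, panel_trim, "ACL_rupture")$raw_score)
})

test_that("risk-allele count is bounded by twice the matched loci", {
  panel <- fixture_panel()
  set.seed(5)
  prof <- profile_from_dosages(panel, sample(0:2, 124, replace = TRUE))
  for (cat in setdiff(unique(panel$variants$category), "sickle_cell_trait")) {
    s <- additive_score(prof, panel, cat)
    expect_lte(s$risk_allele_count, 2 * s$n_matched)
  }
})

test_that("the Mendelian sickle-cell-trait call follows the rs334 dosage", {
  panel <- fixture_panel()
  v334 <- panel$variants[panel$variants$rsid == "rs334", ]
  call_for <- function(genotype) {
    prof <- genotype_profile("S", data.frame(
      rsid = "rs334", chrom = "11", position = 5248232L,
      genotype = genotype, stringsAsFactors = FALSE))
    call_sickle_cell_trait(prof, v334)
  }
  expect_equal(call_for("AA"), "negative")
  expect_equal(call_for("AT"), "trait_carrier")
  expect_equal(call_for("TT"), "homozygous_variant")
  expect_equal(call_for("--"), "no_call")
  no334 <- genotype_profile("S", data.frame(rsid = "rs1", chrom = "1",
                                            position = 1L, genotype = "AA"))
  expect_equal(call_sickle_cell_trait(no334, v334), "no_call")
  # usage error on a non-Mendelian variant
  expect_error(call_sickle_cell_trait(no334, variant_row()), "mendelian")
})
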