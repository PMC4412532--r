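## Generates the bundled fixture panel (inst/extdata/injury_panel.tsv).
## All rsIDs, positions, weights and allele frequencies except those of
## rs1800012 and rs334 are synthetic, seeded placeholders with realistic
## magnitudes; only the category structure and those two variants carry
## published semantics. Run from the package root:
##   Rscript data-raw/make_panel.R

set.seed(20150428)

## effect/other pairs excluding palindromic (A/T, C/G) combinations
allele_pairs <- list(c("A","C"), c("A","G"), c("C","A"), c("C","T"),
                     c("G","A"), c("G","T"), c("T","C"), c("T","G"))

used_rsids <- c("rs1800012", "rs334")
synth_rsid <- function(n) {
  out <- character(0)
  while (length(out) < n) {
    cand <- paste0("rs", sample(1000000:9999999, n - length(out)))
    cand <- setdiff(unique(cand), c(used_rsids, out))
    out <- c(out, cand)
  }
  used_rsids <<- c(used_rsids, out)
  out
}

mk <- function(n, category, subcategory, or, weight, freq, in_combined,
               prev_used, evidence, study, source) {
  pair_idx <- sample(length(allele_pairs), n, replace = TRUE)
  eff <- vapply(allele_pairs[pair_idx], `[`, "", 1)
  oth <- vapply(allele_pairs[pair_idx], `[`, "", 2)
  data.frame(
    rsid = synth_rsid(n),
    chrom = as.character(sample(1:22, n, replace = TRUE)),
    position = sample(1e6:2e8, n),
    effect_allele = eff, other_allele = oth,
    weight = weight, odds_ratio = or, effect_model = "additive",
    category = category, subcategory = subcategory,
    allele_freq = freq, in_combined_score = in_combined,
    previously_used = prev_used, evidence_level = evidence,
    study_type = study, source = source, stringsAsFactors = FALSE)
}

or_block <- function(n, lo, hi) round(runif(n, lo, hi), 2)
freq_block <- function(n, lo = 0.1, hi = 0.9) round(runif(n, lo, hi), 3)

## ACL rupture: 4 candidate-gene SNPs, large ORs (published range 2.4-50)
or_acl <- c(2.4, or_block(2, 2.5, 8), 12.6)
acl <- mk(4, "ACL_rupture", "", or_acl, round(log(or_acl), 4),
          freq_block(4, 0.1, 0.5), FALSE, TRUE, "weak", "candidate_gene",
          c("col1a1_acl", "col5a1_acl", "col12a1_acl", "mmp12_acl"))

## Achilles tendon: 6 candidate-gene SNPs; rs1800012 (COL1A1 Sp1) OR 11,
## G risk allele
or_ach <- or_block(5, 2.1, 8)
ach <- mk(5, "achilles_tendon", "", or_ach, round(log(or_ach), 4),
          freq_block(5, 0.15, 0.6), FALSE, TRUE, "weak", "candidate_gene",
          c("mmp3_ach", "col5a1_ach", "casp8_ach", "gdf5_ach", "mmp3b_ach"))
rs1800012 <- data.frame(
  rsid = "rs1800012", chrom = "17", position = 48276297,
  effect_allele = "G", other_allele = "T", weight = round(log(11), 4),
  odds_ratio = 11, effect_model = "additive", category = "achilles_tendon",
  subcategory = "", allele_freq = 0.81, in_combined_score = FALSE,
  previously_used = TRUE, evidence_level = "weak",
  study_type = "candidate_gene", source = "col1a1_sp1",
  stringsAsFactors = FALSE)

## Bone mineral density: 67 GWAS SNPs. 64 from the 2012 BMD meta-analysis
## (63 of which form the combined genetic score) + 3 from later studies.
bmd_meta <- mk(64, "bone_mineral_density", "", NA_real_,
               round(runif(64, 0.02, 0.12), 4), freq_block(64),
               c(rep(TRUE, 63), FALSE), FALSE, "strong", "GWAS",
               "estrada_2012")
bmd_extra <- mk(3, "bone_mineral_density", "", NA_real_,
                round(runif(3, 0.02, 0.12), 4), freq_block(3), FALSE, FALSE,
                "strong", "GWAS", c("bmd_2013a", "bmd_2013b", "bmd_2014"))

## Osteoarthritis: 7 GWAS SNPs, small ORs (published range 1.1-1.2)
or_oa <- or_block(7, 1.1, 1.2)
oa <- mk(7, "osteoarthritis", "", or_oa, round(log(or_oa), 4),
         freq_block(7, 0.2, 0.7), FALSE, FALSE, "strong", "GWAS", "oa_gwas")

## Vitamin/mineral deficiencies: 39 unique SNPs; label counts per
## subcategory sum to 41 because two folate-pathway variants are
## dual-labelled b_vitamins + homocysteine.
vit_spec <- list(
  list(n = 8, sub = "iron", ev = "moderate"),
  list(n = 3, sub = "vitamin_E", ev = "moderate"),
  list(n = 6, sub = "vitamin_D", ev = "moderate"),
  list(n = 2, sub = "calcium", ev = "strong"),
  list(n = 4, sub = "magnesium", ev = "moderate"),
  list(n = 5, sub = "b_vitamins", ev = "moderate"),
  list(n = 2, sub = "b_vitamins;homocysteine", ev = "moderate"),
  list(n = 6, sub = "homocysteine", ev = "moderate"),
  list(n = 3, sub = "phytosterols", ev = "moderate"))
vit <- do.call(rbind, lapply(vit_spec, function(s) {
  mk(s$n, "vitamin_mineral", s$sub, NA_real_,
     round(runif(s$n, 0.03, 0.25), 4), freq_block(s$n), FALSE, FALSE,
     s$ev, "GWAS", paste0(sub(";.*", "", s$sub), "_gwas"))
}))

## Sickle cell trait: rs334, Mendelian; effect allele is the sickle (HbS)
## allele as reported on the forward strand (an A/T site).
rs334 <- data.frame(
  rsid = "rs334", chrom = "11", position = 5248232,
  effect_allele = "T", other_allele = "A", weight = 0,
  odds_ratio = NA_real_, effect_model = "mendelian",
  category = "sickle_cell_trait", subcategory = "", allele_freq = 0.01,
  in_combined_score = FALSE, previously_used = TRUE,
  evidence_level = "strong", study_type = "candidate_gene",
  source = "hbb_sct", stringsAsFactors = FALSE)

panel_df <- rbind(acl, rs1800012, ach, bmd_meta, bmd_extra, oa, vit, rs334)

stopifnot(nrow(panel_df) == 124,
          sum(panel_df$in_combined_score) == 63,
          sum(!panel_df$previously_used) == 113,
          sum(panel_df$category == "bone_mineral_density") == 67,
          sum(panel_df$category == "vitamin_mineral") == 39)

devtools_root <- "."
library(injuryrisk)
panel <- injury_panel(panel_df, build = "GRCh37")
out <- file.path(devtools_root, "inst", "extdata", "injury_panel.tsv")
dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
write_panel(panel, out)

## prepend documentation comments after the build line
lines <- readLines(out)
doc <- c(
  "# injuryrisk fixture panel: 124 injury-associated SNPs across six categories.",
  "# SYNTHETIC FIXTURE: rsIDs, positions, weights and allele frequencies are",
  "# seeded placeholders except rs1800012 (COL1A1, Achilles, OR 11, G risk",
  "# allele) and rs334 (HBB, sickle cell trait, HbS = T on the forward strand).",
  "# Category counts follow the published review table: ACL 4, Achilles 6,",
  "# BMD 67, osteoarthritis 7, vitamin/mineral 39, SCT 1 (total 124).",
  "# Note: the source text reports 66 BMD SNPs in prose but 67 in its summary",
  "# table; this fixture carries 67 so the total equals the printed 124.",
  "# The 63 rows flagged in_combined_score form the combined BMD genetic score.",
  "# vitamin/mineral holds 39 unique SNPs; two folate-pathway rows are",
  "# dual-labelled 'b_vitamins;homocysteine', so per-label counts sum to 41.")
writeLines(c(lines[1], doc, lines[-1]), out)
cat("wrote", out, ":", nrow(panel_df), "variants\n")
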