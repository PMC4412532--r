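# Fixtures are built in code: small hand-rolled panels/profiles plus the
# bundled 124-SNP fixture panel.

fixture_panel_path <- function() {
  system.file("extdata", "injury_panel.tsv", package = "injuryrisk")
}

fixture_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_panel(fixture_panel_path())
    cache
  }
})

# One schema-complete variant row with overridable fields.
variant_row <- function(rsid = "rs100001", chrom = "1", position = 1000L,
                        effect_allele = "G", other_allele = "T",
                        weight = 0.1, odds_ratio = NA_real_,
                        effect_model = "additive",
                        category = "bone_mineral_density", subcategory = "",
                        allele_freq = 0.5, in_combined_score = FALSE,
                        previously_used = FALSE, evidence_level = "strong",
                        study_type = "GWAS", source = "test") {
  data.frame(rsid = rsid, chrom = chrom, position = position,
             effect_allele = effect_allele, other_allele = other_allele,
             weight = weight, odds_ratio = odds_ratio,
             effect_model = effect_model, category = category,
             subcategory = subcategory, allele_freq = allele_freq,
             in_combined_score = in_combined_score,
             previously_used = previously_used,
             evidence_level = evidence_level, study_type = study_type,
             source = source, stringsAsFactors = FALSE)
}

# n additive variants with non-palindromic alleles and given weights/freqs.
variant_block <- function(n, weight = 0.1, allele_freq = 0.5, ...) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    variant_row(rsid = sprintf("rs2%06d", i), position = 1000L + i,
                weight = rep_len(weight, n)[i],
                allele_freq = rep_len(allele_freq, n)[i], ...)
  }))
}

# Profile carrying a given effect-allele dosage at every panel variant;
# complement = TRUE reports genotypes on the opposite strand.
profile_from_dosages <- function(panel, dosages, id = "T1",
                                 complement = FALSE) {
  v <- if (inherits(panel, "injury_panel")) panel$variants else panel
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  eff <- v$effect_allele
  oth <- v$other_allele
  if (complement) {
    eff <- unname(comp[eff])
    oth <- unname(comp[oth])
  }
  dosages <- rep_len(dosages, nrow(v))
  geno <- mapply(function(d, e, o) {
    paste(sort(c(rep(e, d), rep(o, 2 - d))), collapse = "")
  }, dosages, eff, oth)
  build <- if (inherits(panel, "injury_panel")) panel$build else "GRCh37"
  genotype_profile(id, data.frame(rsid = v$rsid, chrom = v$chrom,
                                  position = v$position, genotype = geno,
                                  stringsAsFactors = FALSE),
                   build = build)
}

write_temp_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".txt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
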