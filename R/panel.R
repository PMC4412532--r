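#' @keywords internal
"_PACKAGE"

## Controlled vocabularies for the panel schema. Order of categories is the
## order assessments appear in reports.
panel_categories <- c(
  "ACL_rupture", "achilles_tendon", "bone_mineral_density",
  "osteoarthritis", "vitamin_mineral", "sickle_cell_trait"
)
effect_models <- c("additive", "mendelian")
evidence_levels <- c("weak", "moderate", "strong")
study_types <- c("candidate_gene", "GWAS")

panel_columns <- c(
  "rsid", "chrom", "position", "effect_allele", "other_allele", "weight",
  "odds_ratio", "effect_model", "category", "subcategory", "allele_freq",
  "in_combined_score", "previously_used", "evidence_level", "study_type",
  "source"
)

valid_chroms <- c(as.character(1:22), "X", "Y", "MT")
snp_bases <- c("A", "C", "G", "T")

#' Construct an injury-SNP panel from a variant table
#'
#' Validates a data frame of panel variants against the panel schema and
#' wraps it, together with a genome-build label, as an `injury_panel`
#' object. Most users load the bundled or an external panel with
#' [load_panel()] instead of calling this directly.
#'
#' @param variants Data frame with the sixteen panel schema columns (see
#'   [load_panel()]). Logical columns may be given as 0/1.
#' @param build Genome-build label (an opaque string); profile and panel
#'   builds must match at assessment time.
#' @return An object of class `injury_panel`: a list with elements
#'   `variants` (validated data frame, file order preserved) and `build`.
#' @seealso [load_panel()], [panel_summary()]
#' @export
injury_panel <- function(variants, build = "GRCh37") {
  stopifnot(is.data.frame(variants))
  missing_cols <- setdiff(panel_columns, names(variants))
  if (length(missing_cols) > 0) {
    stop("panel is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  variants <- variants[, panel_columns, drop = FALSE]
  for (col in c("in_combined_score", "previously_used")) {
    variants[[col]] <- as.logical(variants[[col]])
  }
  variants$position <- as.integer(variants$position)
  variants$chrom <- as.character(variants$chrom)
  variants$weight <- as.numeric(variants$weight)
  variants$odds_ratio <- as.numeric(variants$odds_ratio)
  variants$allele_freq <- as.numeric(variants$allele_freq)
  validate_panel_variants(variants)
  structure(list(variants = variants, build = build), class = "injury_panel")
}

validate_panel_variants <- function(v) {
  n <- nrow(v)
  if (n == 0) return(invisible(TRUE))
  fail <- function(rows, msg) {
    stop(sprintf("panel validation failed (row %s): %s",
                 paste(rows, collapse = ", "), msg), call. = FALSE)
  }
  bad <- which(!grepl("^rs[0-9]+$", v$rsid))
  if (length(bad)) fail(bad, paste("malformed rsid:", v$rsid[bad[1]]))
  dup <- v$rsid[duplicated(v$rsid)]
  if (length(dup)) {
    stop("duplicate rsid in panel: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!(v$chrom %in% valid_chroms))
  if (length(bad)) fail(bad, paste("invalid chromosome:", v$chrom[bad[1]]))
  bad <- which(is.na(v$position) | v$position < 1)
  if (length(bad)) fail(bad, "position must be a positive integer")
  bad <- which(!(v$effect_allele %in% snp_bases) |
                 !(v$other_allele %in% snp_bases))
  if (length(bad)) fail(bad, "alleles must be single bases A/C/G/T")
  bad <- which(v$effect_allele == v$other_allele)
  if (length(bad)) fail(bad, "effect_allele must differ from other_allele")
  bad <- which(!is.finite(v$weight))
  if (length(bad)) fail(bad, "weight must be finite")
  bad <- which(!is.na(v$odds_ratio) & v$odds_ratio <= 0)
  if (length(bad)) fail(bad, "odds_ratio must be positive when present")
  bad <- which(!(v$effect_model %in% effect_models))
  if (length(bad)) fail(bad, paste("unknown effect_model:", v$effect_model[bad[1]]))
  bad <- which(!(v$category %in% panel_categories))
  if (length(bad)) fail(bad, paste("unknown category:", v$category[bad[1]]))
  bad <- which(!(v$evidence_level %in% evidence_levels))
  if (length(bad)) fail(bad, paste("unknown evidence_level:", v$evidence_level[bad[1]]))
  bad <- which(!(v$study_type %in% study_types))
  if (length(bad)) fail(bad, paste("unknown study_type:", v$study_type[bad[1]]))
  add <- v$effect_model == "additive"
  bad <- which(add & (is.na(v$allele_freq) | v$allele_freq <= 0 | v$allele_freq >= 1))
  if (length(bad)) fail(bad, "allele_freq must lie strictly in (0,1) for additive variants")
  bad <- which(!add & (is.na(v$allele_freq) | v$allele_freq < 0 | v$allele_freq > 1))
  if (length(bad)) fail(bad, "allele_freq must lie in [0,1]")
  bad <- which(v$in_combined_score & v$category != "bone_mineral_density")
  if (length(bad)) fail(bad, "in_combined_score requires category bone_mineral_density")
  bad <- which(v$effect_model == "mendelian" & v$category != "sickle_cell_trait")
  if (length(bad)) fail(bad, "mendelian effect model is reserved for sickle_cell_trait")
  invisible(TRUE)
}

#' Load an injury-SNP panel from a TSV file
#'
#' Reads a tab-separated panel file (UTF-8, `#`-prefixed comment lines, a
#' header row with the sixteen schema columns) and returns a validated
#' [injury_panel()]. Booleans are serialized as 0/1 and a missing
#' odds ratio as `NA`. A comment line of the form `# build: <label>`
#' sets the panel's genome-build label.
#'
#' The bundled fixture panel lives at
#' `system.file("extdata", "injury_panel.tsv", package = "injuryrisk")`.
#'
#' @param path Path to a panel TSV file.
#' @param build Optional build label overriding any `# build:` comment.
#' @return A validated `injury_panel` with rows in file order.
#' @examples
#' panel <- load_panel(system.file("extdata", "injury_panel.tsv",
#'                                 package = "injuryrisk"))
#' panel_summary(panel)$total
#' @export
load_panel <- function(path, build = NULL) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  if (is.null(build)) {
    m <- grep("^#\\s*build\\s*:", lines, value = TRUE)
    build <- if (length(m)) trimws(sub("^#\\s*build\\s*:", "", m[1])) else "unknown"
  }
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  body <- lines[keep]
  if (length(body) == 0) stop("panel file has no header row: ", path, call. = FALSE)
  df <- utils::read.delim(text = body, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA",
                          colClasses = "character")
  if (!identical(names(df), panel_columns)) {
    stop("panel header does not match the schema; expected columns: ",
         paste(panel_columns, collapse = ", "), call. = FALSE)
  }
  for (col in c("position", "weight", "odds_ratio", "allele_freq",
                "in_combined_score", "previously_used")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df$subcategory[is.na(df$subcategory)] <- ""
  injury_panel(df, build = build)
}

#' Write an injury-SNP panel to a TSV file
#'
#' Inverse of [load_panel()]: loading a written panel returns an identical
#' panel (round-trip identity).
#'
#' @param panel An `injury_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "injury_panel"))
  v <- panel$variants
  v$in_combined_score <- as.integer(v$in_combined_score)
  v$previously_used <- as.integer(v$previously_used)
  v$odds_ratio <- ifelse(is.na(v$odds_ratio), "NA",
                         format(v$odds_ratio, digits = 15, trim = TRUE,
                                scientific = FALSE))
  v$weight <- format(v$weight, digits = 15, trim = TRUE, scientific = FALSE)
  v$allele_freq <- format(v$allele_freq, digits = 15, trim = TRUE,
                          scientific = FALSE)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# build: %s", panel$build), con)
  writeLines(paste(panel_columns, collapse = "\t"), con)
  apply_rows <- do.call(paste, c(v[panel_columns], sep = "\t"))
  writeLines(apply_rows, con)
  invisible(path)
}

#' Classify an allelic odds ratio into the small/medium/large scale
#'
#' Effect sizes are rated from the allelic odds ratio: small for OR in
#' \[1.0, 1.3\], medium in (1.3, 2.0\], large above 2.0. Protective odds
#' ratios (OR < 1) are classified by magnitude, i.e. 1/OR, so an OR of
#' 0.38 rates the same as 2.6.
#'
#' @param odds_ratio Positive numeric vector of allelic odds ratios.
#' @return An ordered factor with levels `small < medium < large`.
#' @examples
#' classify_effect_size(c(1.0, 1.56, 11))
#' @export
classify_effect_size <- function(odds_ratio) {
  if (any(!is.finite(odds_ratio) | odds_ratio <= 0)) {
    stop("odds_ratio must be positive and finite", call. = FALSE)
  }
  m <- ifelse(odds_ratio < 1, 1 / odds_ratio, odds_ratio)
  lab <- ifelse(m <= 1.3, "small", ifelse(m <= 2.0, "medium", "large"))
  factor(lab, levels = c("small", "medium", "large"), ordered = TRUE)
}

#' Summarize a panel's composition and novelty
#'
#' @param panel An `injury_panel`.
#' @return A list with `total` (variant count), `by_category` (named
#'   integer vector over the six categories), `n_combined` (size of the
#'   combined-score subset), `n_new` and `pct_new` (count and percentage,
#'   rounded to the nearest integer, of variants not previously used in
#'   sports genetics).
#' @examples
#' panel <- load_panel(system.file("extdata", "injury_panel.tsv",
#'                                 package = "injuryrisk"))
#' panel_summary(panel)
#' @export
panel_summary <- function(panel) {
  stopifnot(inherits(panel, "injury_panel"))
  v <- panel$variants
  by_cat <- vapply(panel_categories, function(cc) sum(v$category == cc), 0L)
  n_new <- sum(!v$previously_used)
  total <- nrow(v)
  list(
    total = total,
    by_category = by_cat,
    n_combined = sum(v$in_combined_score),
    n_new = n_new,
    pct_new = if (total > 0) round(100 * n_new / total) else NA_real_
  )
}

#' @export
print.injury_panel <- function(x, ...) {
  s <- panel_summary(x)
  cat(sprintf("<injury_panel> %d variants, build %s\n", s$total, x$build))
  for (cc in names(s$by_category)) {
    cat(sprintf("  %-22s %3d\n", cc, s$by_category[[cc]]))
  }
  cat(sprintf("  combined-score subset  %3d\n", s$n_combined))
  cat(sprintf("  not previously used in sports genetics: %d (%s%%)\n",
              s$n_new, s$pct_new))
  invisible(x)
}
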