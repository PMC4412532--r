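base_complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Match every panel variant against a profile
#'
#' Reconciles the profile's unphased calls with the panel's effect/other
#' alleles and returns one risk-allele dosage row per panel variant.
#' Dosage counts copies of the panel's effect allele (0/1/2 diploid,
#' 0/1 hemizygous). A call whose alleles sit on the opposite strand is
#' counted on the complemented alleles with `strand_flipped = TRUE`.
#' Palindromic panel sites (A/T or C/G) cannot be strand-resolved from
#' genotype data alone and are excluded as `ambiguous_site` unless
#' `trust_palindromic = TRUE` asserts same-strand reporting.
#'
#' Exclusion reasons, in order of precedence: `missing_call` (no call or
#' `"--"`), `non_snp` (insertion/deletion codes), `ambiguous_site`,
#' `allele_mismatch`; matched rows carry `excluded_reason = "none"` and a
#' dosage, and only those rows contribute to scores.
#'
#' @param profile A [genotype_profile()].
#' @param panel An [injury_panel()] (or its `variants` data frame).
#' @param trust_palindromic Count palindromic sites as if reported on the
#'   panel strand (default `FALSE`).
#' @return Data frame with columns `rsid`, `dosage` (integer or `NA`),
#'   `strand_flipped`, `ambiguous`, `excluded_reason`.
#' @export
match_panel <- function(profile, panel, trust_palindromic = FALSE) {
  stopifnot(inherits(profile, "genotype_profile"))
  v <- if (inherits(panel, "injury_panel")) panel$variants else panel
  n <- nrow(v)
  g <- profile$calls$genotype[match(v$rsid, profile$calls$rsid)]
  eff <- v$effect_allele
  oth <- v$other_allele
  ceff <- unname(base_complement[eff])
  coth <- unname(base_complement[oth])

  a1 <- substr(g, 1, 1)
  a2 <- ifelse(!is.na(g) & nchar(g) == 2, substr(g, 2, 2), NA_character_)

  missing_call <- is.na(g) | g == "--"
  non_snp <- !missing_call & grepl("[ID]", g)
  palindromic <- eff == coth
  callable <- !missing_call & !non_snp

  in_set <- function(a, x, y) !is.na(a) & (a == x | a == y)
  hemi <- is.na(a2)
  direct <- callable & in_set(a1, eff, oth) & (hemi | in_set(a2, eff, oth))
  flipped <- callable & !direct &
    in_set(a1, ceff, coth) & (hemi | in_set(a2, ceff, coth))

  dosage <- rep(NA_integer_, n)
  dosage[direct] <- (a1[direct] == eff[direct]) +
    ifelse(hemi[direct], 0L, a2[direct] == eff[direct])
  dosage[flipped] <- (a1[flipped] == ceff[flipped]) +
    ifelse(hemi[flipped], 0L, a2[flipped] == ceff[flipped])

  reason <- rep("allele_mismatch", n)
  reason[direct | flipped] <- "none"
  if (!trust_palindromic) reason[callable & palindromic] <- "ambiguous_site"
  reason[non_snp] <- "non_snp"
  reason[missing_call] <- "missing_call"
  dosage[reason != "none"] <- NA_integer_

  data.frame(rsid = v$rsid, dosage = as.integer(dosage),
             strand_flipped = flipped & reason == "none",
             ambiguous = palindromic,
             excluded_reason = reason, stringsAsFactors = FALSE)
}

#' Match a single panel variant against a profile
#'
#' Single-variant convenience wrapper around [match_panel()].
#'
#' @inheritParams match_panel
#' @param variant One panel variant: a one-row data frame or a list with
#'   at least `rsid`, `effect_allele`, `other_allele`.
#' @return A one-row data frame as in [match_panel()].
#' @export
match_variant <- function(profile, variant, trust_palindromic = FALSE) {
  v <- as.data.frame(variant, stringsAsFactors = FALSE)
  stopifnot(nrow(v) == 1)
  match_panel(profile, v, trust_palindromic = trust_palindromic)
}

#' Additive category score
#'
#' Computes the weighted risk-allele score S = sum(w_i * x_i) and the raw
#' risk-allele count sum(x_i) over the non-excluded loci of one panel
#' category, where x_i is the effect-allele dosage and w_i the per-allele
#' weight (ln OR for binary outcomes, beta for quantitative traits).
#'
#' When some loci are missing and `rescale = TRUE`, the score is
#' multiplied by (sum of all category weights) / (sum of matched weights)
#' so that it stays on the scale of the complete panel; `rescaled` flags
#' that this was applied.
#'
#' @inheritParams match_panel
#' @param category One of the panel's category labels.
#' @param combined_only Restrict to the combined-score subset
#'   (`in_combined_score`), e.g. the 63-SNP bone-mineral-density score.
#' @param rescale Rescale for missing loci (default `FALSE`).
#' @return An object of class `category_score`: list with `category`,
#'   `raw_score`, `risk_allele_count`, `n_matched`, `n_panel`, `coverage`,
#'   `rescaled`, and the per-locus `matches` data frame.
#' @export
additive_score <- function(profile, panel, category, combined_only = FALSE,
                           rescale = FALSE, trust_palindromic = FALSE) {
  stopifnot(inherits(panel, "injury_panel"))
  v <- panel$variants
  keep <- v$category == category & v$effect_model == "additive"
  if (combined_only) keep <- keep & v$in_combined_score
  v <- v[keep, , drop = FALSE]
  if (nrow(v) == 0) {
    stop("no additive panel loci in category '", category, "'", call. = FALSE)
  }
  m <- match_panel(profile, v, trust_palindromic = trust_palindromic)
  ok <- m$excluded_reason == "none"
  raw <- sum(v$weight[ok] * m$dosage[ok])
  count <- sum(m$dosage[ok])
  coverage <- sum(ok) / nrow(v)
  rescaled <- FALSE
  if (rescale && coverage < 1 && sum(ok) > 0) {
    w_all <- sum(v$weight)
    w_matched <- sum(v$weight[ok])
    if (w_matched > 0) {
      raw <- raw * w_all / w_matched
      rescaled <- TRUE
    }
  }
  structure(list(category = category, raw_score = raw,
                 risk_allele_count = as.integer(count),
                 n_matched = sum(ok), n_panel = nrow(v),
                 coverage = coverage, rescaled = rescaled, matches = m),
            class = "category_score")
}

#' @export
print.category_score <- function(x, ...) {
  cat(sprintf("<category_score> %s: score %.4f (%d risk alleles, %d/%d loci%s)\n",
              x$category, x$raw_score, x$risk_allele_count, x$n_matched,
              x$n_panel, if (x$rescaled) ", rescaled" else ""))
  invisible(x)
}

#' Call sickle cell trait from the rs334 genotype
#'
#' Sickle cell trait is Mendelian: carriers inherit one normal hemoglobin
#' allele (HbA) and one sickle allele (HbS, rs334). The call is derived
#' solely from the effect-allele dosage at the panel's Mendelian variant:
#' 0 copies is negative, 1 a trait carrier, 2 homozygous for the variant,
#' and a missing or unmatchable genotype yields no call.
#'
#' rs334 is an A/T substitution, hence palindromic; the Mendelian call
#' trusts the DTC convention of same-strand (forward) reporting for this
#' single site.
#'
#' @inheritParams match_variant
#' @param variant The panel's Mendelian variant (effect_model
#'   `"mendelian"`); the effect allele is the sickle (HbS) allele.
#' @return One of `"negative"`, `"trait_carrier"`, `"homozygous_variant"`,
#'   `"no_call"`.
#' @export
call_sickle_cell_trait <- function(profile, variant) {
  v <- as.data.frame(variant, stringsAsFactors = FALSE)
  stopifnot(nrow(v) == 1)
  if (!identical(v$effect_model, "mendelian")) {
    stop("call_sickle_cell_trait() requires a mendelian-model variant",
         call. = FALSE)
  }
  m <- match_panel(profile, v, trust_palindromic = TRUE)
  if (m$excluded_reason != "none") return("no_call")
  c("negative", "trait_carrier", "homozygous_variant")[m$dosage + 1L]
}
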