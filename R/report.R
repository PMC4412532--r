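## Static per-category annotation text: prevention notes carried verbatim
## into reports (content, not computation).
category_annotations <- data.frame(
  category = c("ACL_rupture", "achilles_tendon", "bone_mineral_density",
               "osteoarthritis", "vitamin_mineral", "sickle_cell_trait"),
  display = c("ACL rupture", "Achilles tendon injury",
              "Bone mineral density / stress fracture", "Osteoarthritis",
              "Vitamin and mineral deficiencies", "Sickle cell trait"),
  prevention = c(
    "prevention: dynamic warm-up targeting landing/cutting form, core and hamstring strength",
    "prevention: gastrocnemius/soleus eccentric strengthening, calf and Achilles stretching, softer running surfaces",
    "prevention: redistribute training volume to low-impact disciplines; consider DEXA scan and bone-health nutrition",
    "prevention: protect joints from injury; revisit training intensity and duration with age",
    "prevention: review micronutrient intake; consider targeted supplementation or fortified electrolyte drinks",
    "NCAA guidance for carriers: gradual conditioning, adequate rest between repetitions, stop activity on symptoms, optimal hydration, prompt medical care under unusual distress"
  ),
  stringsAsFactors = FALSE
)

#' Assess one athlete across every panel category
#'
#' Runs the full per-athlete pipeline: allele matching, additive scoring,
#' the Mendelian sickle-cell-trait call, bin assignment against the
#' reference distribution, and mapping to the four-tier report levels.
#' Deterministic given its inputs.
#'
#' The combined bone-mineral-density score (the `in_combined_score`
#' subset) is binned against `scheme`; other additive categories are
#' binned against their own exact HWE reference distribution with the
#' same quintile cuts. If the combined score's locus coverage falls below
#' `coverage_floor` it is reported as insufficient data (tier average
#' with a coverage warning) rather than rescaled into a bin.
#'
#' @param profile A [genotype_profile()]; its build label must match the
#'   panel's.
#' @param panel An [injury_panel()].
#' @param scheme A [derive_bins()] scheme for the combined
#'   bone-mineral-density score; computed from the panel's exact
#'   distribution when `NULL`.
#' @param coverage_floor Minimum combined-score coverage (default 0.9).
#' @param grid_step Grid width for on-the-fly reference distributions.
#' @param trust_palindromic Passed to the matcher (the Mendelian call
#'   always trusts same-strand reporting at its single site).
#' @return An object of class `athlete_report`: `individual_id`,
#'   `assessments` (one per panel category, each with `category`,
#'   `score`, `bin`, `tier`, `color`, `annotations`,
#'   `coverage_warning`), `panel_version`, `calibration_version`.
#' @export
assess_athlete <- function(profile, panel, scheme = NULL,
                           coverage_floor = 0.9, grid_step = 0.01,
                           trust_palindromic = FALSE) {
  stopifnot(inherits(profile, "genotype_profile"),
            inherits(panel, "injury_panel"))
  if (!identical(profile$build, panel$build)) {
    stop(sprintf("genome build mismatch: profile '%s' vs panel '%s'",
                 profile$build, panel$build), call. = FALSE)
  }
  if (is.null(scheme)) {
    scheme <- derive_bins(exact_score_distribution(panel, grid_step,
                                                   combined_only = TRUE))
  }
  v <- panel$variants
  cats <- panel_categories[panel_categories %in% v$category]
  assessments <- lapply(cats, function(cat) {
    if (cat == "sickle_cell_trait") {
      assess_mendelian_category(profile, v[v$category == cat, , drop = FALSE][1, ])
    } else if (cat == "bone_mineral_density") {
      assess_combined_category(profile, panel, scheme, coverage_floor,
                               trust_palindromic)
    } else {
      assess_additive_category(profile, panel, cat, grid_step,
                               trust_palindromic)
    }
  })
  names(assessments) <- cats
  structure(list(individual_id = profile$individual_id,
                 assessments = assessments,
                 panel_version = sprintf("%s/%d-variants", panel$build, nrow(v)),
                 calibration_version = sprintf("%d-bins/grid-%g",
                                               scheme$n_bins, grid_step)),
            class = "athlete_report")
}

new_assessment <- function(category, score, bin, tier, annotations,
                           coverage_warning = FALSE) {
  list(category = category, score = score, bin = bin, tier = tier,
       color = tier_color(tier), annotations = annotations,
       coverage_warning = coverage_warning)
}

prevention_note <- function(category) {
  category_annotations$prevention[category_annotations$category == category]
}

assess_mendelian_category <- function(profile, variant) {
  status <- call_sickle_cell_trait(profile, variant)
  tier <- switch(status, negative = "average", trait_carrier = "increased",
                 homozygous_variant = "increased", no_call = "average")
  ann <- sprintf("sickle cell trait status: %s (%s)", status, variant$rsid)
  if (status %in% c("trait_carrier", "homozygous_variant")) {
    ann <- c(ann, prevention_note("sickle_cell_trait"))
  }
  new_assessment("sickle_cell_trait", status, NA_integer_, tier, ann,
                 coverage_warning = status == "no_call")
}

assess_combined_category <- function(profile, panel, scheme, coverage_floor,
                                     trust_palindromic) {
  score <- additive_score(profile, panel, "bone_mineral_density",
                          combined_only = TRUE, rescale = TRUE,
                          trust_palindromic = trust_palindromic)
  if (score$n_matched == 0 || score$coverage < coverage_floor) {
    return(new_assessment(
      "bone_mineral_density", score, NA_integer_, "average",
      sprintf("insufficient data: combined score coverage %.0f%% below floor",
              100 * score$coverage),
      coverage_warning = TRUE))
  }
  bin <- assign_bin(score$raw_score, scheme)
  tier <- assign_tier(score$raw_score, scheme)
  ann <- sprintf("combined genetic score %.3f, bin %d of %d: %s",
                 score$raw_score, bin, scheme$n_bins,
                 scheme$annotations[bin])
  if (tier %in% c("slightly_increased", "increased")) {
    ann <- c(ann, prevention_note("bone_mineral_density"))
  }
  new_assessment("bone_mineral_density", score, bin, tier, ann,
                 coverage_warning = score$coverage < 1)
}

assess_additive_category <- function(profile, panel, category, grid_step,
                                     trust_palindromic) {
  score <- additive_score(profile, panel, category,
                          trust_palindromic = trust_palindromic)
  if (score$n_matched == 0) {
    return(new_assessment(category, score, NA_integer_, "average",
                          "no genotype calls matched this category's loci",
                          coverage_warning = TRUE))
  }
  v <- panel$variants
  ref <- exact_score_distribution(v[v$category == category, , drop = FALSE],
                                  grid_step)
  cat_scheme <- derive_bins(ref, annotations = sprintf(
    "bin %d of 5 of the %s reference score distribution", 1:5, category))
  bin <- assign_bin(score$raw_score, cat_scheme)
  tier <- assign_tier(score$raw_score, cat_scheme)
  ann <- sprintf("score %.3f (%d risk alleles over %d/%d loci), bin %d of %d",
                 score$raw_score, score$risk_allele_count, score$n_matched,
                 score$n_panel, bin, cat_scheme$n_bins)
  ann <- c(ann, named_snp_notes(profile, panel, category))
  if (tier %in% c("slightly_increased", "increased")) {
    ann <- c(ann, prevention_note(category))
  }
  new_assessment(category, score, bin, tier, ann,
                 coverage_warning = score$coverage < 1)
}

## Per-SNP findings worth surfacing by name: any large-effect risk allele
## carried at a candidate-gene locus with a published OR.
named_snp_notes <- function(profile, panel, category) {
  v <- panel$variants
  v <- v[v$category == category & !is.na(v$odds_ratio), , drop = FALSE]
  if (nrow(v) == 0) return(character())
  v <- v[classify_effect_size(v$odds_ratio) == "large", , drop = FALSE]
  if (nrow(v) == 0) return(character())
  m <- match_panel(profile, v)
  hit <- m$excluded_reason == "none" & m$dosage >= 1
  if (!any(hit)) return(character())
  sprintf("%s: %d cop%s of the %s risk allele (OR %g, %s effect)",
          v$rsid[hit], m$dosage[hit], ifelse(m$dosage[hit] == 1, "y", "ies"),
          v$effect_allele[hit], v$odds_ratio[hit],
          as.character(classify_effect_size(v$odds_ratio[hit])))
}

#' Render an athlete report
#'
#' @param report An [assess_athlete()] report.
#' @param format `"tsv"` (one row per category, the machine-readable
#'   default), `"text"` (the summary-page layout), or `"html"`.
#' @return Character vector of output lines; identical bytes for
#'   identical reports.
#' @export
render_report <- function(report, format = c("tsv", "text", "html")) {
  stopifnot(inherits(report, "athlete_report"))
  format <- match.arg(format)
  switch(format,
         tsv = render_report_tsv(report),
         text = render_report_text(report),
         html = render_report_html(report))
}

assessment_row <- function(a) {
  score_str <- if (inherits(a$score, "category_score")) {
    sprintf("%.6g", a$score$raw_score)
  } else {
    as.character(a$score)
  }
  count_str <- if (inherits(a$score, "category_score")) {
    as.character(a$score$risk_allele_count)
  } else "NA"
  cov_str <- if (inherits(a$score, "category_score")) {
    sprintf("%.3f", a$score$coverage)
  } else "NA"
  paste(a$category, score_str, count_str, cov_str,
        ifelse(is.na(a$bin), "NA", a$bin), a$tier, a$color,
        as.integer(a$coverage_warning),
        paste(a$annotations, collapse = "; "), sep = "\t")
}

render_report_tsv <- function(report) {
  header <- paste("category", "score", "risk_allele_count", "coverage",
                  "bin", "tier", "color", "coverage_warning", "annotations",
                  sep = "\t")
  c(sprintf("# individual_id: %s", report$individual_id),
    sprintf("# panel_version: %s", report$panel_version),
    sprintf("# calibration_version: %s", report$calibration_version),
    header,
    vapply(report$assessments, assessment_row, character(1)))
}

render_report_text <- function(report) {
  lines <- c(sprintf("Genetic injury risk summary for %s", report$individual_id),
             sprintf("(panel %s, calibration %s)", report$panel_version,
                     report$calibration_version), "")
  for (a in report$assessments) {
    disp <- category_annotations$display[
      category_annotations$category == a$category]
    if (length(disp) == 0) disp <- a$category
    lines <- c(lines,
               sprintf("%-40s %s (%s)", disp, gsub("_", " ", a$tier), a$color),
               paste0("    ", a$annotations))
  }
  lines
}

render_report_html <- function(report) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  rows <- vapply(report$assessments, function(a) {
    sprintf("<tr><td>%s</td><td style=\"color:%s\">%s</td><td>%s</td></tr>",
            esc(a$category), a$color, esc(gsub("_", " ", a$tier)),
            esc(paste(a$annotations, collapse = "; ")))
  }, character(1))
  c("<html><body>",
    sprintf("<h1>Genetic injury risk summary: %s</h1>",
            esc(report$individual_id)),
    "<table><tr><th>category</th><th>risk level</th><th>details</th></tr>",
    rows, "</table>", "</body></html>")
}

#' @export
print.athlete_report <- function(x, ...) {
  writeLines(render_report_text(x))
  invisible(x)
}
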