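profile_kinds <- c("all_heterozygous", "max_risk", "min_risk", "sct_carrier")

#' Specify a synthetic athlete cohort
#'
#' Describes a cohort to be simulated by [simulate_profiles()]: cohort
#' size, seed, sexes, deterministic profile injections (extreme-risk or
#' carrier genotypes overriding the random draws), and a per-individual
#' injury table. Injury labels are static fixture attributes, not
#' modelled outcomes.
#'
#' @param n_individuals Cohort size.
#' @param seed Integer seed controlling all genotype draws.
#' @param sexes Character vector (`"male"`/`"female"`) of length
#'   `n_individuals`, recycled from `sex_ratio` if omitted.
#' @param sex_ratio Fraction male, used only when `sexes` is `NULL`.
#' @param injections Data frame with columns `individual_id`, `category`,
#'   `kind` (one of `all_heterozygous`, `max_risk`, `min_risk`,
#'   `sct_carrier`); ids must be unique and within the cohort.
#' @param injury_table Data frame with columns `individual_id`, `sex`,
#'   `season1_injured`, `season2_injured` (logical, `NA` = unknown), or
#'   `NULL`.
#' @param sct_negative Force a sickle-cell-negative cohort: every
#'   individual without an `sct_carrier` injection gets zero copies of
#'   the sickle allele, regardless of the draw.
#' @param ids Individual identifiers; default `A01`, `A02`, ...
#' @return An object of class `cohort_spec`.
#' @seealso [default_cohort_spec()] for the 14-athlete study fixture.
#' @export
cohort_spec <- function(n_individuals, seed = 2015, sexes = NULL,
                        sex_ratio = 0.5, injections = NULL,
                        injury_table = NULL, sct_negative = FALSE,
                        ids = sprintf("A%02d", seq_len(n_individuals))) {
  stopifnot(n_individuals >= 1, length(ids) == n_individuals,
            !anyDuplicated(ids))
  if (is.null(sexes)) {
    n_male <- round(sex_ratio * n_individuals)
    sexes <- rep(c("male", "female"), c(n_male, n_individuals - n_male))
  }
  stopifnot(length(sexes) == n_individuals,
            all(sexes %in% c("male", "female")))
  if (is.null(injections)) {
    injections <- data.frame(individual_id = character(),
                             category = character(), kind = character())
  }
  stopifnot(all(c("individual_id", "category", "kind") %in% names(injections)))
  if (anyDuplicated(injections$individual_id)) {
    stop("injected individual ids must be unique", call. = FALSE)
  }
  if (nrow(injections) > n_individuals) {
    stop("more injected profiles than individuals", call. = FALSE)
  }
  if (!all(injections$individual_id %in% ids)) {
    stop("injected individual ids must belong to the cohort", call. = FALSE)
  }
  if (!all(injections$kind %in% profile_kinds)) {
    stop("unknown profile kind: ",
         paste(setdiff(injections$kind, profile_kinds), collapse = ", "),
         call. = FALSE)
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 seed = as.integer(seed), ids = ids, sexes = sexes,
                 injections = injections, injury_table = injury_table,
                 sct_negative = isTRUE(sct_negative)),
            class = "cohort_spec")
}

#' The 14-athlete study cohort fixture
#'
#' Reproduces the structure of the pilot cohort: 14 triathletes, 9 male
#' and 5 female; 10 of 14 injured in season one (71.4%); season-two
#' status known for 12, of whom 4 were injured (33.3%, two individuals
#' unknown). The cohort is sickle-cell negative, one individual is
#' injected heterozygous at every osteoarthritis locus, and two carry the
#' extreme (maximum- and minimum-risk) combined bone-mineral-density
#' genotypes, mirroring the individuals highlighted in the study.
#'
#' @param seed Integer seed for the genotype draws.
#' @return A [cohort_spec()].
#' @export
default_cohort_spec <- function(seed = 2015) {
  sexes <- rep(c("male", "female"), c(9, 5))
  ids <- sprintf("A%02d", 1:14)
  ## season 1: 6/9 males + 4/5 females injured = 10/14
  s1 <- c(rep(TRUE, 6), rep(FALSE, 3), rep(TRUE, 4), FALSE)
  ## season 2: unknown for A09 (male) and A14 (female); 4/12 injured
  s2 <- c(TRUE, TRUE, rep(FALSE, 6), NA, TRUE, TRUE, FALSE, FALSE, NA)
  injury <- data.frame(individual_id = ids, sex = sexes,
                       season1_injured = s1, season2_injured = s2,
                       stringsAsFactors = FALSE)
  inj <- data.frame(
    individual_id = c("A01", "A02", "A03"),
    category = c("bone_mineral_density", "bone_mineral_density",
                 "osteoarthritis"),
    kind = c("max_risk", "min_risk", "all_heterozygous"),
    stringsAsFactors = FALSE
  )
  cohort_spec(14, seed = seed, sexes = sexes, injections = inj,
              injury_table = injury, sct_negative = TRUE, ids = ids)
}

#' Simulate genotype profiles for a cohort
#'
#' Draws unphased genotypes at every panel locus independently from HWE
#' at the panel's effect-allele frequencies, applies the spec's injected
#' profiles (`all_heterozygous`: dosage 1 at every locus of the injected
#' category; `max_risk`/`min_risk`: dosage 2/0; `sct_carrier`: one copy
#' of the sickle allele), and optionally writes each profile as a
#' DTC-dialect raw file. Byte-identical output for the same spec and
#' seed.
#'
#' @param panel An [injury_panel()].
#' @param spec A [cohort_spec()].
#' @param out_dir Optional directory; when given, each profile is written
#'   to `<out_dir>/<individual_id>.txt` via [write_raw_genotypes()].
#' @return Named list of [genotype_profile()] objects.
#' @export
simulate_profiles <- function(panel, spec, out_dir = NULL) {
  stopifnot(inherits(panel, "injury_panel"), inherits(spec, "cohort_spec"))
  v <- panel$variants
  missing_cat <- setdiff(spec$injections$category, v$category)
  if (length(missing_cat) > 0) {
    stop("injected category not in panel: ",
         paste(missing_cat, collapse = ", "), call. = FALSE)
  }
  L <- nrow(v)
  n <- spec$n_individuals
  dos <- with_seed(spec$seed, {
    matrix(stats::rbinom(n * L, 2L, rep(v$allele_freq, each = n)), nrow = n)
  })
  if (spec$sct_negative) {
    mend <- which(v$effect_model == "mendelian")
    if (length(mend)) dos[, mend] <- 0L
  }
  for (j in seq_len(nrow(spec$injections))) {
    row <- which(spec$ids == spec$injections$individual_id[j])
    loci <- which(v$category == spec$injections$category[j])
    dos[row, loci] <- switch(spec$injections$kind[j],
                             all_heterozygous = 1L,
                             max_risk = 2L,
                             min_risk = 0L,
                             sct_carrier = 1L)
  }
  ## per-locus genotype strings for dosage 0/1/2 (alleles in lexicographic order)
  g0 <- paste0(v$other_allele, v$other_allele)
  g1 <- ifelse(v$effect_allele < v$other_allele,
               paste0(v$effect_allele, v$other_allele),
               paste0(v$other_allele, v$effect_allele))
  g2 <- paste0(v$effect_allele, v$effect_allele)
  gmat <- cbind(g0, g1, g2)
  profiles <- lapply(seq_len(n), function(i) {
    geno <- gmat[cbind(seq_len(L), dos[i, ] + 1L)]
    genotype_profile(spec$ids[i],
                     data.frame(rsid = v$rsid, chrom = v$chrom,
                                position = v$position, genotype = geno,
                                stringsAsFactors = FALSE),
                     build = panel$build)
  })
  names(profiles) <- spec$ids
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (p in profiles) {
      write_raw_genotypes(p, file.path(out_dir, paste0(p$individual_id, ".txt")))
    }
  }
  profiles
}

#' Write a cohort injury table to TSV
#'
#' @param injury_table Data frame as in [cohort_spec()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(injury_table, path) {
  df <- injury_table
  df$season1_injured <- as.integer(df$season1_injured)
  df$season2_injured <- as.integer(df$season2_injured)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = "NA")
  df$season1_injured <- as.logical(df$season1_injured)
  df$season2_injured <- as.logical(df$season2_injured)
  df
}

#' Summarize per-season injury proportions
#'
#' Computes the percentage of individuals injured in each season, overall
#' and by sex, over individuals with known status for that season (an
#' athlete with unknown season-two status is excluded from the season-two
#' denominator). Percentages are reported to one decimal and, for
#' display, rounded to the nearest integer.
#'
#' @param injury_table Data frame with columns `individual_id`, `sex`,
#'   `season1_injured`, `season2_injured` (logical, `NA` allowed).
#' @return Data frame with columns `group` (`all`/`male`/`female`),
#'   `season` (1 or 2), `n_known`, `n_injured`, `pct` (one decimal),
#'   `pct_display` (integer).
#' @examples
#' spec <- default_cohort_spec()
#' cohort_injury_summary(spec$injury_table)
#' @export
cohort_injury_summary <- function(injury_table) {
  if (is.null(injury_table) || nrow(injury_table) == 0) {
    stop("injury table is empty", call. = FALSE)
  }
  stopifnot(all(c("sex", "season1_injured", "season2_injured") %in%
                  names(injury_table)))
  groups <- list(all = rep(TRUE, nrow(injury_table)),
                 male = injury_table$sex == "male",
                 female = injury_table$sex == "female")
  rows <- list()
  for (g in names(groups)) {
    for (season in 1:2) {
      status <- injury_table[[paste0("season", season, "_injured")]][groups[[g]]]
      known <- !is.na(status)
      n_known <- sum(known)
      n_inj <- sum(status[known])
      pct <- if (n_known > 0) round(100 * n_inj / n_known, 1) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, season = season, n_known = n_known, n_injured = n_inj,
        pct = pct, pct_display = round(pct), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
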