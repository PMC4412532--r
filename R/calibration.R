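## Reference-population score distributions under Hardy-Weinberg
## equilibrium (HWE): per locus, effect-allele dosage x ~ Binomial(2, p)
## with genotype probabilities ((1-p)^2, 2p(1-p), p^2), loci independent.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

additive_variants <- function(panel, combined_only = FALSE) {
  v <- if (inherits(panel, "injury_panel")) panel$variants else panel
  v <- v[v$effect_model == "additive", , drop = FALSE]
  if (combined_only) v <- v[v$in_combined_score, , drop = FALSE]
  v
}

new_score_distribution <- function(support, pmf, method, grid_step,
                                   n_samples = NULL, seed = NULL) {
  o <- order(support)
  structure(list(support = support[o], pmf = pmf[o], method = method,
                 grid_step = grid_step, n_samples = n_samples, seed = seed),
            class = "score_distribution")
}

#' Exact score distribution in an HWE reference population
#'
#' Computes the probability mass function of the additive score
#' S = sum(w_i * x_i) when each dosage x_i is drawn independently from
#' HWE genotype probabilities at the variant's effect-allele frequency.
#' The pmf is built by dynamic-programming convolution over loci, with
#' every per-dosage contribution snapped to a grid of width `grid_step`,
#' so the support stays small (a few thousand points for ~60 loci).
#'
#' @param variants An [injury_panel()] or a variant data frame with
#'   `weight` and `allele_freq`; only additive-model rows are used.
#' @param grid_step Score grid width (default 0.01 on the weight scale).
#' @param combined_only Restrict to the combined-score subset.
#' @return A `score_distribution`: `support` (strictly ascending grid
#'   values), `pmf` (sums to 1), `method = "exact"`, `grid_step`.
#' @examples
#' v <- data.frame(weight = 1, allele_freq = 0.5, effect_model = "additive",
#'                 in_combined_score = FALSE)
#' d <- exact_score_distribution(v, grid_step = 1)
#' rbind(d$support, d$pmf)  # HWE: 1/4, 1/2, 1/4
#' @export
exact_score_distribution <- function(variants, grid_step = 0.01,
                                     combined_only = FALSE) {
  if (!is.numeric(grid_step) || length(grid_step) != 1 || grid_step <= 0) {
    stop("grid_step must be a positive real", call. = FALSE)
  }
  v <- additive_variants(variants, combined_only)
  L <- nrow(v)
  if (L == 0) {
    return(new_score_distribution(0, 1, "exact", grid_step))
  }
  if (any(v$allele_freq <= 0 | v$allele_freq >= 1)) {
    stop("allele_freq must lie strictly in (0,1)", call. = FALSE)
  }
  ## pmf[i] is the probability of grid index off + i - 1
  pmf <- 1
  off <- 0L
  for (i in seq_len(L)) {
    p <- v$allele_freq[i]
    probs <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    shifts <- as.integer(round(c(0, 1, 2) * v$weight[i] / grid_step))
    lo <- off + min(shifts)
    hi <- off + length(pmf) - 1L + max(shifts)
    acc <- numeric(hi - lo + 1L)
    for (k in 1:3) {
      start <- off + shifts[k] - lo + 1L
      idx <- start:(start + length(pmf) - 1L)
      acc[idx] <- acc[idx] + probs[k] * pmf
    }
    pmf <- acc
    off <- lo
  }
  support <- (off + seq_along(pmf) - 1L) * grid_step
  keep <- pmf > 0
  new_score_distribution(support[keep], pmf[keep], "exact", grid_step)
}

#' Monte-Carlo score distribution in an HWE reference population
#'
#' Empirical counterpart of [exact_score_distribution()]: draws dosages
#' from Binomial(2, p) per locus, sums the weighted dosages, and snaps
#' scores to the grid. Reproducible given `seed`; used as an independent
#' cross-check of the exact convolution.
#'
#' @inheritParams exact_score_distribution
#' @param n_samples Number of simulated individuals (>= 1).
#' @param seed Integer seed (default 2015).
#' @return A `score_distribution` with `method = "monte_carlo"`.
#' @export
mc_score_distribution <- function(variants, n_samples, seed = 2015,
                                  grid_step = 0.01, combined_only = FALSE) {
  if (!is.numeric(n_samples) || length(n_samples) != 1 || n_samples < 1) {
    stop("n_samples must be a positive integer", call. = FALSE)
  }
  if (grid_step <= 0) stop("grid_step must be a positive real", call. = FALSE)
  n_samples <- as.integer(n_samples)
  v <- additive_variants(variants, combined_only)
  L <- nrow(v)
  scores <- if (L == 0) {
    numeric(n_samples)
  } else {
    with_seed(seed, {
      dos <- matrix(stats::rbinom(n_samples * L, 2L,
                                  rep(v$allele_freq, each = n_samples)),
                    nrow = n_samples)
      as.numeric(dos %*% v$weight)
    })
  }
  idx <- round(scores / grid_step)
  tab <- table(idx)
  support <- as.numeric(names(tab)) * grid_step
  new_score_distribution(support, as.numeric(tab) / n_samples,
                         "monte_carlo", grid_step,
                         n_samples = n_samples, seed = seed)
}

#' Mean of a score distribution
#' @param dist A `score_distribution`.
#' @return The expectation sum(support * pmf).
#' @export
score_dist_mean <- function(dist) {
  stopifnot(inherits(dist, "score_distribution"))
  sum(dist$support * dist$pmf)
}

#' Quantiles of a score distribution
#'
#' Convention for discrete pmfs: the q-quantile is the smallest support
#' value whose cumulative probability reaches q.
#'
#' @param dist A `score_distribution`.
#' @param probs Probabilities in (0, 1\].
#' @return Numeric vector of quantile values.
#' @export
score_dist_quantile <- function(dist, probs) {
  stopifnot(inherits(dist, "score_distribution"),
            all(probs > 0 & probs <= 1))
  cdf <- cumsum(dist$pmf)
  vapply(probs, function(q) {
    dist$support[which(cdf >= q - 1e-12)[1]]
  }, numeric(1))
}

#' @export
print.score_distribution <- function(x, ...) {
  cat(sprintf("<score_distribution> %s: %d support points in [%.4g, %.4g], grid %.3g\n",
              x$method, length(x$support), min(x$support), max(x$support),
              x$grid_step))
  if (x$method == "monte_carlo") {
    cat(sprintf("  n_samples %d, seed %d\n", x$n_samples, x$seed))
  }
  invisible(x)
}

#' Derive risk bins from a score distribution
#'
#' Cuts the reference distribution at the given cumulative probabilities
#' (default quintile cuts 0.2/0.4/0.6/0.8, giving five bins as in the
#' published combined bone-mineral-density score). Bin i is the half-open
#' interval \[edge_{i-1}, edge_i); the last bin is closed above. The
#' default 5-bin scheme carries the published bin odds as annotations:
#' the top bin's increased odds for osteoporosis (OR 1.56) and fracture
#' (OR 1.60), the bottom bin's decreased odds (0.38 and 0.54).
#'
#' @param dist A `score_distribution`.
#' @param quantiles Strictly ascending cut probabilities in (0,1).
#' @param annotations Optional character vector, one per bin.
#' @return An object of class `bin_scheme`: `edges`, `quantiles`,
#'   `n_bins`, `annotations`.
#' @export
derive_bins <- function(dist, quantiles = c(0.2, 0.4, 0.6, 0.8),
                        annotations = NULL) {
  stopifnot(inherits(dist, "score_distribution"))
  if (length(quantiles) == 0 || any(quantiles <= 0 | quantiles >= 1) ||
      is.unsorted(quantiles, strictly = TRUE)) {
    stop("quantiles must be strictly ascending within (0,1)", call. = FALSE)
  }
  n_bins <- length(quantiles) + 1L
  if (is.null(annotations)) annotations <- default_bin_annotations(n_bins)
  stopifnot(length(annotations) == n_bins)
  structure(list(edges = score_dist_quantile(dist, quantiles),
                 quantiles = quantiles, n_bins = n_bins,
                 annotations = annotations),
            class = "bin_scheme")
}

default_bin_annotations <- function(n_bins) {
  ann <- sprintf("bin %d of %d of the reference score distribution",
                 seq_len(n_bins), n_bins)
  if (n_bins == 5) {
    ann[1] <- paste("lowest risk quintile: decreased odds of osteoporosis",
                    "(OR 0.38) and fracture (OR 0.54)")
    ann[5] <- paste("highest risk quintile: increased odds of osteoporosis",
                    "(OR 1.56) and fracture (OR 1.60)")
  }
  ann
}

#' Assign a score to a risk bin
#'
#' @param score Numeric score(s).
#' @param scheme A [derive_bins()] scheme.
#' @return Integer bin index in 1..n_bins; scores below the first edge
#'   fall in bin 1, scores at or above the last edge in the last bin.
#' @export
assign_bin <- function(score, scheme) {
  stopifnot(inherits(scheme, "bin_scheme"))
  findInterval(score, scheme$edges) + 1L
}

risk_tiers <- c("decreased", "average", "slightly_increased", "increased")
tier_color_map <- c(decreased = "green", average = "black",
                    slightly_increased = "yellow", increased = "red")

#' Map a score to one of the four report risk tiers
#'
#' The report uses four colour-coded risk levels: decreased (green),
#' average (black), slightly increased (yellow), increased (red). For a
#' 5-bin scheme the mapping is bin 1 -> decreased, bins 2-3 -> average,
#' bin 4 -> slightly increased, bin 5 -> increased; for other bin counts
#' the first bin is decreased, the last increased, the second-to-last
#' slightly increased, and the rest average.
#'
#' @inheritParams assign_bin
#' @return Character vector of tiers.
#' @export
assign_tier <- function(score, scheme) {
  tiers <- tier_for_bins(scheme$n_bins)
  tiers[assign_bin(score, scheme)]
}

tier_for_bins <- function(n_bins) {
  tiers <- rep("average", n_bins)
  tiers[1] <- "decreased"
  if (n_bins >= 2) tiers[n_bins] <- "increased"
  if (n_bins >= 4) tiers[n_bins - 1] <- "slightly_increased"
  tiers
}

#' Risk tier for a single-SNP finding
#'
#' Dosage-based tier for categories judged from a named SNP rather than a
#' calibrated score: any copy of a large-effect risk allele is increased
#' risk; one copy at a medium-effect site slightly increased, two copies
#' increased; zero copies at a site with protective evidence decreased;
#' anything else (including a missing dosage) average.
#'
#' @param dosage Effect-allele dosage (0/1/2 or `NA`).
#' @param effect_class `"small"`, `"medium"` or `"large"` (see
#'   [classify_effect_size()]).
#' @param protective Does the evidence at this site support protection
#'   when the risk allele is absent?
#' @return One of the four tiers.
#' @export
tier_for_dosage <- function(dosage, effect_class, protective = FALSE) {
  effect_class <- as.character(effect_class)
  if (is.na(dosage)) return("average")
  if (effect_class == "large" && dosage >= 1) return("increased")
  if (effect_class == "medium" && dosage == 2) return("increased")
  if (effect_class == "medium" && dosage == 1) return("slightly_increased")
  if (protective && dosage == 0) return("decreased")
  "average"
}

#' Tier/colour lookup
#'
#' The report's four tiers map bijectively onto colours: decreased is
#' green, average black, slightly increased yellow, increased red.
#'
#' @param tier Character vector of tiers.
#' @return Colours for `tier_color()`.
#' @export
tier_color <- function(tier) {
  unname(tier_color_map[match(tier, names(tier_color_map))])
}

#' @rdname tier_color
#' @param color Character vector of colours.
#' @export
color_tier <- function(color) {
  names(tier_color_map)[match(color, tier_color_map)]
}

#' Serialize a score distribution to TSV
#'
#' Calibrations are cacheable: the support/pmf table is written with the
#' method, grid step and (for Monte-Carlo) sample count and seed recorded
#' in comment lines, and [read_score_distribution()] restores the object.
#'
#' @param dist A `score_distribution`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "score_distribution"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# method: %s", dist$method), con)
  writeLines(sprintf("# grid_step: %.17g", dist$grid_step), con)
  if (!is.null(dist$n_samples)) {
    writeLines(sprintf("# n_samples: %d", dist$n_samples), con)
  }
  if (!is.null(dist$seed)) writeLines(sprintf("# seed: %d", dist$seed), con)
  writeLines("support\tpmf", con)
  writeLines(sprintf("%.17g\t%.17g", dist$support, dist$pmf), con)
  invisible(path)
}

#' @rdname write_score_distribution
#' @export
read_score_distribution <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta <- function(key) {
    m <- grep(sprintf("^#\\s*%s\\s*:", key), lines, value = TRUE)
    if (length(m)) trimws(sub(sprintf("^#\\s*%s\\s*:", key), "", m[1])) else NULL
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  df <- utils::read.delim(text = body, header = TRUE, sep = "\t")
  ns <- meta("n_samples")
  sd <- meta("seed")
  new_score_distribution(df$support, df$pmf, meta("method"),
                         as.numeric(meta("grid_step")),
                         n_samples = if (!is.null(ns)) as.integer(ns),
                         seed = if (!is.null(sd)) as.integer(sd))
}

#' Serialize a bin scheme to TSV
#'
#' @param scheme A `bin_scheme`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bin_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "bin_scheme"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# quantiles: %s",
                     paste(sprintf("%.17g", scheme$quantiles), collapse = ",")), con)
  writeLines("bin\tlower_edge\tannotation", con)
  lower <- c(NA, scheme$edges)
  writeLines(sprintf("%d\t%s\t%s", seq_len(scheme$n_bins),
                     ifelse(is.na(lower), "NA", sprintf("%.17g", lower)),
                     scheme$annotations), con)
  invisible(path)
}

#' @rdname write_bin_scheme
#' @export
read_bin_scheme <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  qline <- grep("^#\\s*quantiles\\s*:", lines, value = TRUE)
  quantiles <- as.numeric(strsplit(trimws(sub("^#\\s*quantiles\\s*:", "",
                                              qline[1])), ",")[[1]])
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  df <- utils::read.delim(text = body, header = TRUE, sep = "\t",
                          na.strings = "NA", colClasses = "character")
  structure(list(edges = as.numeric(df$lower_edge[-1]),
                 quantiles = quantiles, n_bins = nrow(df),
                 annotations = df$annotation),
            class = "bin_scheme")
}
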