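test_that("single-locus exact distribution is the HWE genotype law", {
  v <- variant_row(weight = 1, allele_freq = 0.5)
  d <- exact_score_distribution(v, grid_step = 1)
  expect_equal(d$support, c(0, 1, 2))
  expect_equal(d$pmf, c(0.25, 0.5, 0.25))
  expect_equal(sum(d$pmf), 1, tolerance = 1e-12)
})

test_that("equal-weight exact convolution equals the binomial closed form", {
  n <- 8
  p <- 0.3
  v <- variant_block(n, weight = 1, allele_freq = p)
  d <- exact_score_distribution(v, grid_step = 1)
  # sum of n iid Binomial(2, p) dosages is Binomial(2n, p)
  expect_equal(d$support, 0:(2 * n))
  expect_equal(d$pmf, stats::dbinom(0:(2 * n), 2 * n, p), tolerance = 1e-12)
})

test_that("degenerate inputs: zero loci and invalid grid", {
  v0 <- variant_row()[0, ]
  d <- exact_score_distribution(v0)
  expect_equal(d$support, 0)
  expect_equal(d$pmf, 1)
  expect_error(exact_score_distribution(variant_row(), grid_step = 0),
               "grid_step")
  expect_error(exact_score_distribution(variant_row(), grid_step = -1),
               "grid_step")
  expect_error(mc_score_distribution(variant_row(), n_samples = 0),
               "n_samples")
})

test_that("exact pmf sums to one and matches the analytic mean", {
  panel <- fixture_panel()
  d <- exact_score_distribution(panel, combined_only = TRUE)
  expect_equal(sum(d$pmf), 1, tolerance = 1e-9)
  expect_false(is.unsorted(d$support, strictly = TRUE))
  v <- panel$variants[panel$variants$in_combined_score, ]
  analytic <- sum(v$weight * 2 * v$allele_freq)
  # each locus contributes at most grid_step/2 of snapping error to the mean
  expect_equal(score_dist_mean(d), analytic,
               tolerance = nrow(v) * d$grid_step / 2 / abs(analytic))
})

test_that("Monte-Carlo calibration is reproducible and HWE-consistent", {
  v <- variant_row(weight = 1, allele_freq = 0.5)
  d1 <- mc_score_distribution(v, 20000, seed = 99, grid_step = 1)
  d2 <- mc_score_distribution(v, 20000, seed = 99, grid_step = 1)
  expect_identical(d1, d2)
  # genotype fractions approach (0.25, 0.5, 0.25) within 3 SE
  se <- 3 * sqrt(0.25 * 0.75 / 20000)
  expect_equal(d1$support, c(0, 1, 2))
  expect_lt(abs(d1$pmf[1] - 0.25), se)
  expect_lt(abs(d1$pmf[3] - 0.25), se)
  expect_lt(abs(d1$pmf[2] - 0.5), 3 * sqrt(0.5 * 0.5 / 20000))
})

test_that("Monte-Carlo quantiles agree with the exact convolution", {
  panel <- fixture_panel()
  exact <- exact_score_distribution(panel, combined_only = TRUE)
  n <- 100000
  mc <- mc_score_distribution(panel, n, seed = 2015, combined_only = TRUE)
  cdf <- cumsum(exact$pmf)
  step_mass <- max(exact$pmf)
  for (p in c(0.2, 0.4, 0.6, 0.8)) {
    q_mc <- score_dist_quantile(mc, p)
    f_at_q <- max(cdf[exact$support <= q_mc + 1e-9], 0)
    # exact CDF at the MC quantile within 3 binomial SE plus grid slack
    expect_lt(abs(f_at_q - p),
              3 * sqrt(p * (1 - p) / n) + 2 * step_mass)
  }
})

test_that("quantile convention takes the smallest support value reaching q", {
  d <- injuryrisk:::new_score_distribution(c(-1, 1), c(0.5, 0.5), "exact", 1)
  expect_equal(score_dist_quantile(d, 0.5), -1)
  expect_equal(score_dist_quantile(d, 0.51), 1)
  expect_equal(score_dist_quantile(d, c(0.2, 1)), c(-1, 1))
})

test_that("default binning yields five quintile bins with the published odds", {
  panel <- fixture_panel()
  d <- exact_score_distribution(panel, combined_only = TRUE)
  scheme <- derive_bins(d)
  expect_s3_class(scheme, "bin_scheme")
  expect_equal(scheme$n_bins, 5L)
  expect_equal(length(scheme$edges), 4L)
  expect_false(is.unsorted(scheme$edges))
  expect_match(scheme$annotations[5], "1.56", fixed = TRUE)
  expect_match(scheme$annotations[5], "1.60", fixed = TRUE)
  expect_match(scheme$annotations[1], "0.38", fixed = TRUE)
  expect_match(scheme$annotations[1], "0.54", fixed = TRUE)
  expect_error(derive_bins(d, quantiles = c(0.4, 0.2)), "ascending")
  expect_error(derive_bins(d, quantiles = c(0, 0.5)), "ascending|within")
})

test_that("each default bin captures a fifth of the generating mass", {
  panel <- fixture_panel()
  d <- exact_score_distribution(panel, combined_only = TRUE)
  scheme <- derive_bins(d)
  bins <- assign_bin(d$support, scheme)
  mass <- vapply(1:5, function(b) sum(d$pmf[bins == b]), numeric(1))
  # discretization slack: at most one support point's mass at each edge
  expect_true(all(abs(mass - 0.2) <= 2 * max(d$pmf) + 1e-9))
})

test_that("degenerate point-mass distributions put every score in the last bin", {
  d <- injuryrisk:::new_score_distribution(0.7, 1, "exact", 0.01)
  scheme <- derive_bins(d)
  expect_true(all(scheme$edges == 0.7))
  expect_equal(assign_bin(0.7, scheme), 5L)
  expect_equal(assign_tier(0.7, scheme), "increased")
})

test_that("bins are half-open below and tier assignment is monotone", {
  panel <- fixture_panel()
  scheme <- derive_bins(exact_score_distribution(panel, combined_only = TRUE))
  # a score exactly on an edge belongs to the upper bin
  expect_equal(assign_bin(scheme$edges[1], scheme), 2L)
  expect_equal(assign_bin(scheme$edges[1] - 1e-9, scheme), 1L)
  scores <- seq(min(scheme$edges) - 1, max(scheme$edges) + 1, length.out = 101)
  tier_rank <- match(assign_tier(scores, scheme),
                     c("decreased", "average", "slightly_increased", "increased"))
  expect_true(all(diff(tier_rank) >= 0))
  # 5-bin map: 1 decreased, 2-3 average, 4 slightly increased, 5 increased
  mids <- c(min(scheme$edges) - 1, scheme$edges + 1e-9)
  expect_equal(assign_tier(mids, scheme),
               c("decreased", "average", "average", "slightly_increased",
                 "increased"))
})

test_that("tier and colour are in bijection", {
  tiers <- c("decreased", "average", "slightly_increased", "increased")
  expect_equal(tier_color(tiers), c("green", "black", "yellow", "red"))
  expect_equal(color_tier(tier_color(tiers)), tiers)
})

test_that("single-SNP dosage tiers follow the effect-size rule table", {
  expect_equal(tier_for_dosage(2, classify_effect_size(11)), "increased")
  expect_equal(tier_for_dosage(1, "large"), "increased")
  expect_equal(tier_for_dosage(1, "medium"), "slightly_increased")
  expect_equal(tier_for_dosage(2, "medium"), "increased")
  expect_equal(tier_for_dosage(0, "large", protective = TRUE), "decreased")
  expect_equal(tier_for_dosage(0, "large"), "average")
  expect_equal(tier_for_dosage(1, "small"), "average")
  expect_equal(tier_for_dosage(NA, "large"), "average")
})

test_that("score distributions and bin schemes serialize to TSV and back", {
  panel <- fixture_panel()
  d <- mc_score_distribution(panel, 5000, seed = 7, combined_only = TRUE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_score_distribution(d, path)
  back <- read_score_distribution(path)
  expect_equal(back$support, d$support)
  expect_equal(back$pmf, d$pmf)
  expect_equal(back$method, "monte_carlo")
  expect_equal(back$n_samples, d$n_samples)
  expect_equal(back$seed, d$seed)

  scheme <- derive_bins(d)
  spath <- withr::local_tempfile(fileext = ".tsv")
  write_bin_scheme(scheme, spath)
  sback <- read_bin_scheme(spath)
  expect_equal(sback$edges, scheme$edges)
  expect_equal(sback$quantiles, scheme$quantiles)
  expect_equal(sback$annotations, scheme$annotations)
  expect_equal(sback$n_bins, scheme$n_bins)
})
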