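Package: injuryrisk
Title: Genotype-Based Sports Injury Risk Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assess an athlete's genetic predisposition to common sports
    injuries from a direct-to-consumer raw genotype file. Loads and
    validates a curated panel of injury-associated SNPs spanning six
    categories (ACL rupture, Achilles tendon injury, bone mineral density,
    osteoarthritis, vitamin/mineral deficiencies, sickle cell trait),
    reconciles effect alleles against unphased genotype calls including
    strand flips, computes additive polygenic scores and a Mendelian
    sickle-cell-trait call, calibrates scores against an exact
    Hardy-Weinberg reference distribution with quintile binning, and
    renders a four-tier colour-coded risk report. Includes a seeded
    synthetic cohort generator so the full pipeline runs without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
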