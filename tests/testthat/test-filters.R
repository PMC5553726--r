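test_that("quality thresholds use inclusive depth and strict genotype quality", {
  va <- simple_variants(4)
  geno <- matrix(c(2L, 2L, 2L, NA), 4, 1, dimnames = list(NULL, "P"))
  dp <- matrix(c(15, 14, 30, 50), 4, 1)
  gq <- matrix(c(21, 99, 20, 99), 4, 1)
  co <- make_cohort(va, geno, dp, gq, "P")
  expect_equal(quality_pass(co, "P"),
               c(TRUE,   # DP 15 / GQ 21: both boundaries in the keep region
                 FALSE,  # DP 14 fails the >=15 bound
                 FALSE,  # GQ 20 fails the strict >20 bound
                 FALSE)) # missing genotype fails regardless of DP/GQ
  expect_error(quality_pass(co, "NOBODY"), "unknown sample")
})

test_that("frequency exclusion is strict-greater with missing sources passing", {
  va <- simple_variants(4)
  va$freq_dbsnp <- c(0.02, NA, NA, 0.004)
  va$freq_1kgp <- c(NA, NA, 0.01, NA)
  co <- make_cohort(va, matrix(2L, 4, 1, dimnames = list(NULL, "P")))
  expect_equal(frequency_pass(co, 0.01),
               c(FALSE,  # 0.02 > 0.01 excluded
                 TRUE,   # all sources missing: a novel variant passes
                 TRUE,   # equality is not "> threshold"
                 TRUE))
  # strict mode: pass only when every reported frequency is < threshold
  expect_equal(frequency_pass(co, 0.005, strict = TRUE),
               c(FALSE, TRUE, FALSE, TRUE))
  strict_eq <- make_cohort(dplyr::mutate(simple_variants(1), freq_dbsnp = 0.005),
                           matrix(2L, 1, 1, dimnames = list(NULL, "P")))
  expect_false(frequency_pass(strict_eq, 0.005, strict = TRUE))
})

test_that("effect filter keeps HIGH/MODERATE and spares splice-linked intronic terms", {
  va <- simple_variants(5)
  va$impact <- c("HIGH", "LOW", "MODIFIER", "MODERATE", "MODERATE")
  va$consequence <- c("stop_gained", "synonymous_variant",
                      "splice_donor_variant&intron_variant",
                      "missense_variant", "synonymous_variant")
  co <- make_cohort(va, matrix(2L, 5, 1, dimnames = list(NULL, "P")))
  expect_equal(effect_pass(co), c(TRUE, FALSE, FALSE, TRUE, FALSE))
  # the splice-linked intronic consequence is spared once its impact is kept
  cfg_all <- filter_config(impact_keep = impact_levels())
  expect_true(effect_pass(co, cfg_all)[3])
  intronic <- make_cohort(
    dplyr::mutate(simple_variants(1), impact = "MODIFIER",
                  consequence = "intron_variant"),
    matrix(2L, 1, 1, dimnames = list(NULL, "P")))
  expect_false(effect_pass(intronic, cfg_all))
  bad <- make_cohort(simple_variants(1), matrix(2L, 1, 1, dimnames = list(NULL, "P")))
  bad$variants$impact <- "SEVERE"
  expect_error(effect_pass(bad), "unknown impact")
})

test_that("the cascade keeps exactly the designed survivors with a faithful audit", {
  # 20 hand-built variants; rows 1-3 pass everything, the rest each have
  # one designed defect (checked against independent per-row evaluation)
  n <- 20
  va <- simple_variants(n)
  va$impact <- rep("MODERATE", n)
  va$consequence <- rep("missense_variant", n)
  va$freq_dbsnp <- NA_real_
  geno <- matrix(2L, n, 1, dimnames = list(NULL, "P"))
  dp <- matrix(40, n, 1); gq <- matrix(90, n, 1)
  dp[4:8] <- 10                       # quality: shallow
  gq[9:10] <- 15                      # quality: low GQ
  geno[11] <- NA                      # quality: missing call
  va$freq_dbsnp[12:14] <- 0.05        # frequency
  va$impact[15:17] <- "MODIFIER"      # effect: impact
  va$consequence[15:17] <- "intron_variant"
  va$impact[18:20] <- "LOW"           # effect: synonymous
  va$consequence[18:20] <- "synonymous_variant"
  co <- make_cohort(va, geno, dp, gq, "P")

  # independent oracle: evaluate the three predicates row by row
  cfg <- filter_config()
  expected <- vapply(seq_len(n), function(i) {
    q <- !is.na(geno[i]) && dp[i] >= 15 && gq[i] > 20
    f <- is.na(va$freq_dbsnp[i]) || va$freq_dbsnp[i] <= 0.01
    e <- va$impact[i] %in% c("HIGH", "MODERATE") &&
      !va$consequence[i] %in% c("synonymous_variant", "intron_variant")
    q && f && e
  }, logical(1))
  expect_equal(which(expected), 1:3)

  res <- apply_cascade(co, "P", cfg)
  expect_equal(res$audit$pass, expected)
  expect_equal(n_variants(res$cohort), 3)
  expect_equal(res$audit$first_fail[4], "quality")
  expect_equal(res$audit$first_fail[12], "frequency")
  expect_equal(res$audit$first_fail[15], "effect")
  expect_true(all(is.na(res$audit$first_fail[1:3])))
  expect_true(all(diff(res$stage_counts) <= 0))
})

test_that("vacuous thresholds keep every called genotype", {
  co <- random_cohort(50, seed = 7)
  cfg <- filter_config(min_depth = 0, min_gq = 0, max_freq_standard = 1,
                       max_freq_strict = 1, impact_keep = impact_levels(),
                       exclude_consequences = character(0))
  res <- apply_cascade(co, "P", cfg)
  called <- !is.na(co$geno[, "P"]) & co$gq[, "P"] > 0
  expect_equal(res$audit$pass, unname(called))
})

test_that("the cascade is a pure conjunction: order-independent and monotone", {
  for (seed in 1:5) {
    co <- random_cohort(60, seed = seed)
    cfg <- filter_config()
    q <- quality_pass(co, "P", cfg)
    f <- frequency_pass(co, cfg$max_freq_standard)
    e <- effect_pass(co, cfg)
    res <- apply_cascade(co, "P", cfg)
    # any evaluation order of the predicates gives the same survivor set
    expect_equal(res$audit$pass, e & q & f)
    expect_equal(res$audit$pass, f & e & q)

    # frequency monotonicity: survivors at t1 <= t2 are nested
    s1 <- frequency_pass(co, 0.005)
    s2 <- frequency_pass(co, 0.02)
    expect_true(all(!s1 | s2))

    # raising depth/GQ thresholds never adds survivors
    strict_q <- quality_pass(co, "P", filter_config(min_depth = 30, min_gq = 50))
    expect_true(all(!strict_q | q))
  }
})
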