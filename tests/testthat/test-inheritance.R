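test_that("homozygous candidate selection keeps 1/1 and drops het/missing", {
  va <- simple_variants(3, gene = "BBS2")
  va$impact <- "HIGH"; va$consequence <- "stop_gained"
  geno <- matrix(c(2L, 1L, NA), 3, 1, dimnames = list(NULL, "P"))
  co <- make_cohort(va, geno, samples = "P")
  hom <- homozygous_candidates(co, "P")
  expect_equal(n_variants(hom), 1)
  expect_equal(hom$variants$pos, 1000L)
  expect_error(homozygous_candidates(co, "X"), "unknown sample")
  # a variant cannot feed both inheritance models
  het_ids <- co$variants$variant_id[!is.na(co$geno[, "P"]) & co$geno[, "P"] == 1]
  expect_length(intersect(hom$variants$variant_id, het_ids), 0)
})

comphet_cohort <- function(geno_father, geno_mother, geno_p = c(1L, 1L)) {
  va <- simple_variants(length(geno_p), gene = "MKKS")
  geno <- cbind(F1_F = geno_father, F1_M = geno_mother, F1_P = geno_p)
  make_cohort(va, geno, samples = colnames(geno))
}

f1_ped <- function() {
  as_pedigree(tibble::tibble(
    family = "F1", id = c("F1_F", "F1_M", "F1_P"),
    father = c(NA, NA, "F1_F"), mother = c(NA, NA, "F1_M"),
    sex = c("male", "female", "female"),
    affected = c("unaffected", "unaffected", "affected")))
}

test_that("compound-het phase is resolved from parental carriage", {
  ped <- f1_ped()
  trans <- compound_het_candidates(comphet_cohort(c(1L, 0L), c(0L, 1L)),
                                   "MKKS", "F1_P", ped)
  expect_equal(trans$phase_status, "trans_confirmed")
  cis <- compound_het_candidates(comphet_cohort(c(0L, 0L), c(1L, 1L)),
                                 "MKKS", "F1_P", ped)
  expect_equal(cis$phase_status, "cis_excluded")
  # parents not genotyped: restrict the cohort to the proband
  solo <- comphet_cohort(c(1L, 0L), c(0L, 1L))
  solo_co <- make_cohort(solo$variants,
                         solo$geno[, "F1_P", drop = FALSE], samples = "F1_P")
  unknown <- compound_het_candidates(solo_co, "MKKS", "F1_P", ped)
  expect_equal(unknown$phase_status, "phase_unknown")
  # fewer than two het variants: no call
  expect_null(compound_het_candidates(comphet_cohort(1L, 0L, geno_p = 1L),
                                      "MKKS", "F1_P", ped))
})

test_that("compound-het calls match brute-force pair enumeration", {
  ped <- f1_ped()
  set.seed(11)
  for (rep in 1:60) {
    k <- sample(2:6, 1)
    gf <- sample(0:1, k, replace = TRUE)
    gm <- sample(0:1, k, replace = TRUE)
    co <- comphet_cohort(as.integer(gf), as.integer(gm),
                         geno_p = rep(1L, k))
    got <- compound_het_candidates(co, "MKKS", "F1_P", ped)$phase_status
    expect_equal(got, comphet_oracle(co, "MKKS", "F1_P", ped))
  }
})

test_that("segregation check applies autosomal-recessive carrier logic", {
  ped6 <- as_pedigree(tibble::tibble(
    family = "F6", id = c("F6_F", "F6_M", "F6_P", "F6_S"),
    father = c(NA, NA, "F6_F", "F6_F"), mother = c(NA, NA, "F6_M", "F6_M"),
    sex = c("male", "female", "female", "male"),
    affected = c("unaffected", "unaffected", "affected", "unknown")))
  # classic trio: both parents obligate carriers
  expect_equal(segregation_check(c(F6_P = 2L, F6_M = 1L, F6_F = 1L), ped6, "F6_P"),
               "consistent")
  # carrier sibling of unknown affection status does not contradict AR
  expect_equal(segregation_check(c(F6_P = 2L, F6_M = 1L, F6_F = 1L, F6_S = 1L),
                                 ped6, "F6_P"), "consistent")
  # an unaffected homozygous mother contradicts the model
  expect_equal(segregation_check(c(F6_P = 2L, F6_M = 2L), ped6, "F6_P"),
               "inconsistent")
  # a het affected sibling points to a different cause in that sibling
  ped6b <- ped6; ped6b$affected[4] <- "affected"
  expect_equal(segregation_check(c(F6_P = 2L, F6_M = 1L, F6_F = 1L, F6_S = 1L),
                                 ped6b, "F6_P"), "inconsistent")
  # nobody else genotyped
  expect_equal(segregation_check(c(F6_P = 2L), ped6, "F6_P"), "untestable")
  expect_error(segregation_check(c(F6_P = 1L, F6_M = 1L), ped6, "F6_P"),
               "homozygous")
})

test_that("planted recessive variants segregate consistently across seeded trios", {
  small <- function(seed) sim_config(seed = seed, n_background_hom_after_qc = 15,
                                     marker_density = 4)
  arch3 <- case_archetypes()[[3]]  # trio family
  ok <- 0L
  for (seed in 1:100) {
    fam <- simulate_family(arch3, small(seed))
    g <- setNames(as.integer(fam$cohort$geno[fam$truth$causal_ids, , drop = FALSE]),
                  fam$cohort$samples)
    if (segregation_check(g, fam$pedigree, fam$proband) == "consistent") ok <- ok + 1L
  }
  expect_equal(ok, 100L)
})
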