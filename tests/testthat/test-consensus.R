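published_calls <- function() {
  utils::read.table(system.file("extdata", "ciliopathy_variant_predictions.tsv",
                                package = "ciliowes"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

test_that("protein consensus reproduces the published scores, truncating included", {
  calls <- published_calls()
  sc <- protein_consensus(calls$polyphen2, calls$sift,
                          calls$mutation_taster, calls$lrt)
  expected <- c(BBS2.1 = 2L, BBS2.2 = 2L, ALMS1 = 2L, CORO2B = 3L,
                SLC3A1 = 3L, LMO7 = 4L, ZNF17 = 2L)
  expect_equal(sc$positives, unname(expected))
  # the denominator never shrinks when PolyPhen-2/SIFT cannot be run
  expect_true(all(sc$denominator == 4L))
  expect_equal(sc$applicable[calls$consequence == "stop_gained"], rep(2L, 4))
  expect_equal(sc$score[calls$gene == "LMO7"], "4/4")
})

test_that("positives equal the sum of per-tool indicators for any call mix", {
  vocab <- default_predictor_vocab()
  pp2 <- c("Probably damaging", "Possibly damaging", "Benign", "not_applicable")
  sift <- c("Damaging", "Tolerated", "not_applicable")
  mt <- c("Disease-causing", "Polymorphism")
  lrt <- c("Deleterious", "Neutral", "Unknown")
  grid <- expand.grid(pp2 = pp2, sift = sift, mt = mt, lrt = lrt,
                      stringsAsFactors = FALSE)
  sc <- protein_consensus(grid$pp2, grid$sift, grid$mt, grid$lrt)
  # independent count: classify each call by direct vocabulary lookup
  is_pos <- function(call, pos_set) {
    norm <- gsub("[_-]", " ", tolower(call))
    norm %in% pos_set
  }
  expected <- mapply(function(a, b, c, d) {
    is_pos(a, c("probably damaging", "possibly damaging")) +
      is_pos(b, "damaging") + is_pos(c, "disease causing") +
      is_pos(d, "deleterious")
  }, grid$pp2, grid$sift, grid$mt, grid$lrt, USE.NAMES = FALSE)
  expect_equal(sc$positives, as.integer(expected))
  # the count only depends on how many tools are positive, not which
  expect_equal(
    protein_consensus("Probably damaging", "Tolerated", "Polymorphism", "Deleterious")$positives,
    protein_consensus("Benign", "Damaging", "Disease-causing", "Neutral")$positives)
})

test_that("unrecognized predictor calls fail loudly, naming the tool", {
  expect_error(protein_consensus("Probably damaging", "Damaging",
                                 "definitely fine", "Neutral"),
               "mutation_taster")
})

test_that("splice consensus counts positives over a fixed denominator of four", {
  sp <- read.table(system.file("extdata", "ciliopathy_variant_splicing.tsv",
                               package = "ciliowes"),
                   header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  sc <- splice_consensus(sp$nnsplice, sp$netgene2, sp$hsf, sp$asseda)
  expect_equal(sc$positives, 3L)
  expect_equal(sc$score, "3/4")
  expect_equal(splice_consensus("negative", "negative", "negative", "negative")$positives, 0L)
  expect_equal(splice_consensus("positive", "positive", "positive", "positive")$score, "4/4")
  # a tool that was not run counts as negative, not as a smaller panel
  nr <- splice_consensus("positive", "positive", "not_run", "positive")
  expect_equal(nr$positives, 3L)
  expect_equal(nr$denominator, 4L)
  expect_error(splice_consensus("not_run", "not_run", "not_run", "not_run"),
               "no tool was run")
})

test_that("minimum-positive threshold is monotone and respects boundaries", {
  sc <- protein_consensus(c("Probably damaging", "Benign", "not_applicable"),
                          c("Tolerated", "Tolerated", "not_applicable"),
                          c("Disease-causing", "Polymorphism", "Disease-causing"),
                          c("Neutral", "Neutral", "Deleterious"))
  expect_equal(passes_min_positive(sc, 2), c(TRUE, FALSE, TRUE))
  expect_equal(passes_min_positive(sc, 0), c(TRUE, TRUE, TRUE))
  for (k in 0:3) {
    expect_true(all(passes_min_positive(sc, k + 1) <= passes_min_positive(sc, k)))
  }
})
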