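toy_features <- function() {
  list(src1 = list(T1 = c("a", "b", "c"), T2 = c("d", "e"),
                   CAND1 = c("a", "b", "c"), CAND2 = c("x", "y"),
                   CAND3 = c("A", "B")))
}

test_that("source similarity is the best Jaccard match against the training set", {
  f <- toy_features()$src1
  expect_equal(source_similarity("CAND1", c("T1", "T2"), f), 1.0)
  expect_equal(source_similarity("CAND2", c("T1", "T2"), f), 0.0)
  # candidate {A,B} against best training gene {B,C} -> 1/3, verified by
  # brute force over all training genes
  f2 <- list(CAND = c("A", "B"), G1 = c("B", "C"), G2 = c("C", "D"),
             G3 = c("E", "F", "G"), G4 = "E", G5 = character(0))
  brute <- max(vapply(paste0("G", 1:5), function(g) {
    length(intersect(f2$CAND, f2[[g]])) / length(union(f2$CAND, f2[[g]]))
  }, numeric(1)))
  expect_equal(brute, 1 / 3)
  expect_equal(source_similarity("CAND", paste0("G", 1:5), f2), brute)
  # self-matches are excluded
  expect_equal(source_similarity("CAND1", c("CAND1"), f), 0.0)
})

test_that("rank fusion is the geometric mean of normalised informative ranks", {
  expect_equal(rank_fuse(matrix(c(1, 1, 1), 1), n = 10), 0.1)
  expect_equal(rank_fuse(matrix(c(1, 4), 1), n = 4), sqrt(0.25 * 1.0))
  # a source where every candidate ties contributes nothing
  m <- cbind(a = c(1, 2), b = c(1.5, 1.5))
  expect_equal(rank_fuse(m, 2), rank_fuse(m[, "a", drop = FALSE], 2))
  # no informative source: everyone at 1
  expect_equal(rank_fuse(cbind(c(1.5, 1.5)), 2), c(1, 1))
})

test_that("prioritisation is deterministic and handles degenerate inputs", {
  f <- toy_features()
  one <- prioritize_candidates("CAND2", c("T1", "T2"), f)
  expect_equal(one$rankings$full$final_rank, 1L)
  expect_equal(one$rankings$full$fused_score, 1)
  # all-disjoint candidates tie at 1 and order alphabetically
  f_dis <- list(s = list(T1 = "t", Z9 = "z", A1 = "a", M5 = "m"))
  r <- prioritize_candidates(c("Z9", "A1", "M5"), "T1", f_dis)$rankings$full
  expect_equal(r$gene, c("A1", "M5", "Z9"))
  expect_equal(r$fused_score, rep(1, 3))
  expect_equal(sort(r$final_rank), 1:3)
  # absent candidate warns and lands last
  expect_warning(out <- prioritize_candidates(c("CAND1", "GHOST"),
                                              c("T1", "T2"), f),
                 "GHOST")
  expect_equal(out$rankings$full$gene[out$rankings$full$final_rank == 2], "GHOST")
})

test_that("an uninformative source and duplicated features leave rankings unchanged", {
  set.seed(9)
  f <- build_feature_matrix(training = c("T1", "T2", "T3"),
                            promote = "GOOD", background = c("B1", "B2", "B3"))
  cands <- c("GOOD", "B1", "B2", "B3")
  base <- prioritize_candidates(cands, c("T1", "T2", "T3"), f)$rankings$full
  # add a source where every candidate has the same features
  f_flat <- c(f, list(flat = setNames(rep(list("same"), 7),
                                      c("T1", "T2", "T3", cands))))
  with_flat <- prioritize_candidates(cands, c("T1", "T2", "T3"),
                                     f_flat)$rankings$full
  expect_equal(with_flat[, c("gene", "final_rank")],
               base[, c("gene", "final_rank")])
  # duplicating every feature id preserves all Jaccard indices
  f_dup <- lapply(f, function(src) lapply(src, function(x) c(x, paste0(x, "#dup"))))
  dup <- prioritize_candidates(cands, c("T1", "T2", "T3"), f_dup)$rankings$full
  expect_equal(dup[, c("gene", "final_rank", "fused_score")],
               base[, c("gene", "final_rank", "fused_score")])
})

test_that("a planted high-similarity candidate is recovered at rank 1", {
  training <- sprintf("TR%02d", 1:10)
  hits <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    feats <- list()
    for (src in c("s1", "s2")) {
      pool <- sprintf("%s_f%03d", src, 1:80)
      m <- list()
      for (g in training) m[[g]] <- sample(pool, 8)
      # planted candidate: superset of one training gene's features
      m[["PLANT"]] <- c(m[[sample(training, 1)]], sample(pool, 2))
      for (b in sprintf("BG%02d", 1:7)) m[[b]] <- sample(pool, 8)
      feats[[src]] <- m
    }
    r <- prioritize_candidates(c("PLANT", sprintf("BG%02d", 1:7)),
                               training, feats)$rankings$full
    if (r$gene[r$final_rank == 1] == "PLANT") hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})
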