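#' Similarity of a candidate gene to a training set within one source
#'
#' The similarity is the maximum Jaccard index between the candidate's
#' feature set and each training gene's feature set for the given
#' evidence source. The candidate itself never contributes (self-matches
#' are excluded); a candidate with no features scores 0.
#'
#' @param candidate gene symbol.
#' @param training character vector of training gene symbols (or a
#'   `gene_panel`).
#' @param source_features named list gene -> feature ids for one source
#'   (see [read_feature_source()]).
#' @return Similarity in `[0, 1]`.
#' @export
source_similarity <- function(candidate, training, source_features) {
  if (inherits(training, "gene_panel")) training <- training$genes
  training <- setdiff(toupper(training), toupper(candidate))
  cand_set <- source_features[[candidate]]
  if (is.null(cand_set) || length(cand_set) == 0) return(0)
  best <- 0
  for (g in training) {
    tset <- source_features[[g]]
    if (is.null(tset) || length(tset) == 0) next
    j <- length(intersect(cand_set, tset)) / length(union(cand_set, tset))
    if (j > best) best <- j
  }
  best
}

#' Fuse per-source ranks into one score
#'
#' The fused score is the geometric mean of `rank / n` across evidence
#' sources (lower is better), an order-statistic stand-in for
#' kernel-based rank aggregation. Sources in which every candidate ties
#' are uninformative and are excluded from the mean; when no source is
#' informative every candidate receives fused score 1 and the final
#' ordering is alphabetical.
#'
#' @param rank_matrix numeric matrix (candidates x sources) of ranks in
#'   `1..n` (mid-ranked ties allowed).
#' @param n candidate count.
#' @return Numeric vector of fused scores in `(0, 1]`.
#' @export
rank_fuse <- function(rank_matrix, n) {
  rank_matrix <- as.matrix(rank_matrix)
  stopifnot(all(rank_matrix >= 1 - 1e-9), all(rank_matrix <= n + 1e-9))
  # a tie among all candidates makes a source uninformative; with a single
  # candidate's rank vector there is nothing to tie against
  informative <- if (nrow(rank_matrix) == 1) rep(TRUE, ncol(rank_matrix))
                 else apply(rank_matrix, 2, function(r) length(unique(r)) > 1)
  if (!any(informative)) return(rep(1, nrow(rank_matrix)))
  m <- rank_matrix[, informative, drop = FALSE] / n
  exp(rowMeans(log(m)))
}

rank_one_subset <- function(candidates, training_genes, features) {
  n <- length(candidates)
  sim <- sapply(names(features), function(src) {
    vapply(candidates, source_similarity, numeric(1),
           training = training_genes, source_features = features[[src]])
  })
  sim <- matrix(sim, nrow = n, dimnames = list(candidates, names(features)))
  ranks <- apply(sim, 2, function(s) rank(-s, ties.method = "average"))
  ranks <- matrix(ranks, nrow = n, dimnames = dimnames(sim))
  fused <- unname(rank_fuse(ranks, n))
  ord <- order(fused, candidates)
  final_rank <- integer(n)
  final_rank[ord] <- seq_len(n)
  out <- tibble::tibble(gene = candidates, fused_score = fused,
                        final_rank = final_rank)
  for (src in colnames(ranks)) out[[paste0("rank_", src)]] <- ranks[, src]
  out[order(out$final_rank), ]
}

#' Rank candidate genes by similarity to a ciliary training set
#'
#' Produces one ranking per training subset plus the full training set,
#' and reports which genes place in the top 2 under every subset.
#' Candidates absent from the feature matrix are kept (they rank last
#' with similarity 0) and a warning is issued.
#'
#' @param candidates character vector of candidate gene symbols (>= 1).
#' @param training a `gene_panel` (or character vector) of training
#'   genes.
#' @param features multi-source feature matrix from
#'   [read_feature_matrix()].
#' @param subsets optional named list of training-gene subsets; each is
#'   ranked in addition to the `full` set.
#' @return List with `rankings` (named list of tibbles: `gene`,
#'   `fused_score`, `final_rank`, per-source ranks) and `robust_top2`
#'   (genes in the top 2 of every subset).
#' @export
prioritize_candidates <- function(candidates, training, features,
                                  subsets = NULL) {
  if (length(candidates) < 1) stop("at least one candidate gene is required")
  candidates <- unique(toupper(candidates))
  if (inherits(training, "gene_panel")) training <- training$genes
  training <- toupper(training)
  known <- unique(unlist(lapply(features, names)))
  absent <- setdiff(candidates, known)
  if (length(absent) > 0) {
    warning("candidate gene(s) absent from the feature matrix (ranked last): ",
            paste(absent, collapse = ", "))
  }
  sets <- c(list(full = training), subsets)
  rankings <- lapply(sets, function(tr) {
    if (inherits(tr, "gene_panel")) tr <- tr$genes
    rank_one_subset(candidates, toupper(tr), features)
  })
  top2 <- lapply(rankings, function(r) r$gene[r$final_rank <= 2])
  robust <- Reduce(intersect, top2)
  list(rankings = rankings, robust_top2 = robust)
}
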