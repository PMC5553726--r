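#' Default call vocabularies for the four protein predictors
#'
#' Maps each tool's source vocabulary onto a positive (deleterious) or
#' negative class. PolyPhen-2 "possibly damaging" counts positive: the
#' consensus is a candidate screen, not a classifier, so the permissive
#' reading is used (this assumption is echoed in pipeline logs).
#' Matching is case-insensitive and tolerant of `_`/`-` separators.
#'
#' @return Named list: tool -> list(positive=, negative=) call strings.
#' @export
default_predictor_vocab <- function() {
  list(
    polyphen2 = list(
      positive = c("probably damaging", "possibly damaging"),
      negative = c("benign", "unknown")
    ),
    sift = list(
      positive = c("damaging", "deleterious"),
      negative = c("tolerated", "tolerated low confidence")
    ),
    mutation_taster = list(
      positive = c("disease causing", "disease causing automatic"),
      negative = c("polymorphism", "polymorphism automatic")
    ),
    lrt = list(
      positive = "deleterious",
      negative = c("neutral", "unknown")
    )
  )
}

normalize_call <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]_-]+", " ", x)
}

NOT_APPLICABLE <- "not_applicable"

classify_call <- function(call, tool, vocab) {
  if (is.na(call) || normalize_call(call) %in% c("not applicable", "na", "."))
    return("not_applicable")
  norm <- normalize_call(call)
  if (norm %in% normalize_call(vocab[[tool]]$positive)) return("positive")
  if (norm %in% normalize_call(vocab[[tool]]$negative)) return("negative")
  stop("unrecognized ", tool, " call: '", call, "'")
}

new_consensus_score <- function(positives, applicable, denominator = 4L) {
  stopifnot(all(positives >= 0), all(positives <= applicable),
            all(applicable <= denominator))
  tibble::tibble(positives = as.integer(positives),
                 denominator = as.integer(denominator),
                 applicable = as.integer(applicable),
                 score = sprintf("%d/%d", positives, denominator))
}

#' Consensus deleteriousness over the fixed four-predictor panel
#'
#' Counts positive calls from PolyPhen-2, SIFT, MutationTaster and LRT.
#' For truncating variants (stop-gain, frameshift) PolyPhen-2 and SIFT
#' cannot be run and are marked not-applicable, but the denominator
#' stays 4, so such variants score at most 2/4.
#'
#' @param polyphen2,sift,mutation_taster,lrt call strings (vectors of
#'   equal length); `NA` or `"not_applicable"` marks an inapplicable
#'   tool.
#' @param vocab call vocabulary, see [default_predictor_vocab()].
#' @return Tibble with `positives`, `denominator` (always 4),
#'   `applicable` and the printed `score` ("k/4").
#' @export
protein_consensus <- function(polyphen2, sift, mutation_taster, lrt,
                              vocab = default_predictor_vocab()) {
  calls <- cbind(polyphen2 = polyphen2, sift = sift,
                 mutation_taster = mutation_taster, lrt = lrt)
  classes <- matrix(NA_character_, nrow(calls), 4,
                    dimnames = list(NULL, colnames(calls)))
  for (tool in colnames(calls)) {
    classes[, tool] <- vapply(calls[, tool], classify_call, character(1),
                              tool = tool, vocab = vocab, USE.NAMES = FALSE)
  }
  new_consensus_score(rowSums(classes == "positive"),
                      rowSums(classes != "not_applicable"))
}

#' Consensus splicing alteration over the four splice tools
#'
#' Counts positive predictions from NNSplice, NetGene2, Human Splicing
#' Finder and ASSEDA. A tool that was not run counts as negative rather
#' than shrinking the denominator, matching the fixed "k/4"
#' presentation.
#'
#' @param nnsplice,netgene2,hsf,asseda call vectors with values
#'   `"positive"`, `"negative"` or `"not_run"` (`NA` = not run).
#' @return Tibble as in [protein_consensus()]; `applicable` is the
#'   number of tools actually run.
#' @export
splice_consensus <- function(nnsplice, netgene2, hsf, asseda) {
  calls <- cbind(nnsplice = nnsplice, netgene2 = netgene2,
                 hsf = hsf, asseda = asseda)
  norm <- apply(calls, c(1, 2), function(x) {
    if (is.na(x)) return("not_run")
    x <- normalize_call(x)
    if (x %in% c("positive", "+", "altered", "yes")) return("positive")
    if (x %in% c("negative", "-", "no", "unaffected")) return("negative")
    if (x %in% c("not run", "na", ".")) return("not_run")
    stop("unrecognized splice call: '", x, "'")
  })
  if (nrow(norm) > 0 && any(rowSums(norm != "not_run") == 0)) {
    stop("splice panel present but no tool was run")
  }
  new_consensus_score(rowSums(norm == "positive"), rowSums(norm != "not_run"))
}

#' Minimum-positive-predictions threshold
#'
#' TRUE iff the consensus has at least `k` positive calls (the
#' exome-wide escalation requires at least 2 of 4).
#'
#' @param score tibble from [protein_consensus()] / [splice_consensus()].
#' @param k required positive count, in 0..4.
#' @return Logical vector.
#' @export
passes_min_positive <- function(score, k = 2) {
  stopifnot(k >= 0, k <= 4)
  score$positives >= k
}

#' Score the variants of a cohort with both consensus panels
#'
#' @param cohort a [wes_cohort()].
#' @param vocab predictor vocabulary.
#' @return Tibble aligned with the variant rows: protein `positives`,
#'   `applicable`, `score`, plus `splice_positives`/`splice_score` (`NA`
#'   when no splice panel was recorded for the variant).
#' @export
score_cohort <- function(cohort, vocab = default_predictor_vocab()) {
  va <- cohort$variants
  if (nrow(va) == 0) {
    return(tibble::tibble(variant_id = character(0), positives = integer(0),
                          applicable = integer(0), score = character(0),
                          splice_positives = integer(0),
                          splice_score = character(0)))
  }
  prot <- protein_consensus(va$polyphen2, va$sift, va$mutation_taster, va$lrt,
                            vocab = vocab)
  has_splice <- !(is.na(va$nnsplice) & is.na(va$netgene2) &
                    is.na(va$hsf) & is.na(va$asseda))
  splice_positives <- rep(NA_integer_, nrow(va))
  splice_score <- rep(NA_character_, nrow(va))
  if (any(has_splice)) {
    sp <- splice_consensus(va$nnsplice[has_splice], va$netgene2[has_splice],
                           va$hsf[has_splice], va$asseda[has_splice])
    splice_positives[has_splice] <- sp$positives
    splice_score[has_splice] <- sp$score
  }
  tibble::tibble(variant_id = va$variant_id,
                 positives = prot$positives, applicable = prot$applicable,
                 score = prot$score,
                 splice_positives = splice_positives,
                 splice_score = splice_score)
}
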