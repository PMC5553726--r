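#' Filtering thresholds for the variant cascade
#'
#' Defaults encode the diagnostic cascade: genotypes are confident at a
#' depth of at least 15 reads and a genotype quality strictly above 20
#' phred; variants with any population frequency above 0.01 are
#' excluded (equality passes); the strict mode used for exome-wide
#' escalation requires every reported frequency to be strictly below
#' 0.005; only HIGH/MODERATE impact variants are kept, and synonymous or
#' intronic consequences without a splice-site term are dropped.
#'
#' @param min_depth minimum read depth (reads), inclusive.
#' @param min_gq minimum genotype quality (phred), strict inequality.
#' @param max_freq_standard standard frequency exclusion threshold
#'   (exclude when frequency > threshold).
#' @param max_freq_strict strict threshold (pass only when frequency <
#'   threshold).
#' @param impact_keep impact classes retained by the effect filter.
#' @param exclude_consequences consequence terms excluded unless a
#'   splice term co-occurs.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_depth = 15, min_gq = 20,
                          max_freq_standard = 0.01, max_freq_strict = 0.005,
                          impact_keep = c("HIGH", "MODERATE"),
                          exclude_consequences = c("synonymous_variant",
                                                   "intron_variant")) {
  stopifnot(min_depth >= 0, min_gq >= 0,
            max_freq_strict >= 0, max_freq_strict <= max_freq_standard,
            max_freq_standard <= 1)
  impact_keep <- toupper(impact_keep)
  bad <- setdiff(impact_keep, impact_levels())
  if (length(bad) > 0) stop("unknown impact class(es): ", paste(bad, collapse = ", "))
  structure(list(min_depth = min_depth, min_gq = min_gq,
                 max_freq_standard = max_freq_standard,
                 max_freq_strict = max_freq_strict,
                 impact_keep = impact_keep,
                 exclude_consequences = exclude_consequences),
            class = "filter_config")
}

#' Genotype-confidence predicate
#'
#' TRUE iff the sample's genotype at each variant is non-missing with
#' depth >= `min_depth` and quality strictly > `min_gq`.
#'
#' @param cohort a [wes_cohort()].
#' @param sample sample id (must exist in the cohort).
#' @param cfg a [filter_config()].
#' @return Logical vector over variant rows.
#' @export
quality_pass <- function(cohort, sample, cfg = filter_config()) {
  stop_unknown_sample(cohort, sample)
  g <- cohort$geno[, sample]
  dp <- cohort$dp[, sample]
  gq <- cohort$gq[, sample]
  ok <- !is.na(g) & !is.na(dp) & !is.na(gq) & dp >= cfg$min_depth & gq > cfg$min_gq
  unname(ok)
}

#' Population-frequency predicate
#'
#' A variant fails when any *present* frequency source (dbSNP MAF,
#' 1000GP, ESP) exceeds the threshold; missing values never cause
#' exclusion, so novel variants pass. With `strict = TRUE` the pass
#' condition is frequency strictly below the threshold (the "very low
#' population frequency" rule); equality then fails.
#'
#' @param cohort a [wes_cohort()] (or its variants tibble).
#' @param threshold frequency in `[0, 1]`.
#' @param strict use strict `<` pass semantics instead of excluding `>`.
#' @return Logical vector over variant rows.
#' @export
frequency_pass <- function(cohort, threshold = 0.01, strict = FALSE) {
  stopifnot(threshold >= 0, threshold <= 1)
  va <- if (inherits(cohort, "wes_cohort")) cohort$variants else cohort
  f <- cbind(va$freq_dbsnp, va$freq_1kgp, va$freq_esp)
  exceeds <- if (strict) f >= threshold else f > threshold
  exceeds[is.na(exceeds)] <- FALSE
  rowSums(exceeds) == 0
}

has_splice_term <- function(consequence) {
  grepl("splice", consequence, ignore.case = TRUE)
}

#' Functional-effect predicate
#'
#' TRUE iff the impact class is retained and the consequence is not an
#' excluded term; a consequence carrying a splice-region/acceptor/donor
#' term is never excluded even when an intronic term co-occurs.
#' Consequence strings may join several terms with `&` (annotator
#' style).
#'
#' @inheritParams frequency_pass
#' @param cfg a [filter_config()].
#' @return Logical vector over variant rows.
#' @export
effect_pass <- function(cohort, cfg = filter_config()) {
  va <- if (inherits(cohort, "wes_cohort")) cohort$variants else cohort
  bad <- setdiff(unique(va$impact[!is.na(va$impact)]), impact_levels())
  if (length(bad) > 0) stop("unknown impact value(s): ", paste(bad, collapse = ", "))
  keep_impact <- !is.na(va$impact) & va$impact %in% cfg$impact_keep
  excluded <- vapply(va$consequence, function(csq) {
    if (is.na(csq)) return(FALSE)
    terms <- strsplit(csq, "&", fixed = TRUE)[[1]]
    any(terms %in% cfg$exclude_consequences) && !any(has_splice_term(terms))
  }, logical(1), USE.NAMES = FALSE)
  keep_impact & !excluded
}

#' Apply the full per-variant cascade with an audit trail
#'
#' Survivors are the conjunction of the genotype-confidence,
#' population-frequency and functional-effect predicates; because the
#' predicates are pure, the survivor set does not depend on evaluation
#' order. The audit trail records, per variant, the first failing
#' predicate in the canonical order quality -> frequency -> effect.
#'
#' @param cohort a [wes_cohort()].
#' @param sample proband sample id driving the quality filter.
#' @param cfg a [filter_config()].
#' @param strict also apply the strict frequency rule
#'   (`max_freq_strict`, `<` semantics) on top of the standard one.
#' @return List with `cohort` (surviving rows), `audit` (tibble:
#'   `variant_id`, per-predicate logicals, `first_fail`) and
#'   `stage_counts` (named non-increasing vector).
#' @export
apply_cascade <- function(cohort, sample, cfg = filter_config(), strict = FALSE) {
  q <- quality_pass(cohort, sample, cfg)
  f <- frequency_pass(cohort, cfg$max_freq_standard)
  if (strict) f <- f & frequency_pass(cohort, cfg$max_freq_strict, strict = TRUE)
  e <- effect_pass(cohort, cfg)
  keep <- q & f & e
  first_fail <- rep(NA_character_, length(keep))
  first_fail[!e] <- "effect"
  first_fail[!f] <- "frequency"
  first_fail[!q] <- "quality"
  audit <- tibble::tibble(
    variant_id = cohort$variants$variant_id,
    quality = q, frequency = f, effect = e,
    pass = keep, first_fail = first_fail
  )
  counts <- c(input = length(keep), quality = sum(q),
              frequency = sum(q & f), effect = sum(keep))
  list(cohort = cohort_subset(cohort, keep), audit = audit, stage_counts = counts)
}
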