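variant_label <- function(va) {
  paste0(va$chrom, ":", va$pos, va$ref, ">", va$alt)
}

candidate_rows <- function(cohort, idx, model, zygosity, phase_status = NA_character_,
                           vocab = default_predictor_vocab()) {
  sub <- cohort_subset(cohort, idx)
  va <- sub$variants
  scores <- score_cohort(sub, vocab = vocab)
  tibble::tibble(
    variant_id = va$variant_id, gene = va$gene,
    chrom = va$chrom, pos = va$pos, ref = va$ref, alt = va$alt,
    variant = variant_label(va),
    impact = va$impact, consequence = va$consequence,
    model = model, zygosity = zygosity, phase_status = phase_status,
    positives = scores$positives, applicable = scores$applicable,
    consensus_score = scores$score,
    splice_positives = scores$splice_positives,
    splice_score = scores$splice_score
  )
}

empty_candidates <- function() {
  candidate_rows(
    wes_cohort(empty_variants(), matrix(integer(0), 0, 0),
               matrix(numeric(0), 0, 0), matrix(numeric(0), 0, 0),
               character(0)),
    logical(0), "homozygous", "hom")
}

new_tier_result <- function(tier, stage_counts, candidates) {
  stopifnot(all(diff(stage_counts) <= 0))
  structure(list(tier = tier, stage_counts = stage_counts,
                 candidates = candidates),
            class = "tier_result")
}

#' @export
print.tier_result <- function(x, ...) {
  cat("<tier_result> ", x$tier, "\n  stages: ",
      paste(names(x$stage_counts), x$stage_counts, sep = "=", collapse = " -> "),
      "\n", sep = "")
  invisible(x)
}

#' Tier 1: panel-restricted recessive candidate search
#'
#' Restricts the cohort to the known-ciliary-gene panel, applies the
#' standard cascade to the proband, and reports homozygous candidates
#' first, followed by compound-heterozygote calls (with phase status
#' resolved from the parents where possible). Every candidate carries
#' the protein consensus score, and the splice consensus when splice
#' calls are present.
#'
#' @param cohort a [wes_cohort()].
#' @param proband proband sample id.
#' @param panel a `gene_panel` of known ciliary genes.
#' @param pedigree a `pedigree` tibble (for compound-het phasing).
#' @param cfg a [filter_config()].
#' @param vocab predictor vocabulary.
#' @return A `tier_result` with non-increasing `stage_counts`
#'   (`input`, `panel`, `quality`, `frequency`, `effect`, `model`).
#' @export
run_tier1 <- function(cohort, proband, panel, pedigree = NULL,
                      cfg = filter_config(),
                      vocab = default_predictor_vocab()) {
  in_panel <- !is.na(cohort$variants$gene) &
    toupper(cohort$variants$gene) %in% panel$genes
  restricted <- cohort_subset(cohort, in_panel)
  cas <- apply_cascade(restricted, proband, cfg)
  surv <- cas$cohort
  hom <- !is.na(surv$geno[, proband]) & surv$geno[, proband] == 2
  cands <- candidate_rows(surv, hom, "homozygous", "hom", vocab = vocab)
  het_genes <- unique(surv$variants$gene[!is.na(surv$variants$gene) &
                                           !is.na(surv$geno[, proband]) &
                                           surv$geno[, proband] == 1])
  comphet <- list()
  if (!is.null(pedigree)) {
    for (g in het_genes) {
      call <- compound_het_candidates(surv, g, proband, pedigree)
      if (is.null(call)) next
      idx <- surv$variants$variant_id %in% call$variants$variant_id
      comphet[[g]] <- candidate_rows(surv, idx, "compound_het", "het",
                                     phase_status = call$phase_status,
                                     vocab = vocab)
    }
  }
  cands <- dplyr::bind_rows(c(list(cands), comphet))
  counts <- c(input = n_variants(cohort), panel = n_variants(restricted),
              cas$stage_counts[-1], model = nrow(cands))
  new_tier_result("T1_panel", counts, cands)
}

tier2_modes <- function() c("high_only", "high_moderate", "moderate_only")

#' Tier 2: exome-wide homozygous search with impact-mode ladder
#'
#' Modes correspond to the per-case escalation strategies:
#' `high_only` keeps HIGH-impact variants under the standard Methods
#' criteria; `high_moderate` and `moderate_only` widen/narrow the
#' impact set and additionally apply the strict rules used when no
#' HIGH-impact candidate explains a case — every reported population
#' frequency strictly below `max_freq_strict` and at least 2 of 4
#' positive protein predictions.
#'
#' @param cohort a [wes_cohort()].
#' @param proband proband sample id.
#' @param cfg a [filter_config()].
#' @param mode one of `"high_only"`, `"high_moderate"`, `"moderate_only"`.
#' @param min_positive positive-prediction threshold for strict modes.
#' @param vocab predictor vocabulary.
#' @return A `tier_result`; candidate genes are the input to
#'   prioritisation.
#' @export
run_tier2 <- function(cohort, proband, cfg = filter_config(),
                      mode = tier2_modes(), min_positive = 2,
                      vocab = default_predictor_vocab()) {
  mode <- match.arg(mode)
  impact_keep <- switch(mode,
                        high_only = "HIGH",
                        high_moderate = c("HIGH", "MODERATE"),
                        moderate_only = "MODERATE")
  strict <- mode %in% c("high_moderate", "moderate_only")
  mode_cfg <- cfg
  mode_cfg$impact_keep <- impact_keep
  cas <- apply_cascade(cohort, proband, mode_cfg, strict = strict)
  surv <- cas$cohort
  hom <- !is.na(surv$geno[, proband]) & surv$geno[, proband] == 2
  homc <- cohort_subset(surv, hom)
  counts <- c(input = n_variants(cohort), cas$stage_counts[-1],
              homozygous = n_variants(homc))
  if (strict) {
    sc <- score_cohort(homc, vocab = vocab)
    keep <- passes_min_positive(sc, k = min_positive)
    homc <- cohort_subset(homc, keep)
    counts <- c(counts, consensus = n_variants(homc))
  }
  cands <- candidate_rows(homc, rep(TRUE, n_variants(homc)),
                          "homozygous", "hom", vocab = vocab)
  counts <- c(counts, model = nrow(cands))
  new_tier_result(paste0("T2_exome_", mode), counts, cands)
}

annotate_candidates <- function(cands, cohort, proband, pedigree, roh_segments) {
  if (nrow(cands) == 0) {
    cands$segregation <- character(0)
    cands$in_roh <- logical(0)
    return(cands)
  }
  seg <- character(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    if (cands$model[i] != "homozygous") { seg[i] <- NA_character_; next }
    g <- setNames(as.integer(cohort$geno[cands$variant_id[i], , drop = FALSE]),
                  cohort$samples)
    fam_ped <- pedigree[pedigree$id %in% names(g), , drop = FALSE]
    seg[i] <- segregation_check(g, fam_ped, proband)
  }
  cands$segregation <- seg
  cands$in_roh <- variant_in_roh(cands, roh_segments)
  cands
}

candidate_passes <- function(cands) {
  ifelse(cands$model == "homozygous",
         cands$segregation %in% c("consistent", "untestable"),
         cands$phase_status %in% "trans_confirmed")
}

#' Run the full tiered workflow for a cohort of families
#'
#' For every family: tier 1 on the panel; when no tier-1 candidate in a
#' known ciliary gene passes the checks, escalate exome-wide —
#' `high_only` under the standard criteria, then `high_moderate` under
#' the strict criteria (the `moderate_only` mode is its subset and is
#' available through [run_tier2()] directly). Escalation stops as soon
#' as a passing candidate falls in a known ciliary gene
#' (`solved-known-gene`); otherwise the final candidate genes are
#' ranked against the training set (`candidate-novel-gene`), or the
#' family is `unsolved` when nothing survives. All candidates are
#' annotated with consensus scores, ROH colocalization and segregation
#' status.
#'
#' @param families named list; each element has `family` (id), `cohort`
#'   (a [wes_cohort()]), `pedigree` (tibble) and `proband` (sample id).
#' @param panel tier-1 `gene_panel`.
#' @param training training `gene_panel` for prioritisation.
#' @param features multi-source feature matrix.
#' @param cfg a [filter_config()].
#' @param roh_cfg a [roh_config()].
#' @param known_genes `gene_panel` of all genes accepted as a known
#'   ciliary diagnosis (defaults to `panel`; may be a superset covering
#'   less common ciliary genes found only exome-wide).
#' @param subsets optional named training subsets for prioritisation.
#' @param vocab predictor vocabulary.
#' @return List of per-family results (`label`, `tiers`, `candidates`,
#'   `prioritisation`, `roh_segments`) plus a cohort-level `report`
#'   tibble with the stable report columns.
#' @export
run_pipeline <- function(families, panel, training, features,
                         cfg = filter_config(), roh_cfg = roh_config(),
                         known_genes = panel, subsets = NULL,
                         vocab = default_predictor_vocab()) {
  results <- list()
  for (fam in families) {
    cohort <- fam$cohort
    proband <- fam$proband
    pedigree <- fam$pedigree
    roh_segments <- detect_roh(roh_markers(cohort, proband), roh_cfg)
    tiers <- list()
    label <- "unsolved"
    final_cands <- empty_candidates()
    final_cands$segregation <- character(0)
    final_cands$in_roh <- logical(0)
    prioritisation <- NULL

    t1 <- run_tier1(cohort, proband, panel, pedigree, cfg, vocab)
    t1$candidates <- annotate_candidates(t1$candidates, cohort, proband,
                                         pedigree, roh_segments)
    tiers[[t1$tier]] <- t1
    pass1 <- candidate_passes(t1$candidates)
    known1 <- toupper(t1$candidates$gene) %in% known_genes$genes
    if (any(pass1 & known1)) {
      label <- "solved-known-gene"
      final_cands <- t1$candidates
    } else {
      for (mode in c("high_only", "high_moderate")) {
        t2 <- run_tier2(cohort, proband, cfg, mode, vocab = vocab)
        t2$candidates <- annotate_candidates(t2$candidates, cohort, proband,
                                             pedigree, roh_segments)
        tiers[[t2$tier]] <- t2
        passing <- candidate_passes(t2$candidates)
        known <- toupper(t2$candidates$gene) %in% known_genes$genes
        final_cands <- t2$candidates
        if (any(passing & known)) {
          label <- "solved-known-gene"
          break
        }
      }
      if (label != "solved-known-gene" && nrow(final_cands) > 0) {
        label <- "candidate-novel-gene"
        genes <- unique(stats::na.omit(final_cands$gene))
        prioritisation <- prioritize_candidates(genes, training, features,
                                                subsets = subsets)
        full <- prioritisation$rankings$full
        final_cands$fused_rank <- full$final_rank[match(toupper(final_cands$gene),
                                                        full$gene)]
      }
    }
    if (!"fused_rank" %in% names(final_cands)) {
      final_cands$fused_rank <- rep(NA_integer_, nrow(final_cands))
    }
    results[[fam$family]] <- list(
      family = fam$family, label = label, tiers = tiers,
      candidates = final_cands, prioritisation = prioritisation,
      roh_segments = roh_segments
    )
  }
  report <- dplyr::bind_rows(lapply(results, function(r) {
    if (nrow(r$candidates) == 0) return(NULL)
    tibble::tibble(
      family = r$family, gene = r$candidates$gene,
      variant = r$candidates$variant, zygosity = r$candidates$zygosity,
      tier = names(r$tiers)[length(r$tiers)],
      consensus_score = r$candidates$consensus_score,
      in_roh = r$candidates$in_roh,
      segregation = r$candidates$segregation,
      fused_rank = r$candidates$fused_rank
    )
  }))
  list(families = results, report = report)
}
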