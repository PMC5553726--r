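#' Annotated variant cohort container
#'
#' A `wes_cohort` bundles one normalized alternate allele per row with its
#' annotations and the per-sample genotype matrices extracted from a
#' multi-sample VCF. Rows of the genotype matrices align with rows of the
#' `variants` tibble.
#'
#' @param variants tibble with one row per (site, alt allele): columns
#'   `variant_id`, `chrom`, `pos`, `ref`, `alt`, `gene`, `impact`,
#'   `consequence`, `freq_dbsnp`, `freq_1kgp`, `freq_esp`, the four
#'   protein-predictor call columns (`polyphen2`, `sift`,
#'   `mutation_taster`, `lrt`) and the four splice-tool call columns
#'   (`nnsplice`, `netgene2`, `hsf`, `asseda`). Missing annotations are
#'   `NA`, never 0.
#' @param geno integer matrix (variants x samples) of focal-alt genotype
#'   codes: 0 hom-ref (or non-focal alt), 1 het, 2 hom-alt, `NA` missing.
#' @param dp,gq numeric matrices (variants x samples) of read depth and
#'   phred genotype quality.
#' @param samples character vector of sample ids, in VCF column order.
#'
#' @return An object of class `wes_cohort`.
#' @export
wes_cohort <- function(variants, geno, dp, gq, samples) {
  variants <- tibble::as_tibble(variants)
  required <- c("variant_id", "chrom", "pos", "ref", "alt", "gene", "impact",
                "consequence", "freq_dbsnp", "freq_1kgp", "freq_esp",
                "polyphen2", "sift", "mutation_taster", "lrt",
                "nnsplice", "netgene2", "hsf", "asseda")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols) > 0) {
    stop("variants tibble is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(variants)
  for (m in list(geno = geno, dp = dp, gq = gq)) {
    stopifnot(is.matrix(m), nrow(m) == n, ncol(m) == length(samples))
  }
  if (any(variants$pos < 1, na.rm = TRUE)) stop("positions must be >= 1")
  if (any(variants$alt == variants$ref, na.rm = TRUE)) stop("alt allele equals ref")
  freqs <- c(variants$freq_dbsnp, variants$freq_1kgp, variants$freq_esp)
  if (any(freqs < 0 | freqs > 1, na.rm = TRUE)) stop("frequency fields must lie in [0, 1]")
  bad_imp <- setdiff(unique(variants$impact[!is.na(variants$impact)]), impact_levels())
  if (length(bad_imp) > 0) {
    stop("unknown impact value(s): ", paste(bad_imp, collapse = ", "))
  }
  dimnames(geno) <- dimnames(dp) <- dimnames(gq) <- list(variants$variant_id, samples)
  structure(
    list(variants = variants, geno = geno, dp = dp, gq = gq,
         samples = as.character(samples)),
    class = "wes_cohort"
  )
}

#' snpEff-style impact severity vocabulary, most severe first
#' @return Character vector `HIGH`, `MODERATE`, `LOW`, `MODIFIER`.
#' @export
impact_levels <- function() c("HIGH", "MODERATE", "LOW", "MODIFIER")

#' @export
print.wes_cohort <- function(x, ...) {
  cat("<wes_cohort> ", nrow(x$variants), " variant allele(s), ",
      length(x$samples), " sample(s): ",
      paste(utils::head(x$samples, 6), collapse = ", "),
      if (length(x$samples) > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Number of variant alleles in a cohort
#' @param cohort a `wes_cohort`.
#' @return Integer count of (site, alt) rows.
#' @export
n_variants <- function(cohort) nrow(cohort$variants)

#' Subset a cohort by variant rows
#'
#' @param cohort a `wes_cohort`.
#' @param idx logical or integer row index into the variant table.
#' @return A `wes_cohort` with the selected rows, sample set unchanged.
#' @export
cohort_subset <- function(cohort, idx) {
  wes_cohort(cohort$variants[idx, , drop = FALSE],
             cohort$geno[idx, , drop = FALSE],
             cohort$dp[idx, , drop = FALSE],
             cohort$gq[idx, , drop = FALSE],
             cohort$samples)
}

stop_unknown_sample <- function(cohort, sample) {
  if (!sample %in% cohort$samples) {
    stop("unknown sample '", sample, "'; cohort samples: ",
         paste(cohort$samples, collapse = ", "))
  }
  invisible(TRUE)
}
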