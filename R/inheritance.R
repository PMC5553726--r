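#' Homozygous-alt candidates in the proband
#'
#' Consanguineous probands are expected to carry the causal allele
#' homozygous by descent; this selects variants where the proband
#' genotype is 1/1 for the focal alt. Hemizygous calls (single-allele
#' genotypes, e.g. male X) were coded as homozygous on read and are
#' selected under the same rule.
#'
#' @param cohort a [wes_cohort()].
#' @param proband sample id.
#' @return A `wes_cohort` restricted to hom-alt rows.
#' @export
homozygous_candidates <- function(cohort, proband) {
  stop_unknown_sample(cohort, proband)
  g <- cohort$geno[, proband]
  cohort_subset(cohort, !is.na(g) & g == 2)
}

carrier_state <- function(geno) {
  # TRUE carrier, FALSE confirmed absent, NA untyped
  ifelse(is.na(geno), NA, geno >= 1)
}

#' Compound-heterozygote call for one gene
#'
#' Considers the variants of a single gene that are heterozygous in the
#' proband. With fewer than two such variants no call is made. Phase is
#' resolved from parental genotypes by enumerating variant pairs: a pair
#' is in trans when one variant is carried by the father only and the
#' other by the mother only; the call is `cis_excluded` when every
#' heterozygous variant is carried by the same single parent and
#' confirmed absent from the other, and `phase_unknown` otherwise (e.g.
#' parents not genotyped).
#'
#' @param cohort a [wes_cohort()] (any gene mix; rows are restricted to
#'   `gene` internally).
#' @param gene gene symbol.
#' @param proband proband sample id.
#' @param pedigree a `pedigree` tibble naming the proband's parents.
#' @return `NULL`, or a list with `model = "compound_het"`, the variant
#'   tibble and `phase_status`.
#' @export
compound_het_candidates <- function(cohort, gene, proband, pedigree) {
  stop_unknown_sample(cohort, proband)
  idx <- !is.na(cohort$variants$gene) & cohort$variants$gene == gene
  sub <- cohort_subset(cohort, idx)
  g <- sub$geno[, proband]
  het <- !is.na(g) & g == 1
  if (sum(het) < 2) return(NULL)
  sub <- cohort_subset(sub, het)
  i <- match(proband, pedigree$id)
  father <- if (!is.na(i)) pedigree$father[i] else NA_character_
  mother <- if (!is.na(i)) pedigree$mother[i] else NA_character_
  fa <- if (!is.na(father) && father %in% sub$samples)
    carrier_state(sub$geno[, father]) else rep(NA, n_variants(sub))
  mo <- if (!is.na(mother) && mother %in% sub$samples)
    carrier_state(sub$geno[, mother]) else rep(NA, n_variants(sub))

  paternal_only <- !is.na(fa) & fa & !is.na(mo) & !mo
  maternal_only <- !is.na(mo) & mo & !is.na(fa) & !fa
  n <- n_variants(sub)
  any_trans <- FALSE
  all_cis <- TRUE
  for (a in seq_len(n - 1)) {
    for (b in seq(a + 1, n)) {
      trans_pair <- (paternal_only[a] && maternal_only[b]) ||
        (maternal_only[a] && paternal_only[b])
      cis_pair <- (paternal_only[a] && paternal_only[b]) ||
        (maternal_only[a] && maternal_only[b])
      if (trans_pair) any_trans <- TRUE
      if (!cis_pair) all_cis <- FALSE
    }
  }
  phase <- if (any_trans) "trans_confirmed"
           else if (all_cis) "cis_excluded"
           else "phase_unknown"
  list(model = "compound_het", gene = gene, variants = sub$variants,
       phase_status = phase)
}

#' Co-segregation check of a homozygous candidate in the family
#'
#' Under autosomal-recessive inheritance with a homozygous proband,
#' every available unaffected parent must be heterozygous, no available
#' unaffected relative may be homozygous-alt, and affected relatives
#' must share the homozygous genotype (a heterozygous affected relative
#' makes the variant inconsistent for that relative, pointing to a
#' different cause in that individual). Relatives with unknown affection
#' status constrain nothing. With no genotyped relatives the check is
#' untestable.
#'
#' @param genotypes named integer vector of focal-alt genotype codes
#'   (0/1/2, `NA` missing) for the family's samples, proband included.
#' @param pedigree a `pedigree` tibble.
#' @param proband proband sample id (must be homozygous alt).
#' @return `"consistent"`, `"inconsistent"` or `"untestable"`.
#' @export
segregation_check <- function(genotypes, pedigree, proband) {
  if (!proband %in% names(genotypes)) stop("proband '", proband, "' not genotyped")
  if (is.na(genotypes[proband]) || genotypes[proband] != 2) {
    stop("segregation_check expects a proband homozygous for the alt allele")
  }
  i <- match(proband, pedigree$id)
  parents <- if (!is.na(i)) stats::na.omit(c(pedigree$father[i], pedigree$mother[i]))
             else character(0)
  relatives <- setdiff(intersect(pedigree$id, names(genotypes)), proband)
  relatives <- relatives[!is.na(genotypes[relatives])]
  if (length(relatives) == 0) return("untestable")
  status <- setNames(pedigree$affected, pedigree$id)
  for (r in relatives) {
    g <- genotypes[[r]]
    if (r %in% parents) {
      # an unaffected parent of a hom child must be an obligate carrier
      if (status[r] == "unaffected" && g != 1) return("inconsistent")
      if (status[r] == "unknown" && g == 0) return("inconsistent")
    } else {
      if (status[r] == "unaffected" && g == 2) return("inconsistent")
    }
    if (status[r] == "affected" && g != 2) return("inconsistent")
  }
  "consistent"
}
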