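#' Synthetic-cohort generator configuration
#'
#' The generator emulates the statistical structure the analysis
#' assumes: consanguineous nuclear families, a causal allele planted
#' homozygous in the proband inside an autozygous haplotype block, and
#' a realistic background variant load calibrated so that roughly 300
#' homozygous positions per exome survive the standard cascade.
#'
#' @param seed integer seed; a fixed seed reproduces the cohort
#'   byte-for-byte.
#' @param n_background_hom_after_qc target count of homozygous
#'   background variants surviving the standard cascade per family.
#' @param marker_density exome markers per Mb of the miniature genome.
#' @param contig_length_mb length of each of the six synthetic contigs.
#' @param autozygous_block_kb length of each planted autozygous block
#'   (0 places causal variants outside any ROH-detectable block — a
#'   negative control).
#' @param common_frac fraction of background markers drawn from the
#'   common-frequency mixture component.
#' @param dp_mean,dp_size negative-binomial read-depth parameters.
#' @param lowq_frac fraction of genotype entries degraded below the
#'   quality thresholds.
#' @param missing_frac fraction of genotype entries set to missing.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_background_hom_after_qc = 300,
                       marker_density = 30, contig_length_mb = 10,
                       autozygous_block_kb = 2500, common_frac = 0.8,
                       dp_mean = 60, dp_size = 8, lowq_frac = 0.03,
                       missing_frac = 0.01) {
  stopifnot(seed == as.integer(seed), n_background_hom_after_qc >= 0,
            marker_density > 0, contig_length_mb > 0,
            autozygous_block_kb >= 0, common_frac >= 0, common_frac <= 1)
  structure(as.list(environment()), class = "sim_config")
}

sim_contigs <- function(cfg) {
  setNames(rep(as.integer(cfg$contig_length_mb * 1e6), 6),
           paste0("chr", 1:6))
}

plan_variant <- function(gene, chrom, impact, consequence,
                         polyphen2 = NA, sift = NA,
                         mutation_taster = NA, lrt = NA,
                         nnsplice = NA, netgene2 = NA, hsf = NA, asseda = NA,
                         freq = NA_real_, in_roh = TRUE, role = "causal",
                         ref = "C", alt = "T") {
  list(gene = gene, chrom = chrom, impact = impact, consequence = consequence,
       polyphen2 = polyphen2, sift = sift, mutation_taster = mutation_taster,
       lrt = lrt, nnsplice = nnsplice, netgene2 = netgene2, hsf = hsf,
       asseda = asseda, freq = freq, in_roh = in_roh, role = role,
       ref = ref, alt = alt, carrier_parents = 2L)
}

truncating_calls <- list(polyphen2 = "not_applicable", sift = "not_applicable",
                         mutation_taster = "Disease_causing", lrt = "Deleterious")

#' The six family archetypes of the synthetic cohort
#'
#' Archetypes mirror a six-family consanguineous study design: four
#' families carry a homozygous truncating or splice-disrupting causal
#' variant in a known ciliary gene (BBS2 twice, ALMS1, CRB1); two carry
#' candidate variants in genes outside the ciliary panel (CORO2B/SLC3A1
#' and LMO7/ZNF17) alongside a handful of background variants that pass
#' even the strict filters, so prioritisation is required. Gene symbols
#' are real so panel logic is exercised, but all coordinates and
#' sequences are synthetic.
#'
#' @return List of six `case_archetype` objects.
#' @export
case_archetypes <- function() {
  miss <- function(gene, chrom, pp2, sift, freq = NA_real_, role = "causal",
                   in_roh = TRUE) {
    plan_variant(gene, chrom, "MODERATE", "missense_variant",
                 polyphen2 = pp2, sift = sift,
                 mutation_taster = "Disease_causing", lrt = "Deleterious",
                 freq = freq, in_roh = in_roh, role = role, ref = "T", alt = "A")
  }
  qual <- function(gene, chrom) {
    # background variants engineered to pass even the strict criteria
    plan_variant(gene, chrom, "MODERATE", "missense_variant",
                 polyphen2 = "Probably_damaging", sift = "Tolerated",
                 mutation_taster = "Disease_causing", lrt = "Neutral",
                 freq = 0.001, in_roh = FALSE, role = "qualifying",
                 ref = "G", alt = "A")
  }
  stopg <- function(gene, chrom, role = "causal") {
    do.call(plan_variant, c(list(gene = gene, chrom = chrom, impact = "HIGH",
                                 consequence = "stop_gained", role = role),
                            truncating_calls))
  }
  arch <- list(
    list(id = 1L, family = "F1", available = c("P", "M"),
         plans = c(list(miss("CORO2B", "chr1", "Probably_damaging", "Tolerated"),
                        miss("SLC3A1", "chr2", "Probably_damaging", "Tolerated",
                             freq = 0.001)),
                   lapply(1:5, function(i) qual(sprintf("SYNG%02d", i),
                                                paste0("chr", (i %% 6) + 1)))),
         comphet_gene = "BBS9"),
    list(id = 2L, family = "F2", available = c("P", "M"),
         plans = list(stopg("BBS2", "chr3"))),
    list(id = 3L, family = "F3", available = c("P", "M", "F"),
         plans = list(stopg("BBS2", "chr3"))),
    list(id = 4L, family = "F4", available = "P",
         plans = list(stopg("ALMS1", "chr4"))),
    list(id = 5L, family = "F5", available = "P",
         plans = c(list(plan_variant("LMO7", "chr5", "MODERATE",
                                     "missense_variant",
                                     polyphen2 = "Probably_damaging",
                                     sift = "Damaging",
                                     mutation_taster = "Disease_causing",
                                     lrt = "Deleterious", ref = "C", alt = "T"),
                        stopg("ZNF17", "chr6")),
                   lapply(6:11, function(i) qual(sprintf("SYNG%02d", i),
                                                 paste0("chr", (i %% 6) + 1))))),
    list(id = 6L, family = "F6", available = c("P", "M", "F", "S"),
         plans = list(plan_variant("CRB1", "chr1", "HIGH", "frameshift_variant",
                                   mutation_taster = "Disease_causing",
                                   lrt = "Deleterious",
                                   polyphen2 = "not_applicable",
                                   sift = "not_applicable",
                                   nnsplice = "negative", netgene2 = "positive",
                                   hsf = "positive", asseda = "positive",
                                   ref = "CATAGGAA", alt = "C")))
  )
  lapply(arch, function(a) {
    a$comphet_gene <- a$comphet_gene %||% NA_character_
    structure(a, class = "case_archetype")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_archetype <- function(arch) {
  if (!all(c("id", "family", "available", "plans") %in% names(arch))) {
    stop("archetype is missing required fields")
  }
  if (!"P" %in% arch$available) stop("archetype must include the proband 'P'")
  for (p in arch$plans) {
    if (p$carrier_parents < 2) {
      stop("impossible archetype: a homozygous child requires both parents ",
           "to carry the allele (gene ", p$gene, ")")
    }
  }
  invisible(TRUE)
}

sample_ids <- function(family, roles) paste(family, roles, sep = "_")

# draw founder haplotype alleles for all four founder haplotypes
draw_haplotypes <- function(freq) {
  n <- length(freq)
  matrix(stats::rbinom(4L * n, 1L, rep(freq, 4)), nrow = n, ncol = 4,
         dimnames = list(NULL, c("fh1", "fh2", "mh1", "mh2")))
}

#' Simulate one consanguineous family
#'
#' Produces an annotated [wes_cohort()] plus pedigree for one archetype.
#' Parental haplotypes are drawn from the background allele-frequency
#' mixture; autozygosity is simulated by copying one shared ancestral
#' haplotype segment into one haplotype of each parent and transmitting
#' it to the proband from both sides (identity by descent by
#' construction), which makes the proband homozygous across the block.
#' Planted variants are validated to survive the cascade they were
#' designed to survive.
#'
#' @param arch a `case_archetype` (see [case_archetypes()]).
#' @param cfg a [sim_config()].
#' @return List: `family`, `cohort` ([wes_cohort()] with only the
#'   available samples), `pedigree`, `proband`, and `truth` (planted
#'   variant ids, block coordinates, background survivor count).
#' @export
simulate_family <- function(arch, cfg = sim_config()) {
  validate_archetype(arch)
  set.seed(as.integer(cfg$seed) + 7919L * arch$id)
  contigs <- sim_contigs(cfg)

  ## background marker map
  n_per <- as.integer(round(cfg$marker_density * cfg$contig_length_mb))
  chrom <- rep(names(contigs), each = n_per)
  pos <- unlist(lapply(contigs, function(L) sort(sample.int(L, n_per))),
                use.names = FALSE)
  n_bg <- length(pos)
  is_common <- stats::runif(n_bg) < cfg$common_frac
  freq <- ifelse(is_common,
                 0.05 + stats::rbeta(n_bg, 2, 2) * 0.45,
                 10 ^ stats::runif(n_bg, -5, -2))

  ## autozygous blocks: one per in_roh planted variant, on its contig
  blocks <- list()
  block_len <- as.integer(cfg$autozygous_block_kb * 1000)
  for (p in arch$plans) {
    if (!isTRUE(p$in_roh) || block_len <= 0) next
    L <- contigs[[p$chrom]]
    start <- sample.int(L - block_len - 2L, 1)
    blocks[[length(blocks) + 1]] <- list(chrom = p$chrom, start = start,
                                         end = start + block_len - 1L)
  }
  in_block <- rep(FALSE, n_bg)
  for (b in blocks) {
    in_block <- in_block | (chrom == b$chrom & pos >= b$start & pos <= b$end)
  }
  # block markers come from the common pool: ROH mapping rides on common
  # polymorphisms; rare variation inside the block is represented by the
  # planted causal allele itself
  redraw <- in_block & !is_common
  freq[redraw] <- 0.05 + stats::rbeta(sum(redraw), 2, 2) * 0.45
  is_common[redraw] <- TRUE

  ## background annotation: impact mixture weighted toward MODIFIER/LOW
  imp_mix <- sample(c("MODIFIER", "LOW", "MODERATE", "HIGH"), n_bg,
                    replace = TRUE, prob = c(0.60, 0.25, 0.12, 0.03))
  csq_of <- c(MODIFIER = "intron_variant", LOW = "synonymous_variant",
              MODERATE = "missense_variant", HIGH = "stop_gained")
  gene_bin <- sprintf("G%s_%03d", sub("^chr", "", chrom),
                      pmin(999L, pos %/% 100000L))
  # predictor calls only for coding missense background, weakly tied to impact
  call_mat <- matrix(NA_character_, n_bg, 4)
  moder <- which(imp_mix == "MODERATE")
  pos_call <- list(c("Probably_damaging", "Benign"),
                   c("Damaging", "Tolerated"),
                   c("Disease_causing", "Polymorphism"),
                   c("Deleterious", "Neutral"))
  for (k in 1:4) {
    call_mat[moder, k] <- ifelse(stats::runif(length(moder)) < 0.25,
                                 pos_call[[k]][1], pos_call[[k]][2])
  }

  bg <- tibble::tibble(
    chrom = chrom, pos = pos, ref = "A", alt = "G",
    gene = gene_bin, impact = imp_mix,
    consequence = unname(csq_of[imp_mix]),
    freq_dbsnp = freq,
    freq_1kgp = ifelse(stats::runif(n_bg) < 0.8, freq, NA_real_),
    freq_esp = NA_real_,
    polyphen2 = call_mat[, 1], sift = call_mat[, 2],
    mutation_taster = call_mat[, 3], lrt = call_mat[, 4],
    nnsplice = NA_character_, netgene2 = NA_character_,
    hsf = NA_character_, asseda = NA_character_,
    kind = "marker", forced_hom = FALSE, forced_het_parents = FALSE
  )

  ## designed background survivors of the standard cascade (~target)
  n_surv <- stats::rbinom(1, 2L * cfg$n_background_hom_after_qc, 0.5)
  sv_chrom <- sample(names(contigs), n_surv, replace = TRUE)
  sv_pos <- vapply(sv_chrom, function(ch) sample.int(contigs[[ch]], 1),
                   integer(1))
  sv_freqknown <- stats::runif(n_surv) < 0.7
  sv_freq <- ifelse(sv_freqknown, stats::runif(n_surv, 0.0055, 0.0095), NA_real_)
  sv_pospred <- stats::runif(n_surv) < 0.4  # at most one positive predictor
  sv <- tibble::tibble(
    chrom = sv_chrom, pos = as.integer(sv_pos), ref = "C", alt = "G",
    gene = sprintf("G%s_%03d", sub("^chr", "", sv_chrom),
                   pmin(999L, sv_pos %/% 100000L)),
    impact = "MODERATE", consequence = "missense_variant",
    freq_dbsnp = sv_freq, freq_1kgp = sv_freq, freq_esp = NA_real_,
    polyphen2 = ifelse(sv_pospred, "Probably_damaging", "Benign"),
    sift = "Tolerated",
    mutation_taster = ifelse(sv_pospred, "Polymorphism", "Polymorphism"),
    lrt = "Neutral",
    nnsplice = NA_character_, netgene2 = NA_character_,
    hsf = NA_character_, asseda = NA_character_,
    kind = "designed_survivor", forced_hom = TRUE, forced_het_parents = TRUE
  )

  ## planted causal / qualifying variants
  block_i <- 0L
  pl_rows <- lapply(arch$plans, function(p) {
    if (isTRUE(p$in_roh) && block_len > 0) {
      block_i <<- block_i + 1L
      b <- blocks[[block_i]]
      vpos <- as.integer(b$start + sample.int(b$end - b$start - 1L, 1))
    } else {
      vpos <- sample.int(contigs[[p$chrom]], 1)
    }
    tibble::tibble(
      chrom = p$chrom, pos = vpos, ref = p$ref, alt = p$alt,
      gene = p$gene, impact = p$impact, consequence = p$consequence,
      freq_dbsnp = p$freq, freq_1kgp = p$freq, freq_esp = NA_real_,
      polyphen2 = as.character(p$polyphen2), sift = as.character(p$sift),
      mutation_taster = as.character(p$mutation_taster),
      lrt = as.character(p$lrt),
      nnsplice = as.character(p$nnsplice), netgene2 = as.character(p$netgene2),
      hsf = as.character(p$hsf), asseda = as.character(p$asseda),
      kind = paste0("planted_", p$role), forced_hom = TRUE,
      forced_het_parents = TRUE
    )
  })

  ## optional non-convincing compound-het pair in a panel gene (cis pair,
  ## both alleles on one maternal haplotype)
  ch_rows <- NULL
  if (!is.na(arch$comphet_gene)) {
    ch_chr <- "chr4"  # a contig without a planted autozygous block
    p1 <- sample.int(contigs[[ch_chr]] - 2000L, 1)
    ch_rows <- tibble::tibble(
      chrom = ch_chr, pos = as.integer(c(p1, p1 + 1500L)), ref = "T", alt = "C",
      gene = arch$comphet_gene, impact = "MODERATE",
      consequence = "missense_variant",
      freq_dbsnp = NA_real_, freq_1kgp = NA_real_, freq_esp = NA_real_,
      polyphen2 = "Possibly_damaging", sift = "Tolerated",
      mutation_taster = "Disease_causing", lrt = "Neutral",
      nnsplice = NA_character_, netgene2 = NA_character_,
      hsf = NA_character_, asseda = NA_character_,
      kind = "comphet_cis", forced_hom = FALSE, forced_het_parents = FALSE
    )
  }

  va <- dplyr::bind_rows(c(list(bg, sv), pl_rows, list(ch_rows)))
  # planted records win over background markers at colliding positions
  va <- va[order(va$chrom, va$pos, va$kind == "marker"), ]
  dup <- duplicated(va[, c("chrom", "pos")])
  va <- va[!dup, ]
  n <- nrow(va)

  ## haplotypes: founder draws + IBD copy inside blocks
  hap_freq <- ifelse(is.na(va$freq_dbsnp), 0.0005, va$freq_dbsnp)
  hap_freq <- pmin(hap_freq, 0.999)
  H <- draw_haplotypes(hap_freq)
  for (b in blocks) {
    sel <- va$chrom == b$chrom & va$pos >= b$start & va$pos <= b$end
    ancestral <- H[sel, "fh1"]
    H[sel, "mh1"] <- ancestral
  }
  # planted sites: alt on the shared (first) haplotype of each parent only
  forced <- va$forced_het_parents
  H[forced, "fh1"] <- 1L; H[forced, "fh2"] <- 0L
  H[forced, "mh1"] <- 1L; H[forced, "mh2"] <- 0L
  # cis compound-het pair: both alleles on the first maternal haplotype
  cis <- va$kind == "comphet_cis"
  H[cis, "mh1"] <- 1L; H[cis, "mh2"] <- 0L
  H[cis, "fh1"] <- 0L; H[cis, "fh2"] <- 0L

  in_block_v <- rep(FALSE, n)
  for (b in blocks) {
    in_block_v <- in_block_v | (va$chrom == b$chrom & va$pos >= b$start &
                                  va$pos <= b$end)
  }

  transmit <- function(forced_first) {
    tf <- ifelse(forced_first, 1L, sample(1:2, n, replace = TRUE))
    tm <- ifelse(forced_first, 1L, sample(1:2, n, replace = TRUE))
    cbind(tf, tm)
  }
  t_p <- transmit(in_block_v | va$forced_hom | cis)  # proband
  # proband inherits the cis pair from the mother (mh1), ref from father
  t_p[cis, 1] <- 1L  # father's fh1 is ref at cis sites anyway
  # sibling: never the IBD pair; carries one causal allele (father's fh1)
  t_s <- cbind(ifelse(in_block_v | va$forced_hom, 1L,
                      sample(1:2, n, replace = TRUE)),
               ifelse(in_block_v | va$forced_hom, 2L,
                      sample(1:2, n, replace = TRUE)))

  geno_child <- function(tr) {
    H[cbind(seq_len(n), tr[, 1])] + H[cbind(seq_len(n), 2L + tr[, 2])]
  }
  geno_all <- cbind(
    F = H[, "fh1"] + H[, "fh2"],
    M = H[, "mh1"] + H[, "mh2"],
    P = geno_child(t_p),
    S = geno_child(t_s)
  )

  roles <- arch$available
  ids <- sample_ids(arch$family, roles)
  geno <- geno_all[, roles, drop = FALSE]
  colnames(geno) <- ids

  ## depth / quality noise
  ns <- length(ids)
  dp <- matrix(stats::rnbinom(n * ns, size = cfg$dp_size, mu = cfg$dp_mean),
               n, ns, dimnames = list(NULL, ids))
  gq <- matrix(pmin(99L, 25L + stats::rpois(n * ns, 45)), n, ns,
               dimnames = list(NULL, ids))
  lowq <- matrix(stats::runif(n * ns) < cfg$lowq_frac, n, ns)
  gq[lowq] <- sample(0:20, sum(lowq), replace = TRUE)
  miss <- matrix(stats::runif(n * ns) < cfg$missing_frac, n, ns)
  protected <- va$kind %in% c("planted_causal", "planted_qualifying",
                              "designed_survivor", "comphet_cis")
  lowq[protected, ] <- FALSE
  miss[protected, ] <- FALSE
  dp[protected, ] <- pmax(dp[protected, ], 20L)
  gq[protected, ] <- pmax(gq[protected, ], 30L)
  geno[miss] <- NA_integer_

  variant_id <- paste(va$chrom, va$pos, va$ref, va$alt, sep = ":")
  variants <- tibble::add_column(
    va[, setdiff(names(va), c("kind", "forced_hom", "forced_het_parents"))],
    variant_id = variant_id, .before = 1)
  cohort <- wes_cohort(variants, geno, dp, gq, ids)

  pedigree <- as_pedigree(tibble::tibble(
    family = arch$family,
    id = sample_ids(arch$family, c("F", "M", "P", "S"))[c(1, 2, 3,
                                                          if (arch$id == 6) 4)],
    father = c(NA, NA, sample_ids(arch$family, "F"),
               if (arch$id == 6) sample_ids(arch$family, "F")),
    mother = c(NA, NA, sample_ids(arch$family, "M"),
               if (arch$id == 6) sample_ids(arch$family, "M")),
    sex = c("male", "female", "female", if (arch$id == 6) "male"),
    affected = c("unaffected", "unaffected", "affected",
                 if (arch$id == 6) "unknown")
  ))

  truth <- list(
    causal_ids = variant_id[va$kind == "planted_causal"],
    qualifying_ids = variant_id[va$kind == "planted_qualifying"],
    survivor_ids = variant_id[va$kind == "designed_survivor"],
    comphet_ids = variant_id[va$kind == "comphet_cis"],
    blocks = blocks,
    n_designed_survivors = n_surv
  )
  fam <- list(family = arch$family, cohort = cohort, pedigree = pedigree,
              proband = sample_ids(arch$family, "P"), truth = truth)
  validate_planted(fam)
  fam
}

# generation-time self check: planted variants survive the cascade they
# were planted to survive, and the proband is homozygous for them
validate_planted <- function(fam) {
  cohort <- fam$cohort
  cas <- apply_cascade(cohort, fam$proband)
  surv <- cas$audit$variant_id[cas$audit$pass]
  planted <- c(fam$truth$causal_ids, fam$truth$qualifying_ids,
               fam$truth$survivor_ids)
  if (!all(planted %in% surv)) {
    stop("internal generator error: planted variant failed its cascade")
  }
  g <- cohort$geno[planted, fam$proband]
  if (!all(g == 2)) stop("internal generator error: planted variant not homozygous")
  invisible(TRUE)
}

#' Exhaustive Mendelian-consistency check of a simulated family
#'
#' Verifies for every called genotype that each child allele count is
#' achievable from its parents' genotypes (a child cannot carry more
#' copies than transmissible, nor fewer than obligate).
#'
#' @param fam family object from [simulate_family()].
#' @return TRUE (invisibly) or an error describing the first violation.
#' @export
check_mendelian <- function(fam) {
  cohort <- fam$cohort
  ped <- fam$pedigree
  for (i in seq_len(nrow(ped))) {
    child <- ped$id[i]
    if (!child %in% cohort$samples) next
    fa <- ped$father[i]; mo <- ped$mother[i]
    if (is.na(fa) || is.na(mo)) next
    if (!fa %in% cohort$samples || !mo %in% cohort$samples) next
    gc <- cohort$geno[, child]; gf <- cohort$geno[, fa]; gm <- cohort$geno[, mo]
    ok <- is.na(gc) | is.na(gf) | is.na(gm) |
      (gc >= (gf == 2) + (gm == 2) & gc <= (gf >= 1) + (gm >= 1))
    if (!all(ok)) {
      bad <- which(!ok)[1]
      stop("Mendelian violation at ", cohort$variants$variant_id[bad],
           " for child ", child)
    }
  }
  invisible(TRUE)
}
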