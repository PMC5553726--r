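# Shared fixtures and independent oracles for the suite. Fixtures are
# built in code at test time; nothing binary is stored.

.cache <- new.env(parent = emptyenv())

# one shared six-family cohort per seed, reused across test files
cached_bundle <- function(seed = 1) {
  key <- paste0("bundle_", seed)
  if (is.null(.cache[[key]])) {
    .cache[[key]] <- simulate_cohort(cfg = sim_config(seed = seed))
  }
  .cache[[key]]
}

cached_pipeline <- function(seed = 1) {
  key <- paste0("pipe_", seed)
  if (is.null(.cache[[key]])) {
    b <- cached_bundle(seed)
    .cache[[key]] <- run_pipeline(b$families, b$panel, b$training, b$features,
                                  known_genes = b$known_genes,
                                  subsets = b$subsets)
  }
  .cache[[key]]
}

# ---- toy annotated VCF -------------------------------------------------

toy_vcf_lines <- function() {
  c("##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000000>",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"g\">",
    "##INFO=<ID=IMPACT,Number=1,Type=String,Description=\"i\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"c\">",
    "##INFO=<ID=MAF_DBSNP,Number=A,Type=Float,Description=\"f\">",
    "##INFO=<ID=AF_1KGP,Number=A,Type=Float,Description=\"f\">",
    "##INFO=<ID=AF_ESP,Number=A,Type=Float,Description=\"f\">",
    "##INFO=<ID=PRED_PP2,Number=1,Type=String,Description=\"p\">",
    "##INFO=<ID=PRED_SIFT,Number=1,Type=String,Description=\"p\">",
    "##INFO=<ID=PRED_MT,Number=1,Type=String,Description=\"p\">",
    "##INFO=<ID=PRED_LRT,Number=1,Type=String,Description=\"p\">",
    "##INFO=<ID=SPL_NNSPLICE,Number=1,Type=String,Description=\"s\">",
    "##INFO=<ID=SPL_NETGENE2,Number=1,Type=String,Description=\"s\">",
    "##INFO=<ID=SPL_HSF,Number=1,Type=String,Description=\"s\">",
    "##INFO=<ID=SPL_ASSEDA,Number=1,Type=String,Description=\"s\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"gq\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2", "S3"), collapse = "\t"),
    paste(c("chr1", "100", ".", "C", "T", ".", "PASS",
            "GENE=BBS2;IMPACT=HIGH;CSQ=stop_gained;MAF_DBSNP=0.001;PRED_MT=Disease_causing;PRED_LRT=Deleterious",
            "GT:DP:GQ", "1/1:40:99", "0/1:35:88", "0/0:20:60"), collapse = "\t"),
    paste(c("chr1", "200", ".", "G", "A", ".", "PASS",
            "GENE=ALMS1;IMPACT=MODERATE;CSQ=missense_variant;MAF_DBSNP=0.02;AF_1KGP=0.015;AF_ESP=0.01;PRED_PP2=Probably_damaging;PRED_SIFT=Tolerated;PRED_MT=Disease_causing;PRED_LRT=Neutral",
            "GT:DP:GQ", "0/1:14:99", "1/1:30:20", "./.:0:0"), collapse = "\t"),
    # no frequency INFO keys at this site at all
    paste(c("chr1", "300", ".", "T", "G", ".", "PASS",
            "GENE=CRB1;IMPACT=LOW;CSQ=synonymous_variant",
            "GT:DP:GQ", "0/0:15:21", "0/1:22:45", "1/1:33:70"), collapse = "\t"))
}

write_toy_vcf <- function(path = tempfile(fileext = ".vcf")) {
  writeLines(toy_vcf_lines(), path)
  path
}

write_multiallelic_vcf <- function(path = tempfile(fileext = ".vcf")) {
  lines <- toy_vcf_lines()
  header <- lines[1:20]
  rec <- paste(c("chr1", "500", ".", "G", "A,T", ".", "PASS",
                 "GENE=BBS1;IMPACT=HIGH,MODERATE;CSQ=stop_gained,missense_variant;MAF_DBSNP=0.001,0.2",
                 "GT:DP:GQ", "1/2:50:99", "0/1:40:80", "2/2:30:70"),
               collapse = "\t")
  writeLines(c(header, rec), path)
  path
}

# ---- hand-built cohorts ------------------------------------------------

make_cohort <- function(variants, geno, dp = NULL, gq = NULL,
                        samples = colnames(geno)) {
  va <- tibble::as_tibble(variants)
  defaults <- list(gene = NA_character_, impact = "MODERATE",
                   consequence = "missense_variant",
                   freq_dbsnp = NA_real_, freq_1kgp = NA_real_,
                   freq_esp = NA_real_,
                   polyphen2 = NA_character_, sift = NA_character_,
                   mutation_taster = NA_character_, lrt = NA_character_,
                   nnsplice = NA_character_, netgene2 = NA_character_,
                   hsf = NA_character_, asseda = NA_character_)
  for (col in names(defaults)) {
    if (!col %in% names(va)) va[[col]] <- defaults[[col]]
  }
  if (!"variant_id" %in% names(va)) {
    va$variant_id <- paste(va$chrom, va$pos, va$ref, va$alt, sep = ":")
  }
  geno <- as.matrix(geno)
  if (is.null(dp)) dp <- matrix(50, nrow(geno), ncol(geno))
  if (is.null(gq)) gq <- matrix(90, nrow(geno), ncol(geno))
  wes_cohort(va, geno, as.matrix(dp), as.matrix(gq), samples)
}

simple_variants <- function(n, chrom = "chr1", gene = NA_character_) {
  tibble::tibble(chrom = chrom, pos = seq_len(n) * 1000L,
                 ref = "A", alt = "G", gene = gene)
}

# random cohort for filter property tests
random_cohort <- function(n = 40, seed = 1) {
  set.seed(seed)
  va <- tibble::tibble(
    chrom = "chr1", pos = sort(sample.int(1e6, n)), ref = "A", alt = "C",
    gene = sprintf("G%02d", sample.int(15, n, replace = TRUE)),
    impact = sample(impact_levels(), n, replace = TRUE),
    consequence = sample(c("missense_variant", "synonymous_variant",
                           "stop_gained", "intron_variant",
                           "splice_donor_variant&intron_variant"),
                         n, replace = TRUE),
    freq_dbsnp = ifelse(runif(n) < 0.3, NA, runif(n, 0, 0.05)),
    freq_1kgp = ifelse(runif(n) < 0.5, NA, runif(n, 0, 0.05)),
    freq_esp = NA_real_
  )
  geno <- matrix(sample(c(NA, 0L, 1L, 2L), n, replace = TRUE,
                        prob = c(0.05, 0.4, 0.3, 0.25)), n, 1,
                 dimnames = list(NULL, "P"))
  dp <- matrix(sample(5:60, n, replace = TRUE), n, 1)
  gq <- matrix(sample(5:99, n, replace = TRUE), n, 1)
  make_cohort(va, geno, dp, gq, samples = "P")
}

# ---- independent brute-force ROH oracle --------------------------------

# direct loop implementation of the windowed eligibility rule and the
# segment screens; shares no code with detect_roh()
roh_oracle <- function(markers, cfg = roh_config()) {
  out <- list()
  for (chr in unique(markers$chrom)) {
    m <- markers[markers$chrom == chr, ]
    n <- nrow(m)
    if (n == 0) next
    het <- !is.na(m$geno) & m$geno == 1
    miss <- is.na(m$geno)
    w <- min(cfg$window_size, n)
    win_good <- logical(n - w + 1)
    for (s in seq_len(n - w + 1)) {
      idx <- s:(s + w - 1)
      win_good[s] <- sum(het[idx]) <= cfg$max_het_per_window &&
        sum(miss[idx]) <= cfg$max_missing_per_window
    }
    eligible <- logical(n)
    for (j in seq_len(n)) {
      windows <- intersect(seq_len(n - w + 1), (j - w + 1):j)
      eligible[j] <- mean(win_good[windows]) > cfg$eligible_frac
    }
    j <- 1
    while (j <= n) {
      if (!eligible[j]) { j <- j + 1; next }
      k <- j
      while (k < n && eligible[k + 1] &&
             (m$pos[k + 1] - m$pos[k]) / 1000 <= cfg$max_gap) k <- k + 1
      len_kb <- (m$pos[k] - m$pos[j] + 1) / 1000
      nm <- k - j + 1
      if (nm >= cfg$min_segment_markers && len_kb >= cfg$min_segment_length &&
          nm >= cfg$min_density * len_kb / 50) {
        out[[length(out) + 1]] <- data.frame(
          chrom = chr, start = m$pos[j], end = m$pos[k],
          n_markers = nm, n_het = sum(het[j:k]), length_kb = len_kb)
      }
      j <- k + 1
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(chrom = character(0), start = integer(0),
                          end = integer(0), n_markers = integer(0),
                          n_het = integer(0), length_kb = numeric(0)))
  }
  res <- tibble::as_tibble(do.call(rbind, out))
  res[order(res$chrom, res$start), ]
}

random_roh_markers <- function(seed, max_n = 200) {
  set.seed(seed)
  n <- sample(10:max_n, 1)
  # mix long homozygous stretches with noisy stretches so segments of
  # every fate (kept, split, screened out) occur
  state <- sample(c("hom", "noisy"), 1)
  geno <- integer(0)
  while (length(geno) < n) {
    len <- sample(5:80, 1)
    g <- if (state == "hom") {
      sample(c(0L, 2L, 1L, NA), len, replace = TRUE,
             prob = c(0.55, 0.40, 0.02, 0.03))
    } else {
      sample(c(0L, 2L, 1L, NA), len, replace = TRUE,
             prob = c(0.35, 0.25, 0.35, 0.05))
    }
    geno <- c(geno, g)
    state <- if (state == "hom") "noisy" else "hom"
  }
  geno <- geno[seq_len(n)]
  gaps <- sample(c(sample(1000:40000, n, replace = TRUE),
                   sample(1500000:2500000, max(1, n %/% 30), replace = TRUE)),
                 n, replace = TRUE)
  tibble::tibble(chrom = "chrT", pos = cumsum(gaps), geno = geno)
}

# ---- brute-force compound-het pair oracle ------------------------------

comphet_oracle <- function(cohort, gene, proband, pedigree) {
  idx <- which(!is.na(cohort$variants$gene) & cohort$variants$gene == gene &
                 !is.na(cohort$geno[, proband]) & cohort$geno[, proband] == 1)
  if (length(idx) < 2) return(NULL)
  i <- match(proband, pedigree$id)
  get_g <- function(id) {
    if (is.na(id) || !id %in% cohort$samples) return(rep(NA_integer_, length(idx)))
    cohort$geno[idx, id]
  }
  gf <- get_g(pedigree$father[i])
  gm <- get_g(pedigree$mother[i])
  pat_only <- !is.na(gf) & gf >= 1 & !is.na(gm) & gm == 0
  mat_only <- !is.na(gm) & gm >= 1 & !is.na(gf) & gf == 0
  pairs <- utils::combn(seq_along(idx), 2)
  trans <- cis <- logical(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1, p]; b <- pairs[2, p]
    trans[p] <- (pat_only[a] && mat_only[b]) || (mat_only[a] && pat_only[b])
    cis[p] <- (pat_only[a] && pat_only[b]) || (mat_only[a] && mat_only[b])
  }
  if (any(trans)) "trans_confirmed" else if (all(cis)) "cis_excluded"
  else "phase_unknown"
}

# ---- tiny trio builder for segregation properties ----------------------

trio_pedigree <- function(fam = "T1") {
  as_pedigree(tibble::tibble(
    family = fam,
    id = paste0(fam, c("_F", "_M", "_P")),
    father = c(NA, NA, paste0(fam, "_F")),
    mother = c(NA, NA, paste0(fam, "_M")),
    sex = c("male", "female", "female"),
    affected = c("unaffected", "unaffected", "affected")
  ))
}
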