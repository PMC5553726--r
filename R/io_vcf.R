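#' Default INFO-key configuration for annotated VCFs
#'
#' Annotation key names are configuration, not hard-coded: upstream
#' annotators (snpEff + snpSift/dbNSFP) spell INFO keys differently across
#' versions, so every key the reader consumes can be remapped. The
#' defaults below are the spellings written by [write_annotated_vcf()]
#' and the synthetic-cohort generator.
#'
#' @param ... overrides, e.g. `gene = "ANN_GENE"`.
#' @return Named list mapping model fields to INFO keys.
#' @export
default_field_map <- function(...) {
  map <- list(
    gene = "GENE", impact = "IMPACT", consequence = "CSQ",
    freq_dbsnp = "MAF_DBSNP", freq_1kgp = "AF_1KGP", freq_esp = "AF_ESP",
    polyphen2 = "PRED_PP2", sift = "PRED_SIFT",
    mutation_taster = "PRED_MT", lrt = "PRED_LRT",
    nnsplice = "SPL_NNSPLICE", netgene2 = "SPL_NETGENE2",
    hsf = "SPL_HSF", asseda = "SPL_ASSEDA"
  )
  utils::modifyList(map, list(...))
}

severity_rank <- function(impact) match(impact, impact_levels())

# Pick the most severe impact (and its consequence, when parallel) from
# comma-separated multi-transcript annotations.
most_severe <- function(impact_str, csq_str) {
  if (is.na(impact_str)) return(c(NA_character_, csq_str))
  imps <- toupper(strsplit(impact_str, ",", fixed = TRUE)[[1]])
  csqs <- if (is.na(csq_str)) NA_character_ else strsplit(csq_str, ",", fixed = TRUE)[[1]]
  k <- which.min(severity_rank(imps))
  if (length(k) == 0) k <- 1L
  csq <- if (length(csqs) == length(imps)) csqs[k] else csq_str
  c(imps[k], csq)
}

parse_info_field <- function(info) {
  if (is.na(info) || info == "." || info == "") return(list())
  parts <- strsplit(info, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- vapply(kv, function(x) if (length(x) >= 2) x[2] else "TRUE", character(1))
  names(vals) <- vapply(kv, `[`, character(1), 1)
  as.list(vals)
}

# Per-alt selection for Number=A style values ("0.01,0.2" at a 2-alt site).
pick_alt_value <- function(value, alt_index, n_alt) {
  if (is.null(value) || is.na(value)) return(NA_character_)
  pieces <- strsplit(value, ",", fixed = TRUE)[[1]]
  out <- if (length(pieces) == n_alt) pieces[alt_index] else value
  if (out %in% c(".", "")) NA_character_ else out
}

parse_gt_code <- function(gt, alt_index) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NA_integer_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_integer_)
  a <- suppressWarnings(as.integer(alleles))
  if (any(is.na(a))) return(NA_integer_)
  # haploid calls (e.g. male X) are treated as homozygous for that allele
  if (length(a) == 1) a <- c(a, a)
  sum(a == alt_index)
}

header_info_ids <- function(meta) {
  m <- regmatches(meta, regexec("^##INFO=<ID=([^,>]+)", meta))
  ids <- vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, character(1))
  ids[!is.na(ids)]
}

#' Read an annotated multi-sample VCF into the internal model
#'
#' Multi-allelic sites are decomposed into one record per alternate
#' allele before any filtering; genotypes are re-expressed against the
#' focal alt (other alternate alleles count as non-focal). Annotations
#' absent from a record stay missing (`NA`) and are never imputed to 0.
#'
#' @param path VCF 4.x file (plain or bgzip/gzip).
#' @param field_map named list from [default_field_map()] telling which
#'   INFO keys carry gene/impact/frequency/predictor annotations. Every
#'   mapped key must be declared in the VCF header.
#' @return A [wes_cohort()].
#' @export
read_annotated_vcf <- function(path, field_map = default_field_map()) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ", conditionMessage(e))
  )
  ids <- header_info_ids(v@meta)
  absent <- setdiff(unlist(field_map), ids)
  if (length(absent) > 0) {
    stop("field_map key(s) not declared in VCF header of '", path, "': ",
         paste(absent, collapse = ", "))
  }
  fix <- v@fix
  if (nrow(fix) == 0) {
    empty <- matrix(integer(0), nrow = 0, ncol = max(0L, ncol(v@gt) - 1L))
    samples <- if (ncol(v@gt) > 1) colnames(v@gt)[-1] else character(0)
    return(wes_cohort(empty_variants(), empty, empty, empty, samples))
  }
  samples <- colnames(v@gt)[-1]
  gt_raw <- vcfR::extract.gt(v, element = "GT", return.alleles = FALSE)
  dp_raw <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  gq_raw <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
  if (is.null(dim(gt_raw))) gt_raw <- matrix(gt_raw, ncol = length(samples))
  if (is.null(dim(dp_raw))) dp_raw <- matrix(dp_raw, ncol = length(samples))
  if (is.null(dim(gq_raw))) gq_raw <- matrix(gq_raw, ncol = length(samples))

  info_list <- lapply(fix[, "INFO"], parse_info_field)
  info_value <- function(field) {
    key <- field_map[[field]]
    vapply(info_list, function(info) {
      v <- info[[key]]
      if (is.null(v) || v %in% c(".", "")) NA_character_ else v
    }, character(1))
  }

  alt_list <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  site_of <- rep(seq_len(nrow(fix)), n_alt)   # expanded row -> source site
  alt_idx <- unlist(lapply(n_alt, seq_len))   # focal alt index per row

  expand_field <- function(field) {
    v <- info_value(field)[site_of]
    multi <- n_alt[site_of] > 1
    if (any(multi)) {
      v[multi] <- mapply(pick_alt_value, v[multi], alt_idx[multi],
                         n_alt[site_of][multi], USE.NAMES = FALSE)
    }
    v
  }

  imp_raw <- expand_field("impact")
  csq_raw <- expand_field("consequence")
  sev <- t(mapply(most_severe, imp_raw, csq_raw, USE.NAMES = FALSE))
  variants <- tibble::tibble(
    chrom = fix[site_of, "CHROM"],
    pos = as.integer(fix[site_of, "POS"]),
    ref = fix[site_of, "REF"],
    alt = unlist(alt_list),
    gene = expand_field("gene"),
    impact = toupper(sev[, 1]),
    consequence = sev[, 2],
    freq_dbsnp = as.numeric(expand_field("freq_dbsnp")),
    freq_1kgp = as.numeric(expand_field("freq_1kgp")),
    freq_esp = as.numeric(expand_field("freq_esp")),
    polyphen2 = expand_field("polyphen2"),
    sift = expand_field("sift"),
    mutation_taster = expand_field("mutation_taster"),
    lrt = expand_field("lrt"),
    nnsplice = expand_field("nnsplice"),
    netgene2 = expand_field("netgene2"),
    hsf = expand_field("hsf"),
    asseda = expand_field("asseda")
  )
  variants <- tibble::add_column(
    variants,
    variant_id = paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":"),
    .before = 1
  )

  # genotype codes against the focal alt; fast path for plain diploid calls
  geno <- matrix(NA_integer_, nrow(variants), length(samples))
  gt_exp <- gt_raw[site_of, , drop = FALSE]
  fast <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
            "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
  for (j in seq_along(samples)) {
    g <- gt_exp[, j]
    code <- unname(fast[g])
    plain <- !is.na(code) & alt_idx == 1L
    geno[plain, j] <- code[plain]
    rest <- which(!plain)
    if (length(rest) > 0) {
      geno[rest, j] <- mapply(parse_gt_code, g[rest], alt_idx[rest],
                              USE.NAMES = FALSE)
    }
  }
  wes_cohort(variants, geno, dp_raw[site_of, , drop = FALSE],
             gq_raw[site_of, , drop = FALSE], samples)
}

empty_variants <- function() {
  tibble::tibble(
    variant_id = character(0), chrom = character(0), pos = integer(0),
    ref = character(0), alt = character(0), gene = character(0),
    impact = character(0), consequence = character(0),
    freq_dbsnp = numeric(0), freq_1kgp = numeric(0), freq_esp = numeric(0),
    polyphen2 = character(0), sift = character(0),
    mutation_taster = character(0), lrt = character(0),
    nnsplice = character(0), netgene2 = character(0), hsf = character(0),
    asseda = character(0)
  )
}

fmt_num <- function(x) {
  ifelse(is.na(x), NA_character_, format(x, scientific = FALSE, trim = TRUE, digits = 10))
}

#' Write a cohort back to an annotated VCF
#'
#' Each (site, alt) row becomes one biallelic VCF record with GT:DP:GQ
#' genotypes and the INFO keys named by `field_map`. Missing annotations
#' are omitted from INFO rather than written as 0, so read -> write ->
#' read round-trips preserve missingness.
#'
#' @param cohort a [wes_cohort()].
#' @param path output file.
#' @param field_map INFO key configuration, see [default_field_map()].
#' @param contigs optional named integer vector of contig lengths for the
#'   header (defaults to max position per chromosome).
#' @return `path`, invisibly.
#' @export
write_annotated_vcf <- function(cohort, path, field_map = default_field_map(),
                                contigs = NULL) {
  va <- cohort$variants
  if (is.null(contigs)) {
    contigs <- tapply(va$pos, va$chrom, max)
    contigs <- contigs[unique(va$chrom)]
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=ciliowes",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs)),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Gene symbol\">", field_map$gene),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"snpEff impact class\">", field_map$impact),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Consequence term\">", field_map$consequence),
    sprintf("##INFO=<ID=%s,Number=A,Type=Float,Description=\"dbSNP minor allele frequency\">", field_map$freq_dbsnp),
    sprintf("##INFO=<ID=%s,Number=A,Type=Float,Description=\"1000 Genomes alt allele frequency\">", field_map$freq_1kgp),
    sprintf("##INFO=<ID=%s,Number=A,Type=Float,Description=\"ESP alt allele frequency\">", field_map$freq_esp),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"PolyPhen-2 call\">", field_map$polyphen2),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"SIFT call\">", field_map$sift),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"MutationTaster call\">", field_map$mutation_taster),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"LRT call\">", field_map$lrt),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"NNSplice call\">", field_map$nnsplice),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"NetGene2 call\">", field_map$netgene2),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Human Splicing Finder call\">", field_map$hsf),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"ASSEDA call\">", field_map$asseda),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$samples), collapse = "\t")
  )
  info_of <- function(i) {
    vals <- c(
      setNames(va$gene[i], field_map$gene),
      setNames(va$impact[i], field_map$impact),
      setNames(va$consequence[i], field_map$consequence),
      setNames(fmt_num(va$freq_dbsnp[i]), field_map$freq_dbsnp),
      setNames(fmt_num(va$freq_1kgp[i]), field_map$freq_1kgp),
      setNames(fmt_num(va$freq_esp[i]), field_map$freq_esp),
      setNames(va$polyphen2[i], field_map$polyphen2),
      setNames(va$sift[i], field_map$sift),
      setNames(va$mutation_taster[i], field_map$mutation_taster),
      setNames(va$lrt[i], field_map$lrt),
      setNames(va$nnsplice[i], field_map$nnsplice),
      setNames(va$netgene2[i], field_map$netgene2),
      setNames(va$hsf[i], field_map$hsf),
      setNames(va$asseda[i], field_map$asseda)
    )
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) return(".")
    paste(names(vals), vals, sep = "=", collapse = ";")
  }
  gt_string <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  body <- character(nrow(va))
  for (i in seq_len(nrow(va))) {
    g <- cohort$geno[i, ]
    gts <- ifelse(is.na(g), "./.", gt_string[as.character(g)])
    dp <- ifelse(is.na(cohort$dp[i, ]), ".", as.integer(cohort$dp[i, ]))
    gq <- ifelse(is.na(cohort$gq[i, ]), ".", as.integer(cohort$gq[i, ]))
    body[i] <- paste(c(va$chrom[i], va$pos[i], ".", va$ref[i], va$alt[i], ".",
                       "PASS", info_of(i), "GT:DP:GQ",
                       paste(gts, dp, gq, sep = ":")), collapse = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
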