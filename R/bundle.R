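#' The 51-gene ciliary training set shipped with the package
#'
#' A curated set of 51 well-established ciliary genes (BBS, MKS, NPHP,
#' ALMS and intraflagellar-transport families) used to train the
#' prioritiser. The list ships as an editable text file
#' (`inst/extdata/training_ciliary_genes.txt`); it is a reasonable
#' stand-in for any gold-standard ciliary set, not an assertion of one
#' specific published build.
#'
#' @return Character vector of 51 gene symbols.
#' @export
ciliary_training_genes <- function() {
  c("BBS1", "BBS2", "ARL6", "BBS4", "BBS5", "MKKS", "BBS7", "TTC8", "BBS9",
    "BBS10", "TRIM32", "BBS12",
    "MKS1", "TMEM67", "CC2D2A", "CEP290", "RPGRIP1L", "TMEM216", "B9D1",
    "B9D2", "TCTN1", "TCTN2", "TCTN3", "TMEM138", "TMEM231", "TMEM237",
    "CEP41",
    "ALMS1", "NPHP1", "INVS", "NPHP3", "NPHP4", "IQCB1", "SDCCAG8", "OFD1",
    "AHI1", "ARL13B", "INPP5E", "KIF7",
    "IFT80", "IFT88", "IFT122", "IFT140", "IFT172", "WDR19", "WDR35",
    "TTC21B", "DYNC2H1", "KIAA0586", "PKHD1", "CEP164")
}

bbs_subset <- function() {
  c("BBS1", "BBS2", "ARL6", "BBS4", "BBS5", "MKKS", "BBS7", "TTC8", "BBS9",
    "BBS10", "TRIM32", "BBS12")
}

mks_subset <- function() {
  c("MKS1", "TMEM67", "CC2D2A", "CEP290", "RPGRIP1L", "TMEM216", "B9D1",
    "B9D2", "TCTN1", "TCTN2", "TCTN3", "TMEM138", "TMEM231", "TMEM237",
    "CEP41")
}

#' Engineer a multi-source gene feature matrix for a synthetic cohort
#'
#' Training genes draw features from a shared per-source ciliary pool,
#' so they resemble one another; `promote` genes receive feature sets
#' overlapping both a BBS-family and an MKS-family training gene (so
#' they rank at the top under the full set and under either subset);
#' `background` genes receive private features disjoint from the pool,
#' so they rank last.
#'
#' @param training training gene symbols.
#' @param promote candidate genes engineered to rank top.
#' @param background candidate genes engineered to rank bottom.
#' @param sources evidence-source labels.
#' @return Named list of per-source feature maps.
#' @export
build_feature_matrix <- function(training = ciliary_training_genes(),
                                 promote = c("CORO2B", "SLC3A1", "LMO7", "ZNF17"),
                                 background = sprintf("SYNG%02d", 1:11),
                                 sources = c("pathway", "go_bp", "ppi",
                                             "expression")) {
  out <- list()
  for (src in sources) {
    pool <- sprintf("%s:cil%03d", src, 1:60)
    feats <- list()
    for (g in training) feats[[g]] <- sample(pool, 10)
    bbs_pool <- intersect(bbs_subset(), training)
    if (length(bbs_pool) == 0) bbs_pool <- training
    mks_pool <- intersect(mks_subset(), training)
    if (length(mks_pool) == 0) mks_pool <- training
    for (i in seq_along(promote)) {
      g <- promote[i]
      anchor_bbs <- bbs_pool[1 + (i %% min(3, length(bbs_pool)))]
      anchor_mks <- mks_pool[1 + (i %% min(4, length(mks_pool)))]
      feats[[g]] <- unique(c(sample(feats[[anchor_bbs]], 5),
                             sample(feats[[anchor_mks]], 5),
                             sprintf("%s:own:%s", src, g)))
    }
    for (g in background) feats[[g]] <- sprintf("%s:bg:%s:%d", src, g, 1:5)
    out[[src]] <- feats
  }
  out
}

#' Simulate a full multi-family cohort bundle
#'
#' Generates one family per archetype plus everything the workflow
#' needs: the tier-1 panel (common ciliary genes), the known-genes list
#' (panel plus less common ciliary genes such as CRB1), the 51-gene
#' training set, BBS/MKS training subsets and an engineered feature
#' matrix. With `out_dir` set, the bundle is written as a
#' self-contained directory (per-family VCF + PED, gene lists, GMT
#' feature files and a JSON manifest of all parameters).
#'
#' @param archetypes list from [case_archetypes()] (any subset).
#' @param cfg a [sim_config()].
#' @param out_dir optional output directory.
#' @return Bundle list: `families`, `panel`, `known_genes`, `training`,
#'   `subsets`, `features`, `cfg` and (when written) `dir`.
#' @export
simulate_cohort <- function(archetypes = case_archetypes(),
                            cfg = sim_config(), out_dir = NULL) {
  stopifnot(length(archetypes) >= 1)
  families <- lapply(archetypes, simulate_family, cfg = cfg)
  names(families) <- vapply(families, `[[`, character(1), "family")
  set.seed(as.integer(cfg$seed) + 31L)
  features <- build_feature_matrix()
  bundle <- list(
    families = families,
    panel = gene_panel("common_ciliary_panel", ciliary_training_genes()),
    known_genes = gene_panel("known_ciliary_genes",
                             c(ciliary_training_genes(), "CRB1")),
    training = gene_panel("ciliary_training_51", ciliary_training_genes()),
    subsets = list(bbs = bbs_subset(), mks = mks_subset()),
    features = features,
    cfg = cfg
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "features"), showWarnings = FALSE)
    files <- list()
    for (fam in families) {
      vcf <- file.path(out_dir, paste0(fam$family, ".vcf"))
      ped <- file.path(out_dir, paste0(fam$family, ".ped"))
      write_annotated_vcf(fam$cohort, vcf, contigs = sim_contigs(cfg))
      write_pedigree(fam$pedigree, ped)
      files[[fam$family]] <- list(vcf = basename(vcf), ped = basename(ped),
                                  proband = fam$proband)
    }
    writeLines(bundle$panel$genes, file.path(out_dir, "panel.txt"))
    writeLines(bundle$known_genes$genes, file.path(out_dir, "known_genes.txt"))
    writeLines(bundle$training$genes, file.path(out_dir, "training_genes.txt"))
    writeLines(bundle$subsets$bbs, file.path(out_dir, "subset_bbs.txt"))
    writeLines(bundle$subsets$mks, file.path(out_dir, "subset_mks.txt"))
    for (src in names(features)) {
      write_feature_source(features[[src]],
                           file.path(out_dir, "features", paste0(src, ".gmt")))
    }
    manifest <- list(
      tool = paste0("ciliowes ", as.character(utils::packageVersion("ciliowes"))),
      config = unclass(cfg),
      families = files,
      archetype_ids = vapply(archetypes, `[[`, integer(1), "id")
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    bundle$dir <- out_dir
  }
  bundle
}

#' Load a written cohort bundle from disk
#'
#' @param dir directory written by [simulate_cohort()].
#' @param field_map INFO key configuration for the VCFs.
#' @return Bundle list in the same shape as [simulate_cohort()] returns.
#' @export
load_bundle <- function(dir, field_map = default_field_map()) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                                 simplifyVector = FALSE)
  families <- lapply(names(manifest$families), function(famid) {
    entry <- manifest$families[[famid]]
    cohort <- read_annotated_vcf(file.path(dir, entry$vcf), field_map)
    pedigree <- read_pedigree(file.path(dir, entry$ped))
    list(family = famid, cohort = cohort, pedigree = pedigree,
         proband = entry$proband)
  })
  names(families) <- names(manifest$families)
  src_files <- list.files(file.path(dir, "features"), pattern = "\\.gmt$",
                          full.names = TRUE)
  names(src_files) <- sub("\\.gmt$", "", basename(src_files))
  list(
    families = families,
    panel = read_gene_list(file.path(dir, "panel.txt"), "common_ciliary_panel"),
    known_genes = read_gene_list(file.path(dir, "known_genes.txt"),
                                 "known_ciliary_genes"),
    training = read_gene_list(file.path(dir, "training_genes.txt"),
                              "ciliary_training_51"),
    subsets = list(
      bbs = read_gene_list(file.path(dir, "subset_bbs.txt"))$genes,
      mks = read_gene_list(file.path(dir, "subset_mks.txt"))$genes
    ),
    features = read_feature_matrix(src_files),
    dir = dir
  )
}
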