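#' Read a PLINK-style 6-column pedigree file
#'
#' Columns: family id, sample id, father id, mother id, sex (1 male,
#' 2 female, 0 unknown), phenotype (2 affected, 1 unaffected, 0 or -9
#' unknown). Parent id 0 means no parent recorded. Row order is
#' irrelevant.
#'
#' @param path whitespace-delimited PED file.
#' @return A tibble of class `pedigree` with columns `family`, `id`,
#'   `father`, `mother` (NA when absent), `sex` and `affected`
#'   (`"affected"`, `"unaffected"`, `"unknown"`).
#' @export
read_pedigree <- function(path) {
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("family", "id", "father", "mother",
                                         "sex", "phenotype"),
                           colClasses = "character")
  as_pedigree(tibble::tibble(
    family = raw$family,
    id = raw$id,
    father = ifelse(raw$father %in% c("0", ""), NA_character_, raw$father),
    mother = ifelse(raw$mother %in% c("0", ""), NA_character_, raw$mother),
    sex = c(`1` = "male", `2` = "female")[raw$sex],
    affected = dplyr::case_when(
      raw$phenotype == "2" ~ "affected",
      raw$phenotype == "1" ~ "unaffected",
      TRUE ~ "unknown"
    )
  ))
}

#' Build a validated pedigree from a tibble
#'
#' @param ped tibble with columns `family`, `id`, `father`, `mother`,
#'   `sex`, `affected`.
#' @return The tibble with class `pedigree` after validation: parental
#'   ids must reference samples of the same family and no sample may be
#'   its own ancestor.
#' @export
as_pedigree <- function(ped) {
  ped <- tibble::as_tibble(ped)
  if (anyDuplicated(ped$id)) stop("duplicate sample ids in pedigree")
  for (i in seq_len(nrow(ped))) {
    for (par in c("father", "mother")) {
      p <- ped[[par]][i]
      if (is.na(p)) next
      j <- match(p, ped$id)
      if (is.na(j)) {
        stop("pedigree validation: ", par, " id '", p, "' of sample '",
             ped$id[i], "' is not a sample in the file")
      }
      if (ped$family[j] != ped$family[i]) {
        stop("pedigree validation: ", par, " '", p, "' of sample '",
             ped$id[i], "' belongs to a different family")
      }
    }
  }
  # ancestor cycle check by iterated parent lookup
  for (s in ped$id) {
    seen <- character(0)
    frontier <- s
    while (length(frontier) > 0) {
      idx <- match(frontier, ped$id)
      parents <- stats::na.omit(c(ped$father[idx], ped$mother[idx]))
      if (s %in% parents) stop("pedigree validation: sample '", s, "' is its own ancestor")
      frontier <- setdiff(parents, seen)
      seen <- union(seen, parents)
    }
  }
  class(ped) <- c("pedigree", class(ped))
  ped
}

#' Write a pedigree back to PED format
#' @param ped a `pedigree` tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(
    family = ped$family, id = ped$id,
    father = ifelse(is.na(ped$father), "0", ped$father),
    mother = ifelse(is.na(ped$mother), "0", ped$mother),
    sex = ifelse(is.na(ped$sex), "0", ifelse(ped$sex == "male", "1", "2")),
    phenotype = c(affected = "2", unaffected = "1", unknown = "0")[ped$affected]
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene panel from a plain-text list
#'
#' One symbol per line; `#` starts a comment. Symbols are de-duplicated
#' and upper-cased.
#'
#' @param path text file.
#' @param name panel label (defaults to the file name).
#' @return A `gene_panel`: list with `name` and the character set `genes`.
#' @export
read_gene_list <- function(path, name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  genes <- toupper(trimws(lines))
  genes <- unique(genes[genes != ""])
  if (length(genes) == 0) stop("gene list '", path, "' contains no symbols")
  gene_panel(name, genes)
}

#' Construct a gene panel
#' @param name label.
#' @param genes character vector of symbols (upper-cased, de-duplicated).
#' @return A `gene_panel` object.
#' @export
gene_panel <- function(name, genes) {
  genes <- unique(toupper(trimws(genes)))
  genes <- genes[genes != ""]
  if (length(genes) == 0) stop("gene panel must be non-empty")
  structure(list(name = name, genes = genes), class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat("<gene_panel> ", x$name, ": ", length(x$genes), " gene(s)\n", sep = "")
  invisible(x)
}

#' Read a GMT-style gene feature source
#'
#' Each line is `feature<TAB>gene1<TAB>gene2...`; the transpose (per-gene
#' feature sets) is returned. Two-column `gene<TAB>feature` TSVs are also
#' accepted.
#'
#' @param path text file.
#' @return Named list: gene symbol -> character vector of feature ids.
#' @export
read_feature_source <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  out <- list()
  fields <- strsplit(lines, "\t", fixed = TRUE)
  two_col <- all(vapply(fields, length, integer(1)) == 2)
  for (f in fields) {
    feature <- f[1]
    genes <- toupper(f[-1])
    if (two_col) { genes <- toupper(f[1]); feature <- f[2] }
    for (g in genes) out[[g]] <- c(out[[g]], feature)
  }
  lapply(out, unique)
}

#' Read a multi-source gene feature matrix
#' @param paths named character vector of per-source GMT files; names are
#'   the evidence-source labels.
#' @return Named list of per-source feature maps (see [read_feature_source()]).
#' @export
read_feature_matrix <- function(paths) {
  if (is.null(names(paths)) || any(names(paths) == "")) {
    names(paths) <- sub("\\.[^.]*$", "", basename(paths))
  }
  lapply(paths, read_feature_source)
}

#' Write a feature source in GMT form (`feature<TAB>genes...`)
#' @param features named list gene -> feature ids.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_feature_source <- function(features, path) {
  inv <- list()
  for (g in names(features)) {
    for (f in features[[g]]) inv[[f]] <- c(inv[[f]], g)
  }
  lines <- vapply(names(inv),
                  function(f) paste(c(f, sort(unique(inv[[f]]))), collapse = "\t"),
                  character(1))
  writeLines(sort(lines), path)
  invisible(path)
}

report_columns <- function() {
  c("family", "gene", "variant", "zygosity", "tier", "consensus_score",
    "in_roh", "segregation", "fused_rank")
}

#' Write a candidate report as TSV or JSON
#'
#' Column order is stable (`family`, `gene`, `variant`, `zygosity`,
#' `tier`, `consensus_score`, `in_roh`, `segregation`, `fused_rank`) and
#' the two formats carry identical content.
#'
#' @param candidates tibble of ranked candidate records.
#' @param path output file.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(candidates, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  cols <- report_columns()
  candidates <- tibble::as_tibble(candidates)
  for (col in setdiff(cols, names(candidates))) candidates[[col]] <- NA
  candidates <- candidates[, cols]
  if (format == "tsv") {
    utils::write.table(candidates, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  } else {
    jsonlite::write_json(candidates, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read back a JSON candidate report
#' @param path JSON file written by [write_report()].
#' @return Tibble with the stable report columns.
#' @export
read_report_json <- function(path) {
  df <- jsonlite::fromJSON(path)
  if (length(df) == 0 || is.null(dim(df))) {
    df <- as.data.frame(matrix(nrow = 0, ncol = length(report_columns()),
                               dimnames = list(NULL, report_columns())))
  }
  tibble::as_tibble(df)[, report_columns()]
}
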