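#' Configuration of the windowed run-of-homozygosity scan
#'
#' The scan emulates the conventional exome-tuned windowed approach: a
#' sliding window of `window_size` markers tolerates at most
#' `max_het_per_window` heterozygous and `max_missing_per_window`
#' missing calls; a marker is ROH-eligible when more than
#' `eligible_frac` of the windows overlapping it satisfy both bounds.
#' Maximal runs of eligible markers become segments, split at
#' inter-marker gaps above `max_gap`, then screened on marker support,
#' physical length and marker density. All values are exposed because
#' exome marker maps are sparse and irregular; the defaults are
#' deliberately conservative for exome data and every report records
#' the configuration used.
#'
#' @param window_size markers per window.
#' @param max_het_per_window maximum heterozygous calls per window.
#' @param max_missing_per_window maximum missing calls per window.
#' @param min_segment_markers minimum markers supporting a segment.
#' @param min_segment_length minimum segment length (kb).
#' @param min_density minimum markers per 50 kb of segment.
#' @param max_gap maximum gap between consecutive markers (kb) before a
#'   run is split.
#' @param eligible_frac fraction of satisfying overlapping windows above
#'   which a marker is eligible.
#' @param consanguinity_min_length segment length (kb) above which a
#'   sample is flagged as consistent with consanguinity. Figures quoted
#'   as ">100,000 kb" read as a unit misprint (100 Mb exceeds most
#'   chromosome arms); reports print the value actually used.
#' @return A `roh_config` list.
#' @export
roh_config <- function(window_size = 50, max_het_per_window = 1,
                       max_missing_per_window = 5, min_segment_markers = 25,
                       min_segment_length = 1000, min_density = 1,
                       max_gap = 1000, eligible_frac = 0.05,
                       consanguinity_min_length = 1000) {
  stopifnot(window_size >= 1, max_het_per_window >= 0,
            max_missing_per_window >= 0, min_segment_markers >= 0,
            min_segment_length > 0, min_density >= 0, max_gap > 0,
            eligible_frac >= 0, eligible_frac < 1)
  structure(as.list(environment()), class = "roh_config")
}

# Eligibility of each marker on one chromosome. het/miss are logical
# vectors; windows are all length-w contiguous marker spans (a single
# all-marker window when fewer markers than w exist).
roh_eligible <- function(het, miss, cfg) {
  n <- length(het)
  w <- min(cfg$window_size, n)
  n_win <- n - w + 1
  het_cs <- cumsum(c(0, het))
  miss_cs <- cumsum(c(0, miss))
  starts <- seq_len(n_win)
  good <- (het_cs[starts + w] - het_cs[starts]) <= cfg$max_het_per_window &
    (miss_cs[starts + w] - miss_cs[starts]) <= cfg$max_missing_per_window
  good_cs <- cumsum(c(0, good))
  j <- seq_len(n)
  lo <- pmax(1L, j - w + 1L)
  hi <- pmin(j, n_win)
  n_overlap <- hi - lo + 1L
  n_good <- good_cs[hi + 1L] - good_cs[lo]
  n_good / n_overlap > cfg$eligible_frac
}

segment_runs <- function(eligible, pos, het, cfg) {
  out <- list()
  r <- rle(eligible)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in which(r$values)) {
    idx <- starts[k]:ends[k]
    # split where the inter-marker gap exceeds max_gap (kb)
    gaps <- diff(pos[idx]) / 1000
    piece <- cumsum(c(0, gaps > cfg$max_gap))
    for (p in unique(piece)) {
      sel <- idx[piece == p]
      length_kb <- (pos[sel[length(sel)]] - pos[sel[1]] + 1) / 1000
      n_markers <- length(sel)
      if (n_markers < cfg$min_segment_markers) next
      if (length_kb < cfg$min_segment_length) next
      if (n_markers < cfg$min_density * length_kb / 50) next
      out[[length(out) + 1]] <- tibble::tibble(
        start = pos[sel[1]], end = pos[sel[length(sel)]],
        n_markers = n_markers, n_het = sum(het[sel]),
        length_kb = length_kb
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Detect runs of homozygosity for one sample
#'
#' @param markers tibble with columns `chrom`, `pos` (1-based bp,
#'   sorted within chromosome) and `geno` (0 hom-ref, 1 het, 2 hom-alt,
#'   `NA` missing).
#' @param cfg a [roh_config()].
#' @return Tibble of segments: `chrom`, `start`, `end` (1-based,
#'   inclusive), `n_markers`, `n_het`, `length_kb`, sorted by chromosome
#'   and start.
#' @export
detect_roh <- function(markers, cfg = roh_config()) {
  markers <- tibble::as_tibble(markers)
  stopifnot(all(c("chrom", "pos", "geno") %in% names(markers)))
  segs <- list()
  for (chr in unique(markers$chrom)) {
    m <- markers[markers$chrom == chr, ]
    if (is.unsorted(m$pos)) stop("markers on ", chr, " are not sorted by position")
    if (nrow(m) == 0) next
    het <- !is.na(m$geno) & m$geno == 1
    miss <- is.na(m$geno)
    eligible <- roh_eligible(het, miss, cfg)
    s <- segment_runs(eligible, m$pos, het, cfg)
    if (nrow(s) > 0) segs[[chr]] <- tibble::add_column(s, chrom = chr, .before = 1)
  }
  out <- dplyr::bind_rows(segs)
  if (nrow(out) == 0) {
    return(tibble::tibble(chrom = character(0), start = integer(0),
                          end = integer(0), n_markers = integer(0),
                          n_het = integer(0), length_kb = numeric(0)))
  }
  out[order(out$chrom, out$start), ]
}

#' Extract the ROH marker track of one sample from a cohort
#'
#' All VCF sites with a called genotype for the sample become markers.
#'
#' @param cohort a [wes_cohort()].
#' @param sample sample id.
#' @return Marker tibble suitable for [detect_roh()].
#' @export
roh_markers <- function(cohort, sample) {
  stop_unknown_sample(cohort, sample)
  m <- tibble::tibble(chrom = cohort$variants$chrom,
                      pos = cohort$variants$pos,
                      geno = cohort$geno[, sample])
  m[order(m$chrom, m$pos), ]
}

#' Test whether variants fall inside detected ROH segments
#'
#' Boundaries are inclusive on both sides.
#'
#' @param variants tibble with `chrom` and `pos` columns (e.g.
#'   `cohort$variants`).
#' @param segments segment tibble from [detect_roh()].
#' @return Logical vector over variant rows.
#' @export
variant_in_roh <- function(variants, segments) {
  if (nrow(segments) == 0) return(rep(FALSE, nrow(variants)))
  vapply(seq_len(nrow(variants)), function(i) {
    any(segments$chrom == variants$chrom[i] &
          segments$start <= variants$pos[i] &
          variants$pos[i] <= segments$end)
  }, logical(1))
}

#' Export ROH segments as BED (0-based half-open)
#' @param segments segment tibble from [detect_roh()].
#' @param path output BED file.
#' @return `path`, invisibly.
#' @export
write_roh_bed <- function(segments, path) {
  bed <- data.frame(chrom = segments$chrom,
                    start = segments$start - 1L,
                    end = segments$end)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
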