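# Window-based mRNA-lncRNA pairing: the core screening step. A lncRNA is
# paired with an mRNA when the gap between their collapsed gene spans is
# within the proximity window (50 kb by default, boundary inclusive).

#' Pair mRNAs with lncRNAs by genomic proximity
#'
#' Finds every (mRNA, lncRNA) pair on the same chromosome whose boundary
#' gap is within `window_bp`. Distances are gaps between collapsed gene
#' spans (see [feature_distance()]); overlapping or abutting features have
#' distance 0. The comparison is boundary-inclusive by default
#' (`distance <= window_bp`); `inclusive = FALSE` uses a strict `<`.
#' Pairing is many-to-many: one lncRNA may pair with several mRNAs and
#' vice versa. Strand is ignored unless `stranded = TRUE` (experimental),
#' which restricts pairs to features on the same strand.
#'
#' Candidate pairs are generated through the per-chromosome interval index
#' (`IRanges::findOverlaps` with `maxgap`), which is tested for exact
#' equality against brute-force all-pairs enumeration.
#'
#' @param mrnas,lncrnas `FeatureCatalog`s (typically [catalog_subset()]
#'   by class).
#' @param window_bp non-negative window in bp (default 50000).
#' @param inclusive logical; include pairs at exactly `window_bp`
#'   (default TRUE).
#' @param stranded logical; require matching strands (default FALSE).
#' @return data.frame of pairs: `mrna_id`, `lncrna_id`, `chrom`,
#'   `distance_bp`, `relation` (`overlapping`, `upstream_of_mrna` — the
#'   lncRNA lies before the mRNA span on the reference strand — or
#'   `downstream_of_mrna`), ordered by chrom, mrna_id, lncrna_id.
#' @export
pair_by_proximity <- function(mrnas, lncrnas, window_bp = 50000L,
                              inclusive = TRUE, stranded = FALSE) {
  if (window_bp < 0) stop("window_bp must be non-negative")
  m <- mrnas$features[mrnas$features$feature_class == "mRNA", , drop = FALSE]
  l <- lncrnas$features[lncrnas$features$feature_class == "lncRNA", ,
                        drop = FALSE]
  if (nrow(m) == 0L || nrow(l) == 0L) {
    message("pair_by_proximity: one input set is empty, no pairs")
    return(.empty_pairs())
  }
  gr_m <- GenomicRanges::GRanges(m$chrom,
                                 IRanges::IRanges(m$start + 1L, m$end))
  gr_l <- GenomicRanges::GRanges(l$chrom,
                                 IRanges::IRanges(l$start + 1L, l$end))
  # maxgap hits give gap <= window; the exact distance and the strict
  # boundary are recomputed below so both modes share one candidate pass
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    gr_m, gr_l, maxgap = as.integer(window_bp), ignore.strand = TRUE))
  mi <- S4Vectors::queryHits(hits)
  li <- S4Vectors::subjectHits(hits)
  if (!length(mi)) return(.empty_pairs())
  d <- gap_bp(m$start[mi], m$end[mi], l$start[li], l$end[li])
  keep <- if (inclusive) d <= window_bp else d < window_bp
  if (stranded)
    keep <- keep & m$strand[mi] == l$strand[li] &
      m$strand[mi] %in% c("+", "-")
  mi <- mi[keep]; li <- li[keep]; d <- d[keep]
  if (!length(mi)) return(.empty_pairs())
  overlaps <- m$start[mi] < l$end[li] & l$start[li] < m$end[mi]
  relation <- ifelse(overlaps, "overlapping",
              ifelse(l$end[li] <= m$start[mi], "upstream_of_mrna",
                     "downstream_of_mrna"))
  out <- data.frame(mrna_id = m$feature_id[mi],
                    lncrna_id = l$feature_id[li],
                    chrom = m$chrom[mi],
                    distance_bp = d,
                    relation = relation,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$mrna_id, out$lncrna_id), ]
  rownames(out) <- NULL
  out
}

.empty_pairs <- function() {
  data.frame(mrna_id = character(0), lncrna_id = character(0),
             chrom = character(0), distance_bp = integer(0),
             relation = character(0), stringsAsFactors = FALSE)
}

#' Summarize a pair set
#'
#' @param pairs a [pair_by_proximity()] result.
#' @return list with `n_pairs`, `per_chrom` (named counts),
#'   `distance_quantiles` (0/25/50/75/100%), `overlap_fraction`.
#' @export
summarize_pairs <- function(pairs) {
  if (nrow(pairs) == 0L)
    return(list(n_pairs = 0L, per_chrom = integer(0),
                distance_quantiles = stats::setNames(rep(NA_real_, 5),
                  c("0%", "25%", "50%", "75%", "100%")),
                overlap_fraction = 0))
  list(n_pairs = nrow(pairs),
       per_chrom = table(pairs$chrom),
       distance_quantiles = stats::quantile(pairs$distance_bp),
       overlap_fraction = mean(pairs$relation == "overlapping"))
}

#' Write pairs as TSV and BEDPE
#'
#' Writes the pair table as TSV and, when both catalogs are given, a
#' BEDPE-style paired-interval file for genome-browser use.
#'
#' @param pairs a [pair_by_proximity()] result.
#' @param path output TSV path.
#' @param mrnas,lncrnas optional `FeatureCatalog`s; when both are present
#'   a `.bedpe` file is written next to `path`.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path, mrnas = NULL, lncrnas = NULL) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(mrnas) && !is.null(lncrnas) && nrow(pairs)) {
    fm <- catalog_get(mrnas, pairs$mrna_id)
    fl <- catalog_get(lncrnas, pairs$lncrna_id)
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s|%s\t%d\t.\t.",
                     fm$chrom, fm$start, fm$end,
                     fl$chrom, fl$start, fl$end,
                     pairs$mrna_id, pairs$lncrna_id, pairs$distance_bp)
    writeLines(lines, sub("\\.tsv$", ".bedpe", path))
  }
  invisible(path)
}
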