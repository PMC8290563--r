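# Internal coordinate convention: 0-based, half-open [start, end).
# GTF input (1-based, closed) is shifted by start - 1 on read; BED input is
# ingested unchanged. All distances and pairings operate on this convention.

.norm_chrom <- function(x) sub("^chr", "", x)

#' Construct a feature catalog
#'
#' A `FeatureCatalog` holds located mRNA and lncRNA loci (gene-level spans,
#' 0-based half-open coordinates) together with a per-chromosome interval
#' index used for overlap and proximity queries.
#'
#' @param features data.frame with columns `feature_id`, `feature_class`
#'   (`"mRNA"` or `"lncRNA"`), `chrom`, `strand` (`"+"`, `"-"` or `"*"`),
#'   `start`, `end` (0-based half-open).
#' @param n_skipped integer, number of input records dropped during parsing
#'   (recorded for the funnel log).
#' @return An object of class `FeatureCatalog`.
#' @export
feature_catalog <- function(features, n_skipped = 0L) {
  required <- c("feature_id", "feature_class", "chrom", "strand", "start", "end")
  missing_cols <- setdiff(required, names(features))
  if (length(missing_cols))
    stop("feature table lacks columns: ", paste(missing_cols, collapse = ", "))
  features <- as.data.frame(features)[required]
  features$feature_id <- as.character(features$feature_id)
  features$chrom <- .norm_chrom(as.character(features$chrom))
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  bad <- which(!(features$start >= 0L & features$start < features$end))
  if (length(bad))
    stop("invalid interval (need 0 <= start < end) for feature ",
         features$feature_id[bad[1]])
  if (anyDuplicated(features$feature_id))
    stop("duplicate feature_id: ",
         features$feature_id[duplicated(features$feature_id)][1])
  if (!all(features$feature_class %in% c("mRNA", "lncRNA")))
    stop("feature_class must be 'mRNA' or 'lncRNA'")
  features$strand[!features$strand %in% c("+", "-")] <- "*"
  rownames(features) <- NULL
  gr <- GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = features$strand
  )
  names(gr) <- features$feature_id
  structure(
    list(features = features, index = gr, n_skipped = as.integer(n_skipped)),
    class = "FeatureCatalog"
  )
}

#' @export
print.FeatureCatalog <- function(x, ...) {
  tab <- table(x$features$feature_class)
  cat(sprintf(
    "FeatureCatalog: %d features (%s) on %d chromosome(s)\n",
    nrow(x$features),
    paste(sprintf("%s %s", tab, names(tab)), collapse = ", "),
    length(unique(x$features$chrom))
  ))
  if (x$n_skipped > 0L)
    cat(sprintf("  %d input record(s) skipped during parsing\n", x$n_skipped))
  invisible(x)
}

#' @export
length.FeatureCatalog <- function(x) nrow(x$features)

#' Look up features by id
#'
#' @param catalog a `FeatureCatalog`.
#' @param ids character vector of feature ids.
#' @return data.frame of the matching features, in the order of `ids`.
#' @export
catalog_get <- function(catalog, ids) {
  idx <- match(ids, catalog$features$feature_id)
  if (anyNA(idx)) stop("unknown feature id: ", ids[which(is.na(idx))[1]])
  catalog$features[idx, , drop = FALSE]
}

#' Interval query against the catalog index
#'
#' Returns every feature whose interval intersects the query interval
#' (0-based half-open). Equivalent to, and tested against, a linear scan.
#'
#' @param catalog a `FeatureCatalog`.
#' @param chrom chromosome name (with or without a "chr" prefix).
#' @param start,end query interval, 0-based half-open.
#' @return data.frame of overlapping features.
#' @export
catalog_query <- function(catalog, chrom, start, end) {
  if (start < 0 || start >= end) stop("need 0 <= start < end")
  q <- GenomicRanges::GRanges(.norm_chrom(chrom),
                              IRanges::IRanges(start + 1L, end))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(q, catalog$index, ignore.strand = TRUE))
  catalog$features[S4Vectors::subjectHits(hits), , drop = FALSE]
}

#' Subset a catalog by feature class or id
#'
#' @param catalog a `FeatureCatalog`.
#' @param feature_class optional, `"mRNA"` or `"lncRNA"`.
#' @param ids optional character vector of ids to keep.
#' @return a new `FeatureCatalog`.
#' @export
catalog_subset <- function(catalog, feature_class = NULL, ids = NULL) {
  keep <- rep(TRUE, nrow(catalog$features))
  if (!is.null(feature_class))
    keep <- keep & catalog$features$feature_class %in% feature_class
  if (!is.null(ids))
    keep <- keep & catalog$features$feature_id %in% ids
  feature_catalog(catalog$features[keep, , drop = FALSE])
}

.parse_gtf_attrs <- function(attr_string, key) {
  m <- regmatches(attr_string,
                  regexec(paste0(key, '[ =]+"?([^";]+)"?'), attr_string))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_,
         character(1))
}

#' Read a GTF annotation into a feature catalog
#'
#' Coordinates in GTF are 1-based closed; they are converted to the internal
#' 0-based half-open convention (`start - 1`, `end`). Records belonging to
#' the same gene (by `gene_id`) are collapsed to their genomic span
#' (minimum start, maximum end), i.e. the catalog is gene-level, not
#' isoform-aware. Records whose biotype is absent from `class_map` are
#' skipped and counted in the catalog's `n_skipped` field.
#'
#' @param path path to a GTF2.2/GFF-style file.
#' @param class_map named character vector mapping biotype attribute values
#'   to feature classes; the default maps common Ensembl biotypes.
#' @param biotype_keys attribute keys searched (in order) for the biotype.
#' @return a `FeatureCatalog`.
#' @export
read_gtf <- function(path,
                     class_map = c(protein_coding = "mRNA",
                                   mRNA = "mRNA",
                                   lncRNA = "lncRNA",
                                   lincRNA = "lncRNA",
                                   antisense = "lncRNA"),
                     biotype_keys = c("gene_biotype", "transcript_biotype",
                                      "gene_type", "biotype")) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("empty catalog: no records in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L))
    stop("malformed GTF line ", lineno[which(nf < 9L)[1]],
         ": expected 9 tab-separated fields, got ", nf[which(nf < 9L)[1]])
  mat <- do.call(rbind, lapply(fields, `[`, 1:9))
  start1 <- suppressWarnings(as.integer(mat[, 4]))
  end1 <- suppressWarnings(as.integer(mat[, 5]))
  bad <- which(is.na(start1) | is.na(end1) | start1 < 1L | end1 < start1)
  if (length(bad))
    stop("malformed GTF line ", lineno[bad[1]], ": bad coordinates")
  attrs <- mat[, 9]
  gene_id <- .parse_gtf_attrs(attrs, "gene_id")
  bad <- which(is.na(gene_id))
  if (length(bad))
    stop("malformed GTF line ", lineno[bad[1]], ": missing gene_id attribute")
  biotype <- rep(NA_character_, length(attrs))
  for (key in biotype_keys) {
    miss <- is.na(biotype)
    if (!any(miss)) break
    biotype[miss] <- .parse_gtf_attrs(attrs[miss], key)
  }
  cls <- unname(class_map[biotype])
  skipped_ids <- unique(gene_id[is.na(cls)])
  ok <- !is.na(cls)
  if (!any(ok)) stop("empty catalog: no record in ", path,
                     " has a biotype mappable through class_map")
  # collapse to gene span: min start, max end over all records of a gene
  df <- data.frame(feature_id = gene_id[ok], feature_class = cls[ok],
                   chrom = .norm_chrom(mat[ok, 1]), strand = mat[ok, 7],
                   start = start1[ok] - 1L, end = end1[ok],
                   stringsAsFactors = FALSE)
  sp <- split(seq_len(nrow(df)), df$feature_id)
  collapsed <- do.call(rbind, lapply(sp, function(i) {
    chroms <- unique(df$chrom[i])
    if (length(chroms) > 1L)
      stop("feature ", df$feature_id[i[1]], " spans multiple chromosomes")
    data.frame(feature_id = df$feature_id[i[1]],
               feature_class = df$feature_class[i[1]],
               chrom = chroms, strand = df$strand[i[1]],
               start = min(df$start[i]), end = max(df$end[i]),
               stringsAsFactors = FALSE)
  }))
  collapsed <- collapsed[order(collapsed$chrom, collapsed$start,
                               collapsed$feature_id), ]
  n_skipped <- length(setdiff(skipped_ids, collapsed$feature_id))
  feature_catalog(collapsed, n_skipped = n_skipped)
}

#' Read a BED file into a feature catalog
#'
#' BED is already 0-based half-open, so coordinates are ingested without
#' shifting. The name column (4th) supplies `feature_id`; ids are
#' auto-generated for BED3 input.
#'
#' @param path path to a BED3+ file.
#' @param feature_class class assigned to every record (`"mRNA"` or
#'   `"lncRNA"`).
#' @return a `FeatureCatalog`.
#' @export
read_bed <- function(path, feature_class = c("mRNA", "lncRNA")) {
  feature_class <- match.arg(feature_class)
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("empty catalog: no records in ", path)
  fields <- strsplit(lines, "[\t ]+")
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed BED line ", lineno[which(nf < 3L)[1]],
         ": fewer than 3 fields")
  chrom <- vapply(fields, `[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0L | start >= end)
  if (length(bad))
    stop("malformed BED line ", lineno[bad[1]],
         ": need integer 0 <= start < end")
  name <- vapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) >= 4L && nzchar(f[4]) && f[4] != ".") f[4]
    else sprintf("%s_feat_%d", feature_class, i)
  }, character(1))
  strand <- vapply(fields, function(f)
    if (length(f) >= 6L && f[6] %in% c("+", "-")) f[6] else "*", character(1))
  feature_catalog(data.frame(
    feature_id = name, feature_class = feature_class, chrom = chrom,
    strand = strand, start = start, end = end, stringsAsFactors = FALSE))
}

#' Write a catalog as BED6
#'
#' The name field carries the feature id with the feature class as a suffix
#' (`id|class`), so a written catalog round-trips its class labels.
#'
#' @param catalog a `FeatureCatalog`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(catalog, path) {
  f <- catalog$features
  strand <- ifelse(f$strand %in% c("+", "-"), f$strand, ".")
  lines <- sprintf("%s\t%d\t%d\t%s|%s\t0\t%s",
                   f$chrom, f$start, f$end, f$feature_id, f$feature_class,
                   strand)
  writeLines(lines, path)
  invisible(path)
}

#' Write a catalog as GTF (gene records)
#'
#' Internal 0-based half-open coordinates are converted back to the GTF
#' 1-based closed convention (`start + 1`, `end`), so a GTF read and
#' re-written preserves the printed coordinates.
#'
#' @param catalog a `FeatureCatalog`.
#' @param path output path.
#' @param source source field for the GTF records.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(catalog, path, source = "hmlnet") {
  f <- catalog$features
  biotype <- ifelse(f$feature_class == "mRNA", "protein_coding", "lncRNA")
  strand <- ifelse(f$strand %in% c("+", "-"), f$strand, ".")
  lines <- sprintf(
    '%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_biotype "%s";',
    f$chrom, source, f$start + 1L, f$end, strand, f$feature_id, biotype)
  writeLines(lines, path)
  invisible(path)
}

#' Genomic gap between two features
#'
#' The quantity thresholded by the proximity window: `NA` if the features
#' lie on different chromosomes; 0 if their intervals overlap or abut;
#' otherwise the gap in base pairs between the nearest boundaries,
#' `max(start_a, start_b) - min(end_a, end_b)`. Symmetric in its arguments;
#' strand is ignored.
#'
#' @param a,b single-row data.frames (or lists) with `chrom`, `start`,
#'   `end` in the internal 0-based half-open convention.
#' @return a non-negative integer, or `NA_integer_` for features on
#'   different chromosomes.
#' @export
feature_distance <- function(a, b) {
  if (.norm_chrom(a$chrom) != .norm_chrom(b$chrom)) return(NA_integer_)
  gap_bp(a$start, a$end, b$start, b$end)
}

# vectorized gap between half-open intervals on one chromosome
gap_bp <- function(start_a, end_a, start_b, end_b) {
  as.integer(pmax(0L, pmax(start_a, start_b) - pmin(end_a, end_b)))
}
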