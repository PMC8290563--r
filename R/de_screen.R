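# Differential-expression filtering and coding-potential screening of
# lncRNA candidates. DE tables are precomputed contrasts (high-fat vs
# low-fat); no DE estimation from raw data happens here.

#' Read a differential-expression table
#'
#' @param path TSV/CSV with header columns `feature_id`, `class`
#'   (mRNA/lncRNA), `log2fc`, and optionally `pvalue`.
#' @param sep field separator; `"\t"` (default) or `","`.
#' @return data.frame with columns `feature_id`, `feature_class`,
#'   `log2fc`, `pvalue`.
#' @export
read_de_table <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("DE table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!is.null(df$class) && is.null(df$feature_class))
    names(df)[names(df) == "class"] <- "feature_class"
  need <- c("feature_id", "feature_class", "log2fc")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("DE table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (is.null(df$pvalue)) df$pvalue <- NA_real_
  df[c("feature_id", "feature_class", "log2fc", "pvalue")]
}

#' Filter a DE table by fold change
#'
#' The screening rule is "log fold change above 2": by default the
#' magnitude `|log2fc| > logfc_threshold` is used, so that strongly
#' downregulated features (such as Cpt1b in the high-fat liver) are
#' retained alongside upregulated ones; `absolute = FALSE` gives the
#' strict one-sided rule `log2fc > logfc_threshold`.
#'
#' @param records data.frame as returned by [read_de_table()].
#' @param logfc_threshold positive log2 fold-change threshold (default 2).
#' @param p_threshold optional p-value cutoff applied in addition
#'   (`pvalue < p_threshold`); records with missing p fail it.
#' @param absolute logical; threshold the magnitude (default) or the
#'   signed value.
#' @return the retained records, ordered by `|log2fc|` descending with
#'   ties broken by `feature_id`.
#' @export
filter_differential <- function(records, logfc_threshold = 2,
                                p_threshold = NULL, absolute = TRUE) {
  if (logfc_threshold <= 0) stop("logfc_threshold must be positive")
  if (nrow(records) == 0L) return(records)
  if (any(!is.finite(records$log2fc)))
    stop("non-finite log2fc for feature ",
         records$feature_id[which(!is.finite(records$log2fc))[1]])
  keep <- if (absolute) abs(records$log2fc) > logfc_threshold
          else records$log2fc > logfc_threshold
  if (!is.null(p_threshold))
    keep <- keep & !is.na(records$pvalue) & records$pvalue < p_threshold
  out <- records[keep, , drop = FALSE]
  out <- out[order(-abs(out$log2fc), out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a coding-potential score table
#'
#' @param path TSV with header columns `feature_id`, `score` (higher =
#'   more coding-like), `label` (one of coding / noncoding / weak_coding).
#' @return data.frame with those columns.
#' @export
read_cp_table <- function(path) {
  if (!file.exists(path)) stop("coding-potential table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  miss <- setdiff(c("feature_id", "score", "label"), names(df))
  if (length(miss)) stop("coding-potential table lacks columns: ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$label), c("coding", "noncoding", "weak_coding"))
  if (length(bad)) stop("unknown coding-potential label: ", bad[1])
  df
}

#' Length of the longest open reading frame
#'
#' Scans the three forward frames for ATG-to-stop spans and returns the
#' length (in nt, including the stop codon) of the longest one, or 0 when
#' no complete ORF exists. Used as the fallback coding-potential heuristic
#' when no external score table is supplied.
#'
#' @param seq nucleotide string over A, C, G, T, N (case-insensitive).
#' @return integer ORF length in nt.
#' @export
longest_orf <- function(seq) {
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) stop("invalid character in sequence")
  n <- nchar(seq)
  if (n < 6L) return(0L)
  best <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    starts_at <- seq.int(1L + frame, n - 2L, by = 3L)
    if (!length(starts_at)) next
    codons <- substring(seq, starts_at, starts_at + 2L)
    open_from <- NA_integer_  # codon index of the current unclosed ATG
    for (i in seq_along(codons)) {
      if (is.na(open_from) && codons[i] == "ATG") open_from <- i
      if (!is.na(open_from) && codons[i] %in% stops) {
        best <- max(best, (i - open_from + 1L) * 3L)
        open_from <- NA_integer_
      }
    }
  }
  best
}

#' Screen lncRNA candidates for absence of strong coding potential
#'
#' Keeps candidates lacking strong coding potential. Evidence is used in
#' this order: an external score table (labels `noncoding` and
#' `weak_coding` are retained, `coding` removed); otherwise, if a
#' transcript sequence is available, the built-in ORF heuristic (a
#' candidate is called coding when its longest ORF is at least
#' `orf_min_len` nt or covers at least `orf_min_frac` of the transcript);
#' candidates with neither kind of evidence are retained and flagged in
#' the `cp_evidence` column, since the screen removes demonstrated coding
#' potential rather than requiring proof of non-coding status.
#'
#' @param candidates data.frame of DE records, all with
#'   `feature_class == "lncRNA"`.
#' @param cp optional coding-potential table ([read_cp_table()]).
#' @param fallback_sequences optional named character vector of transcript
#'   sequences, names matching `feature_id`.
#' @param orf_min_len ORF length (nt) at or above which the heuristic
#'   calls a transcript coding (default 300).
#' @param orf_min_frac ORF fraction of transcript length at or above which
#'   the heuristic calls it coding (default 0.3).
#' @return the retained candidates with an added `cp_evidence` column
#'   (`"score_table"`, `"orf_heuristic"`, or `"none"`).
#' @export
screen_noncoding <- function(candidates, cp = NULL,
                             fallback_sequences = NULL,
                             orf_min_len = 300L, orf_min_frac = 0.3) {
  if (nrow(candidates) && any(candidates$feature_class != "lncRNA"))
    stop("screen_noncoding expects lncRNA candidates only")
  if (nrow(candidates) == 0L) {
    candidates$cp_evidence <- character(0)
    return(candidates)
  }
  evidence <- rep("none", nrow(candidates))
  coding <- rep(FALSE, nrow(candidates))
  if (!is.null(cp)) {
    idx <- match(candidates$feature_id, cp$feature_id)
    has <- !is.na(idx)
    evidence[has] <- "score_table"
    coding[has] <- cp$label[idx[has]] == "coding"
  }
  if (!is.null(fallback_sequences)) {
    need <- evidence == "none" &
      candidates$feature_id %in% names(fallback_sequences)
    for (i in which(need)) {
      s <- fallback_sequences[[candidates$feature_id[i]]]
      orf <- longest_orf(s)
      evidence[i] <- "orf_heuristic"
      coding[i] <- orf >= orf_min_len || orf / nchar(s) >= orf_min_frac
    }
  }
  n_unscored <- sum(evidence == "none")
  if (n_unscored > 0L)
    warning(n_unscored, " candidate(s) had no coding-potential evidence; ",
            "retained with cp_evidence = 'none'")
  out <- candidates[!coding, , drop = FALSE]
  out$cp_evidence <- evidence[!coding]
  rownames(out) <- NULL
  out
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta_seqs <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file: ", path)
  id <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste0, character(1),
                 collapse = "")
  stats::setNames(unname(seqs), id)
}
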