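# Independent oracles and fixture builders shared across test files.
# Each oracle is a deliberately naive computation (brute force,
# enumeration) kept separate from the implementation path it checks.

# brute-force all-pairs proximity enumeration over feature data.frames
brute_pairs <- function(m, l, window, inclusive = TRUE) {
  rows <- list()
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(nrow(l))) {
      if (m$chrom[i] != l$chrom[j]) next
      d <- max(0L, max(m$start[i], l$start[j]) - min(m$end[i], l$end[j]))
      hit <- if (inclusive) d <= window else d < window
      if (hit)
        rows[[length(rows) + 1L]] <- data.frame(
          mrna_id = m$feature_id[i], lncrna_id = l$feature_id[j],
          chrom = m$chrom[i], distance_bp = as.integer(d),
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(mrna_id = character(0), lncrna_id = character(0),
                      chrom = character(0), distance_bp = integer(0)))
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$mrna_id, out$lncrna_id), ]
}

# random feature table (0-based half-open, non-degenerate intervals)
rand_features <- function(n, class, chroms = 5, max_pos = 1e6,
                          max_len = 5000, prefix = class) {
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(feature_id = sprintf("%s_%04d", prefix, seq_len(n)),
             feature_class = class,
             chrom = as.character(sample.int(chroms, n, replace = TRUE)),
             strand = sample(c("+", "-"), n, replace = TRUE),
             start = start, end = start + len,
             stringsAsFactors = FALSE)
}

# exhaustive hypergeometric upper tail P(X >= k): enumeration over the pmf
hyper_enum_p <- function(N, K, n, k) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# quadratic ORF scan: every ATG, walk codons to the first in-frame stop
brute_orf <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  best <- 0L
  for (i in seq_len(max(0L, n - 2L))) {
    if (substring(seq, i, i + 2L) != "ATG") next
    j <- i
    while (j + 2L <= n) {
      codon <- substring(seq, j, j + 2L)
      if (j > i && codon %in% c("TAA", "TAG", "TGA")) {
        best <- max(best, j + 3L - i)
        break
      }
      j <- j + 3L
    }
  }
  best
}

# neighbor-counting degree from an edge data.frame (a, b)
brute_degree <- function(edges, nodes) {
  vapply(nodes, function(v)
    sum((edges$a == v | edges$b == v) & edges$a != edges$b), integer(1))
}

# all-pairs rank counting AUC, ties count one half
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# a 900-nt sequence whose only ORF is 60 nt (ATG + 18 codons + TAA),
# embedded in C-homopolymer filler that contains no start codon
orf60_seq <- function() {
  paste0(strrep("C", 420), "ATG", strrep("AAC", 18), "TAA",
         strrep("C", 420))
}

# small catalog straight from a feature data.frame
as_catalog <- function(df) feature_catalog(df)
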