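# Gene-set over-representation analysis (file-based replacement for the
# DAVID/KEGG web step) with metabolic-category tagging.

#' Read gene sets from a GMT file
#'
#' @param path GMT file (set id, description, then member ids, tab
#'   separated).
#' @param categories optional path to a sidecar TSV (`set_id`,
#'   `categories` with comma-separated values among
#'   carbohydrate_metabolism / lipid_metabolism / other).
#' @return a named list of class `gene_sets`; each element is a character
#'   vector of member ids, with attributes `name` and `categories`.
#' @export
read_gmt <- function(path, categories = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  sets <- fgsea::gmtPathways(path)
  if (!length(sets)) stop("no gene sets in ", path)
  cat_map <- list()
  if (!is.null(categories)) {
    if (!file.exists(categories))
      stop("category sidecar not found: ", categories)
    cdf <- utils::read.table(categories, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    cat_map <- stats::setNames(
      strsplit(cdf$categories, ",", fixed = TRUE), cdf$set_id)
  }
  for (id in names(sets)) {
    attr(sets[[id]], "categories") <-
      if (id %in% names(cat_map)) trimws(cat_map[[id]]) else "other"
  }
  class(sets) <- "gene_sets"
  sets
}

#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper around `stats::p.adjust(method = "BH")`, exposed so that
#' enrichment results and validation reports use one documented procedure.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, capped at 1.
#' @export
adjust_bh <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Gene-set over-representation analysis
#'
#' For each gene set, tests whether the query over-represents the set's
#' members relative to the background universe, using the upper-tail
#' hypergeometric probability P(X >= k) with parameters (N = universe
#' size, K = set size within the universe, n = query size) — the standard
#' one-sided Fisher test of over-representation. Sets with zero overlap
#' are reported with p = 1. The EASE variant (overlap decremented by one
#' before taking the tail, a more conservative score used by some
#' annotation servers) is available via `ease = TRUE`.
#'
#' @param query character vector of feature ids; must be a subset of
#'   `universe`.
#' @param sets a `gene_sets` list from [read_gmt()], or any named list of
#'   id vectors.
#' @param universe character vector of background feature ids.
#' @param ease logical, apply the EASE k-1 correction (default FALSE).
#' @return data.frame with one row per gene set: `set_id`, `k`, `n`, `K`,
#'   `N`, `pvalue`, `p_adjusted` (BH), `neg_log10_p`, `categories`
#'   (comma-joined), sorted by p-value then set id. Sets with no members
#'   in the universe are dropped.
#' @export
enrich <- function(query, sets, universe, ease = FALSE) {
  universe <- unique(universe)
  query <- unique(query)
  if (!length(universe)) stop("empty universe")
  out_of_universe <- setdiff(query, universe)
  if (length(out_of_universe))
    stop("query ids absent from universe: ",
         paste(utils::head(out_of_universe, 5), collapse = ", "),
         if (length(out_of_universe) > 5) ", ...")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(id) {
    members <- intersect(unique(sets[[id]]), universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(query, members))
    k_eff <- if (ease) max(0L, k - 1L) else k
    p <- if (k == 0L) 1 else
      stats::phyper(k_eff - 1L, K, N - K, n, lower.tail = FALSE)
    cats <- attr(sets[[id]], "categories")
    data.frame(set_id = id, k = k, n = n, K = K, N = N, pvalue = p,
               categories = paste(if (is.null(cats)) "other" else cats,
                                  collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no gene set has members in the universe")
  res$p_adjusted <- adjust_bh(res$pvalue)
  res$neg_log10_p <- -log10(res$pvalue)
  res <- res[order(res$pvalue, res$set_id), ]
  rownames(res) <- NULL
  res[c("set_id", "k", "n", "K", "N", "pvalue", "p_adjusted",
        "neg_log10_p", "categories")]
}

#' Tag query genes with the metabolic categories of significant sets
#'
#' Each query gene is annotated with the union of the categories of the
#' significant gene sets that contain it; genes appearing in both a
#' carbohydrate-metabolism and a lipid-metabolism set are additionally
#' flagged `both` — the criterion used to call a gene "common to
#' carbohydrate and lipid metabolism".
#'
#' @param results an [enrich()] result.
#' @param sets the `gene_sets` used to produce it.
#' @param query the query gene ids.
#' @param alpha significance cutoff (default 0.05).
#' @param use_adjusted apply `alpha` to BH-adjusted p-values (default);
#'   `FALSE` applies it to raw p-values.
#' @return data.frame with `feature_id`, `categories` (comma-joined,
#'   possibly empty), `carbohydrate`, `lipid`, `both` (logicals),
#'   `n_pathways` (number of significant sets containing the gene).
#' @export
tag_categories <- function(results, sets, query, alpha = 0.05,
                           use_adjusted = TRUE) {
  p <- if (use_adjusted) results$p_adjusted else results$pvalue
  sig <- results$set_id[p < alpha]
  rows <- lapply(unique(query), function(g) {
    containing <- sig[vapply(sig, function(id) g %in% sets[[id]],
                             logical(1))]
    cats <- unique(unlist(lapply(containing, function(id) {
      cc <- attr(sets[[id]], "categories")
      if (is.null(cc)) "other" else cc
    })))
    carb <- "carbohydrate_metabolism" %in% cats
    lip <- "lipid_metabolism" %in% cats
    data.frame(feature_id = g,
               categories = paste(sort(cats), collapse = ","),
               carbohydrate = carb, lipid = lip, both = carb && lip,
               n_pathways = length(containing),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write enrichment results as TSV
#'
#' @param results an [enrich()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
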