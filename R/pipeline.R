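# End-to-end orchestration: the screening phase (DE filter -> coding
# screen -> enrichment -> proximity -> network -> shortlist) with a
# structured funnel report, and the validation phase (ddCT, ANOVA,
# correlations, HOMA-IR, tolerance AUC, ROC).

#' Build a run configuration
#'
#' Defaults mirror the screening parameters of the motivating study
#' where it states them (|log2FC| > 2, 50 kb window); the remaining
#' defaults are declared substitutes for parameters the study leaves
#' unstated (STRING medium confidence 0.4, BH q = 0.05).
#'
#' @param de_table,gtf,gmt paths to the DE table, annotation GTF, and
#'   gene-set GMT (required for [run_screen()]).
#' @param set_categories,ppi_edges,cp_table,lnc_annotations optional
#'   paths: category sidecar TSV, scored edge TSV, coding-potential TSV,
#'   and a TSV (`lncrna_id`, `annotated`) of lncRNA annotation flags.
#' @param ct_table,phenotypes optional paths for [run_validation()].
#' @param logfc_threshold,absolute_logfc DE screening rule (default
#'   |log2fc| > 2).
#' @param window_bp proximity window (default 50000).
#' @param score_threshold minimum ppi combined score (default 0.4).
#' @param enrichment_q BH significance cutoff for category tagging
#'   (default 0.05); `use_adjusted = FALSE` applies it to raw p-values.
#' @param use_adjusted logical, see above.
#' @param target_pathway_id gene-set id whose members define the target
#'   pathway for the shortlist (default `"insulin_resistance"`).
#' @param dual_rule `"both_categories"` or `"multi_pathway"`.
#' @param top_k shortlist size cap (default 10).
#' @param reference,calibrator_group ddCT settings.
#' @param seed RNG seed for any stochastic step (ROC bootstrap).
#' @param out_dir where [run_screen()] writes its outputs.
#' @return list of class `run_config`.
#' @export
run_config <- function(de_table = NULL, gtf = NULL, gmt = NULL,
                       set_categories = NULL, ppi_edges = NULL,
                       cp_table = NULL, lnc_annotations = NULL,
                       ct_table = NULL, phenotypes = NULL,
                       logfc_threshold = 2, absolute_logfc = TRUE,
                       window_bp = 50000L, score_threshold = 0.4,
                       enrichment_q = 0.05, use_adjusted = TRUE,
                       target_pathway_id = "insulin_resistance",
                       dual_rule = "both_categories", top_k = 10L,
                       reference = "18SrRNA", calibrator_group = "Ctrl",
                       seed = 1L, out_dir = NULL) {
  stopifnot(logfc_threshold > 0, window_bp >= 0,
            score_threshold >= 0, score_threshold <= 1,
            enrichment_q > 0, enrichment_q <= 1, top_k >= 1)
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys match the [run_config()] arguments;
#'   relative input paths are resolved against the file's directory.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  path_keys <- c("de_table", "gtf", "gmt", "set_categories", "ppi_edges",
                 "cp_table", "lnc_annotations", "ct_table", "phenotypes")
  base <- dirname(normalizePath(path))
  for (k in intersect(path_keys, names(vals)))
    if (!grepl("^/", vals[[k]])) vals[[k]] <- file.path(base, vals[[k]])
  do.call(run_config, vals)
}

.require_path <- function(path, what) {
  if (is.null(path)) stop("config is missing a path for the ", what)
  if (!file.exists(path)) stop(what, " file not found: ", path)
  path
}

#' Run the screening phase end-to-end
#'
#' Stages, in order: differential-expression filter; coding-potential
#' screen of the lncRNA candidates; gene-set over-representation of the
#' candidate mRNAs against the full annotated mRNA universe; proximity
#' pairing within the window; combined network construction; hub-pair
#' shortlist. Every filtering stage's before/after counts enter the
#' funnel report. All outputs are written under `config$out_dir` when
#' set, with the configuration echoed into `run_manifest.json`; reruns
#' with identical inputs are byte-identical.
#'
#' @param config a [run_config()].
#' @return list with `pairs`, `shortlist`, `funnel` (data.frame of
#'   stage/n_in/n_out/parameters), `enrichment`, `gene_tags`, `graph`,
#'   and `catalog`.
#' @export
run_screen <- function(config) {
  de_path <- .require_path(config$de_table, "DE table")
  gtf_path <- .require_path(config$gtf, "annotation GTF")
  gmt_path <- .require_path(config$gmt, "gene-set GMT")

  funnel <- data.frame(stage = character(0), n_in = integer(0),
                       n_out = integer(0), parameters = character(0),
                       stringsAsFactors = FALSE)
  add <- function(stage, n_in, n_out, parameters = "") {
    message(sprintf("run_screen: %-18s %6d -> %6d  %s",
                    stage, n_in, n_out, parameters))
    rbind(funnel, data.frame(stage = stage, n_in = n_in, n_out = n_out,
                             parameters = parameters,
                             stringsAsFactors = FALSE))
  }

  de <- read_de_table(de_path)
  de_pass <- filter_differential(de, config$logfc_threshold,
                                 absolute = config$absolute_logfc)
  funnel <- add("de_filter", nrow(de), nrow(de_pass),
                sprintf("|log2fc| > %g", config$logfc_threshold))

  lnc_cand <- de_pass[de_pass$feature_class == "lncRNA", , drop = FALSE]
  cp <- if (!is.null(config$cp_table))
    read_cp_table(.require_path(config$cp_table, "coding-potential table"))
  lnc_kept <- suppressWarnings(screen_noncoding(lnc_cand, cp = cp))
  funnel <- add("coding_screen", nrow(lnc_cand), nrow(lnc_kept),
                if (is.null(cp)) "no evidence supplied" else "score table")
  mrna_cand <- de_pass[de_pass$feature_class == "mRNA", , drop = FALSE]

  catalog <- read_gtf(gtf_path)
  located <- intersect(c(mrna_cand$feature_id, lnc_kept$feature_id),
                       catalog$features$feature_id)
  funnel <- add("catalog_match", nrow(mrna_cand) + nrow(lnc_kept),
                length(located), basename(gtf_path))

  sets <- read_gmt(gmt_path, categories = config$set_categories)
  universe <- catalog$features$feature_id[
    catalog$features$feature_class == "mRNA"]
  query <- intersect(mrna_cand$feature_id, universe)
  enr <- enrich(query, sets, universe)

  mr_cat <- catalog_subset(catalog, feature_class = "mRNA",
                           ids = intersect(mrna_cand$feature_id, located))
  ln_cat <- catalog_subset(catalog, feature_class = "lncRNA",
                           ids = intersect(lnc_kept$feature_id, located))
  pairs <- pair_by_proximity(mr_cat, ln_cat, window_bp = config$window_bp)
  funnel <- add("proximity", length(mr_cat),
                length(unique(pairs$mrna_id)),
                sprintf("window %d bp, %d pairs", config$window_bp,
                        nrow(pairs)))

  ppi <- if (!is.null(config$ppi_edges))
    read_string_edges(.require_path(config$ppi_edges, "ppi edge table"))
  else data.frame(node_a = character(0), node_b = character(0),
                  score = numeric(0))
  graph <- build_network(ppi, pairs,
                         score_threshold = config$score_threshold)

  tags <- tag_categories(enr, sets, query = unique(pairs$mrna_id),
                         alpha = config$enrichment_q,
                         use_adjusted = config$use_adjusted)
  target <- if (config$target_pathway_id %in% names(sets))
    sets[[config$target_pathway_id]] else character(0)
  lnc_ann <- stats::setNames(rep(FALSE, length(ln_cat)),
                             ln_cat$features$feature_id)
  if (!is.null(config$lnc_annotations)) {
    ann <- utils::read.table(
      .require_path(config$lnc_annotations, "lncRNA annotation table"),
      header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    lnc_ann[ann$lncrna_id[ann$annotated %in% c(TRUE, "TRUE", "true")]] <- TRUE
  }
  shortlist <- suppressMessages(
    select_hub_pairs(graph, tags, pairs, lnc_ann, target,
                     top_k = config$top_k, dual_rule = config$dual_rule))
  hub_funnel <- attr(shortlist, "funnel")
  hub_funnel$parameters <- c(config$target_pathway_id, config$dual_rule,
                             "NCBI-style annotation flag",
                             sprintf("top_k %d", config$top_k))[
                               seq_len(nrow(hub_funnel))]
  funnel <- rbind(funnel, hub_funnel)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    o <- function(f) file.path(config$out_dir, f)
    write_pairs(pairs, o("pairs.tsv"), mr_cat, ln_cat)
    write_enrichment(enr, o("enrichment.tsv"))
    write_network(graph, o("network_edges.tsv"), o("network_nodes.tsv"))
    .write_tsv(shortlist, o("shortlist.tsv"))
    .write_tsv(funnel, o("funnel.tsv"))
    cfg <- config
    class(cfg) <- NULL
    cfg$out_dir <- NULL  # the manifest's own location; keep reruns
                         # into different directories byte-identical
    jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1))],
                         o("run_manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  list(pairs = pairs, shortlist = shortlist, funnel = funnel,
       enrichment = enr, gene_tags = tags, graph = graph,
       catalog = catalog)
}

#' Run the validation phase
#'
#' For each shortlisted pair: ddCT fold changes and one-way ANOVA across
#' groups for both transcripts, the direction of each group-vs-calibrator
#' contrast, and the Pearson correlation between the pair's delta-CT
#' profiles. Phenotypes (when supplied) yield per-sample HOMA-IR and
#' tolerance-test AUC with group ANOVAs, and a ROC of the first
#' shortlisted lncRNA's expression against case status (non-calibrator,
#' non-exercised groups).
#'
#' @param config a [run_config()] carrying `ct_table` (and optionally
#'   `phenotypes`).
#' @param pairs data.frame with `mrna_id`, `lncrna_id` — typically the
#'   shortlist from [run_screen()] (columns `mrna_id`, `lncrna_ids`
#'   comma-joined are also accepted).
#' @return list with `expression` (tidy per pair x contrast rows:
#'   fold changes, directions, ANOVA p), `correlations` (per pair: r, p,
#'   n, significance flags at p < 0.05 and BH q), `phenotype` (per-group
#'   HOMA-IR / AUC summaries, or NULL), `roc` (or NULL).
#' @export
run_validation <- function(config, pairs) {
  if (!is.null(pairs[["lncrna_ids"]]) && is.null(pairs[["lncrna_id"]])) {
    expanded <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      data.frame(mrna_id = pairs$mrna_id[i],
                 lncrna_id = strsplit(pairs$lncrna_ids[i], ",")[[1]],
                 stringsAsFactors = FALSE)
    }))
    pairs <- expanded
  }
  if (is.null(pairs) || nrow(pairs) == 0L) {
    message("run_validation: empty shortlist, nothing to validate")
    return(list(expression = NULL, correlations = NULL,
                phenotype = NULL, roc = NULL))
  }
  ct <- read_ct_table(.require_path(config$ct_table, "CT table"))
  targets <- unique(c(pairs$mrna_id, pairs$lncrna_id))
  absent <- setdiff(targets, unique(ct$target))
  if (length(absent))
    stop("shortlisted target(s) absent from CT table: ",
         paste(absent, collapse = ", "))
  rel <- ddct(ct[ct$target %in% c(targets, config$reference), ],
              reference = config$reference,
              calibrator_group = config$calibrator_group)

  contrasts <- setdiff(unique(rel$group), config$calibrator_group)
  expr_rows <- list()
  for (tg in targets) {
    d <- rel[rel$target == tg, ]
    vals <- split(d$delta_ct, d$group)
    an <- group_anova(vals)
    cal_mean_fold <- mean(d$fold[d$group == config$calibrator_group])
    for (cn in contrasts) {
      fold <- mean(d$fold[d$group == cn])
      expr_rows[[paste(tg, cn)]] <- data.frame(
        target = tg, contrast = sprintf("%s_vs_%s", cn,
                                        config$calibrator_group),
        fold = fold,
        direction = if (fold > cal_mean_fold) "up" else "down",
        anova_F = an$F, anova_p = an$p, stringsAsFactors = FALSE)
    }
  }
  expression <- do.call(rbind, expr_rows)
  rownames(expression) <- NULL

  cor_rows <- lapply(seq_len(nrow(pairs)), function(i) {
    m <- rel[rel$target == pairs$mrna_id[i], ]
    l <- rel[rel$target == pairs$lncrna_id[i], ]
    common <- intersect(m$sample, l$sample)
    pr <- pearson(m$delta_ct[match(common, m$sample)],
                  l$delta_ct[match(common, l$sample)])
    data.frame(mrna_id = pairs$mrna_id[i],
               lncrna_id = pairs$lncrna_id[i],
               r = pr$r, p = pr$p, n = pr$n, stringsAsFactors = FALSE)
  })
  correlations <- do.call(rbind, cor_rows)
  correlations$sig_raw <- correlations$p < 0.05
  correlations$sig_bh <- adjust_bh(correlations$p) < 0.05

  phenotype <- NULL
  roc <- NULL
  if (!is.null(config$phenotypes)) {
    ph <- utils::read.table(
      .require_path(config$phenotypes, "phenotype table"),
      header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    ph$homa_ir <- homa_ir(ph$fasting_insulin, ph$fasting_glucose)
    tc_cols <- grep("^g[0-9]+$", names(ph), value = TRUE)
    minutes <- as.numeric(sub("^g", "", tc_cols))
    ph$gtt_auc <- vapply(seq_len(nrow(ph)), function(i)
      tolerance_auc(minutes, as.numeric(ph[i, tc_cols])), numeric(1))
    homa_an <- group_anova(split(ph$homa_ir, ph$group))
    auc_an <- group_anova(split(ph$gtt_auc, ph$group))
    phenotype <- list(samples = ph, homa_anova = homa_an,
                      auc_anova = auc_an)
  }
  # ROC: expression of the top shortlisted lncRNA discriminating cases
  # (sedentary high-fat + diabetic) from controls
  first_lnc <- pairs$lncrna_id[1]
  d <- rel[rel$target == first_lnc, ]
  case_groups <- setdiff(unique(d$group),
                         c(config$calibrator_group, "HF-Exe"))
  lab <- d$group %in% case_groups
  if (length(unique(lab)) == 2L)
    roc <- c(list(target = first_lnc),
             roc_auc(-d$delta_ct, lab, seed = config$seed))
  list(expression = expression, correlations = correlations,
       phenotype = phenotype, roc = roc)
}
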