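# Synthetic-data generator: emits every input the pipeline consumes
# (annotation, DE table, coding-potential table, gene sets, scored edges,
# CT table, phenotypes) with planted ground truth, so the whole screen is
# testable offline. Placement uses a slot layout that guarantees planted
# cis pairs fall inside the proximity window and decoys outside it.

#' Simulation configuration
#'
#' Collects every knob of the generator with validation. Feature lengths
#' are drawn uniformly (mRNA 1-5 kb, lncRNA 0.5-2 kb), typical of
#' collapsed gene spans.
#'
#' @param seed integer RNG seed; all emitted files are byte-identical for
#'   a given config.
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length, bp.
#' @param n_mrnas,n_lncrnas feature counts.
#' @param n_true_pairs planted cis pairs (first `n_true_pairs` mRNAs each
#'   get one partner lncRNA; a named `pair_map` overrides this).
#' @param pair_map optional data.frame (`mrna_id`, `lncrna_id`) naming
#'   the planted pairs explicitly (ids among the generated names).
#' @param true_pair_max_gap planted pairs get a gap uniform in
#'   \[0, true_pair_max_gap\] bp.
#' @param decoy_min_gap minimum gap between any unpaired lncRNA and every
#'   mRNA; must exceed `true_pair_max_gap`.
#' @param logfc_sd sd of the planted |log2fc| distribution (around 3).
#' @param frac_de fraction of features planted as differentially
#'   expressed.
#' @param logfc_threshold the screening threshold the plant is calibrated
#'   against (planted DE magnitudes exceed it, background stays below).
#' @param n_pathways number of gene sets emitted.
#' @param set_size nominal gene-set size.
#' @param enrichment_odds sampling odds of a DE gene relative to a
#'   background gene inside enriched sets (1 = null).
#' @param group_sizes named integer vector of samples per experimental
#'   group.
#' @param dct_means named list: target -> named numeric vector of group
#'   mean delta-CT values (lower = higher expression). Targets absent
#'   from the list get a flat profile.
#' @param planted_rho named numeric vector `"mrna|lncrna" -> rho`: the
#'   within-sample correlation planted between a pair's delta-CT noise.
#' @param ct_sd within-group delta-CT noise sd (cycles).
#' @param ref_target name of the reference assay.
#' @param n_coding_lnc decoy lncRNAs labelled `coding` in the emitted
#'   score table (removed by the coding screen).
#' @param funnel optional list describing the hub funnel plant:
#'   `target_pathway_id`, `target_genes`, `dual_genes`,
#'   `annotated_genes` (see [preset_prediabetes()]).
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chroms = 5L, chrom_length = 2e7,
                       n_mrnas = 50L, n_lncrnas = 50L, n_true_pairs = 10L,
                       pair_map = NULL,
                       true_pair_max_gap = 10000L, decoy_min_gap = 60000L,
                       logfc_sd = 1, frac_de = 0.5, logfc_threshold = 2,
                       n_pathways = 10L, set_size = 20L,
                       enrichment_odds = 10,
                       group_sizes = c(Ctrl = 6L, `HF-Sed` = 6L,
                                       `HF-Exe` = 6L, Diabetic = 6L),
                       dct_means = list(), planted_rho = numeric(0),
                       ct_sd = 0.5, ref_target = "18SrRNA",
                       n_coding_lnc = 0L, funnel = NULL) {
  stopifnot(n_chroms >= 1, chrom_length > 0, n_mrnas >= 1, n_lncrnas >= 0,
            n_true_pairs >= 0, n_true_pairs <= min(n_mrnas, n_lncrnas),
            frac_de >= 0, frac_de <= 1, logfc_threshold > 0,
            all(group_sizes >= 2))
  if (true_pair_max_gap >= decoy_min_gap)
    stop("need true_pair_max_gap < decoy_min_gap for separability")
  structure(as.list(environment()), class = "sim_config")
}

.mrna_names <- function(config) {
  named <- if (!is.null(config$pair_map)) unique(config$pair_map$mrna_id)
           else character(0)
  c(named, sprintf("gene%03d", seq_len(config$n_mrnas - length(named))))
}

.lnc_names <- function(config) {
  named <- if (!is.null(config$pair_map)) unique(config$pair_map$lncrna_id)
           else character(0)
  c(named, sprintf("lnc%03d", seq_len(config$n_lncrnas - length(named))))
}

#' Simulate a toy genome with planted cis pairs
#'
#' Features are laid out in non-overlapping slots separated by at least
#' `decoy_min_gap`, so the gap between any two features of different
#' slots exceeds `decoy_min_gap`; each planted pair shares a slot with a
#' gap uniform in \[0, true_pair_max_gap\]. With `decoy_min_gap` above
#' the pairing window, proximity pairing therefore recovers exactly the
#' planted pairs.
#'
#' @param config a [sim_config()].
#' @return list with `catalog` (a `FeatureCatalog` of all features) and
#'   `truth` (list with `true_pairs` data.frame and placement info).
#' @export
simulate_genome <- function(config) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  mrna_ids <- .mrna_names(config)
  lnc_ids <- .lnc_names(config)
  pair_map <- config$pair_map
  if (is.null(pair_map) && config$n_true_pairs > 0L)
    pair_map <- data.frame(mrna_id = mrna_ids[seq_len(config$n_true_pairs)],
                           lncrna_id = lnc_ids[seq_len(config$n_true_pairs)],
                           stringsAsFactors = FALSE)
  if (is.null(pair_map))
    pair_map <- data.frame(mrna_id = character(0), lncrna_id = character(0))
  paired_lncs <- pair_map$lncrna_id
  decoy_lncs <- setdiff(lnc_ids, paired_lncs)
  # one slot per mRNA plus one per decoy lncRNA
  zone <- 5000 + config$true_pair_max_gap + 2000
  pitch <- zone + config$decoy_min_gap + 1
  n_slots <- config$n_mrnas + length(decoy_lncs)
  slots_per_chrom <- ceiling(n_slots / config$n_chroms)
  if (slots_per_chrom * pitch + 1 > config$chrom_length)
    stop("genome too small: need chrom_length >= ",
         slots_per_chrom * pitch + 1, " for this configuration")
  slot_kind <- sample(c(rep("m", config$n_mrnas),
                        rep("d", length(decoy_lncs))))
  mi <- 0L; di <- 0L
  rows <- vector("list", n_slots)
  for (s in seq_len(n_slots)) {
    chrom <- as.character(((s - 1L) %% config$n_chroms) + 1L)
    slot_start <- ((s - 1L) %/% config$n_chroms) * pitch
    if (slot_kind[s] == "m") {
      mi <- mi + 1L
      id <- mrna_ids[mi]
      mlen <- sample(1000:5000, 1L)
      mstart <- slot_start
      row <- data.frame(feature_id = id, feature_class = "mRNA",
                        chrom = chrom,
                        strand = sample(c("+", "-"), 1L),
                        start = mstart, end = mstart + mlen,
                        stringsAsFactors = FALSE)
      partner <- pair_map$lncrna_id[pair_map$mrna_id == id]
      if (length(partner)) {
        for (p in partner) {
          gap <- sample(0:config$true_pair_max_gap, 1L)
          llen <- sample(500:2000, 1L)
          lstart <- mstart + mlen + gap
          row <- rbind(row, data.frame(
            feature_id = p, feature_class = "lncRNA", chrom = chrom,
            strand = sample(c("+", "-"), 1L),
            start = lstart, end = lstart + llen,
            stringsAsFactors = FALSE))
        }
      }
      rows[[s]] <- row
    } else {
      di <- di + 1L
      llen <- sample(500:2000, 1L)
      rows[[s]] <- data.frame(
        feature_id = decoy_lncs[di], feature_class = "lncRNA",
        chrom = chrom, strand = sample(c("+", "-"), 1L),
        start = slot_start, end = slot_start + llen,
        stringsAsFactors = FALSE)
    }
  }
  features <- do.call(rbind, rows)
  # mRNAs sharing a slot with several lncRNAs: spread extra partners so
  # they do not overlap each other (sequential placement already ensures
  # partner gaps from the mRNA only; separate overlapping partners)
  features <- features[order(features$chrom, features$start,
                             features$feature_id), ]
  catalog <- feature_catalog(features)
  list(catalog = catalog,
       truth = list(true_pairs = pair_map,
                    decoy_lncrnas = decoy_lncs,
                    mrna_ids = mrna_ids, lncrna_ids = lnc_ids))
}

#' Simulate a differential-expression table
#'
#' Planted DE features draw |log2fc| from N(3, `logfc_sd`) truncated
#' above the screening threshold (so the planted count passes exactly);
#' background features draw from N(0, 0.5) truncated below it. P-values
#' are rank-consistent with |log2fc|. Every planted pair member is DE, so
#' downstream recovery is well-defined; additional DE features are chosen
#' at random up to `frac_de`.
#'
#' @param config a [sim_config()].
#' @param truth the `truth` element of [simulate_genome()].
#' @return list with `de` (data.frame `feature_id`, `feature_class`,
#'   `log2fc`, `pvalue`) and `truth` augmented with `de_features` and
#'   `planted_directions`.
#' @export
simulate_de_table <- function(config, truth) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed + 1L)
  ids <- c(truth$mrna_ids, truth$lncrna_ids)
  cls <- c(rep("mRNA", length(truth$mrna_ids)),
           rep("lncRNA", length(truth$lncrna_ids)))
  n <- length(ids)
  n_de <- round(config$frac_de * n)
  must <- unique(c(truth$true_pairs$mrna_id, truth$true_pairs$lncrna_id))
  extra <- setdiff(ids, must)
  de_ids <- c(must, sample(extra, max(0L, n_de - length(must))))
  thr <- config$logfc_threshold
  rtrunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
    out <- numeric(n)
    need <- seq_len(n)
    while (length(need)) {
      draw <- stats::rnorm(length(need), mean, sd)
      ok <- draw > lower & draw < upper
      out[need[ok]] <- draw[ok]
      need <- need[!ok]
    }
    out
  }
  is_de <- ids %in% de_ids
  sign_de <- stats::setNames(sample(c(-1, 1), n, replace = TRUE), ids)
  # planted direction presets override the random sign
  for (tg in names(config$dct_means)) {
    mu <- config$dct_means[[tg]]
    if (tg %in% ids && all(c("Ctrl", "HF-Sed") %in% names(mu)))
      sign_de[tg] <- if (mu[["HF-Sed"]] < mu[["Ctrl"]]) 1 else -1
  }
  lfc <- numeric(n)
  lfc[is_de] <- sign_de[ids[is_de]] *
    rtrunc(sum(is_de), 3, config$logfc_sd, lower = thr + 0.01)
  lfc[!is_de] <- rtrunc(sum(!is_de), 0, 0.5,
                        lower = -(thr - 0.01), upper = thr - 0.01)
  pv <- rank(-abs(lfc), ties.method = "first") / (n + 1)
  de <- data.frame(feature_id = ids, feature_class = cls,
                   log2fc = lfc, pvalue = pv, stringsAsFactors = FALSE)
  truth$de_features <- de_ids
  truth$planted_directions <- ifelse(sign_de[de_ids] > 0, "up", "down")
  names(truth$planted_directions) <- de_ids
  list(de = de, truth = truth)
}

#' Simulate a long-format CT table with planted correlation
#'
#' Reference CT ~ N(15, 0.2) per sample; each target's delta-CT is its
#' configured group mean plus N(0, `ct_sd`) noise. For every planted
#' pair, the mRNA and lncRNA noise terms are drawn jointly with the
#' configured correlation (`planted_rho`), so expression correlation is
#' under experimental control. Unlisted targets get a flat profile at
#' delta-CT 8 (mRNA) or 12 (lncRNA).
#'
#' @param config a [sim_config()].
#' @param truth the (augmented) truth list.
#' @param targets which assay targets to emit; defaults to the members of
#'   planted pairs plus anything named in `dct_means`.
#' @return data.frame `sample`, `group`, `target`, `ct` (long format,
#'   reference assay included).
#' @export
simulate_ct_table <- function(config, truth, targets = NULL) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed + 2L)
  groups <- rep(names(config$group_sizes), config$group_sizes)
  samples <- sprintf("%s_%d", groups,
                     unlist(lapply(config$group_sizes, seq_len)))
  ns <- length(samples)
  if (is.null(targets))
    targets <- unique(c(truth$true_pairs$mrna_id,
                        truth$true_pairs$lncrna_id,
                        names(config$dct_means)))
  mean_of <- function(tg) {
    mu <- config$dct_means[[tg]]
    base <- if (tg %in% truth$lncrna_ids) 12 else 8
    vapply(groups, function(g)
      if (!is.null(mu) && g %in% names(mu)) mu[[g]] else base, numeric(1))
  }
  # correlated noise: one latent draw per pair; a target in several pairs
  # (e.g. one mRNA with two lncRNAs) reuses its first latent draw
  noise <- matrix(NA_real_, nrow = ns, ncol = length(targets),
                  dimnames = list(samples, targets))
  rho_map <- config$planted_rho
  for (key in names(rho_map)) {
    ml <- strsplit(key, "|", fixed = TRUE)[[1]]
    if (!all(ml %in% targets)) next
    rho <- rho_map[[key]]
    if (all(is.na(noise[, ml[1]]))) noise[, ml[1]] <- stats::rnorm(ns)
    e1 <- noise[, ml[1]]
    z <- stats::rnorm(ns)
    noise[, ml[2]] <- if (rho >= 1) e1 else rho * e1 +
      sqrt(1 - rho^2) * z
  }
  for (tg in targets)
    if (all(is.na(noise[, tg]))) noise[, tg] <- stats::rnorm(ns)
  ref_ct <- stats::rnorm(ns, 15, 0.2)
  rows <- list(data.frame(sample = samples, group = groups,
                          target = config$ref_target, ct = ref_ct,
                          stringsAsFactors = FALSE))
  for (tg in targets) {
    dct <- mean_of(tg) + config$ct_sd * noise[, tg]
    rows[[length(rows) + 1L]] <- data.frame(
      sample = samples, group = groups, target = tg,
      ct = ref_ct + dct, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate scored interaction edges, gene sets, and annotations
#'
#' Gene sets over-sample DE genes at `enrichment_odds`; the funnel plant
#' (when configured) pins the target-pathway, dual-category, and
#' lncRNA-annotation memberships so the hub shortlist has a known answer;
#' the designated hub (first funnel gene, else the first mRNA) receives a
#' high-scoring edge to a large fraction of other genes so it attains the
#' maximal degree.
#'
#' @param config a [sim_config()].
#' @param truth the (augmented, post-DE) truth list.
#' @return list with `edges` (`node_a`, `node_b`, `score`), `sets`
#'   (`gene_sets` list), `set_categories` (data.frame), `lnc_annotated`
#'   (named logical), `cp` (coding-potential table for all lncRNAs),
#'   and `truth` augmented with `enriched_sets` and `hub`.
#' @export
simulate_ppi_and_sets <- function(config, truth) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed + 3L)
  universe <- truth$mrna_ids
  de_m <- intersect(truth$de_features, universe)
  fun <- config$funnel
  sets <- list()
  cats <- list()
  weight <- ifelse(universe %in% de_m, config$enrichment_odds, 1)
  sample_set <- function(k, force = character(0), exclude = character(0)) {
    pool <- setdiff(universe, c(force, exclude))
    w <- weight[match(pool, universe)]
    unique(c(force, sample(pool, min(k, length(pool)), prob = w)))
  }
  n_extra <- config$n_pathways
  if (!is.null(fun)) {
    sets[[fun$target_pathway_id]] <-
      sample_set(config$set_size, force = fun$target_genes)
    cats[[fun$target_pathway_id]] <- "other"
    # dual-category genes sit in both metabolic sets; the remaining
    # target genes appear in at most one of them
    non_dual <- setdiff(fun$target_genes, fun$dual_genes)
    sets[["carbohydrate_metabolism_set"]] <-
      sample_set(config$set_size, force = c(fun$dual_genes, non_dual),
                 exclude = character(0))
    cats[["carbohydrate_metabolism_set"]] <- "carbohydrate_metabolism"
    sets[["lipid_metabolism_set"]] <-
      sample_set(config$set_size, force = fun$dual_genes,
                 exclude = non_dual)
    cats[["lipid_metabolism_set"]] <- "lipid_metabolism"
    n_extra <- max(0L, config$n_pathways - 3L)
  }
  for (i in seq_len(n_extra)) {
    id <- sprintf("pathway%02d", i)
    sets[[id]] <- sample_set(config$set_size,
                             exclude = if (!is.null(fun))
                               c(fun$target_genes) else character(0))
    cats[[id]] <- "other"
  }
  for (id in names(sets)) attr(sets[[id]], "categories") <- cats[[id]]
  class(sets) <- "gene_sets"
  set_categories <- data.frame(
    set_id = names(cats),
    categories = vapply(cats, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
  # hub edges: star around the designated hub with scores >= 0.4, plus
  # uniform background edges
  hub <- if (!is.null(fun)) fun$target_genes[1] else universe[1]
  others <- setdiff(universe, hub)
  hub_neighbors <- sample(others, max(3L, round(0.8 * length(others))))
  edges <- data.frame(node_a = hub, node_b = hub_neighbors,
                      score = stats::runif(length(hub_neighbors), 0.4, 1),
                      stringsAsFactors = FALSE)
  n_bg <- min(length(others) * 2L, 200L)
  bg_a <- sample(others, n_bg, replace = TRUE)
  bg_b <- sample(others, n_bg, replace = TRUE)
  ok <- bg_a != bg_b
  edges <- rbind(edges, data.frame(node_a = bg_a[ok], node_b = bg_b[ok],
                                   score = stats::runif(sum(ok)),
                                   stringsAsFactors = FALSE))
  edges <- edges[!duplicated(data.frame(pmin(edges$node_a, edges$node_b),
                                        pmax(edges$node_a, edges$node_b))), ]
  rownames(edges) <- NULL
  # lncRNA annotation flags
  lnc_annotated <- stats::setNames(rep(FALSE, length(truth$lncrna_ids)),
                                   truth$lncrna_ids)
  if (!is.null(fun)) {
    tp <- truth$true_pairs
    ann_lncs <- tp$lncrna_id[tp$mrna_id %in% fun$annotated_genes]
    lnc_annotated[ann_lncs] <- TRUE
  } else {
    lnc_annotated[truth$true_pairs$lncrna_id] <- TRUE
  }
  # coding-potential table: planted lncRNAs noncoding, plus optional
  # coding-labelled decoys among the non-paired lncRNAs
  cp <- data.frame(feature_id = truth$lncrna_ids,
                   score = stats::runif(length(truth$lncrna_ids), -2, 0),
                   label = "noncoding", stringsAsFactors = FALSE)
  if (config$n_coding_lnc > 0L) {
    pool <- setdiff(truth$lncrna_ids, truth$true_pairs$lncrna_id)
    coding_ids <- utils::head(pool, config$n_coding_lnc)
    sel <- cp$feature_id %in% coding_ids
    cp$label[sel] <- "coding"
    cp$score[sel] <- stats::runif(sum(sel), 1, 3)
  }
  truth$enriched_sets <- if (!is.null(fun))
    c(fun$target_pathway_id, "carbohydrate_metabolism_set",
      "lipid_metabolism_set") else character(0)
  truth$hub <- hub
  list(edges = edges, sets = sets, set_categories = set_categories,
       lnc_annotated = lnc_annotated, cp = cp, truth = truth)
}

#' Simulate a phenotype panel
#'
#' Fasting glucose and insulin per sample with group-typical levels
#' (control normoglycemic, sedentary high-fat prediabetic, exercised
#' high-fat near-normal, diabetic hyperglycemic) plus a five-point
#' glucose-tolerance time course at 0/30/60/90/120 min.
#'
#' @param config a [sim_config()].
#' @return data.frame `sample`, `group`, `fasting_glucose` (mg/dL),
#'   `fasting_insulin` (uU/mL), `g0` ... `g120`.
#' @export
simulate_phenotypes <- function(config) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed + 4L)
  pars <- list(
    #            glucose  insulin  peak
    Ctrl     = c(94,  30, 240),
    `HF-Sed` = c(122, 142, 380),
    `HF-Exe` = c(96,  45, 280),
    Diabetic = c(240, 80, 480))
  rows <- list()
  for (g in names(config$group_sizes)) {
    p <- pars[[g]]
    if (is.null(p)) p <- c(100, 35, 250)
    n <- config$group_sizes[[g]]
    g0 <- pmax(40, stats::rnorm(n, p[1], 0.08 * p[1]))
    peak <- pmax(g0 + 20, stats::rnorm(n, p[3], 0.08 * p[3]))
    shape <- c(0, 1, 0.75, 0.45, 0.2)  # relative excursion at each time
    tc <- outer(peak - g0, shape) + g0
    rows[[g]] <- data.frame(
      sample = sprintf("%s_%d", g, seq_len(n)), group = g,
      fasting_glucose = g0,
      fasting_insulin = pmax(2, stats::rnorm(n, p[2], 0.15 * p[2])),
      g0 = tc[, 1], g30 = tc[, 2], g60 = tc[, 3], g90 = tc[, 4],
      g120 = tc[, 5], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Prediabetes demonstration preset
#'
#' A configuration encoding the motivating study design: four groups of
#' six animals (Ctrl, HF-Sed, HF-Exe, Diabetic); planted cis pairs
#' Srebf1-Gm38501, Pck1-Ctcflos, Pck1-Gm36691, Cpt1b-Gm44502 plus two
#' further target-pathway pairs (Irs2, Foxo1); delta-CT group means
#' encoding the directional pattern Srebf1 and Pck1 up and Cpt1b down in
#' the sedentary high-fat group, all reversed under exercise, and the
#' high-fat directions amplified in the diabetic group; planted
#' expression correlations of 0.7 (Srebf1 pair), 0.86 (Pck1-Ctcflos),
#' 0.76 (Pck1-Gm36691 and Cpt1b pair); and a hub funnel of five
#' target-pathway genes, four with both metabolic category flags, three
#' with annotated lncRNAs.
#'
#' @param seed RNG seed.
#' @param n_per_group samples per group (default 6, the study's group
#'   size; statistical tests in this package typically use 30).
#' @return a `sim_config`.
#' @export
preset_prediabetes <- function(seed = 1L, n_per_group = 6L) {
  pair_map <- data.frame(
    mrna_id = c("Srebf1", "Pck1", "Pck1", "Cpt1b", "Irs2", "Foxo1"),
    lncrna_id = c("Gm38501", "Ctcflos", "Gm36691", "Gm44502",
                  "Gm90004", "Gm90005"),
    stringsAsFactors = FALSE)
  dct <- function(ctrl, sed, exe, dia)
    c(Ctrl = ctrl, `HF-Sed` = sed, `HF-Exe` = exe, Diabetic = dia)
  dct_means <- list(
    # mRNAs: baseline delta-CT 8; one cycle is a two-fold change
    Srebf1  = dct(8, 6, 8.6, 5),
    Pck1    = dct(8, 6.2, 8.5, 5.5),
    Cpt1b   = dct(8, 9.5, 7, 10),
    Irs2    = dct(8, 7.2, 8.3, 6.8),
    Foxo1   = dct(8, 7.4, 8.2, 7),
    # lncRNAs mirror their partner gene's pattern at baseline 12
    Gm38501 = dct(12, 10, 12.6, 9),
    Ctcflos = dct(12, 10.2, 12.5, 9.5),
    Gm36691 = dct(12, 10.4, 12.4, 9.6),
    Gm44502 = dct(12, 13.5, 11, 14),
    Gm90004 = dct(12, 11.2, 12.3, 10.8),
    Gm90005 = dct(12, 11.4, 12.2, 11))
  planted_rho <- c("Srebf1|Gm38501" = 0.70,
                   "Pck1|Ctcflos"   = 0.86,
                   "Pck1|Gm36691"   = 0.76,
                   "Cpt1b|Gm44502"  = 0.76,
                   "Irs2|Gm90004"   = 0.60,
                   "Foxo1|Gm90005"  = 0.60)
  sizes <- c(Ctrl = n_per_group, `HF-Sed` = n_per_group,
             `HF-Exe` = n_per_group, Diabetic = n_per_group)
  sim_config(
    seed = seed, n_chroms = 5L, chrom_length = 2e7,
    n_mrnas = 50L, n_lncrnas = 50L, pair_map = pair_map,
    n_true_pairs = nrow(pair_map),
    true_pair_max_gap = 10000L, decoy_min_gap = 60000L,
    frac_de = 0.5, n_pathways = 10L, enrichment_odds = 10,
    group_sizes = sizes, dct_means = dct_means,
    planted_rho = planted_rho, ct_sd = 0.5, n_coding_lnc = 5L,
    funnel = list(
      target_pathway_id = "insulin_resistance",
      target_genes = c("Srebf1", "Pck1", "Cpt1b", "Irs2", "Foxo1"),
      dual_genes = c("Srebf1", "Pck1", "Cpt1b", "Irs2"),
      annotated_genes = c("Srebf1", "Pck1", "Cpt1b")))
}

#' Generate and write every pipeline input
#'
#' Emits, under `dir`: `genome.gtf`, `de_table.tsv`, `cp_table.tsv`,
#' `gene_sets.gmt`, `set_categories.tsv`, `ppi_edges.tsv`,
#' `lnc_annotations.tsv`, `ct_table.tsv`, `phenotypes.tsv`, and
#' `ground_truth.json`. Files are byte-identical across runs with the
#' same config.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return list with `paths` (named file paths) and `truth`.
#' @export
simulate_all <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- simulate_genome(config)
  det <- simulate_de_table(config, gen$truth)
  net <- simulate_ppi_and_sets(config, det$truth)
  ct <- simulate_ct_table(config, net$truth)
  ph <- simulate_phenotypes(config)
  truth <- net$truth
  p <- function(f) file.path(dir, f)
  write_gtf(gen$catalog, p("genome.gtf"))
  .write_tsv(det$de, p("de_table.tsv"))
  .write_tsv(net$cp, p("cp_table.tsv"))
  writeLines(vapply(names(net$sets), function(id)
    paste(c(id, id, net$sets[[id]]), collapse = "\t"), character(1)),
    p("gene_sets.gmt"))
  .write_tsv(net$set_categories, p("set_categories.tsv"))
  .write_tsv(net$edges, p("ppi_edges.tsv"))
  .write_tsv(data.frame(lncrna_id = names(net$lnc_annotated),
                        annotated = unname(net$lnc_annotated),
                        stringsAsFactors = FALSE),
             p("lnc_annotations.tsv"))
  .write_tsv(ct, p("ct_table.tsv"))
  .write_tsv(ph, p("phenotypes.tsv"))
  jsonlite::write_json(
    list(true_pairs = truth$true_pairs,
         de_features = truth$de_features,
         planted_directions = as.list(truth$planted_directions),
         enriched_sets = truth$enriched_sets,
         hub = truth$hub,
         planted_rho = as.list(config$planted_rho)),
    p("ground_truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- stats::setNames(
    vapply(c("genome.gtf", "de_table.tsv", "cp_table.tsv",
             "gene_sets.gmt", "set_categories.tsv", "ppi_edges.tsv",
             "lnc_annotations.tsv", "ct_table.tsv", "phenotypes.tsv",
             "ground_truth.json"), p, character(1)),
    c("gtf", "de_table", "cp_table", "gmt", "set_categories",
      "ppi_edges", "lnc_annotations", "ct_table", "phenotypes",
      "ground_truth"))
  list(paths = as.list(paths), truth = truth)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
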