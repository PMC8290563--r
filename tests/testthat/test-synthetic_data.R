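# Generator: determinism, planted structure, directionality presets.

test_that("identical config and seed give byte-identical fixture files", {
  cfg <- preset_prediabetes(seed = 13)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_all(cfg, d1)
  simulate_all(cfg, d2)
  files <- list.files(d1)
  expect_gt(length(files), 5)
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("genome placement guarantees pair separability", {
  set.seed(1)
  for (seed in c(2, 20, 200)) {
    cfg <- sim_config(seed = seed, n_mrnas = 15L, n_lncrnas = 15L,
                      n_true_pairs = 5L, true_pair_max_gap = 10000L,
                      decoy_min_gap = 60000L)
    gen <- simulate_genome(cfg)
    f <- gen$catalog$features
    m <- f[f$feature_class == "mRNA", ]
    l <- f[f$feature_class == "lncRNA", ]
    truth_key <- with(gen$truth$true_pairs, paste(mrna_id, lncrna_id))
    # quadratic oracle at the pairing window
    got <- brute_pairs(m, l, 50000)
    expect_setequal(paste(got$mrna_id, got$lncrna_id), truth_key)
    # planted gaps lie in [0, true_pair_max_gap]
    expect_true(all(got$distance_bp <= 10000))
    # decoys keep their guaranteed clearance from every mRNA
    decoys <- l[l$feature_id %in% gen$truth$decoy_lncrnas, ]
    near <- brute_pairs(m, decoys, 60000)
    expect_equal(nrow(near), 0L)
  }
})

test_that("a genome without lncRNAs is valid and yields zero pairs", {
  cfg <- sim_config(seed = 5, n_mrnas = 10L, n_lncrnas = 0L,
                    n_true_pairs = 0L)
  gen <- simulate_genome(cfg)
  expect_equal(sum(gen$catalog$features$feature_class == "lncRNA"), 0L)
  mr <- catalog_subset(gen$catalog, "mRNA")
  lc <- suppressWarnings(feature_catalog(
    gen$catalog$features[gen$catalog$features$feature_class == "lncRNA", ]))
  expect_message(pr <- pair_by_proximity(mr, lc, 50000), "empty")
  expect_equal(nrow(pr), 0L)
})

test_that("an infeasible genome errors instead of violating spacing", {
  cfg <- sim_config(seed = 5, n_chroms = 1L, chrom_length = 1e5,
                    n_mrnas = 10L, n_lncrnas = 10L, n_true_pairs = 2L)
  expect_error(simulate_genome(cfg), "genome too small")
})

test_that("DE plant: zero fraction, exact count, and planted signs", {
  cfg0 <- sim_config(seed = 6, n_mrnas = 30L, n_lncrnas = 30L,
                     n_true_pairs = 0L, frac_de = 0)
  gen0 <- simulate_genome(cfg0)
  det0 <- simulate_de_table(cfg0, gen0$truth)
  expect_equal(nrow(filter_differential(det0$de, 2)), 0L)

  cfg <- preset_prediabetes(seed = 17)
  gen <- simulate_genome(cfg)
  det <- simulate_de_table(cfg, gen$truth)
  kept <- filter_differential(det$de, 2)
  expect_setequal(kept$feature_id, det$truth$de_features)
  # Cpt1b's preset direction is down, Srebf1's up
  expect_lt(det$de$log2fc[det$de$feature_id == "Cpt1b"], 0)
  expect_gt(det$de$log2fc[det$de$feature_id == "Srebf1"], 0)
  dirs <- det$truth$planted_directions
  sign_ok <- vapply(names(dirs), function(id) {
    lfc <- det$de$log2fc[det$de$feature_id == id]
    (dirs[[id]] == "up") == (lfc > 0)
  }, logical(1))
  expect_true(all(sign_ok))
  # p-values are rank-consistent with |log2fc|
  o <- order(-abs(det$de$log2fc))
  expect_true(all(diff(det$de$pvalue[o]) > 0))
})

test_that("CT plant: comonotone pairs give r = 1 within a group", {
  cfg <- sim_config(seed = 21, n_mrnas = 5L, n_lncrnas = 5L,
                    n_true_pairs = 1L,
                    planted_rho = c("gene001|lnc001" = 1),
                    dct_means = list())
  gen <- simulate_genome(cfg)
  det <- simulate_de_table(cfg, gen$truth)
  ct <- simulate_ct_table(cfg, det$truth)
  rel <- ddct(ct)
  sed <- rel[rel$group == "HF-Sed", ]
  r <- pearson(sed$delta_ct[sed$target == "gene001"],
               sed$delta_ct[sed$target == "lnc001"])$r
  expect_equal(r, 1.0, tolerance = 1e-9)
})

test_that("preset directional pattern is recovered by ddct in every group", {
  cfg <- preset_prediabetes(seed = 23, n_per_group = 6L)
  gen <- simulate_genome(cfg)
  det <- simulate_de_table(cfg, gen$truth)
  ct <- simulate_ct_table(cfg, det$truth)
  rel <- ddct(ct)
  mean_fold <- function(tg, grp) mean(rel$fold[rel$target == tg &
                                                 rel$group == grp])
  # up in HF-Sed, reversed toward control under exercise, amplified in
  # the diabetic group
  for (tg in c("Srebf1", "Pck1")) {
    expect_gt(mean_fold(tg, "HF-Sed"), 1)
    expect_lt(mean_fold(tg, "HF-Exe"), mean_fold(tg, "HF-Sed"))
    expect_gt(mean_fold(tg, "Diabetic"), mean_fold(tg, "HF-Sed"))
  }
  expect_lt(mean_fold("Cpt1b", "HF-Sed"), 1)
  expect_gt(mean_fold("Cpt1b", "HF-Exe"), mean_fold("Cpt1b", "HF-Sed"))
})

test_that("network plant: the designated hub attains maximal degree", {
  cfg <- preset_prediabetes(seed = 29)
  gen <- simulate_genome(cfg)
  det <- simulate_de_table(cfg, gen$truth)
  net <- simulate_ppi_and_sets(cfg, det$truth)
  pr <- pair_by_proximity(catalog_subset(gen$catalog, "mRNA"),
                          catalog_subset(gen$catalog, "lncRNA"), 50000)
  g <- build_network(net$edges, pr, 0.4)
  dc <- degree_centrality(g)
  expect_equal(names(which.max(dc)), net$truth$hub)
})

test_that("coding-lnc decoys are labelled and screened out", {
  cfg <- preset_prediabetes(seed = 31)
  gen <- simulate_genome(cfg)
  det <- simulate_de_table(cfg, gen$truth)
  net <- simulate_ppi_and_sets(cfg, det$truth)
  expect_equal(sum(net$cp$label == "coding"), 5L)
  # no planted pair member is ever labelled coding
  expect_false(any(net$cp$feature_id[net$cp$label == "coding"] %in%
                     det$truth$true_pairs$lncrna_id))
})

test_that("phenotypes reflect the group design", {
  cfg <- preset_prediabetes(seed = 37)
  ph <- simulate_phenotypes(cfg)
  expect_equal(nrow(ph), 24L)
  agg <- tapply(ph$fasting_glucose, ph$group, mean)
  expect_gt(agg[["HF-Sed"]], agg[["Ctrl"]])
  expect_gt(agg[["Diabetic"]], agg[["HF-Sed"]])
  expect_lt(agg[["HF-Exe"]], agg[["HF-Sed"]])
  expect_true(all(ph$fasting_insulin > 0))
})
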