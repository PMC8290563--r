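# Combined network construction, degree centrality, hub-pair funnel.

edge_df <- function(a, b, s) data.frame(node_a = a, node_b = b, score = s,
                                        stringsAsFactors = FALSE)
pair_df <- function(m, l) data.frame(
  mrna_id = m, lncrna_id = l, chrom = rep("1", length(m)),
  distance_bp = rep(0L, length(m)),
  relation = rep("overlapping", length(m)), stringsAsFactors = FALSE)

test_that("score threshold and hml edges build the expected graph", {
  ppi <- edge_df(c("a", "a", "b"), c("b", "c", "c"), c(0.2, 0.5, 0.9))
  g <- build_network(ppi, pair_df("g1", "l1"), score_threshold = 0.4)
  expect_equal(igraph::ecount(g), 3L)  # 2 ppi kept + 1 hml
  expect_setequal(igraph::V(g)$name, c("a", "b", "c", "g1", "l1"))
  kinds <- table(igraph::E(g)$kind)
  expect_equal(unname(kinds[["ppi"]]), 2L)
  expect_equal(unname(kinds[["hml"]]), 1L)
  # native 0-1000 scores rescale on read
  path <- tempfile()
  writeLines(c("protein1\tprotein2\tcombined_score", "a\tb\t700"), path)
  expect_equal(read_string_edges(path)$score, 0.7)
})

test_that("self-loops drop with a warning; duplicates collapse", {
  ppi <- edge_df(c("a", "a", "b"), c("a", "b", "a"), c(0.9, 0.9, 0.9))
  expect_warning(g <- build_network(ppi, pair_df(character(0),
                                                 character(0))[0, ],
                                    0.4), "self-loop")
  expect_equal(igraph::ecount(g), 1L)  # a-b and b-a collapse
  # an edge present as both ppi and hml keeps the hml kind
  g2 <- suppressWarnings(build_network(edge_df("g1", "l1", 0.9),
                                       pair_df("g1", "l1"), 0.4))
  expect_equal(igraph::ecount(g2), 1L)
  expect_equal(igraph::E(g2)$kind, "hml")
})

test_that("node count equals the endpoint-id union", {
  set.seed(44)
  for (rep in 1:10) {
    n <- 30
    a <- sprintf("n%02d", sample.int(n, 40, replace = TRUE))
    b <- sprintf("n%02d", sample.int(n, 40, replace = TRUE))
    keep <- a != b
    ppi <- edge_df(a[keep], b[keep], runif(sum(keep), 0.5, 1))
    g <- build_network(ppi, pair_df(character(0), character(0))[0, ], 0.4)
    expect_equal(igraph::vcount(g),
                 length(unique(c(ppi$node_a, ppi$node_b))))
  }
})

test_that("degree centrality: star, complete, and brute-force random graphs", {
  star <- build_network(edge_df(rep("hub", 4), paste0("x", 1:4),
                                rep(1, 4)),
                        pair_df(character(0), character(0))[0, ], 0.4)
  dc <- degree_centrality(star)
  expect_equal(unname(dc["hub"]), 1.0)
  expect_equal(unname(dc[paste0("x", 1:4)]), rep(0.25, 4))
  k4 <- t(combn(paste0("v", 1:4), 2))
  complete <- build_network(edge_df(k4[, 1], k4[, 2], rep(1, 6)),
                            pair_df(character(0), character(0))[0, ], 0.4)
  expect_true(all(degree_centrality(complete) == 1))
  expect_error(degree_centrality(igraph::make_empty_graph(1,
                                                          directed = FALSE)),
               "at least 2 nodes")
  set.seed(91)
  for (rep in 1:10) {
    nodes <- sprintf("n%02d", 1:50)
    a <- sample(nodes, 120, replace = TRUE)
    b <- sample(nodes, 120, replace = TRUE)
    keep <- a != b
    el <- data.frame(a = a[keep], b = b[keep], stringsAsFactors = FALSE)
    key <- paste(pmin(el$a, el$b), pmax(el$a, el$b))
    el <- el[!duplicated(key), ]
    g <- build_network(edge_df(el$a, el$b, rep(1, nrow(el))),
                       pair_df(character(0), character(0))[0, ], 0.4)
    dc <- degree_centrality(g)
    want <- brute_degree(el, igraph::V(g)$name) / (igraph::vcount(g) - 1)
    expect_equal(unname(dc), unname(want[igraph::V(g)$name]))
  }
})

# a hand-built funnel fixture: 6 pair-bearing genes, 5 in the target
# pathway, 4 with both category flags, 3 with annotated lncRNAs
funnel_fixture <- function() {
  genes <- sprintf("G%d", 1:6)
  pairs <- pair_df(genes, sprintf("L%d", 1:6))
  ppi <- edge_df(rep("G1", 5), c(genes[-1]), rep(0.9, 5))
  graph <- build_network(ppi, pairs, 0.4)
  tags <- data.frame(
    feature_id = genes,
    categories = c(rep("carbohydrate_metabolism,lipid_metabolism", 4),
                   "carbohydrate_metabolism", ""),
    carbohydrate = c(rep(TRUE, 5), FALSE),
    lipid = c(rep(TRUE, 4), FALSE, FALSE),
    both = c(rep(TRUE, 4), FALSE, FALSE),
    n_pathways = c(4L, 3L, 3L, 3L, 1L, 0L),
    stringsAsFactors = FALSE)
  list(graph = graph, tags = tags, pairs = pairs,
       lnc_ann = setNames(c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
                          sprintf("L%d", 1:6)),
       target = genes[1:5])
}

test_that("hub funnel reproduces the 5 -> 4 -> 3 shortlist", {
  f <- funnel_fixture()
  sl <- suppressMessages(
    select_hub_pairs(f$graph, f$tags, f$pairs, f$lnc_ann, f$target,
                     top_k = 10))
  expect_equal(nrow(sl), 3L)
  expect_setequal(sl$mrna_id, c("G1", "G2", "G3"))
  funnel <- attr(sl, "funnel")
  expect_equal(funnel$n_out[funnel$stage == "target_pathway"], 5L)
  expect_equal(funnel$n_out[grepl("dual_category", funnel$stage)], 4L)
  expect_equal(funnel$n_out[funnel$stage == "annotated_lncrna"], 3L)
  expect_true(all(funnel$n_out <= funnel$n_in))
  # G1 is the hub: highest centrality ranks first
  expect_equal(sl$mrna_id[1], "G1")
})

test_that("empty target pathway yields an empty, logged shortlist", {
  f <- funnel_fixture()
  sl <- suppressMessages(
    select_hub_pairs(f$graph, f$tags, f$pairs, f$lnc_ann,
                     character(0), top_k = 10))
  expect_equal(nrow(sl), 0L)
  expect_s3_class(attr(sl, "funnel"), "data.frame")
})

test_that("ties resolve by n_pathways then id; top_k truncates", {
  f <- funnel_fixture()
  # G2 and G3 have equal degree (leaves of the star + hml edge)
  sl <- suppressMessages(
    select_hub_pairs(f$graph, f$tags, f$pairs, f$lnc_ann, f$target,
                     top_k = 10))
  sub <- sl[sl$mrna_id %in% c("G2", "G3"), ]
  expect_equal(sub$mrna_id, c("G2", "G3"))  # equal n_pathways -> id order
  top2 <- suppressMessages(
    select_hub_pairs(f$graph, f$tags, f$pairs, f$lnc_ann, f$target,
                     top_k = 2))
  expect_equal(nrow(top2), 2L)
})

test_that("shortlist is invariant to ppi edge input order", {
  f <- funnel_fixture()
  ppi <- edge_df(rep("G1", 5), sprintf("G%d", 2:6), rep(0.9, 5))
  g1 <- build_network(ppi, f$pairs, 0.4)
  g2 <- build_network(ppi[rev(seq_len(nrow(ppi))), ], f$pairs, 0.4)
  s1 <- suppressMessages(select_hub_pairs(g1, f$tags, f$pairs, f$lnc_ann,
                                          f$target, 10))
  s2 <- suppressMessages(select_hub_pairs(g2, f$tags, f$pairs, f$lnc_ann,
                                          f$target, 10))
  attr(s1, "funnel") <- NULL; attr(s2, "funnel") <- NULL
  expect_identical(s1, s2)
})

test_that("multi_pathway dual rule is an alternative reading", {
  f <- funnel_fixture()
  sl <- suppressMessages(
    select_hub_pairs(f$graph, f$tags, f$pairs, f$lnc_ann, f$target,
                     top_k = 10, dual_rule = "multi_pathway"))
  # n_pathways > 2 holds for G1..G4, annotation then keeps G1..G3
  expect_setequal(sl$mrna_id, c("G1", "G2", "G3"))
})

test_that("network export writes edge and node attribute tables", {
  f <- funnel_fixture()
  ep <- tempfile(fileext = ".tsv"); np <- tempfile(fileext = ".tsv")
  write_network(f$graph, ep, np)
  edges <- read.table(ep, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  nodes <- read.table(np, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  expect_equal(nrow(edges), igraph::ecount(f$graph))
  expect_equal(nrow(nodes), igraph::vcount(f$graph))
  expect_true(all(c("degree", "degree_centrality") %in% names(nodes)))
})
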