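# Coordinate conventions, readers, interval index, and distances.

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

test_that("GTF coordinates convert to 0-based half-open and exons collapse", {
  gtf <- write_lines_tmp(c(
    '1\tsrc\tgene\t101\t200\t.\t+\t.\tgene_id "gA"; gene_biotype "protein_coding";',
    '1\tsrc\texon\t100\t200\t.\t-\t.\tgene_id "gB"; gene_biotype "lncRNA";',
    '1\tsrc\texon\t500\t600\t.\t-\t.\tgene_id "gB"; gene_biotype "lncRNA";'
  ), ".gtf")
  cat <- read_gtf(gtf)
  a <- catalog_get(cat, "gA")
  expect_equal(a$start, 100L)
  expect_equal(a$end, 200L)
  expect_equal(a$end - a$start, 100L)
  b <- catalog_get(cat, "gB")
  expect_equal(b$start, 99L)   # min start across exons, shifted
  expect_equal(b$end, 600L)    # max end across exons
  expect_equal(b$feature_class, "lncRNA")
})

test_that("GTF round trip preserves printed 1-based coordinates", {
  cfg <- sim_config(seed = 11, n_mrnas = 3L, n_lncrnas = 3L,
                    n_true_pairs = 2L)
  cat1 <- simulate_genome(cfg)$catalog
  p1 <- tempfile(fileext = ".gtf")
  p2 <- tempfile(fileext = ".gtf")
  write_gtf(cat1, p1)
  cat2 <- read_gtf(p1)
  write_gtf(cat2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_setequal(cat2$features$feature_id, cat1$features$feature_id)
  m <- match(cat1$features$feature_id, cat2$features$feature_id)
  expect_equal(cat2$features$start[m], cat1$features$start)
  expect_equal(cat2$features$end[m], cat1$features$end)
})

test_that("GTF reader agrees with rtracklayer on a synthetic fixture", {
  skip_if_not_installed("rtracklayer")
  cfg <- sim_config(seed = 3, n_mrnas = 8L, n_lncrnas = 8L,
                    n_true_pairs = 4L)
  cat1 <- simulate_genome(cfg)$catalog
  path <- tempfile(fileext = ".gtf")
  write_gtf(cat1, path)
  gr <- rtracklayer::import(path, format = "gtf")
  m <- match(cat1$features$feature_id, gr$gene_id)
  expect_false(anyNA(m))
  # rtracklayer keeps 1-based closed coordinates
  expect_equal(GenomicRanges::start(gr)[m], cat1$features$start + 1L)
  expect_equal(GenomicRanges::end(gr)[m], cat1$features$end)
})

test_that("malformed and unmappable GTF records are reported precisely", {
  bad <- write_lines_tmp(c(
    '1\tsrc\tgene\t101\t200\t.\t+\t.\tgene_id "gA"; gene_biotype "protein_coding";',
    "1\tsrc\tgene\t10"), ".gtf")
  expect_error(read_gtf(bad), "line 2")
  skipme <- write_lines_tmp(c(
    '1\tsrc\tgene\t101\t200\t.\t+\t.\tgene_id "gA"; gene_biotype "protein_coding";',
    '1\tsrc\tgene\t301\t400\t.\t+\t.\tgene_id "gC"; gene_biotype "pseudogene";'
  ), ".gtf")
  cat <- read_gtf(skipme)
  expect_equal(length(cat), 1L)
  expect_equal(cat$n_skipped, 1L)
  empty <- write_lines_tmp("# just a comment", ".gtf")
  expect_error(read_gtf(empty), "empty catalog")
})

test_that("BED ingests without shifting and agrees with GTF encoding", {
  bed <- write_lines_tmp("chr1\t0\t50\tgeneA", ".bed")
  cat <- read_bed(bed, "mRNA")
  a <- catalog_get(cat, "geneA")
  expect_equal(a$start, 0L)
  expect_equal(a$end, 50L)
  expect_equal(a$chrom, "1")  # chr prefix normalized away
  # same locus via GTF (1-based): start 1, end 50
  gtf <- write_lines_tmp(
    '1\tsrc\tgene\t1\t50\t.\t+\t.\tgene_id "geneA"; gene_biotype "protein_coding";',
    ".gtf")
  g <- catalog_get(read_gtf(gtf), "geneA")
  expect_equal(g$start, a$start)
  expect_equal(g$end, a$end)
  bad <- write_lines_tmp(c("chr1\t0\t50\tok", "chr1\t60\t60\tbad"), ".bed")
  expect_error(read_bed(bad, "mRNA"), "line 2")
})

test_that("large random BED round trip keeps every record", {
  set.seed(42)
  f <- rand_features(1000, "lncRNA")
  path <- tempfile(fileext = ".bed")
  write_bed(as_catalog(f), path)
  # name field carries id|class; read back as plain BED names
  cat <- read_bed(path, "lncRNA")
  expect_equal(length(cat), 1000L)
})

test_that("feature_distance: overlap, gap, cross-chromosome, symmetry", {
  f <- function(chrom, s, e) list(chrom = chrom, start = s, end = e)
  expect_equal(feature_distance(f("1", 100, 200), f("1", 150, 300)), 0L)
  expect_equal(feature_distance(f("1", 100, 200), f("1", 250, 300)), 50L)
  expect_equal(feature_distance(f("1", 100, 200), f("1", 200, 300)), 0L)
  expect_true(is.na(feature_distance(f("1", 100, 200), f("2", 250, 300))))
  set.seed(7)
  for (i in 1:50) {
    a <- f("1", s <- sample(1000, 1), s + sample(100, 1))
    b <- f("1", s2 <- sample(1000, 1), s2 + sample(100, 1))
    expect_identical(feature_distance(a, b), feature_distance(b, a))
    overlap_or_abut <- max(a$start, b$start) <= min(a$end, b$end)
    expect_identical(feature_distance(a, b) == 0L, overlap_or_abut)
  }
})

test_that("distance obeys the collinear triangle-like bound", {
  set.seed(8)
  f <- function(s, e) list(chrom = "1", start = s, end = e)
  for (i in 1:100) {
    s <- sort(sample.int(10000, 6))
    a <- f(s[1], s[2]); b <- f(s[3], s[4]); c <- f(s[5], s[6])
    lhs <- feature_distance(a, c)
    rhs <- feature_distance(a, b) + (b$end - b$start) +
      feature_distance(b, c)
    expect_lte(lhs, rhs)
  }
})

test_that("interval index equals brute-force linear scan", {
  set.seed(101)
  f <- rand_features(1000, "mRNA")
  cat <- as_catalog(f)
  for (q in 1:200) {
    chrom <- as.character(sample.int(5, 1))
    qs <- sample.int(1e6, 1)
    qe <- qs + sample.int(20000, 1)
    got <- sort(catalog_query(cat, chrom, qs, qe)$feature_id)
    want <- sort(f$feature_id[f$chrom == chrom & f$start < qe &
                                f$end > qs])
    expect_identical(got, want)
  }
})

test_that("catalog invariants are enforced", {
  f <- rand_features(5, "mRNA")
  f$feature_id[2] <- f$feature_id[1]
  expect_error(feature_catalog(f), "duplicate feature_id")
  g <- rand_features(3, "mRNA")
  g$end[1] <- g$start[1]
  expect_error(feature_catalog(g), "start < end")
  h <- rand_features(3, "mRNA")
  h$feature_class[2] <- "protein"
  expect_error(feature_catalog(h), "feature_class")
})
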