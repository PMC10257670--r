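mk_triples <- function(cell, umi, bc, reads) {
  triples(data.frame(cell_barcode = cell, umi = umi, lineage_barcode = bc,
                     read_count = reads, stringsAsFactors = FALSE))
}

test_that("triple loading aggregates duplicates and enforces barcode length", {
  f <- withr::local_tempfile()
  writeLines(c("cell_barcode\tumi\tlineage_barcode\tread_count",
               "c1\tu1\tAAAACCCCGGGG\t6",
               "c1\tu1\tAAAACCCCGGGG\t5",
               "c2\tu1\tAAAACCCCGGGT\t12"), f)
  tr <- load_triples(f)
  expect_equal(nrow(tr), 2)
  expect_equal(tr$read_count[tr$cell_barcode == "c1"], 11)

  writeLines("cell_barcode\tumi\tlineage_barcode\tread_count", f)
  expect_equal(nrow(load_triples(f)), 0)

  writeLines(c("cell_barcode\tumi\tlineage_barcode\tread_count",
               "c1\tu1\tAAAACCCCGGGG\t6",
               "c2\tu1\tAAAACCCCGGG\t6"), f)
  expect_error(load_triples(f), "same length")

  writeLines(c("cell_barcode\tumi\tread_count", "c1\tu1\t5"), f)
  expect_error(load_triples(f), "lineage_barcode")
})

test_that("read-support filtering keeps the >= 10 boundary", {
  tr <- mk_triples(c("c1", "c2", "c3"), "u1",
                   "ACGTACGTACGT", c(10, 9, 100))
  kept <- filter_triples(tr, 10)
  expect_setequal(kept$cell_barcode, c("c1", "c3"))
  expect_equal(nrow(filter_triples(tr[0, ], 10)), 0)
})

test_that("greedy collapse follows abundance order within the hamming radius", {
  # identical barcodes -> one representative
  t1 <- mk_triples(c("c1", "c2"), c("u1", "u1"),
                   "AAAAAAAAAAAA", c(10, 10))
  m1 <- collapse_lineage_barcodes(t1)
  expect_equal(nrow(m1), 1)
  expect_equal(m1$representative, m1$barcode)

  # hamming 4 apart -> two representatives
  t2 <- mk_triples(c("c1", "c2"), "u1",
                   c("AAAAAAAAAAAA", "TTTTAAAAAAAA"), c(10, 10))
  expect_equal(length(unique(collapse_lineage_barcodes(t2)$representative)), 2)

  # minor variant at hamming 1 joins the major barcode
  t3 <- mk_triples(c("c1", "c2"), "u1",
                   c("AAAAAAAAAAAA", "CAAAAAAAAAAA"), c(100, 5))
  m3 <- collapse_lineage_barcodes(t3)
  expect_equal(unique(m3$representative), "AAAAAAAAAAAA")

  # idempotence: re-collapsing representatives changes nothing
  t4 <- mk_triples("c1", "u1", unique(m3$representative), 10)
  m4 <- collapse_lineage_barcodes(t4)
  expect_equal(m4$representative, m4$barcode)

  # every barcode within the stated radius of its representative
  set.seed(91)
  bcs <- replicate(40, paste(sample(c("A", "C", "G", "T"), 12,
                                    replace = TRUE), collapse = ""))
  t5 <- mk_triples(sprintf("c%02d", 1:40), "u1", bcs,
                   sample(5:100, 40, replace = TRUE))
  m5 <- collapse_lineage_barcodes(t5, 3)
  d <- mapply(brute_hamming, m5$barcode, m5$representative)
  expect_true(all(d <= 3))
})

test_that("greedy collapse equals the brute-force oracle on small instances", {
  set.seed(101)
  for (i in 1:30) {
    n <- sample(2:12, 1)
    # short alphabetic space so hamming hits are common
    bcs <- replicate(n, paste(sample(c("A", "C"), 8, replace = TRUE),
                              collapse = ""))
    tr <- mk_triples(sprintf("c%02d", seq_len(n)), "u1", bcs,
                     sample(1:50, n, replace = TRUE))
    got <- collapse_lineage_barcodes(tr, 3)
    want <- brute_collapse(tr, 3)
    expect_equal(got, want)
  }
})

test_that("cell assignment needs >= 3 distinct UMIs and breaks ties to NA", {
  tr <- rbind(
    mk_triples("c1", c("u1", "u2", "u3"), "AAAAAAAAAAAA", 10),
    mk_triples("c2", c("u1", "u2"), "AAAAAAAAAAAA", 10),
    mk_triples("c3", c("u1", "u2", "u3"), "AAAAAAAAAAAA", 10),
    mk_triples("c3", c("u4", "u5", "u6"), "TTTTTTTTTTTT", 10))
  a <- assign_cells(tr, 3)
  expect_equal(a$lineage[a$cell_barcode == "c1"], "AAAAAAAAAAAA")
  expect_true(is.na(a$lineage[a$cell_barcode == "c2"]))
  expect_true(is.na(a$lineage[a$cell_barcode == "c3"])) # 3-3 tie
  # duplicate UMI rows for the same lineage count once
  dup <- mk_triples("c4", c("u1", "u1", "u2"), "AAAAAAAAAAAA", c(10, 20, 10))
  expect_true(is.na(assign_cells(dup, 3)$lineage))
})

test_that("clone statistics: sizes, groups, dominance, percentages", {
  cells <- sprintf("c%03d", 1:40)
  lin <- c(rep("L1", 25), rep("L2", 5), rep("L3", 2), rep("L4", 1),
           rep(NA, 7))
  a <- data.frame(cell_barcode = cells, lineage = lin, n_umis = 3,
                  stringsAsFactors = FALSE)
  st <- clone_statistics(a)
  expect_equal(sort(st$clones$size, decreasing = TRUE), c(25, 5, 2))
  expect_equal(st$clones$dominant[st$clones$size == 25], TRUE)
  expect_equal(st$clones$size_group[order(-st$clones$size)],
               c(">20", "2-10", "2-10"))
  s <- st$group_summary
  expect_equal(sum(s$percent), 100)
  expect_equal(s$percent[s$size_group == ">20"], 25 / 32 * 100)

  # all singletons -> zero clones
  a1 <- data.frame(cell_barcode = c("x", "y"), lineage = c("A", "B"),
                   n_umis = 3)
  expect_equal(nrow(clone_statistics(a1)$clones), 0)
  expect_equal(nrow(clone_statistics(a1[0, ])$clones), 0)
})

test_that("size-group percentages sum to 100 per sample", {
  set.seed(111)
  a <- data.frame(cell_barcode = sprintf("c%03d", 1:60),
                  lineage = sample(c("L1", "L2", "L3"), 60, replace = TRUE,
                                   prob = c(.6, .3, .1)),
                  n_umis = 3, stringsAsFactors = FALSE)
  labs <- data.frame(cell_barcode = a$cell_barcode,
                     sample = rep(c("wk4", "wk7"), 30))
  s <- clone_statistics(a, labs)$group_summary
  tot <- tapply(s$percent, s$sample, sum)
  expect_equal(as.numeric(tot), c(100, 100))
})

test_that("dominant-clone cluster fractions sum to one per clone", {
  a <- data.frame(cell_barcode = sprintf("c%03d", 1:23),
                  lineage = c(rep("L1", 21), "L2", "L2"),
                  n_umis = 3, stringsAsFactors = FALSE)
  cl <- data.frame(cell_barcode = a$cell_barcode,
                   cluster = c(rep("k2", 14), rep("k1", 7), "k1", "k1"))
  d <- dominant_clone_cluster_density(a, cl)
  expect_equal(unique(d$lineage), "L1") # only the 21-cell clone is dominant
  expect_equal(sort(d$fraction), c(1 / 3, 2 / 3))
  expect_equal(sum(d$fraction), 1)

  expect_error(dominant_clone_cluster_density(a, cl[1:5, ]), "missing")
  none <- dominant_clone_cluster_density(a[22:23, ], cl)
  expect_equal(nrow(none), 0)
})

test_that("end-to-end calling recovers planted clones and thresholds bite", {
  sim <- simulate_barcode_data(clone_sizes = c(25, 5, 2), sub_rate = 0.1,
                               seed = 17)
  res <- call_clones(sim$triples)
  expect_equal(sort(res$clones$size, decreasing = TRUE), c(25, 5, 2))
  expect_equal(sum(res$clones$dominant), 1)
  # memberships match the planted truth exactly (compare as partitions)
  got <- split(res$assignments$cell_barcode, res$assignments$lineage)
  want <- split(sim$truth$cell_barcode, sim$truth$clone_id)
  expect_setequal(unname(lapply(got, sort)), unname(lapply(want, sort)))

  # reads-per-UMI 9 or UMIs 2: zero clones
  sim9 <- simulate_barcode_data(clone_sizes = c(25, 5, 2),
                                reads_per_umi = 9, seed = 17)
  expect_equal(nrow(call_clones(sim9$triples)$clones), 0)
  sim2 <- simulate_barcode_data(clone_sizes = c(25, 5, 2),
                                umis_per_cell = 2, seed = 17)
  expect_equal(nrow(call_clones(sim2$triples)$clones), 0)
})
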