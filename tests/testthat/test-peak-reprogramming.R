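mk_signal <- function(id, wt, mutant) {
  data.frame(peak_id = id,
             condition = rep(c("wt", "mutant"), c(length(wt), length(mutant))),
             replicate = c(seq_along(wt), seq_along(mutant)),
             fpkm = c(wt, mutant), stringsAsFactors = FALSE)
}

test_that("peak classification applies fold-change and p-value cutoffs", {
  pk <- genomic_intervals("chr1", c(0, 1000, 2000), c(500, 1500, 2500),
                          name = c("a", "b", "c"))
  sig <- rbind(
    mk_signal("a", c(5, 5.1), c(5, 5.1)),          # identical -> stable
    mk_signal("b", c(10, 10.1), c(40, 41)),        # lfc = 2, p < 0.01 -> up
    mk_signal("c", c(10, 10), c(17, 17)))          # lfc ~ 0.77 -> stable
  ct <- classify_peaks(pk, sig)
  expect_equal(ct$category, c("stable", "up", "stable"))
  expect_equal(ct$log2fc[1], 0)
  expect_equal(ct$log2fc[2], 2, tolerance = 1e-6)
  expect_lt(ct$p_value[2], 0.01)
  expect_lt(abs(ct$log2fc[3] - log2(17.1 / 10.1)), 1e-12)

  # single replicate per side -> p = 1, never differential
  ct1 <- classify_peaks(pk[2, ], mk_signal("b", 10, 40))
  expect_equal(ct1$category, "stable")
  expect_equal(ct1$p_value, 1)
  # down direction
  ctd <- classify_peaks(pk[2, ], mk_signal("b", c(40, 41), c(10, 10.1)))
  expect_equal(ctd$category, "down")
  expect_error(classify_peaks(pk, sig[sig$peak_id != "c", ]), "c")
})

test_that("midpoint annotation respects the priority order", {
  sizes <- c(chr1 = 100000)
  cat <- annotation_catalog(list(
    promoter = genomic_intervals("chr1", 1000, 2000),
    exon = genomic_intervals("chr1", 1500, 3000),
    intron = genomic_intervals("chr1", 5000, 6000)), sizes)
  pk <- genomic_intervals("chr1", c(1600, 5200, 50000),
                          c(1800, 5400, 50100))
  expect_equal(annotate_peaks(pk, cat),
               c("promoter", "intron", "intergenic"))
  # same midpoint, exon-only coverage
  pk2 <- genomic_intervals("chr1", 2500, 2700)
  expect_equal(annotate_peaks(pk2, cat), "exon")
  expect_equal(annotate_peaks(pk[0, ], cat), character())
})

test_that("enrichment ratio matches the cancelled form and hand values", {
  sizes <- c(chr1 = 100000)
  catalog <- annotation_catalog(
    list(promoter = genomic_intervals("chr1", c(0, 30000), c(10000, 40000))),
    sizes)
  d <- genomic_intervals("chr1", c(500, 60000), c(1000, 60500))   # 500/1000 in
  s <- genomic_intervals("chr1", c(2000, 70000, 80000, 90000),
                         c(2500, 70500, 80500, 90500))            # 500/2000 in
  er <- enrichment_ratio(d, s, catalog)
  expect_equal(er$obs_d, 500)
  expect_equal(er$obs_s, 500)
  expect_equal(er$ratio, 1) # log2((500/1000)/(500/2000)), Lanno/Lg cancels
  expect_equal(er$exp_d, 20000 / 100000 * 1000)

  # equal annotation fractions -> 0
  er0 <- enrichment_ratio(d, d, catalog)
  expect_equal(er0$ratio, 0)

  # no overlap -> undefined, not a number
  far <- genomic_intervals("chr1", 50000, 51000)
  eru <- enrichment_ratio(far, s, catalog)
  expect_false(eru$defined)
  expect_true(is.na(eru$ratio))
  expect_error(enrichment_ratio(d[0, ], s, catalog), "non-empty")
})

test_that("enrichment ratio: Lg-invariance and antisymmetry on random sets", {
  set.seed(61)
  sizes <- c(g1 = 50000)
  for (i in 1:20) {
    anno <- random_intervals(10, sizes, 2000)
    catalog <- annotation_catalog(list(t = anno), sizes)
    d <- random_intervals(15, sizes, 1000)
    s <- random_intervals(15, sizes, 1000)
    er <- enrichment_ratio(d, s, catalog)
    if (!er$defined) next
    cancelled <- log2((er$obs_d / er$L_d) / (er$obs_s / er$L_s))
    expect_equal(er$ratio, cancelled, tolerance = 1e-12)
    expect_equal(enrichment_ratio(s, d, catalog)$ratio, -er$ratio,
                 tolerance = 1e-12)
    # observed lengths are genuine per-base overlaps
    expect_equal(er$obs_d, brute_overlap_length(d, anno, sizes))
  }
})

test_that("compartment assignment is by majority overlap with ties unassigned", {
  comp <- genomic_intervals("chr1", c(0, 10000), c(10000, 20000),
                            name = c("A", "B"))
  pk <- genomic_intervals("chr1",
                          c(2000, 9600, 9500, 30000),
                          c(3000, 10600, 10500, 31000),
                          name = c("inA", "mostB", "tie", "gap"))
  pk$category <- c("up", "up", "stable", "stable")
  res <- compartment_proportions(pk, comp)
  expect_equal(res$assignment, c("A", "B", "unassigned", "unassigned"))
  expect_equal(rowSums(res$proportions[, c("A", "B", "unassigned")]),
               c(1, 1), ignore_attr = TRUE)
  expect_equal(res$proportions$A[res$proportions$category == "up"], 0.5)
})

test_that("enhancer classification matches the enumerated rule table", {
  # all 16 combinations of (K4me3 overlap, near TSS, K27ac, K27me3)
  grid <- expand.grid(k4me3 = c(FALSE, TRUE), near = c(FALSE, TRUE),
                      k27ac = c(FALSE, TRUE), k27me3 = c(FALSE, TRUE))
  oracle <- function(g) {
    if (g$k4me3) "not_enhancer"
    else if (g$near) "excluded_near_TSS"
    else if (g$k27ac) "active"
    else if (g$k27me3) "repressed"
    else "poised"
  }
  slot <- 100000
  n <- nrow(grid)
  start <- (seq_len(n) - 1) * slot + 40000
  k4me1 <- genomic_intervals("chr1", start, start + 1000)
  sub <- function(flag, offset, width) {
    idx <- which(flag)
    if (!length(idx)) return(genomic_intervals())
    genomic_intervals("chr1", start[idx] + offset, start[idx] + offset + width)
  }
  k4me3 <- sub(grid$k4me3, 500, 400)
  k27ac <- sub(grid$k27ac, 200, 300)
  k27me3 <- sub(grid$k27me3, 600, 300)
  tss <- data.frame(chrom = "chr1",
                    pos = start[grid$near] + 500 + 2000) # 2 kb from midpoint
  got <- classify_enhancers(k4me1, k4me3, k27ac, k27me3, tss)
  want <- vapply(seq_len(n), function(i) oracle(grid[i, ]), character(1))
  expect_equal(got, want)
  expect_equal(classify_enhancers(genomic_intervals(), k4me3, k27ac,
                                  k27me3, tss), character())
  # boundary: midpoint exactly 2.5 kb away is still excluded
  one <- genomic_intervals("chr1", 0, 1000)
  tss1 <- data.frame(chrom = "chr1", pos = 3000)
  expect_equal(classify_enhancers(one, genomic_intervals(),
                                  genomic_intervals(), genomic_intervals(),
                                  tss1), "excluded_near_TSS")
  tss2 <- data.frame(chrom = "chr1", pos = 3001)
  expect_equal(classify_enhancers(one, genomic_intervals(),
                                  genomic_intervals(), genomic_intervals(),
                                  tss2), "poised")
})

test_that("TSS points follow strand orientation", {
  g <- genomic_intervals("chr1", c(100, 200), c(150, 260),
                         strand = c("+", "-"))
  p <- tss_points(g)
  expect_equal(p$pos, c(100, 259))
  expect_error(tss_points(genomic_intervals("chr1", 0, 10)), "strand")
})
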