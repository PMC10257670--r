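#' Tile the genome into consecutive bins
#'
#' Consecutive `[i*b, (i+1)*b)` bins per chromosome; a final partial bin is
#' kept so every base is covered.
#'
#' @param chrom_sizes named vector of chromosome lengths.
#' @param bin_size bin width in bp (default 10 kb, the genome-wide
#'   change-ratio resolution).
#' @return A `genomic_intervals` data frame of bins in chromosome order.
#' @export
genome_bins <- function(chrom_sizes, bin_size = 10000) {
  stopifnot(bin_size > 0)
  rows <- lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    start <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = ch, start = start,
               end = pmin(start + bin_size, len),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  genomic_intervals(chrom = df$chrom, start = df$start, end = df$end)
}

#' FPKM over regions
#'
#' `FPKM = count / ((region_length / 1000) * (total_mapped / 1e6))`, where
#' `count` is the number of reads whose 5' position falls inside the region.
#' Regions may overlap each other (each is counted independently).
#'
#' @param reads a `stranded_reads` object.
#' @param regions interval data frame.
#' @param total_mapped total mapped fragments of the library (> 0).
#' @return Numeric FPKM vector, one value per region.
#' @export
region_fpkm <- function(reads, regions, total_mapped) {
  validate_intervals(regions)
  stopifnot(total_mapped > 0)
  if (any(regions$end - regions$start <= 0)) stop("zero-length region")
  counts <- numeric(nrow(regions))
  if (nrow(reads) > 0 && nrow(regions) > 0) {
    pts <- genomic_intervals(chrom = reads$chrom, start = reads$pos5,
                             end = reads$pos5 + 1)
    counts <- GenomicRanges::countOverlaps(.as_granges(regions),
                                           .as_granges(pts),
                                           ignore.strand = TRUE)
  }
  counts / ((regions$end - regions$start) / 1000 * total_mapped / 1e6)
}

#' Per-bin mutant/WT change ratios
#'
#' `ratio = (mutant + eps) / (wt + eps)` per bin; bins with zero signal in
#' both samples are undefined (`NA`) and excluded downstream.
#'
#' @param mutant,wt numeric FPKM vectors over the same bins.
#' @param eps non-negative pseudocount (FPKM units).
#' @return Numeric ratio vector with `NA` at doubly-zero bins.
#' @export
change_ratios <- function(mutant, wt, eps = 0.1) {
  if (eps < 0) stop("pseudocount must be non-negative")
  stopifnot(length(mutant) == length(wt))
  r <- (mutant + eps) / (wt + eps)
  r[mutant == 0 & wt == 0] <- NA_real_
  r
}

#' Pairwise Pearson correlation of log2 change ratios
#'
#' For every pair of marks, computes Pearson r and its two-sided p-value on
#' `log2(ratio)` over the bins defined in both marks (pairwise deletion).
#' A pair with fewer than 3 shared defined bins is skipped with a warning.
#' The `displayed` flag reproduces the reporting gate `p < 0.01`.
#'
#' @param ratios named list of change-ratio vectors (equal length).
#' @param include_self also report each mark against itself (default FALSE).
#' @return Data frame: `mark_a`, `mark_b`, `r`, `p`, `n_bins`, `displayed`.
#' @export
pairwise_ratio_correlation <- function(ratios, include_self = FALSE) {
  stopifnot(is.list(ratios), length(ratios) >= 1, !is.null(names(ratios)))
  lens <- lengths(ratios)
  if (length(unique(lens)) != 1) stop("ratio vectors must share bins")
  marks <- names(ratios)
  rows <- list()
  for (i in seq_along(marks)) {
    for (j in seq(if (include_self) i else i + 1, length(marks))) {
      if (j > length(marks) || (!include_self && j <= i)) next
      x <- log2(ratios[[i]]); y <- log2(ratios[[j]])
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 3) {
        warning("pair ", marks[i], "/", marks[j],
                " skipped: fewer than 3 shared defined bins")
        next
      }
      if (i == j) {
        r <- 1; p <- 0
      } else if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        r <- NA_real_; p <- NA_real_
      } else {
        ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
        r <- unname(ct$estimate); p <- ct$p.value
      }
      rows[[length(rows) + 1]] <- data.frame(
        mark_a = marks[i], mark_b = marks[j], r = r, p = p,
        n_bins = sum(ok), displayed = !is.na(p) & p < 0.01,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(mark_a = character(), mark_b = character(),
                      r = numeric(), p = numeric(), n_bins = integer(),
                      displayed = logical()))
  do.call(rbind, rows)
}

#' Anchor-centered or region meta-profile of read density
#'
#' In `"center"` mode, windows of `±half_window` around anchor centers are
#' scanned in `bin_size` steps; per-bin densities are FPKM-normalized
#' (`count / ((bin_size/1000) * (total_mapped/1e6))`) and averaged over
#' anchors. Windows extending past a chromosome edge are dropped. Minus
#' strand anchors are flipped so profiles read 5' to 3'. In `"region"` mode
#' each region (e.g. gene body, TSS to TES) contributes one overall FPKM
#' plus a length-rescaled profile over `n_rel_bins` relative bins, flipped
#' for minus-strand regions.
#'
#' @param reads a `stranded_reads` object.
#' @param anchors interval data frame (centers taken at the midpoint in
#'   center mode; full span in region mode).
#' @param chrom_sizes named vector of chromosome lengths.
#' @param total_mapped total mapped fragments for FPKM scaling.
#' @param mode `"center"` or `"region"`.
#' @param half_window,bin_size center-mode geometry (default ±10 kb, 100 bp).
#' @param n_rel_bins number of relative bins in region mode (default 100).
#' @return List with `matrix` (anchors x bins densities), `mean_profile`,
#'   and in region mode `region_fpkm`.
#' @export
meta_profile <- function(reads, anchors, chrom_sizes, total_mapped,
                         mode = c("center", "region"),
                         half_window = 10000, bin_size = 100,
                         n_rel_bins = 100) {
  mode <- match.arg(mode)
  validate_intervals(anchors)
  if (nrow(anchors) == 0) stop("empty anchor set")
  stopifnot(total_mapped > 0)
  flip <- !is.null(anchors$strand) & anchors$strand == "-"
  if (mode == "center") {
    center <- floor((anchors$start + anchors$end) / 2)
    keep <- center - half_window >= 0 &
      center + half_window <= chrom_sizes[anchors$chrom]
    if (any(!keep))
      warning(sum(!keep), " anchor(s) with clipped windows dropped")
    if (!any(keep)) stop("no anchor window fits inside the genome")
    anchors <- anchors[keep, , drop = FALSE]
    center <- center[keep]; flip <- flip[keep]
    K2 <- 2L * as.integer(half_window / bin_size)
    M <- matrix(0, nrow(anchors), K2)
    for (ch in unique(anchors$chrom)) {
      ai <- which(anchors$chrom == ch)
      p <- sort(reads$pos5[reads$chrom == ch])
      if (!length(p)) next
      for (i in ai) {
        lo <- center[i] - half_window
        j1 <- findInterval(lo - 0.5, p)
        j2 <- findInterval(center[i] + half_window - 0.5, p)
        if (j2 > j1)
          M[i, ] <- tabulate((p[(j1 + 1):j2] - lo) %/% bin_size + 1,
                             nbins = K2)
      }
    }
    M[flip, ] <- M[flip, K2:1, drop = FALSE]
    dens <- M / (bin_size / 1000 * total_mapped / 1e6)
    list(matrix = dens, mean_profile = colMeans(dens))
  } else {
    fpkm <- region_fpkm(reads, anchors, total_mapped)
    M <- matrix(0, nrow(anchors), n_rel_bins)
    for (i in seq_len(nrow(anchors))) {
      len <- anchors$end[i] - anchors$start[i]
      edges <- anchors$start[i] + len * seq(0, n_rel_bins) / n_rel_bins
      p <- reads$pos5[reads$chrom == anchors$chrom[i]]
      p <- p[p >= anchors$start[i] & p < anchors$end[i]]
      if (length(p)) {
        k <- pmin(findInterval(p, edges), n_rel_bins)
        cnt <- tabulate(k, nbins = n_rel_bins)
        bin_len <- len / n_rel_bins
        M[i, ] <- cnt / (bin_len / 1000 * total_mapped / 1e6)
      }
    }
    M[flip, ] <- M[flip, n_rel_bins:1, drop = FALSE]
    list(matrix = M, mean_profile = colMeans(M), region_fpkm = fpkm)
  }
}
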