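#' Count Watson/Crick reads in bins around replication origins
#'
#' Builds the per-origin strand count matrices that the bias statistic is
#' computed from. Bins are indexed left to right in reference orientation,
#' covering `[center - half_window, center + half_window)` in steps of
#' `bin_size`. Origins whose window would cross a chromosome edge are
#' dropped with a warning so all matrices stay rectangular.
#'
#' @param reads a `stranded_reads` object.
#' @param origins data frame with columns `chrom`, `center` (bp midpoint),
#'   unique per (chrom, center).
#' @param chrom_sizes named vector of chromosome lengths.
#' @param half_window window half-width in bp.
#' @param bin_size bin width in bp; must divide `half_window`.
#' @return A `strand_bin_counts` object: integer matrices `W` and `C`
#'   (origins x 2K bins), the retained `origins`, `bin_size`, `half_window`.
#' @export
count_strand_reads <- function(reads, origins, chrom_sizes,
                               half_window = 250000, bin_size = 100) {
  if (nrow(origins) == 0) stop("empty origin set")
  if (anyDuplicated(origins[c("chrom", "center")]))
    stop("duplicate (chrom, center) origins")
  if (half_window %% bin_size != 0)
    stop("bin_size must divide half_window")
  if (!all(origins$chrom %in% names(chrom_sizes)))
    stop("origin chromosome missing from chrom_sizes")
  inb <- origins$center - half_window >= 0 &
    origins$center + half_window <= chrom_sizes[origins$chrom]
  if (any(!inb)) {
    warning(sum(!inb), " origin(s) with windows crossing a chromosome ",
            "edge dropped")
    origins <- origins[inb, , drop = FALSE]
  }
  if (nrow(origins) == 0) stop("no origin window fits inside the genome")
  K2 <- 2L * as.integer(half_window / bin_size)
  W <- matrix(0L, nrow(origins), K2)
  C <- matrix(0L, nrow(origins), K2)
  for (s in c("W", "C")) {
    M <- if (s == "W") W else C
    for (ch in unique(origins$chrom)) {
      oi <- which(origins$chrom == ch)
      p <- sort(reads$pos5[reads$chrom == ch & reads$strand == s])
      if (!length(p)) next
      for (i in oi) {
        lo <- origins$center[i] - half_window
        hi <- origins$center[i] + half_window
        j1 <- findInterval(lo - 0.5, p)
        j2 <- findInterval(hi - 0.5, p)
        if (j2 > j1) {
          k <- (p[(j1 + 1):j2] - lo) %/% bin_size + 1
          M[i, ] <- M[i, ] + tabulate(k, nbins = K2)
        }
      }
    }
    if (s == "W") W <- M else C <- M
  }
  structure(list(W = W, C = C, origins = origins,
                 bin_size = bin_size, half_window = half_window),
            class = "strand_bin_counts")
}

.new_bias_profile <- function(values, bin_size, half_window,
                              normalized = FALSE, smoothed = FALSE,
                              flank_bins = NA_integer_, n_origins = NULL) {
  structure(list(values = values, bin_size = bin_size,
                 half_window = half_window, normalized = normalized,
                 smoothed = smoothed, flank_bins = flank_bins,
                 n_origins = n_origins),
            class = "bias_profile")
}

#' Strand-partition bias per bin
#'
#' `bias = (W - C) / (W + C)` per bin; bins with no coverage (`W + C = 0`)
#' are undefined (`NA`), not zero: an empty bin carries no evidence of
#' strand balance.
#'
#' @param counts a `strand_bin_counts` object.
#' @return A `bias_profile` whose `values` matrix has one row per origin;
#'   defined values lie in \[-1, 1\].
#' @export
bias_profile <- function(counts) {
  tot <- counts$W + counts$C
  v <- (counts$W - counts$C) / ifelse(tot == 0, NA_real_, tot)
  .new_bias_profile(v, counts$bin_size, counts$half_window)
}

#' Pool strand counts across origins
#'
#' Sums the W and C matrices over origins before forming the bias, i.e.
#' bias per meta-bin is `(sum W - sum C) / (sum W + sum C)`. At typical
#' per-origin depth most individual (origin, bin) cells are empty; pooling
#' uses every read and is the aggregation eSPAN tooling applies.
#'
#' @param counts a `strand_bin_counts` object.
#' @return A single-row `bias_profile` with `n_origins` recorded.
#' @export
pooled_bias_profile <- function(counts) {
  W <- matrix(colSums(counts$W), 1)
  C <- matrix(colSums(counts$C), 1)
  p <- bias_profile(structure(list(W = W, C = C, bin_size = counts$bin_size,
                                   half_window = counts$half_window),
                              class = "strand_bin_counts"))
  p$n_origins <- rep(nrow(counts$W), ncol(W))
  p
}

#' Subtract the control (BrdU) bias profile
#'
#' Normalization to the strand-resolved BrdU input: per-bin subtraction of
#' the control bias removes additive technical strand bias while keeping
#' zero interpretable as "no preference". A bin is undefined if it is
#' undefined in either operand. Values after subtraction lie in \[-2, 2\].
#'
#' @param espan,control `bias_profile` objects with matching geometry; the
#'   control may be a single-row (meta) profile, which is then recycled
#'   across rows of `espan`.
#' @return Normalized `bias_profile`.
#' @export
normalize_to_control <- function(espan, control) {
  if (espan$bin_size != control$bin_size ||
      espan$half_window != control$half_window)
    stop("espan and control profiles have mismatched geometry")
  ev <- espan$values; cv <- control$values
  if (ncol(ev) != ncol(cv)) stop("profile widths differ")
  if (nrow(cv) == 1 && nrow(ev) > 1)
    cv <- matrix(cv, nrow(ev), ncol(ev), byrow = TRUE)
  if (nrow(cv) != nrow(ev)) stop("profile row counts differ")
  out <- espan
  out$values <- ev - cv
  out$normalized <- TRUE
  out
}

# moving average over [i - f, i + f] per row, NA-aware, truncated at edges
.moving_mean <- function(v, f) {
  L <- length(v)
  ok <- !is.na(v)
  cs <- cumsum(ifelse(ok, v, 0))
  cn <- cumsum(ok)
  hi <- pmin(seq_len(L) + f, L)
  lo <- pmax(seq_len(L) - f, 1L)
  s <- cs[hi] - c(0, cs)[lo]
  n <- cn[hi] - c(0, cn)[lo]
  ifelse(n == 0, NA_real_, s / n)
}

#' Smooth a bias profile
#'
#' Centered moving average over `[k - flank_bins, k + flank_bins]`,
#' ignoring undefined bins and truncating the window at the profile edges
#' (no padding: edge values are means over the available bins only).
#' Intended for visualization; summary statistics should be computed from
#' the unsmoothed profile.
#'
#' @param profile a `bias_profile`.
#' @param flank_bins number of bins on each side of the window (default
#'   1000, i.e. 100 kb at 100-bp bins).
#' @return Smoothed `bias_profile`.
#' @export
smooth_profile <- function(profile, flank_bins = 1000) {
  stopifnot(flank_bins >= 0)
  out <- profile
  if (flank_bins > 0)
    out$values <- t(apply(profile$values, 1, .moving_mean, f = flank_bins))
  out$smoothed <- TRUE
  out$flank_bins <- as.integer(flank_bins)
  out
}

#' Average bias profiles across origins
#'
#' Per-bin mean over origins, ignoring undefined entries; a meta-bin is
#' undefined only when undefined in every origin. Records the number of
#' contributing origins per bin.
#'
#' @param profiles a multi-row `bias_profile` (one row per origin).
#' @return Single-row meta `bias_profile` with `n_origins` per bin.
#' @export
aggregate_origins <- function(profiles) {
  v <- profiles$values
  if (is.null(dim(v)) || nrow(v) == 0) stop("no origin profiles to aggregate")
  n <- colSums(!is.na(v))
  m <- colMeans(v, na.rm = TRUE)
  m[n == 0] <- NA_real_
  out <- profiles
  out$values <- matrix(m, 1)
  out$n_origins <- n
  out
}

#' Fold a meta profile into a leading-strand bias score
#'
#' Under this package's simulation/interpretation convention (leading-strand
#' nascent reads map to Watson left of an origin and to Crick right of it),
#' the left flank of an origin-centered bias profile is positive and the
#' right flank negative when parental material prefers the leading strand.
#' The score folds the two flanks:
#' `(mean bias left of center - mean bias right of center) / 2`,
#' over defined bins, and recovers `2 * p_lead - 1` for a transfer
#' probability `p_lead`. Positive score = leading-strand preference.
#'
#' @param meta a single-row meta `bias_profile`.
#' @return A `bias_summary` list: `leading_bias_score`, `n_origins_used`,
#'   `n_bins_defined`.
#' @export
leading_bias_score <- function(meta) {
  v <- drop(meta$values)
  K <- length(v) %/% 2
  left <- v[seq_len(K)]
  right <- v[K + seq_len(K)]
  if (all(is.na(left)) || all(is.na(right)))
    stop("a flank of the meta profile is entirely undefined")
  score <- (mean(left, na.rm = TRUE) - mean(right, na.rm = TRUE)) / 2
  structure(list(
    leading_bias_score = score,
    n_origins_used = if (is.null(meta$n_origins)) NA_integer_
                     else max(meta$n_origins),
    n_bins_defined = sum(!is.na(v))
  ), class = "bias_summary")
}

#' Full origin-centered strand-bias pipeline
#'
#' Counts W/C reads around origins for the eSPAN library and the BrdU
#' control, forms bias profiles, subtracts the control, smooths for
#' visualization, and folds the flanks into a leading-strand bias score.
#' With `aggregate = "pooled"` (default) counts are summed across origins
#' per bin before the bias is formed, which uses every read at realistic
#' per-origin depth; `aggregate = "mean"` instead averages per-origin bias
#' profiles via [aggregate_origins()]. The score is computed from the
#' unsmoothed normalized profile; the smoothed track is returned for
#' plotting.
#'
#' @param espan_reads,control_reads `stranded_reads` objects.
#' @param origins origin data frame (`chrom`, `center`).
#' @param chrom_sizes named vector of chromosome lengths.
#' @param half_window,bin_size window geometry (bp).
#' @param flank_bins smoothing half-width in bins.
#' @param aggregate `"pooled"` or `"mean"`.
#' @return List with `profile` (normalized meta `bias_profile`), `smoothed`,
#'   `summary` (a `bias_summary`), and the two `strand_bin_counts`.
#' @export
espan_pipeline <- function(espan_reads, control_reads, origins, chrom_sizes,
                           half_window = 250000, bin_size = 100,
                           flank_bins = 1000,
                           aggregate = c("pooled", "mean")) {
  aggregate <- match.arg(aggregate)
  ce <- count_strand_reads(espan_reads, origins, chrom_sizes,
                           half_window, bin_size)
  cc <- count_strand_reads(control_reads, origins, chrom_sizes,
                           half_window, bin_size)
  if (aggregate == "pooled") {
    pe <- pooled_bias_profile(ce)
    pc <- pooled_bias_profile(cc)
    norm <- normalize_to_control(pe, pc)
  } else {
    norm <- aggregate_origins(
      normalize_to_control(bias_profile(ce), bias_profile(cc)))
  }
  list(profile = norm,
       smoothed = smooth_profile(norm, flank_bins),
       summary = leading_bias_score(norm),
       espan_counts = ce, control_counts = cc)
}

#' Export a meta bias profile as a TSV table
#'
#' @param meta single-row meta `bias_profile`.
#' @param path output path.
#' @return `path`, invisibly. Columns: `bin_offset_bp` (left edge of the bin
#'   relative to the origin center), `bias`, `n_origins`.
#' @export
write_bias_profile <- function(meta, path) {
  v <- drop(meta$values)
  off <- seq(-meta$half_window, meta$half_window - meta$bin_size,
             by = meta$bin_size)
  n <- meta$n_origins
  if (is.null(n)) n <- rep(NA_integer_, length(v))
  utils::write.table(
    data.frame(bin_offset_bp = off, bias = v, n_origins = n),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
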