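# Seeded generators emulating the data each pipeline stage consumes, with
# ground truth attached so parameter recovery is checkable end to end.

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

.rand_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

#' Simulate an annotation catalog, compartments and genes on a toy genome
#'
#' Per track, non-overlapping features of fixed length are placed one per
#' regular slot (random offset within the slot), covering approximately the
#' configured fraction of each chromosome. A/B compartments tile each
#' chromosome alternately with no gaps. Genes are stranded intervals from
#' which TSS/TES derive.
#'
#' @param chrom_sizes named vector of chromosome lengths.
#' @param track_fractions named numeric vector in \[0, 1\]: target covered
#'   fraction per annotation type.
#' @param feature_length feature size in bp per track element.
#' @param compartment_size A/B tile size in bp.
#' @param n_genes_per_chrom,gene_length gene placement parameters.
#' @param seed RNG seed.
#' @return List: `catalog` (an `annotation_catalog`), `compartments`
#'   (A/B-labeled intervals), `genes` (stranded intervals), `chrom_sizes`.
#' @export
simulate_genome_annotation <- function(chrom_sizes,
                                       track_fractions = c(promoter = 0.05,
                                                           exon = 0.1,
                                                           intron = 0.2,
                                                           LINE = 0.1),
                                       feature_length = 1000,
                                       compartment_size = 100000,
                                       n_genes_per_chrom = 20,
                                       gene_length = 10000,
                                       seed = 1) .with_seed(seed, {
  if (any(track_fractions < 0) || any(track_fractions > 1))
    stop("track fractions must lie in [0, 1]")
  place_track <- function(frac) {
    rows <- lapply(names(chrom_sizes), function(ch) {
      len <- chrom_sizes[[ch]]
      n <- floor(frac * len / feature_length)
      if (n == 0) return(NULL)
      slot <- len / n
      off <- floor(stats::runif(n, 0, slot - feature_length + 1))
      start <- floor((seq_len(n) - 1) * slot) + off
      data.frame(chrom = ch, start = start, end = start + feature_length,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    if (is.null(df)) return(genomic_intervals())
    genomic_intervals(chrom = df$chrom, start = df$start, end = df$end)
  }
  tracks <- lapply(track_fractions, place_track)
  comp_rows <- lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    start <- seq(0, len - 1, by = compartment_size)
    data.frame(chrom = ch, start = start,
               end = pmin(start + compartment_size, len),
               name = rep_len(c("A", "B"), length(start)),
               stringsAsFactors = FALSE)
  })
  comp <- do.call(rbind, comp_rows)
  compartments <- genomic_intervals(chrom = comp$chrom, start = comp$start,
                                    end = comp$end, name = comp$name)
  gene_rows <- lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    n <- min(n_genes_per_chrom, floor(len / (2 * gene_length)))
    if (n == 0) return(NULL)
    slot <- len / n
    start <- floor((seq_len(n) - 1) * slot) +
      floor(stats::runif(n, 0, slot - gene_length + 1))
    data.frame(chrom = ch, start = start, end = start + gene_length,
               strand = sample(c("+", "-"), n, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  gd <- do.call(rbind, gene_rows)
  genes <- genomic_intervals(chrom = gd$chrom, start = gd$start,
                             end = gd$end,
                             name = sprintf("gene_%03d", seq_len(nrow(gd))),
                             strand = gd$strand)
  list(catalog = annotation_catalog(tracks, chrom_sizes),
       compartments = compartments, genes = genes,
       chrom_sizes = chrom_sizes)
})

#' Simulate a strand-resolved nascent-chromatin experiment
#'
#' Places origins on a toy genome and draws reads around them: each read
#' picks an origin, a side (left/right with equal probability) and a
#' uniform offset within the half-window. With probability `p_lead` the
#' read is leading-strand type and maps to Watson on the left side / Crick
#' on the right; otherwise the mirror. The BrdU-style control is generated
#' with transfer probability `0.5 + control_bias / 2`; `control_bias` is
#' also added to the eSPAN library (capped at 1) so subtraction of the
#' control cancels it. After control subtraction the folded score expects
#' `2 * p_lead - 1`.
#'
#' @param n_origins,reads_per_origin experiment size (defaults 200 x 500).
#' @param p_lead leading-strand transfer probability in \[0.5, 1\]
#'   (default 0.875).
#' @param control_bias additive technical strand bias planted in both
#'   libraries (default 0).
#' @param half_window read-placement half-window in bp.
#' @param read_length read length for BED6 export.
#' @param seed RNG seed.
#' @param out_dir optional directory; writes `espan.bed`, `control.bed`,
#'   `origins.bed`, `chrom.sizes`.
#' @return List: `espan_reads`, `control_reads` (`stranded_reads`),
#'   `origins`, `chrom_sizes`, `truth` (`p_lead`, `control_bias`,
#'   `expected_score`).
#' @export
simulate_espan_experiment <- function(n_origins = 200,
                                      reads_per_origin = 500,
                                      p_lead = 0.875, control_bias = 0,
                                      half_window = 250000,
                                      read_length = 50,
                                      seed = 1, out_dir = NULL)
  .with_seed(seed, {
  if (p_lead < 0.5 || p_lead > 1)
    stop("p_lead must lie in [0.5, 1]")
  n_chrom <- min(4, n_origins)
  per_chrom <- ceiling(n_origins / n_chrom)
  spacing <- 2 * half_window + 10000
  chrom_len <- per_chrom * spacing + 2 * half_window
  sizes <- chrom_sizes(stats::setNames(rep(chrom_len, n_chrom),
                                       sprintf("chrS%d", seq_len(n_chrom))))
  origins <- data.frame(
    chrom = rep(names(sizes), each = per_chrom)[seq_len(n_origins)],
    center = rep(half_window + spacing * (seq_len(per_chrom) - 1) +
                   spacing %/% 2, n_chrom)[seq_len(n_origins)],
    stringsAsFactors = FALSE)
  draw_reads <- function(p_transfer) {
    n <- n_origins * reads_per_origin
    oi <- rep(seq_len(n_origins), each = reads_per_origin)
    left <- stats::runif(n) < 0.5
    off <- floor(stats::runif(n, 0, half_window))
    pos <- ifelse(left, origins$center[oi] - 1 - off,
                  origins$center[oi] + off)
    leading <- stats::runif(n) < p_transfer
    w <- (left & leading) | (!left & !leading)
    stranded_reads(chrom = origins$chrom[oi], pos5 = pos,
                   strand = ifelse(w, "W", "C"))
  }
  espan <- draw_reads(min(1, p_lead + control_bias / 2))
  control <- draw_reads(0.5 + control_bias / 2)
  out <- list(espan_reads = espan, control_reads = control,
              origins = origins, chrom_sizes = sizes,
              truth = list(p_lead = p_lead, control_bias = control_bias,
                           expected_score = 2 * p_lead - 1))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(r, f) {
      w <- r$strand == "W"
      write_bed(genomic_intervals(
        chrom = r$chrom,
        start = ifelse(w, r$pos5, r$pos5 - read_length + 1),
        end = ifelse(w, r$pos5 + read_length, r$pos5 + 1),
        name = sprintf("read_%d", seq_len(nrow(r))), score = 0,
        strand = ifelse(w, "+", "-")), file.path(out_dir, f))
    }
    wr(espan, "espan.bed"); wr(control, "control.bed")
    write_bed(genomic_intervals(chrom = origins$chrom,
                                start = origins$center,
                                end = origins$center + 1),
              file.path(out_dir, "origins.bed"))
    write_chrom_sizes(sizes, file.path(out_dir, "chrom.sizes"))
  }
  out
})

#' Simulate peak sets with planted categories and annotation preferences
#'
#' One peak per regular 10-kb slot (sets stay disjoint). Every slot carries
#' a promoter-type feature; with the category's annotation probability the
#' peak is placed fully inside it, else in the slot's intergenic space.
#' Replicate FPKMs are lognormal around planted means; up/down peaks carry
#' planted |log2FC| values (>= 1.5 by default).
#'
#' @param n_up,n_stable,n_down peaks per category.
#' @param f_diff,f_stable probability that a differential / stable peak
#'   lies inside the annotation feature (defaults 0.5 / 0.25).
#' @param planted_lfc_range range of planted |log2FC| for up/down peaks.
#' @param noise_sd replicate noise sd on the log2 scale.
#' @param n_reps replicates per condition.
#' @param peak_width,slot_size,anno_width placement geometry in bp.
#' @param base_fpkm baseline WT FPKM scale.
#' @param seed RNG seed.
#' @return List: `peaks` (ids in `name`), `signal` (long per-replicate
#'   FPKM), `catalog` (promoter-only `annotation_catalog`), `truth`
#'   (per-peak planted category, lfc, in-feature flag).
#' @export
simulate_peak_experiment <- function(n_up = 100, n_stable = 300,
                                     n_down = 100, f_diff = 0.5,
                                     f_stable = 0.25,
                                     planted_lfc_range = c(1.5, 3),
                                     noise_sd = 0.15, n_reps = 3,
                                     peak_width = 500, slot_size = 10000,
                                     anno_width = 2000, base_fpkm = 10,
                                     seed = 1) .with_seed(seed, {
  n <- n_up + n_stable + n_down
  category <- sample(rep(c("up", "stable", "down"),
                         c(n_up, n_stable, n_down)))
  sizes <- chrom_sizes(c(chrP1 = n * slot_size + slot_size))
  slot0 <- (seq_len(n) - 1) * slot_size
  anno <- genomic_intervals(chrom = "chrP1", start = slot0,
                            end = slot0 + anno_width)
  f <- ifelse(category == "stable", f_stable, f_diff)
  inside <- stats::runif(n) < f
  start <- ifelse(inside,
                  slot0 + floor(stats::runif(n, 0,
                                             anno_width - peak_width + 1)),
                  slot0 + anno_width + 1000 +
                    floor(stats::runif(n, 0, slot_size - anno_width -
                                            2000 - peak_width)))
  ids <- sprintf("peak_%04d", seq_len(n))
  peaks <- genomic_intervals(chrom = "chrP1", start = start,
                             end = start + peak_width, name = ids)
  lfc <- numeric(n)
  ndiff <- sum(category != "stable")
  lfc[category == "up"] <- stats::runif(n_up, planted_lfc_range[1],
                                        planted_lfc_range[2])
  lfc[category == "down"] <- -stats::runif(n_down, planted_lfc_range[1],
                                           planted_lfc_range[2])
  wt_mean <- base_fpkm * 2^stats::rnorm(n, 0, 0.5)
  mut_mean <- wt_mean * 2^lfc
  signal <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(
      peak_id = ids[i],
      condition = rep(c("wt", "mutant"), each = n_reps),
      replicate = rep(seq_len(n_reps), 2),
      fpkm = c(wt_mean[i] * 2^stats::rnorm(n_reps, 0, noise_sd),
               mut_mean[i] * 2^stats::rnorm(n_reps, 0, noise_sd)),
      stringsAsFactors = FALSE)
  }))
  list(peaks = peaks, signal = signal,
       catalog = annotation_catalog(list(promoter = anno), sizes),
       truth = data.frame(peak_id = ids, category = category,
                          planted_lfc = lfc, in_feature = inside,
                          stringsAsFactors = FALSE))
})

#' Simulate binned multi-mark signal with planted ratio correlations
#'
#' Per-bin log2 change ratios are drawn from a multivariate normal with the
#' planted correlation matrix (scaled by `sd_log2`); WT FPKM varies
#' lognormally around `base_fpkm` and mutant FPKM is reconstructed as
#' `wt * 2^ratio`.
#'
#' @param n_bins number of genome bins (default 2000).
#' @param cor_matrix planted correlation matrix (positive semi-definite,
#'   unit diagonal); dimnames name the marks.
#' @param sd_log2 sd of the per-bin log2 ratios.
#' @param base_fpkm,base_sd_log2 WT signal level and spread.
#' @param seed RNG seed.
#' @return List: `marks` (named list of data frames `wt`, `mutant`),
#'   `log2_ratio` matrix, `truth` (the planted correlation matrix).
#' @export
simulate_binned_marks <- function(n_bins = 2000,
                                  cor_matrix = diag(2),
                                  sd_log2 = 1, base_fpkm = 10,
                                  base_sd_log2 = 0.5,
                                  seed = 1) .with_seed(seed, {
  k <- nrow(cor_matrix)
  stopifnot(ncol(cor_matrix) == k, all(abs(diag(cor_matrix) - 1) < 1e-12))
  ev <- eigen(cor_matrix, symmetric = TRUE)
  if (min(ev$values) < -1e-8)
    stop("planted correlation matrix is not positive semi-definite")
  fac <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), k)
  z <- matrix(stats::rnorm(n_bins * k), n_bins, k) %*% t(fac)
  ratio <- z * sd_log2
  marks <- if (!is.null(dimnames(cor_matrix)[[1]]))
    dimnames(cor_matrix)[[1]] else sprintf("mark%d", seq_len(k))
  colnames(ratio) <- marks
  out <- stats::setNames(lapply(seq_len(k), function(j) {
    wt <- base_fpkm * 2^stats::rnorm(n_bins, 0, base_sd_log2)
    data.frame(bin = seq_len(n_bins), wt = wt,
               mutant = wt * 2^ratio[, j])
  }), marks)
  list(marks = out, log2_ratio = ratio, truth = cor_matrix)
})

#' Simulate lineage-barcode triples with planted clones
#'
#' Plants clones of the given sizes (or geometric sizes truncated at 1);
#' founder barcodes are drawn with pairwise hamming distance at least
#' `2 * max_hamming + 2` so distinct clones cannot merge under collapse.
#' Each cell emits `umis_per_cell` triples of `reads_per_umi` reads; each
#' emitted barcode copy is mutated at one uniformly chosen position with
#' probability `sub_rate` (at most one substitution per copy).
#'
#' @param clone_sizes integer vector of planted clone sizes; when `NULL`,
#'   `n_clones` sizes are drawn as `1 + rgeom(1/mean_size)`.
#' @param n_clones,mean_size geometric size model used when `clone_sizes`
#'   is `NULL`.
#' @param barcode_length lineage barcode length (>= 12 recommended; shorter
#'   lengths trigger a collision warning).
#' @param umis_per_cell,reads_per_umi per-cell sequencing depth
#'   (defaults 3 x 10, the minimum passing the calling thresholds).
#' @param sub_rate per-copy substitution probability.
#' @param max_hamming collapse radius the founders are separated against.
#' @param seed RNG seed.
#' @param out_dir optional directory; writes `triples.tsv`.
#' @return List: `triples`, `truth` (per cell: `cell_barcode`, `clone_id`,
#'   `clone_size`), `founders`.
#' @export
simulate_barcode_data <- function(clone_sizes = NULL, n_clones = 20,
                                  mean_size = 5, barcode_length = 20,
                                  umis_per_cell = 3, reads_per_umi = 10,
                                  sub_rate = 0.1, max_hamming = 3,
                                  seed = 1, out_dir = NULL)
  .with_seed(seed, {
  if (is.null(clone_sizes))
    clone_sizes <- 1 + stats::rgeom(n_clones, 1 / mean_size)
  if (barcode_length < 12)
    warning("barcode_length < 12: barcode collisions become likely")
  min_sep <- 2 * max_hamming + 2
  founders <- character(0)
  tries <- 0
  while (length(founders) < length(clone_sizes)) {
    cand <- .rand_dna(1, barcode_length)
    tries <- tries + 1
    if (tries > 1000 * length(clone_sizes))
      stop("cannot place founder barcodes this far apart; increase length")
    if (!length(founders) ||
        all(vapply(founders, .hamming, 0, b = cand) >= min_sep))
      founders <- c(founders, cand)
  }
  n_cells <- sum(clone_sizes)
  cell_ids <- sprintf("cell_%05d", seq_len(n_cells))
  clone_of <- rep(seq_along(clone_sizes), clone_sizes)
  rows <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    bc <- founders[clone_of[i]]
    copies <- vapply(seq_len(umis_per_cell), function(u) {
      if (stats::runif(1) < sub_rate) {
        pos <- sample.int(barcode_length, 1)
        ch <- substr(bc, pos, pos)
        sub <- sample(setdiff(c("A", "C", "G", "T"), ch), 1)
        paste0(substr(bc, 1, pos - 1), sub,
               substr(bc, pos + 1, barcode_length))
      } else bc
    }, character(1))
    rows[[i]] <- data.frame(
      cell_barcode = cell_ids[i],
      umi = sprintf("umi_%02d", seq_len(umis_per_cell)),
      lineage_barcode = copies,
      read_count = reads_per_umi,
      stringsAsFactors = FALSE)
  }
  trip <- triples(do.call(rbind, rows))
  truth <- data.frame(cell_barcode = cell_ids,
                      clone_id = founders[clone_of],
                      clone_size = clone_sizes[clone_of],
                      stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(trip, file.path(out_dir, "triples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(triples = trip, truth = truth, founders = founders)
})
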