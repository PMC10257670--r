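#' Classify peaks as up/stable/down between two conditions
#'
#' Simplified differential classifier operating on per-replicate FPKM with
#' the thresholds used downstream: a peak is `up` when
#' `log2fc > lfc_threshold` and `p < p_threshold`, `down` when
#' `log2fc < -lfc_threshold` and `p < p_threshold`, else `stable`.
#' `log2fc = log2((mean mutant FPKM + eps) / (mean WT FPKM + eps))`; the
#' pseudocount `eps` stabilizes the ratio at low signal. The p-value comes
#' from a two-sided two-sample t-test on `log2(FPKM + eps)` across
#' replicates when each condition has at least two; with a single replicate
#' per side `p = 1` (no within-condition variance to test against). When
#' both groups are exactly constant the t statistic is undefined; the
#' classifier then reports `p = 0` if the means differ and `p = 1` if not,
#' so noiseless planted differences are still recovered.
#'
#' @param peaks interval data frame with a `name` column of peak ids.
#' @param signal long data frame: `peak_id`, `condition` (`"wt"`/`"mutant"`),
#'   `replicate`, `fpkm` (>= 0), at least one replicate per condition per
#'   peak.
#' @param lfc_threshold,p_threshold category cutoffs.
#' @param eps pseudocount in FPKM units.
#' @return `peaks` with added columns `log2fc`, `p_value`, `category`.
#' @export
classify_peaks <- function(peaks, signal, lfc_threshold = 1.0,
                           p_threshold = 0.01, eps = 0.1) {
  stopifnot(all(c("peak_id", "condition", "fpkm") %in% names(signal)),
            all(signal$fpkm >= 0), eps >= 0)
  ids <- peaks$name
  if (any(is.na(ids))) stop("peaks need ids in the name column")
  miss <- setdiff(ids, unique(signal$peak_id))
  if (length(miss))
    stop("no signal entries for peak(s): ", paste(utils::head(miss, 5),
                                                  collapse = ", "))
  res <- lapply(ids, function(id) {
    s <- signal[signal$peak_id == id, ]
    mu_fpkm <- s$fpkm[s$condition == "mutant"]
    wt_fpkm <- s$fpkm[s$condition == "wt"]
    if (!length(mu_fpkm) || !length(wt_fpkm))
      stop("peak ", id, " lacks a condition's signal entries")
    lfc <- log2((mean(mu_fpkm) + eps) / (mean(wt_fpkm) + eps))
    mu <- log2(mu_fpkm + eps)
    wt <- log2(wt_fpkm + eps)
    p <- if (length(mu) >= 2 && length(wt) >= 2) {
      if (stats::sd(mu) == 0 && stats::sd(wt) == 0) {
        if (mean(mu) == mean(wt)) 1 else 0
      } else {
        stats::t.test(mu, wt)$p.value
      }
    } else 1
    c(lfc = lfc, p = p)
  })
  res <- do.call(rbind, res)
  out <- as.data.frame(peaks)
  out$log2fc <- res[, "lfc"]
  out$p_value <- res[, "p"]
  out$category <- ifelse(
    out$log2fc > lfc_threshold & out$p_value < p_threshold, "up",
    ifelse(out$log2fc < -lfc_threshold & out$p_value < p_threshold,
           "down", "stable"))
  out
}

#' Build an annotation catalog
#'
#' Named list of merged interval tracks (promoter, UTRs, exon, intron, TTS,
#' repeats, CpG islands, ...) plus chromosome sizes and the priority order
#' used for point annotation.
#'
#' @param tracks named list of interval data frames.
#' @param chrom_sizes named vector of chromosome lengths (supplies the
#'   whole-genome length for expected overlaps).
#' @param priority character vector ordering the track names for midpoint
#'   annotation (default: promoter > 5'UTR > 3'UTR > exon > intron > TTS >
#'   CpG island > LINE > SINE > LTR > simple repeat > satellite, restricted
#'   to names present).
#' @return An `annotation_catalog` list.
#' @export
annotation_catalog <- function(tracks, chrom_sizes, priority = NULL) {
  stopifnot(is.list(tracks), !is.null(names(tracks)))
  tracks <- lapply(tracks, merge_intervals)
  default <- c("promoter", "5UTR", "3UTR", "exon", "intron", "TTS",
               "CpG_island", "LINE", "SINE", "LTR", "simple_repeat",
               "satellite", "enhancer", "intergenic")
  if (is.null(priority))
    priority <- c(intersect(default, names(tracks)),
                  setdiff(names(tracks), default))
  if (!all(names(tracks) %in% priority))
    stop("priority order must cover every track name")
  structure(list(tracks = tracks, chrom_sizes = chrom_sizes,
                 priority = priority), class = "annotation_catalog")
}

#' Annotate peaks by midpoint
#'
#' Each peak receives the highest-priority annotation type whose track
#' contains the peak midpoint (`floor((start + end) / 2)`); peaks hitting no
#' track are `intergenic`.
#'
#' @param peaks interval data frame.
#' @param catalog an `annotation_catalog`.
#' @return Character vector of annotation types, one per peak.
#' @export
annotate_peaks <- function(peaks, catalog) {
  validate_intervals(peaks)
  if (nrow(peaks) == 0) return(character())
  mid <- floor((peaks$start + peaks$end) / 2)
  pts <- genomic_intervals(chrom = peaks$chrom, start = mid, end = mid + 1)
  gp <- .as_granges(pts)
  out <- rep("intergenic", nrow(peaks))
  unhit <- rep(TRUE, nrow(peaks))
  for (ty in catalog$priority) {
    tr <- catalog$tracks[[ty]]
    if (is.null(tr) || nrow(tr) == 0) next
    hit <- IRanges::overlapsAny(gp, .as_granges(tr), ignore.strand = TRUE)
    take <- hit & unhit
    out[take] <- ty
    unhit <- unhit & !hit
  }
  out
}

#' Annotation-type enrichment of differential vs stable peaks
#'
#' For each annotation type, compares how much of the differential peak set
#' overlaps the type against how much of the stable set does, each relative
#' to what uniform genome placement would give:
#' `ratio = log2((obs_d / exp_d) / (obs_s / exp_s))` with
#' `exp = (L_anno / L_g) * L_set`, where `obs` is the merged overlap length
#' of the peak set with the annotation track, `L_anno` the track length,
#' `L_g` the whole-genome length and `L_set` the merged peak-set length.
#' The `L_anno / L_g` factor cancels in the ratio, which therefore equals
#' `log2((obs_d / L_d) / (obs_s / L_s))`. The ratio is undefined (flagged,
#' `NA`) when either observed overlap is zero; no pseudocount is used.
#'
#' @param diff_peaks,stable_peaks non-empty interval data frames.
#' @param catalog an `annotation_catalog`.
#' @return Data frame with one row per annotation type: `type`, `obs_d`,
#'   `exp_d`, `obs_s`, `exp_s`, `L_d`, `L_s`, `L_anno`, `ratio`, `defined`.
#' @export
enrichment_ratio <- function(diff_peaks, stable_peaks, catalog) {
  if (nrow(diff_peaks) == 0 || nrow(stable_peaks) == 0)
    stop("differential and stable peak sets must be non-empty")
  Lg <- sum(catalog$chrom_sizes)
  if (Lg <= 0) stop("whole-genome length must be > 0")
  d <- merge_intervals(diff_peaks)
  s <- merge_intervals(stable_peaks)
  Ld <- total_length(d)
  Ls <- total_length(s)
  rows <- lapply(names(catalog$tracks), function(ty) {
    tr <- catalog$tracks[[ty]]
    La <- total_length(tr)
    od <- overlap_length(d, tr)
    os <- overlap_length(s, tr)
    ed <- La / Lg * Ld
    es <- La / Lg * Ls
    defined <- od > 0 && os > 0 && La > 0
    data.frame(type = ty, obs_d = od, exp_d = ed, obs_s = os, exp_s = es,
               L_d = Ld, L_s = Ls, L_anno = La,
               ratio = if (defined) log2((od / ed) / (os / es)) else NA_real_,
               defined = defined, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assign peaks to A/B compartments and tabulate proportions
#'
#' Each peak is assigned the compartment label (A = open, B = closed) with
#' the larger bp overlap; zero overlap or an exact tie leaves the peak
#' `unassigned`. When `peaks` carries a `category` column the proportions
#' are tabulated per category and sum to 1 within each.
#'
#' @param peaks interval data frame, optionally with a `category` column.
#' @param compartments interval data frame with labels `"A"`/`"B"` in the
#'   `name` column.
#' @return List with `assignment` (per-peak label) and `proportions`
#'   (category x \{A, B, unassigned\} data frame).
#' @export
compartment_proportions <- function(peaks, compartments) {
  validate_intervals(peaks); validate_intervals(compartments)
  if (!all(compartments$name %in% c("A", "B")))
    stop("compartment labels must be 'A' or 'B'")
  gp <- .as_granges(peaks)
  ovl_bp <- function(lab) {
    tr <- merge_intervals(compartments[compartments$name == lab, ])
    if (nrow(tr) == 0) return(numeric(nrow(peaks)))
    gt <- .as_granges(tr)
    hits <- GenomicRanges::findOverlaps(gp, gt, ignore.strand = TRUE)
    w <- GenomicRanges::width(IRanges::pintersect(
      gp[S4Vectors::queryHits(hits)], gt[S4Vectors::subjectHits(hits)]))
    out <- numeric(nrow(peaks))
    agg <- tapply(w, S4Vectors::queryHits(hits), sum)
    out[as.integer(names(agg))] <- agg
    out
  }
  a <- ovl_bp("A"); b <- ovl_bp("B")
  lab <- ifelse(a > b, "A", ifelse(b > a, "B", "unassigned"))
  lab[a == 0 & b == 0] <- "unassigned"
  cat <- if ("category" %in% names(peaks)) peaks$category else
    rep("all", nrow(peaks))
  tab <- table(factor(cat), factor(lab, levels = c("A", "B", "unassigned")))
  prop <- as.data.frame.matrix(sweep(tab, 1, rowSums(tab), "/"))
  prop$category <- rownames(prop)
  rownames(prop) <- NULL
  list(assignment = lab, proportions = prop[c("category", "A", "B",
                                              "unassigned")])
}

#' Classify enhancer candidates from histone-mark peak sets
#'
#' Enhancer candidates are H3K4me1 peaks. A candidate overlapping any
#' H3K4me3 peak is not an enhancer (promoter-like); otherwise, if its
#' midpoint lies within `exclusion_bp` of any TSS it is excluded as
#' promoter-proximal. Remaining candidates are `active` when they overlap
#' an H3K27ac peak; of the rest (poised), those overlapping H3K27me3 are
#' `repressed`, the others `poised`.
#'
#' @param k4me1_peaks,k4me3_peaks,k27ac_peaks,k27me3_peaks interval data
#'   frames of peaks per mark.
#' @param tss data frame of TSS points: columns `chrom`, `pos` (0-based), or
#'   a gene interval set with `strand` from which TSS are taken
#'   (start for `+`, `end - 1` for `-`).
#' @param exclusion_bp TSS exclusion radius in bp (default 2500).
#' @return Character vector over `k4me1_peaks`: `not_enhancer`,
#'   `excluded_near_TSS`, `active`, `poised`, or `repressed`.
#' @export
classify_enhancers <- function(k4me1_peaks, k4me3_peaks, k27ac_peaks,
                               k27me3_peaks, tss, exclusion_bp = 2500) {
  if (nrow(k4me1_peaks) == 0) return(character())
  if (!"pos" %in% names(tss)) tss <- tss_points(tss)
  g1 <- .as_granges(k4me1_peaks)
  ovl <- function(pk) {
    if (nrow(pk) == 0) return(rep(FALSE, nrow(k4me1_peaks)))
    IRanges::overlapsAny(g1, .as_granges(pk), ignore.strand = TRUE)
  }
  mid <- floor((k4me1_peaks$start + k4me1_peaks$end) / 2)
  near_tss <- vapply(seq_len(nrow(k4me1_peaks)), function(i) {
    p <- tss$pos[tss$chrom == k4me1_peaks$chrom[i]]
    length(p) > 0 && min(abs(p - mid[i])) <= exclusion_bp
  }, logical(1))
  ifelse(ovl(k4me3_peaks), "not_enhancer",
    ifelse(near_tss, "excluded_near_TSS",
      ifelse(ovl(k27ac_peaks), "active",
        ifelse(ovl(k27me3_peaks), "repressed", "poised"))))
}

#' Transcription start sites of a stranded gene set
#'
#' @param genes interval data frame with `strand` in \{+, -\}.
#' @return Data frame of TSS points (`chrom`, `pos`, 0-based).
#' @export
tss_points <- function(genes) {
  validate_intervals(genes)
  if (any(genes$strand == "."))
    stop("genes need +/- strands to define TSS")
  data.frame(chrom = genes$chrom,
             pos = ifelse(genes$strand == "+", genes$start, genes$end - 1),
             stringsAsFactors = FALSE)
}
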