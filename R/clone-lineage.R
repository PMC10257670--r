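#' Load (cell barcode, UMI, lineage barcode) triples
#'
#' Reads the tab-separated triple table emitted by barcode extraction.
#' Duplicate (cell, UMI, lineage) rows have their read counts summed. All
#' lineage barcodes must share one length.
#'
#' @param path TSV with header columns `cell_barcode`, `umi`,
#'   `lineage_barcode`, `read_count`.
#' @return Data frame of unique triples with summed `read_count`.
#' @export
load_triples <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  req <- c("cell_barcode", "umi", "lineage_barcode", "read_count")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("triple table missing column(s): ", paste(miss, collapse = ", "))
  tab$read_count <- as.numeric(tab$read_count)
  if (nrow(tab) && any(is.na(tab$read_count) | tab$read_count < 1))
    stop("read_count must be a positive integer")
  triples(tab)
}

#' Construct/validate a triple table
#'
#' @param x data frame with columns `cell_barcode`, `umi`,
#'   `lineage_barcode`, `read_count`; duplicates are aggregated by summing
#'   reads.
#' @return Aggregated, validated data frame.
#' @export
triples <- function(x) {
  if (nrow(x) == 0) {
    out <- data.frame(cell_barcode = character(), umi = character(),
                      lineage_barcode = character(), read_count = numeric(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  if (length(unique(nchar(x$lineage_barcode))) != 1)
    stop("lineage barcodes must all have the same length")
  key <- paste(x$cell_barcode, x$umi, x$lineage_barcode, sep = "\r")
  agg <- rowsum(x$read_count, key)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  data.frame(
    cell_barcode = vapply(parts, `[`, "", 1),
    umi = vapply(parts, `[`, "", 2),
    lineage_barcode = vapply(parts, `[`, "", 3),
    read_count = as.numeric(agg[, 1]),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter triples by read support
#'
#' Keeps triples supported by at least `min_reads` reads (default 10, the
#' read-support threshold applied before barcode collapsing).
#'
#' @param x triple data frame.
#' @param min_reads minimum read count (>= 1).
#' @return Filtered triple data frame.
#' @export
filter_triples <- function(x, min_reads = 10) {
  stopifnot(min_reads >= 1)
  x[x$read_count >= min_reads, , drop = FALSE]
}

.hamming <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Collapse lineage barcodes by hamming distance
#'
#' Greedy abundance-ranked clustering: unique barcodes are sorted by total
#' read support (descending, lexicographic on ties) and scanned in order;
#' each barcode joins the earliest-created representative within
#' `max_hamming` mismatches, else becomes a representative itself. The
#' procedure is deterministic and idempotent (representatives map to
#' themselves).
#'
#' @param x triple data frame (equal-length barcodes).
#' @param max_hamming maximum mismatches for merging (default 3).
#' @return Data frame `barcode` -> `representative`.
#' @export
collapse_lineage_barcodes <- function(x, max_hamming = 3) {
  if (nrow(x) == 0)
    return(data.frame(barcode = character(), representative = character(),
                      stringsAsFactors = FALSE))
  if (length(unique(nchar(x$lineage_barcode))) != 1)
    stop("lineage barcodes must all have the same length")
  support <- rowsum(x$read_count, x$lineage_barcode)
  bc <- rownames(support)
  ord <- order(-support[, 1], bc)
  bc <- bc[ord]
  # barcodes as an integer matrix for vectorized hamming scans
  m <- matrix(unlist(lapply(bc, utf8ToInt)), nrow = length(bc), byrow = TRUE)
  reps_idx <- integer(0)
  assign <- integer(length(bc))
  for (i in seq_along(bc)) {
    hit <- 0L
    if (length(reps_idx)) {
      d <- rowSums(m[reps_idx, , drop = FALSE] !=
                     matrix(m[i, ], length(reps_idx), ncol(m), byrow = TRUE))
      w <- which(d <= max_hamming)
      if (length(w)) hit <- reps_idx[w[1]]
    }
    if (hit == 0L) {
      reps_idx <- c(reps_idx, i)
      assign[i] <- i
    } else {
      assign[i] <- hit
    }
  }
  data.frame(barcode = bc, representative = bc[assign],
             stringsAsFactors = FALSE)
}

#' Apply a collapse map to a triple table
#'
#' @param x triple data frame.
#' @param map collapse map from [collapse_lineage_barcodes()].
#' @return Triple data frame with barcodes replaced by representatives and
#'   duplicates re-aggregated.
#' @export
apply_collapse <- function(x, map) {
  if (nrow(x) == 0) return(x)
  idx <- match(x$lineage_barcode, map$barcode)
  if (any(is.na(idx))) stop("collapse map does not cover all barcodes")
  x$lineage_barcode <- map$representative[idx]
  triples(x)
}

#' Assign cells to lineages by UMI support
#'
#' Per (cell, lineage), support is the number of distinct UMIs. A cell is
#' assigned to its maximal-support lineage when that support reaches
#' `min_umis` (default 3); an exact tie between top lineages leaves the
#' cell unassigned (doublet guard).
#'
#' @param x collapsed triple data frame.
#' @param min_umis minimum distinct-UMI support (default 3).
#' @return Data frame per cell: `cell_barcode`, `lineage` (`NA` when
#'   unassigned), `n_umis`.
#' @export
assign_cells <- function(x, min_umis = 3) {
  if (nrow(x) == 0)
    return(data.frame(cell_barcode = character(), lineage = character(),
                      n_umis = integer(), stringsAsFactors = FALSE))
  key <- paste(x$cell_barcode, x$lineage_barcode, sep = "\r")
  umis <- tapply(x$umi, key, function(u) length(unique(u)))
  parts <- strsplit(names(umis), "\r", fixed = TRUE)
  per <- data.frame(
    cell_barcode = vapply(parts, `[`, "", 1),
    lineage = vapply(parts, `[`, "", 2),
    n_umis = as.integer(umis),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- lapply(split(per, per$cell_barcode), function(d) {
    top <- max(d$n_umis)
    winners <- d$lineage[d$n_umis == top]
    if (top < min_umis || length(winners) > 1)
      data.frame(cell_barcode = d$cell_barcode[1], lineage = NA_character_,
                 n_umis = top, stringsAsFactors = FALSE)
    else
      data.frame(cell_barcode = d$cell_barcode[1], lineage = winners,
                 n_umis = top, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Clone table and size-group percentages
#'
#' A clone is a lineage shared by at least 2 assigned cells. Clones fall
#' into size groups 2-10, 11-20 and >20; clones of more than 20 cells are
#' flagged dominant. Per sample (all cells pooled when `sample_labels` is
#' `NULL`), the percentage of clone-member cells in each size group is
#' reported; the three percentages sum to 100.
#'
#' @param assignments output of [assign_cells()].
#' @param sample_labels optional data frame `cell_barcode`, `sample`.
#' @return List with `clones` (`lineage`, `size`, `size_group`, `dominant`,
#'   `cells`) and `group_summary` (per sample percentage of clone cells per
#'   size group).
#' @export
clone_statistics <- function(assignments, sample_labels = NULL) {
  a <- assignments[!is.na(assignments$lineage), , drop = FALSE]
  sizes <- table(a$lineage)
  sizes <- sizes[sizes >= 2]
  grp <- function(n) ifelse(n > 20, ">20", ifelse(n > 10, "11-20", "2-10"))
  clones <- if (length(sizes) == 0) {
    data.frame(lineage = character(), size = integer(),
               size_group = character(), dominant = logical(),
               stringsAsFactors = FALSE)
  } else {
    data.frame(lineage = names(sizes), size = as.integer(sizes),
               size_group = grp(as.integer(sizes)),
               dominant = as.integer(sizes) > 20,
               stringsAsFactors = FALSE, row.names = NULL)
  }
  clones$cells <- lapply(clones$lineage, function(l)
    a$cell_barcode[a$lineage == l])
  members <- a[a$lineage %in% clones$lineage, , drop = FALSE]
  members$size_group <- clones$size_group[match(members$lineage,
                                                clones$lineage)]
  members$sample <- if (is.null(sample_labels))
    rep("all", nrow(members)) else
    sample_labels$sample[match(members$cell_barcode,
                               sample_labels$cell_barcode)]
  groups <- c("2-10", "11-20", ">20")
  summ <- if (nrow(members) == 0) {
    data.frame(sample = character(), size_group = character(),
               percent = numeric(), stringsAsFactors = FALSE)
  } else {
    tab <- table(members$sample, factor(members$size_group, levels = groups))
    pct <- sweep(tab, 1, rowSums(tab), "/") * 100
    df <- as.data.frame(pct, stringsAsFactors = FALSE)
    names(df) <- c("sample", "size_group", "percent")
    df
  }
  list(clones = clones, group_summary = summ)
}

#' Cluster distribution of dominant clones
#'
#' Cross-tabulates each dominant clone's member cells over cell clusters;
#' fractions sum to 1 per clone.
#'
#' @param assignments output of [assign_cells()].
#' @param cluster_labels data frame `cell_barcode`, `cluster`.
#' @return Data frame: `lineage`, `cluster`, `n_cells`, `fraction`.
#' @export
dominant_clone_cluster_density <- function(assignments, cluster_labels) {
  st <- clone_statistics(assignments)
  dom <- st$clones[st$clones$dominant, , drop = FALSE]
  if (nrow(dom) == 0)
    return(data.frame(lineage = character(), cluster = character(),
                      n_cells = integer(), fraction = numeric(),
                      stringsAsFactors = FALSE))
  a <- assignments[!is.na(assignments$lineage) &
                     assignments$lineage %in% dom$lineage, , drop = FALSE]
  cl <- cluster_labels$cluster[match(a$cell_barcode,
                                     cluster_labels$cell_barcode)]
  if (any(is.na(cl)))
    stop("missing cluster labels for cell(s): ",
         paste(utils::head(a$cell_barcode[is.na(cl)], 5), collapse = ", "))
  tab <- as.data.frame(table(lineage = a$lineage, cluster = as.character(cl)),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "n_cells"
  tab <- tab[tab$n_cells > 0, , drop = FALSE]
  tot <- tapply(tab$n_cells, tab$lineage, sum)
  tab$fraction <- as.numeric(tab$n_cells / tot[tab$lineage])
  rownames(tab) <- NULL
  tab
}

#' End-to-end clone calling
#'
#' Filters triples by read support, collapses lineage barcodes within a
#' hamming radius, assigns cells by distinct-UMI support, and tabulates
#' clones (defaults: >= 10 reads, hamming <= 3, >= 3 UMIs).
#'
#' @param x triple data frame.
#' @param min_reads,max_hamming,min_umis thresholds.
#' @param sample_labels optional per-cell sample labels.
#' @return List: `assignments`, `clones`, `group_summary`, `collapse_map`.
#' @export
call_clones <- function(x, min_reads = 10, max_hamming = 3, min_umis = 3,
                        sample_labels = NULL) {
  f <- filter_triples(x, min_reads)
  map <- collapse_lineage_barcodes(f, max_hamming)
  asn <- assign_cells(apply_collapse(f, map), min_umis)
  st <- clone_statistics(asn, sample_labels)
  list(assignments = asn, clones = st$clones,
       group_summary = st$group_summary, collapse_map = map)
}
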