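#' Construct a set of genomic intervals
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end`,
#' `name`, `score`, `strand`, using 0-based half-open coordinates (BED
#' convention) throughout the package. `name`/`score` may be `NA`; `strand`
#' is one of `"+"`, `"-"`, `"."`.
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start,end integer-valued positions, `0 <= start < end`.
#' @param name optional labels (`NA` allowed).
#' @param score optional numeric scores (`NA` allowed).
#' @param strand strand codes, recycled; one of `"+"`, `"-"`, `"."`.
#' @return A `data.frame` of class `genomic_intervals`.
#' @export
genomic_intervals <- function(chrom = character(), start = integer(),
                              end = integer(), name = NA_character_,
                              score = NA_real_, strand = ".") {
  n <- max(length(chrom), length(start))
  x <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = as.numeric(start),
    end = as.numeric(end),
    name = rep_len(as.character(name), n),
    score = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(x)
  class(x) <- c("genomic_intervals", "data.frame")
  x
}

#' Validate interval invariants
#'
#' Checks `0 <= start < end`, strand codes, and non-empty chromosome names.
#'
#' @param x interval data frame.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_intervals <- function(x) {
  stopifnot(is.data.frame(x))
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(x)))
    stop("intervals need columns: ", paste(req, collapse = ", "))
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom)))
    stop("chromosome names must be non-empty")
  if (any(x$start < 0)) stop("start positions must be >= 0")
  if (any(x$start >= x$end)) stop("intervals must satisfy start < end")
  if (!is.null(x$strand) && !all(x$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  invisible(x)
}

# GRanges bridge: BED half-open [start, end) -> 1-based closed [start+1, end]
.as_granges <- function(x) {
  if (nrow(x) == 0) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end),
    strand = if (is.null(x$strand)) "*" else chartr(".", "*", x$strand)
  )
}

.from_granges <- function(gr) {
  genomic_intervals(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr)
  )
}

#' Read a BED file
#'
#' Reads BED3/BED6 (tab-separated, 0-based half-open). Strand is taken from
#' column 6 when present, `"."` otherwise; `name`/`score` from columns 4-5.
#'
#' @param path file path.
#' @param n_columns_expected optionally require every data line to have
#'   exactly this many columns.
#' @return A `genomic_intervals` data frame.
#' @export
read_bed <- function(path, n_columns_expected = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) return(genomic_intervals())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  bad <- which(ncols < 3 |
                 (if (is.null(n_columns_expected)) FALSE
                  else ncols != n_columns_expected))
  if (length(bad))
    stop("BED parse error at line ", lineno[bad[1]],
         ": expected at least 3 tab-separated columns")
  getcol <- function(i) vapply(fields, function(f)
    if (length(f) >= i) f[i] else NA_character_, character(1))
  start <- suppressWarnings(as.numeric(getcol(2)))
  end <- suppressWarnings(as.numeric(getcol(3)))
  bad <- which(is.na(start) | is.na(end) |
                 start != floor(start) | end != floor(end))
  if (length(bad))
    stop("BED parse error at line ", lineno[bad[1]],
         ": non-integer coordinates")
  bad <- which(start < 0 | start >= end)
  if (length(bad))
    stop("BED parse error at line ", lineno[bad[1]],
         ": requires 0 <= start < end")
  name <- getcol(4)
  score <- suppressWarnings(as.numeric(getcol(5)))
  strand <- getcol(6)
  strand[is.na(strand)] <- "."
  bad <- which(!strand %in% c("+", "-", "."))
  if (length(bad))
    stop("BED parse error at line ", lineno[bad[1]], ": bad strand field")
  genomic_intervals(chrom = getcol(1), start = start, end = end,
                    name = name, score = score, strand = strand)
}

#' Write intervals as BED
#'
#' Writes BED3 when no name/score/strand information is present, BED6
#' otherwise (`NA` name as `"."`, `NA` score as 0). `read_bed()` on the
#' output reproduces fully specified records field-for-field.
#'
#' @param intervals a `genomic_intervals` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  validate_intervals(intervals)
  x <- intervals
  bed6 <- nrow(x) > 0 &&
    (any(!is.na(x$name)) || any(!is.na(x$score)) || any(x$strand != "."))
  lines <- if (nrow(x) == 0) {
    character()
  } else if (bed6) {
    sprintf("%s\t%d\t%d\t%s\t%s\t%s", x$chrom, as.integer(x$start),
            as.integer(x$end), ifelse(is.na(x$name), ".", x$name),
            ifelse(is.na(x$score), "0", format(x$score, trim = TRUE,
                                               scientific = FALSE)),
            x$strand)
  } else {
    sprintf("%s\t%d\t%d", x$chrom, as.integer(x$start), as.integer(x$end))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a chromosome-sizes table
#'
#' Two tab-separated columns: chromosome name, length in bp.
#'
#' @param path file path.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  chrom_sizes(stats::setNames(tab$length, tab$chrom))
}

#' Construct/validate chromosome sizes
#'
#' @param sizes named numeric vector, chromosome name -> length in bp.
#' @return The validated named vector. The sum of lengths is the whole-genome
#'   length used as the denominator of expected annotation overlap.
#' @export
chrom_sizes <- function(sizes) {
  if (is.null(names(sizes)) || any(!nzchar(names(sizes))))
    stop("chromosome sizes must be named")
  if (anyDuplicated(names(sizes))) stop("duplicate chromosome names")
  if (any(sizes <= 0)) stop("chromosome lengths must be > 0")
  sizes
}

#' Write a chromosome-sizes table
#' @param sizes named numeric vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(sizes, path) {
  writeLines(sprintf("%s\t%d", names(sizes), as.integer(sizes)), path)
  invisible(path)
}

#' Read strand-labeled reads
#'
#' Produces the Watson/Crick read-placement set that strand-bias counting
#' consumes: one record per read with its 5'-most aligned base (`pos5`,
#' 0-based) and strand (`W` = plus, `C` = minus). For BED6, `pos5 = start`
#' for `+` reads and `end - 1` for `-` reads. For SAM input (convenience
#' layer via Rsamtools) secondary, supplementary and unmapped records are
#' skipped and, for paired data, only the first mate contributes, so each
#' fragment is counted once with an unambiguous strand.
#'
#' @param path BED6 or SAM file.
#' @param format `"bed6"` (canonical) or `"sam"`.
#' @return A `stranded_reads` object: data frame (`chrom`, `pos5`, `strand`
#'   with levels W/C) plus attribute `total_count`.
#' @export
read_stranded_reads <- function(path, format = c("bed6", "sam")) {
  format <- match.arg(format)
  if (format == "bed6") {
    bed <- read_bed(path)
    if (nrow(bed) > 0 && any(bed$strand == "."))
      stop("stranded-read BED6 input requires a +/- strand column")
    stranded_reads(
      chrom = bed$chrom,
      pos5 = ifelse(bed$strand == "+", bed$start, bed$end - 1),
      strand = ifelse(bed$strand == "+", "W", "C")
    )
  } else {
    .read_sam_reads(path)
  }
}

.read_sam_reads <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("SAM input requires the Rsamtools package")
  bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(what = c("flag", "rname", "pos", "cigar"))
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  flag <- rec$flag
  keep <- !is.na(rec$pos) &
    bitwAnd(flag, 0x4) == 0 &    # mapped
    bitwAnd(flag, 0x100) == 0 &  # primary
    bitwAnd(flag, 0x800) == 0 &  # not supplementary
    (bitwAnd(flag, 0x1) == 0 | bitwAnd(flag, 0x40) != 0)  # first mate if paired
  if (!any(keep)) {
    warning("no usable mapped records in ", path)
    return(stranded_reads())
  }
  flag <- flag[keep]
  pos0 <- rec$pos[keep] - 1  # SAM is 1-based
  reflen <- .cigar_ref_length(rec$cigar[keep])
  minus <- bitwAnd(flag, 0x10) != 0
  stranded_reads(
    chrom = as.character(rec$rname[keep]),
    pos5 = ifelse(minus, pos0 + reflen - 1, pos0),
    strand = ifelse(minus, "C", "W")
  )
}

# reference-consuming CIGAR length (M, D, N, =, X)
.cigar_ref_length <- function(cigar) {
  vapply(regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar)), function(ops) {
    n <- as.numeric(sub("[A-Z=]$", "", ops))
    op <- sub("^\\d+", "", ops)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, numeric(1))
}

#' Construct a stranded read set
#'
#' @param chrom chromosome names.
#' @param pos5 0-based position of the 5'-most aligned base.
#' @param strand `"W"` (Watson/plus) or `"C"` (Crick/minus).
#' @return A `stranded_reads` data frame with attribute `total_count`.
#' @export
stranded_reads <- function(chrom = character(), pos5 = numeric(),
                           strand = character()) {
  if (length(strand) && !all(strand %in% c("W", "C")))
    stop("read strand must be 'W' or 'C'")
  if (length(pos5) && any(pos5 < 0)) stop("pos5 must be >= 0")
  x <- data.frame(chrom = as.character(chrom), pos5 = as.numeric(pos5),
                  strand = as.character(strand), stringsAsFactors = FALSE)
  attr(x, "total_count") <- nrow(x)
  class(x) <- c("stranded_reads", "data.frame")
  x
}

#' Total intersection length of two interval sets
#'
#' Each set is merged (union within set) first, so overlapping intervals are
#' never double-counted; the result is the total bp of
#' `union(A) intersect union(B)` summed over chromosomes. Symmetric in its
#' arguments.
#'
#' @param a,b interval data frames.
#' @return Total overlap in bp.
#' @export
overlap_length <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  ga <- GenomicRanges::reduce(.as_granges(a), ignore.strand = TRUE)
  gb <- GenomicRanges::reduce(.as_granges(b), ignore.strand = TRUE)
  sum(as.numeric(GenomicRanges::width(
    GenomicRanges::intersect(ga, gb, ignore.strand = TRUE))))
}

#' Merge overlapping intervals within a set
#'
#' @param x interval data frame.
#' @return Merged, sorted `genomic_intervals` (strand-agnostic union).
#' @export
merge_intervals <- function(x) {
  validate_intervals(x)
  if (nrow(x) == 0) return(genomic_intervals())
  .from_granges(GenomicRanges::reduce(.as_granges(x), ignore.strand = TRUE))
}

#' Total merged length of an interval set
#' @param x interval data frame.
#' @return Total bp covered after merging.
#' @export
total_length <- function(x) {
  m <- merge_intervals(x)
  if (nrow(m) == 0) 0 else sum(m$end - m$start)
}

#' Count reads per bin
#'
#' Assigns each read to at most one bin by its `pos5`; bins must be sorted
#' and non-overlapping within each chromosome.
#'
#' @param reads a `stranded_reads` object.
#' @param bins interval data frame of bins.
#' @param strand_filter `"both"`, `"W"` or `"C"`.
#' @return Integer vector of counts, one per row of `bins`.
#' @export
bin_counts <- function(reads, bins, strand_filter = c("both", "W", "C")) {
  strand_filter <- match.arg(strand_filter)
  validate_intervals(bins)
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, , drop = FALSE]
    if (is.unsorted(b$start, strictly = TRUE) ||
        any(b$start[-1] < b$end[-nrow(b)]))
      stop("bins must be sorted and non-overlapping within each chromosome")
  }
  if (strand_filter != "both") reads <- reads[reads$strand == strand_filter, ]
  counts <- integer(nrow(bins))
  if (nrow(reads) == 0 || nrow(bins) == 0) return(counts)
  for (ch in unique(bins$chrom)) {
    bi <- which(bins$chrom == ch)
    p <- reads$pos5[reads$chrom == ch]
    if (!length(p)) next
    b <- bins[bi, , drop = FALSE]
    # index of the bin whose start is at or left of each read
    k <- findInterval(p, b$start)
    ok <- k >= 1 & p < b$end[pmax(k, 1)]
    counts[bi] <- counts[bi] + tabulate(k[ok], nbins = nrow(b))
  }
  counts
}
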