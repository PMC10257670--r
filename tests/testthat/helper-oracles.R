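# Independent brute-force oracles used across test files. These deliberately
# avoid the package's own code paths (per-base masks, per-read loops,
# character-level hamming) so agreement is meaningful.

# per-base intersection length on a toy genome (chromosome lengths `sizes`)
brute_overlap_length <- function(a, b, sizes) {
  total <- 0
  for (ch in names(sizes)) {
    mask_of <- function(x) {
      m <- logical(sizes[[ch]])
      xs <- x[x$chrom == ch, , drop = FALSE]
      if (nrow(xs)) for (i in seq_len(nrow(xs)))
        m[(xs$start[i] + 1):xs$end[i]] <- TRUE
      m
    }
    total <- total + sum(mask_of(a) & mask_of(b))
  }
  total
}

# per-read recomputation of origin-window strand counts and bias
brute_bias <- function(reads, origins, half_window, bin_size) {
  K2 <- 2 * half_window / bin_size
  W <- matrix(0, nrow(origins), K2)
  C <- matrix(0, nrow(origins), K2)
  for (i in seq_len(nrow(origins))) {
    for (r in seq_len(nrow(reads))) {
      if (reads$chrom[r] != origins$chrom[i]) next
      off <- reads$pos5[r] - (origins$center[i] - half_window)
      if (off < 0 || off >= 2 * half_window) next
      k <- off %/% bin_size + 1
      if (reads$strand[r] == "W") W[i, k] <- W[i, k] + 1
      else C[i, k] <- C[i, k] + 1
    }
  }
  tot <- W + C
  (W - C) / ifelse(tot == 0, NA, tot)
}

# character-wise hamming distance
brute_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# independent restatement of the greedy abundance-ranked collapse
brute_collapse <- function(triples, max_hamming = 3) {
  supp <- tapply(triples$read_count, triples$lineage_barcode, sum)
  bc <- names(supp)[order(-supp, names(supp))]
  reps <- character(0)
  out <- character(length(bc))
  for (i in seq_along(bc)) {
    hit <- NA_character_
    for (rp in reps) {
      if (brute_hamming(bc[i], rp) <= max_hamming) { hit <- rp; break }
    }
    if (is.na(hit)) { reps <- c(reps, bc[i]); out[i] <- bc[i] }
    else out[i] <- hit
  }
  data.frame(barcode = bc, representative = out, stringsAsFactors = FALSE)
}

random_intervals <- function(n, sizes, max_len = 400) {
  ch <- sample(names(sizes), n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i)
    sample.int(sizes[[ch[i]]] - len[i], 1) - 1, numeric(1))
  genomic_intervals(chrom = ch, start = start, end = start + len)
}
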