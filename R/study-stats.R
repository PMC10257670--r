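#' Pearson chi-square test for a 2x2 incidence table
#'
#' `X^2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with no continuity
#' correction; the p-value is the upper tail of chi-square with 1 df. Used
#' for group-vs-outcome incidence comparisons such as metastasis counts in
#' two xenograft arms. The statistic is invariant under simultaneous row
#' and column swaps and is exactly 0 (p = 1) for equal row proportions.
#'
#' @param table 2x2 numeric matrix, rows = groups, columns =
#'   outcome present/absent (counts >= 0, total > 0, no zero margin).
#' @return List with `statistic` and `p_value`.
#' @export
chi_square_2x2 <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2))
  if (any(table < 0) || any(table != floor(table)))
    stop("counts must be non-negative integers")
  n <- sum(table)
  if (n <= 0) stop("empty table")
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop("chi-square test undefined with a zero margin")
  stat <- n * (a * d - b * c)^2 / prod(margins)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Ellipsoid tumor volume from caliper measurements
#'
#' `volume = 0.52 * length * width^2` (mm^3). By convention length >= width;
#' swapped measurements are corrected with a warning.
#'
#' @param length,width caliper measurements in mm (>= 0).
#' @return Volume in mm^3 (vectorized).
#' @export
tumor_volume <- function(length, width) {
  if (any(length < 0) || any(width < 0))
    stop("measurements must be non-negative")
  swap <- width > length
  if (any(swap)) {
    warning("width > length for ", sum(swap),
            " measurement(s); swapping to the length >= width convention")
    tmp <- length[swap]
    length[swap] <- width[swap]
    width[swap] <- tmp
  }
  0.52 * length * width^2
}
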