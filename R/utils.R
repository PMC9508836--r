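## Shared small helpers.

WINDOW_FLANK <- 20L
WINDOW_LEN <- 41L      # 2 * flank + 1 genomic positions
IMAGE_ROWS <- 160L     # read-depth cap per member
IMAGE_COLS <- 164L     # 4 pixels (one-hot A,C,T,G) per genomic position
BASES <- c("A", "C", "T", "G")   # one-hot column order within a base block
GAP <- "-"

#' Round half away from zero
#'
#' Fixed-rule rounding used wherever the package reports values to a set
#' number of decimals (printed benchmark tables use half-up rounding, which
#' differs from R's default round-half-even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # guard against binary representation error before the half-up floor
  sign(x) * floor(round(abs(x) * p, 9) + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## split "10M2I5M" into ops/lengths without GenomicAlignments
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*") return(list(op = character(), len = integer()))
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  tok <- regmatches(cigar, list(m))[[1]]
  list(
    op = substr(tok, nchar(tok), nchar(tok)),
    len = as.integer(substr(tok, 1L, nchar(tok) - 1L))
  )
}

TRIO_ROLES <- c("child", "father", "mother")
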