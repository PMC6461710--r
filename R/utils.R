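#' @importFrom methods new validObject is slot setValidity show
#' @importFrom stats rbinom runif rgamma optim dnorm dbeta setNames
#' @importFrom utils read.delim write.table head
#' @importFrom S4Vectors mcols
NULL

## Round half away from zero, the rounding rule used by every percentage
## column in the accounting tables (base round() rounds half to even).
roundHalfAway <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

pct1 <- function(num, den) {
  ifelse(is.na(num) | is.na(den) | den == 0, NA_real_,
         roundHalfAway(100 * num / den, 1))
}

#' Reverse complement of nucleotide strings
#'
#' Vectorised reverse complement for plain character vectors (IUPAC codes
#' supported).
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of the same length.
#' @export
revComp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Phred+33 quality string <-> integer scores
phredToInt <- function(q) {
  lapply(q, function(s) as.integer(charToRaw(s)) - 33L)
}

intToPhred <- function(q) {
  vapply(q, function(s) rawToChar(as.raw(pmin(pmax(s, 0L), 93L) + 33L)), "")
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

## number of mismatching positions between two equal-length strings
.hamming1 <- function(a, b) sum(charToRaw(a) != charToRaw(b))

stopifnot_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single string", call. = FALSE)
}
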