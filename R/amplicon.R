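#' AmpliconDef: a marker amplicon definition
#'
#' Primer pair, expected insert length after primer removal, and the
#' minimum-length fraction used by the length filter.
#'
#' @slot marker marker name (e.g. "16S", "12S", "CytB", "COI").
#' @slot fwdPrimer,revPrimer primer sequences (IUPAC allowed).
#' @slot expectedLength expected insert length in bp.
#' @slot minLengthFrac minimum accepted fraction of the expected length.
#' @export
setClass("AmpliconDef", representation(
  marker = "character",
  fwdPrimer = "character",
  revPrimer = "character",
  expectedLength = "integer",
  minLengthFrac = "numeric"
))

setValidity("AmpliconDef", function(object) {
  if (!nzchar(object@fwdPrimer) || !nzchar(object@revPrimer))
    return("primers must be non-empty")
  if (object@expectedLength < 1L) return("expectedLength must be positive")
  if (object@minLengthFrac <= 0 || object@minLengthFrac > 1)
    return("minLengthFrac must be in (0, 1]")
  TRUE
})

#' Construct an AmpliconDef
#'
#' @param marker marker name.
#' @param fwdPrimer,revPrimer primer sequences in 5'-3' orientation.
#' @param expectedLength expected insert length (bp) after primer removal.
#' @param minLengthFrac minimum accepted length as a fraction of
#'   \code{expectedLength} (default 0.9).
#' @return a validated \code{AmpliconDef}.
#' @export
ampliconDef <- function(marker, fwdPrimer, revPrimer, expectedLength,
                        minLengthFrac = 0.9) {
  new("AmpliconDef", marker = marker,
      fwdPrimer = toupper(fwdPrimer), revPrimer = toupper(revPrimer),
      expectedLength = as.integer(expectedLength),
      minLengthFrac = minLengthFrac)
}

setMethod("show", "AmpliconDef", function(object) {
  cat(sprintf("AmpliconDef %s: %d bp insert (>= %.0f%%), primers %s / %s\n",
              object@marker, object@expectedLength,
              100 * object@minLengthFrac, object@fwdPrimer,
              object@revPrimer))
})

#' Default tetrapod mitochondrial marker definitions
#'
#' The four mitochondrial amplicons targeted by the workflow: a 93-bp
#' fragment of 16S rRNA, a 389-bp fragment of 12S rRNA, a 302-bp fragment
#' of cytochrome b, and a 250-bp COI mini-barcode region. The 16S, 12S and
#' CytB primer pairs are the tetrapod screening primers the bundled tag
#' scheme was designed around; the COI pair is a configurable placeholder
#' for the mini-barcode region (reference databases for COI are typically
#' trimmed by similarity rather than by in-silico PCR).
#'
#' @param markers which markers to return.
#' @return named list of \code{AmpliconDef}.
#' @export
markerAmplicons <- function(markers = c("16S", "12S", "CytB", "COI")) {
  defs <- list(
    `16S` = ampliconDef("16S", "CGGTTGGGGTGACCTCGGA",
                        "GCTGTTATCCCTAGGGTAACT", 93L),
    `12S` = ampliconDef("12S", "AAAAAGCTTCAAACTGGGATTAGATACCCCACTAT",
                        "TGACTGCAGAGGGTGACGGGCGGTGTGT", 389L),
    CytB = ampliconDef("CytB", "AAAAAGCTTCCATCCAACATCTCAGCATGATGAAA",
                       "AAACTGCAGCCCCTCAGAATGATATTTGTCCTCA", 302L),
    COI = ampliconDef("COI", "GGTCAACAAATCATAAAGATATTGG",
                      "TAAACTTCAGGGTGACCAAAAAATCA", 250L)
  )
  defs[markers]
}
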