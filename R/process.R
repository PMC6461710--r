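#' Merge an inward-oriented read pair
#'
#' Finds the best ungapped overlap between the forward read and the
#' reverse complement of the reverse read. At overlap agreements the merged
#' base keeps the higher of the two qualities; at mismatches the
#' higher-quality base is kept and its quality reduced to the absolute
#' quality difference (floored at 2). Merging fails -- a counted state, not
#' an error -- when the best overlap is shorter than \code{minOverlap} or
#' its mismatch fraction exceeds \code{maxMismatchFrac}.
#'
#' @param seqFwd,seqRev mate sequences.
#' @param qualFwd,qualRev Phred+33 quality strings.
#' @param minOverlap minimum accepted overlap length (default 16).
#' @param maxMismatchFrac maximum mismatch fraction within the overlap
#'   (default 0.25).
#' @return list with \code{success}; on success also \code{seq},
#'   \code{qual}, \code{overlap}, \code{mismatches}.
#' @export
mergeReadPair <- function(seqFwd, seqRev, qualFwd = NULL, qualRev = NULL,
                          minOverlap = 16L, maxMismatchFrac = 0.25) {
  if (is.null(qualFwd)) qualFwd <- strrep("D", nchar(seqFwd))
  if (is.null(qualRev)) qualRev <- strrep("D", nchar(seqRev))
  rcSeq <- revComp(seqRev)
  rcQual <- paste(rev(strsplit(qualRev, "")[[1]]), collapse = "")
  nf <- nchar(seqFwd); nr <- nchar(rcSeq)
  fr <- charToRaw(seqFwd); rr <- charToRaw(rcSeq)
  best <- NULL; bestScore <- -Inf
  for (L in seq(from = min(nf, nr), to = min(minOverlap, min(nf, nr)))) {
    mm <- sum(fr[(nf - L + 1L):nf] != rr[1:L])
    score <- L - 2L * mm
    if (score > bestScore) { bestScore <- score; best <- c(L, mm) }
  }
  if (is.null(best)) return(list(success = FALSE))
  L <- best[1]; mm <- best[2]
  if (L < minOverlap || mm / L > maxMismatchFrac)
    return(list(success = FALSE))
  qf <- phredToInt(qualFwd)[[1]]; qr <- phredToInt(rcQual)[[1]]
  fOv <- (nf - L + 1L):nf; rOv <- 1:L
  fb <- fr[fOv]; rb <- rr[rOv]
  qfo <- qf[fOv]; qro <- qr[rOv]
  agree <- fb == rb
  consBase <- ifelse(agree | qfo >= qro, rawToChar(fb, multiple = TRUE),
                     rawToChar(rb, multiple = TRUE))
  consQual <- ifelse(agree, pmax(qfo, qro), pmax(abs(qfo - qro), 2L))
  seq <- paste0(substr(seqFwd, 1L, nf - L),
                paste(consBase, collapse = ""),
                substr(rcSeq, L + 1L, nr))
  qual <- intToPhred(list(c(qf[seq_len(nf - L)], consQual,
                            qr[seq.int(L + 1L, length.out = nr - L)])))
  list(success = TRUE, seq = seq, qual = qual, overlap = L,
       mismatches = mm)
}

#' Library-size gate
#'
#' Libraries are only carried forward through a processing step when they
#' hold strictly more units (read pairs, merged pairs, ...) than the gate
#' threshold; gated-out libraries are dropped with a logged reason.
#'
#' @param nUnits observed number of units.
#' @param threshold gate threshold.
#' @return logical.
#' @export
gateLibrary <- function(nUnits, threshold) nUnits > threshold

## best substitution-only match of a primer in a sequence; returns
## c(start, mismatches) or NULL
.findPrimer <- function(seq, primer, maxMM, fromEnd = FALSE) {
  subj <- Biostrings::DNAString(seq)
  hits <- Biostrings::matchPattern(primer, subj, max.mismatch = maxMM,
                                   with.indels = FALSE, fixed = FALSE)
  if (length(hits) == 0L) return(NULL)
  i <- if (fromEnd) length(hits) else 1L
  c(Biostrings::start(hits)[i], Biostrings::end(hits)[i])
}

#' Trim primers from a merged amplicon sequence
#'
#' Locates the forward primer and the reverse complement of the reverse
#' primer (substitutions only, up to \code{maxErrorRate} per primer; IUPAC
#' codes in primers are honoured) and returns the insert between them.
#'
#' @param seq merged sequence.
#' @param adef an \code{AmpliconDef}.
#' @param qual optional Phred+33 quality string, trimmed alongside.
#' @param maxErrorRate per-primer mismatch rate (default 0.12).
#' @return list with \code{success}; on success \code{insert} and, when a
#'   quality was supplied, \code{qual}.
#' @export
trimPrimers <- function(seq, adef, qual = NULL, maxErrorRate = 0.12) {
  fp <- adef@fwdPrimer
  rp <- revComp(adef@revPrimer)
  f <- .findPrimer(seq, fp, floor(maxErrorRate * nchar(fp)))
  if (is.null(f)) return(list(success = FALSE))
  r <- .findPrimer(seq, rp, floor(maxErrorRate * nchar(rp)), fromEnd = TRUE)
  if (is.null(r) || r[1] <= f[2]) return(list(success = FALSE))
  out <- list(success = TRUE,
              insert = substr(seq, f[2] + 1L, r[1] - 1L))
  if (!is.null(qual)) out$qual <- substr(qual, f[2] + 1L, r[1] - 1L)
  out
}

#' Insert length filter
#'
#' Passes inserts whose length is at least
#' \code{ceiling(minLengthFrac * expectedLength)} of the marker.
#'
#' @param insert insert sequence (or its length).
#' @param adef an \code{AmpliconDef}.
#' @return logical vector.
#' @export
filterLength <- function(insert, adef) {
  len <- if (is.numeric(insert)) insert else nchar(insert)
  len >= ceiling(adef@minLengthFrac * adef@expectedLength)
}

#' Expected-error quality filter
#'
#' Passes reads whose summed per-base error probability
#' \eqn{\sum 10^{-Q/10}} does not exceed \code{maxExpectedErrors}.
#'
#' @param qual Phred+33 quality string(s).
#' @param maxExpectedErrors maximum expected errors (default 1.0).
#' @return logical vector.
#' @export
filterQuality <- function(qual, maxExpectedErrors = 1.0) {
  ee <- vapply(phredToInt(qual), function(q) sum(10^(-q / 10)), 0)
  ee <= maxExpectedErrors
}

#' Expected number of sequencing errors of a quality string
#'
#' @param qual Phred+33 quality string(s).
#' @return numeric vector of expected-error sums.
#' @export
expectedErrors <- function(qual) {
  vapply(phredToInt(qual), function(q) sum(10^(-q / 10)), 0)
}

#' Dereplicate a sample's inserts
#'
#' Groups exactly identical sequences, records each group's copy number
#' ("size"), discards singletons, and orders the output by decreasing size
#' with ties broken lexicographically by sequence.
#'
#' @param inserts character vector of insert sequences.
#' @param discardSingletons drop size-1 groups (default TRUE).
#' @return data.frame with columns \code{seq}, \code{size}.
#' @export
dereplicateSample <- function(inserts, discardSingletons = TRUE) {
  if (length(inserts) == 0L)
    return(data.frame(seq = character(0), size = integer(0),
                      stringsAsFactors = FALSE))
  tab <- table(inserts)
  df <- data.frame(seq = names(tab), size = as.integer(tab),
                   stringsAsFactors = FALSE)
  if (discardSingletons) df <- df[df$size > 1L, , drop = FALSE]
  df <- df[order(-df$size, df$seq), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Process one demultiplexed sample to dereplicated inserts
#'
#' Runs the full per-sample read-processing chain: library-size gate on raw
#' pairs, pair merging, gate on merged pairs, primer trimming, length
#' filter, expected-error quality filter, dereplication with singleton
#' removal. Per-step counts are recorded for the loss report.
#'
#' @param reads read-pair data.frame (tags already clipped).
#' @param adef an \code{AmpliconDef}.
#' @param sample sample identifier.
#' @param minOverlap,maxMismatchFrac merge parameters.
#' @param maxErrorRate per-primer trim mismatch rate.
#' @param maxExpectedErrors quality-filter threshold.
#' @param rawGate,mergedGate library gates (defaults 1000 raw read pairs,
#'   500 merged pairs).
#' @return list with \code{sample}, \code{counts} (raw, merged, trimmed,
#'   length_pass, quality_pass, unique), \code{derep} data.frame,
#'   \code{gated} (NA or the gate that dropped the library).
#' @export
processSample <- function(reads, adef, sample = "sample",
                          minOverlap = 16L, maxMismatchFrac = 0.25,
                          maxErrorRate = 0.12, maxExpectedErrors = 1.0,
                          rawGate = 1000L, mergedGate = 500L) {
  counts <- c(raw = nrow(reads), merged = 0L, trimmed = 0L,
              length_pass = 0L, quality_pass = 0L, unique = 0L)
  emptyOut <- function(gate) list(sample = sample, counts = counts,
                                  derep = dereplicateSample(character(0)),
                                  gated = gate)
  if (!gateLibrary(nrow(reads), rawGate)) return(emptyOut("raw"))
  merged <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    m <- mergeReadPair(reads$seq_fwd[i], reads$seq_rev[i],
                       reads$qual_fwd[i], reads$qual_rev[i],
                       minOverlap, maxMismatchFrac)
    if (m$success) merged[[i]] <- m
  }
  merged <- merged[!vapply(merged, is.null, TRUE)]
  counts["merged"] <- length(merged)
  if (!gateLibrary(length(merged), mergedGate)) {
    out <- emptyOut("merged"); out$counts <- counts; return(out)
  }
  ins <- character(0); insQ <- character(0)
  for (m in merged) {
    t <- trimPrimers(m$seq, adef, m$qual, maxErrorRate)
    if (t$success) { ins <- c(ins, t$insert); insQ <- c(insQ, t$qual) }
  }
  counts["trimmed"] <- length(ins)
  keep <- filterLength(ins, adef)
  ins <- ins[keep]; insQ <- insQ[keep]
  counts["length_pass"] <- length(ins)
  keep <- filterQuality(insQ, maxExpectedErrors)
  ins <- ins[keep]
  counts["quality_pass"] <- length(ins)
  derep <- dereplicateSample(ins)
  counts["unique"] <- nrow(derep)
  list(sample = sample, counts = counts, derep = derep, gated = NA)
}

#' Per-step read-loss report
#'
#' One row per sample with the per-step counts and the percentage lost
#' relative to the previous step (one decimal, half away from zero);
#' zero denominators yield NA rather than an error.
#'
#' @param samples list of processed samples (see
#'   \code{\link{processSample}}).
#' @return data.frame report.
#' @export
processingReport <- function(samples) {
  steps <- c("raw", "merged", "trimmed", "length_pass", "quality_pass",
             "unique")
  rows <- lapply(samples, function(s) {
    cn <- s$counts[steps]
    r <- data.frame(sample = s$sample, t(as.integer(cn)),
                    stringsAsFactors = FALSE)
    names(r) <- c("sample", steps)
    ## losses are relative to the preceding read-count step; the unique
    ## column is a dereplication count, not a loss stage
    for (i in 2:5) {
      prev <- cn[[i - 1]]; cur <- cn[[i]]
      r[[paste0(steps[i], "_loss_pct")]] <-
        if (is.na(prev) || prev == 0) NA_real_
        else roundHalfAway(100 * (prev - cur) / prev, 1)
    }
    r
  })
  do.call(rbind, rows)
}
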