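#' Read-pair records
#'
#' Paired reads are carried through the toolkit as plain data.frames with
#' columns \code{id}, \code{seq_fwd}, \code{seq_rev}, \code{qual_fwd},
#' \code{qual_rev} (Phred+33 quality strings). This constructor validates
#' the per-mate length agreement between sequence and quality.
#'
#' @param id read identifiers.
#' @param seq_fwd,seq_rev mate sequences.
#' @param qual_fwd,qual_rev Phred+33 quality strings (default constant Q35).
#' @return a read-pair data.frame.
#' @export
readPairs <- function(id, seq_fwd, seq_rev,
                      qual_fwd = strrep("D", nchar(seq_fwd)),
                      qual_rev = strrep("D", nchar(seq_rev))) {
  if (any(nchar(seq_fwd) != nchar(qual_fwd)) ||
      any(nchar(seq_rev) != nchar(qual_rev)))
    stop("sequence and quality lengths differ", call. = FALSE)
  data.frame(id = unname(as.character(id)), seq_fwd = unname(seq_fwd),
             seq_rev = unname(seq_rev), qual_fwd = unname(qual_fwd),
             qual_rev = unname(qual_rev), stringsAsFactors = FALSE)
}

## Identify the marker of each read by comparing the sequence following the
## two tags against each marker's forward primer (substitutions only).
.markerOfReads <- function(seqAfterTags, markers, maxErrorRate = 0.12) {
  if (length(markers) == 1L) return(rep(names(markers), length(seqAfterTags)))
  best <- rep(NA_character_, length(seqAfterTags))
  bestMM <- rep(Inf, length(seqAfterTags))
  for (m in names(markers)) {
    p <- markers[[m]]@fwdPrimer
    lp <- nchar(p)
    obs <- substr(seqAfterTags, 1L, lp)
    full <- nchar(obs) == lp
    mm <- rep(Inf, length(obs))
    mm[full] <- .mismatchCount(obs[full], p)
    allow <- floor(maxErrorRate * lp)
    hit <- mm <= allow & mm < bestMM
    best[hit] <- m
    bestMM[hit] <- mm[hit]
  }
  best
}

## vectorised mismatch count of many strings against one pattern of equal
## length; IUPAC codes in the pattern match their expansions
.mismatchCount <- function(obs, pattern) {
  if (!length(obs)) return(integer(0))
  if (grepl("[^ACGT]", pattern)) {
    subj <- Biostrings::DNAStringSet(obs)
    vapply(seq_along(obs), function(i) {
      Biostrings::neditAt(Biostrings::DNAString(pattern), subj[[i]],
                          at = 1, fixed = FALSE)
    }, 0L)
  } else {
    pr <- charToRaw(pattern)
    vapply(obs, function(s) sum(charToRaw(s) != pr), 0L, USE.NAMES = FALSE)
  }
}

#' Demultiplex a twin-tagged sequencing run
#'
#' Two-level demultiplexing of paired reads whose 5' layout on each mate is
#' Tag 2, then Tag 1, then the marker primer. Reads are first classified at
#' the Tag 2 (plate/PCR) level and, within Tag 2 twins, at the Tag 1
#' (sample) level; at each level a pair is a \emph{twin} when both mates
#' resolve to the same label, a \emph{jump} when both resolve but differ
#' (a chimeric tag-jump product), and \emph{unassigned} otherwise. Only
#' reads that are twins at both levels and map to a sample-sheet entry are
#' emitted, with both tags clipped; jumps and unassigned reads are diverted
#' to reject streams.
#'
#' @param reads read-pair data.frame (see \code{\link{readPairs}}).
#' @param scheme a \code{TwinTagScheme}.
#' @param run run label recorded in the statistics row.
#' @param primerErrorRate per-primer mismatch rate tolerated when
#'   identifying the marker of a read (default 0.12).
#' @return list with elements \code{samples} (named list of read-pair
#'   data.frames, tags clipped), \code{rejects} (list \code{jump},
#'   \code{unassigned}), and \code{stats} (one-row DemuxStats data.frame
#'   with counts total, tag2_twin, tag2_jump, tag2_unassigned, tag1_twin,
#'   tag1_jump, tag1_unassigned).
#' @export
demultiplexRun <- function(reads, scheme, run = "run01",
                           primerErrorRate = 0.12) {
  if (nrow(scheme@sampleSheet) == 0L)
    stop("empty scheme: sample sheet has no entries", call. = FALSE)
  k2 <- tagLength(scheme@tag2)
  k1 <- tagLength(scheme@tag1)
  n <- nrow(reads)
  stats <- data.frame(run = run, total = n, tag2_twin = 0L, tag2_jump = 0L,
                      tag2_unassigned = 0L, tag1_twin = 0L, tag1_jump = 0L,
                      tag1_unassigned = 0L, stringsAsFactors = FALSE)
  empty <- reads[0, ]
  out <- list(samples = list(), rejects = list(jump = empty,
                                               unassigned = empty),
              stats = stats)
  if (n == 0L) return(out)

  longEnough <- nchar(reads$seq_fwd) >= (k2 + k1) &
    nchar(reads$seq_rev) >= (k2 + k1)

  cls2 <- rep("unassigned", n)
  lab2 <- rep(NA_character_, n)
  cp2 <- classifyTagPair(
    substr(reads$seq_fwd[longEnough], 1L, k2),
    substr(reads$seq_rev[longEnough], 1L, k2),
    scheme@tag2, scheme@maxMismatch)
  cls2[longEnough] <- cp2$category
  lab2[longEnough] <- cp2$label

  is2twin <- cls2 == "twin"
  cls1 <- rep(NA_character_, n)
  lab1 <- rep(NA_character_, n)
  if (any(is2twin)) {
    cp <- classifyTagPair(
      substr(reads$seq_fwd[is2twin], k2 + 1L, k2 + k1),
      substr(reads$seq_rev[is2twin], k2 + 1L, k2 + k1),
      scheme@tag1, scheme@maxMismatch)
    cls1[is2twin] <- cp$category
    lab1[is2twin] <- cp$label
  }

  ## reserved Tag 1 labels (controls) resolve but are never emitted as
  ## samples; they are routed to the unassigned reject stream
  reservedHit <- !is.na(lab1) & lab1 %in% reservedLabels(scheme@tag1)

  emit <- is2twin & cls1 == "twin" & !reservedHit
  sampleId <- rep(NA_character_, n)
  if (any(emit)) {
    marker <- rep(NA_character_, n)
    after <- substr(reads$seq_fwd[emit], k2 + k1 + 1L,
                    nchar(reads$seq_fwd[emit]))
    marker[emit] <- .markerOfReads(after, scheme@markers, primerErrorRate)
    sh <- scheme@sampleSheet
    key <- paste(sh$tag2_label, sh$tag1_label, sh$marker, sep = "\r")
    qk <- paste(lab2, lab1, marker, sep = "\r")
    sampleId[emit] <- sh$sample_id[match(qk[emit], key)]
  }
  mapped <- emit & !is.na(sampleId)

  stats$tag2_twin <- sum(is2twin)
  stats$tag2_jump <- sum(cls2 == "jump")
  stats$tag2_unassigned <- sum(cls2 == "unassigned")
  stats$tag1_twin <- sum(mapped)
  stats$tag1_jump <- sum(is2twin & cls1 == "jump")
  ## twins without a sheet entry (incl. controls/unknown marker) count as
  ## unidentifiable at the sample level
  stats$tag1_unassigned <- stats$tag2_twin - stats$tag1_twin -
    stats$tag1_jump

  clip <- function(df) {
    df$seq_fwd <- substr(df$seq_fwd, k2 + k1 + 1L, nchar(df$seq_fwd))
    df$qual_fwd <- substr(df$qual_fwd, k2 + k1 + 1L, nchar(df$qual_fwd))
    df$seq_rev <- substr(df$seq_rev, k2 + k1 + 1L, nchar(df$seq_rev))
    df$qual_rev <- substr(df$qual_rev, k2 + k1 + 1L, nchar(df$qual_rev))
    df
  }
  out$samples <- lapply(split(which(mapped), sampleId[mapped]),
                        function(i) clip(reads[i, , drop = FALSE]))
  isJump <- cls2 == "jump" | (is2twin & cls1 == "jump")
  out$rejects$jump <- reads[isJump, , drop = FALSE]
  out$rejects$unassigned <- reads[!mapped & !isJump, , drop = FALSE]
  out$stats <- stats
  out
}

#' Per-run demultiplexing statistics table
#'
#' Adds the percentage columns of the run-accounting report to raw
#' DemuxStats count rows and appends a totals row: the Tag 2 jump rate is
#' expressed relative to the total read count, while the Tag 1 jump and
#' unidentifiable rates are relative to the Tag 2 twin count (the reads
#' actually entering sample-level demultiplexing). Totals sum the counts of
#' the included rows and recompute every percentage from the summed counts.
#' All percentages are rounded half away from zero to one decimal.
#'
#' @param rows data.frame of DemuxStats count rows (as produced by
#'   \code{\link{demultiplexRun}} or \code{\link{exampleRunCounts}}).
#' @param includeInTotal logical vector flagging rows that enter the totals
#'   row; defaults to a logical \code{in_total} column if present, else all.
#' @return data.frame with percentage columns and a final "Total" row.
#' @export
demuxStatsTable <- function(rows, includeInTotal = NULL) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  if (is.null(includeInTotal))
    includeInTotal <- if ("in_total" %in% names(rows)) rows$in_total
                      else rep(TRUE, nrow(rows))
  cnt <- c("total", "tag2_twin", "tag2_jump", "tag2_unassigned",
           "tag1_twin", "tag1_jump", "tag1_unassigned")
  for (cc in setdiff(cnt, names(rows))) rows[[cc]] <- NA_real_
  tot <- data.frame(run = "Total", stringsAsFactors = FALSE)
  for (cc in cnt) tot[[cc]] <- sum(rows[[cc]][includeInTotal])
  tot$in_total <- FALSE
  full <- rbind(rows[c("run", cnt, intersect("in_total", names(rows)))][
                  , c("run", cnt)],
                tot[, c("run", cnt)])
  full$tag2_jump_pct <- pct1(full$tag2_jump, full$total)
  full$tag1_jump_pct <- pct1(full$tag1_jump, full$tag2_twin)
  full$tag1_unassigned_pct <- pct1(full$tag1_unassigned, full$tag2_twin)
  full
}
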