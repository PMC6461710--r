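#' Replicate-cell naming
#'
#' The full replicate design of one sample x species combination: 2
#' extraction replicates (A/B) x 2 PCR cycle variants (1 = 30 cycles,
#' 2 = 40 cycles) x 3 markers = 12 PCR reactions.
#'
#' @param markers marker names (default 12S, 16S, CytB).
#' @return character vector of 12 cell names "A.1.12S", ...
#' @export
replicateCells <- function(markers = c("12S", "16S", "CytB")) {
  as.vector(outer(c("A.1", "A.2", "B.1", "B.2"), markers, paste,
                  sep = "."))
}

#' ReplicateGrid: per-replicate read counts for one sample x species
#'
#' Twelve addressable cells indexed by (extraction, cycle, marker); an
#' \code{NA} cell marks a library that was never sequenced (absent), which
#' is distinct from an observed zero and is excluded from all denominators.
#'
#' @slot sample sample identifier.
#' @slot species species label.
#' @slot counts named numeric vector over \code{\link{replicateCells}};
#'   NA = absent.
#' @export
setClass("ReplicateGrid", representation(
  sample = "character", species = "character", counts = "numeric"
))

setValidity("ReplicateGrid", function(object) {
  cells <- replicateCells(unique(vapply(
    strsplit(names(object@counts), ".", fixed = TRUE),
    `[`, "", 3L)))
  if (length(object@counts) != 12L)
    return("exactly 12 replicate cells required")
  if (!setequal(names(object@counts), cells))
    return("cell names must span 2 extractions x 2 cycles x 3 markers")
  if (any(object@counts < 0, na.rm = TRUE)) return("negative read count")
  TRUE
})

#' Construct a ReplicateGrid
#'
#' @param sample,species identifiers.
#' @param counts named numeric vector over the 12 cells (missing cells
#'   filled with 0; NA marks an absent library).
#' @param markers marker names of the design.
#' @return a validated \code{ReplicateGrid}.
#' @export
replicateGrid <- function(sample, species, counts = numeric(0),
                          markers = c("12S", "16S", "CytB")) {
  cells <- replicateCells(markers)
  full <- setNames(rep(0, 12L), cells)
  if (length(counts)) full[names(counts)] <- counts
  new("ReplicateGrid", sample = sample, species = species, counts = full)
}

setMethod("show", "ReplicateGrid", function(object) {
  cat(sprintf("ReplicateGrid %s / %s: %d positive, %d absent cells\n",
              object@sample, object@species,
              sum(object@counts >= 1, na.rm = TRUE),
              sum(is.na(object@counts))))
})

#' Acceptance configuration
#'
#' @param minPositiveLax positives required by the lax criterion
#'   (default 2).
#' @param minReadsPerMarker read threshold of the single-marker rule
#'   (default 10).
#' @param positiveCellThreshold reads needed for a cell to count as a
#'   positive PCR (default 1).
#' @return config list.
#' @export
acceptanceConfig <- function(minPositiveLax = 2L, minReadsPerMarker = 10L,
                             positiveCellThreshold = 1L) {
  stopifnot(minPositiveLax >= 1L, minReadsPerMarker >= 1L,
            positiveCellThreshold >= 1L)
  list(minPositiveLax = minPositiveLax,
       minReadsPerMarker = minReadsPerMarker,
       positiveCellThreshold = positiveCellThreshold)
}

#' Positive cells of a grid
#'
#' A cell is positive when its read count reaches the positive-cell
#' threshold; absent (NA) cells are never positive.
#'
#' @param grid a \code{ReplicateGrid}.
#' @param cfg an \code{\link{acceptanceConfig}}.
#' @return character vector of positive cell names.
#' @export
positiveCells <- function(grid, cfg = acceptanceConfig()) {
  cn <- grid@counts
  names(cn)[!is.na(cn) & cn >= cfg$positiveCellThreshold]
}

#' Lax acceptance criterion
#'
#' Accepts when at least \code{minPositiveLax} (default 2) of the 12 PCR
#' replicates are positive, regardless of which extraction replicate they
#' come from.
#'
#' @inheritParams positiveCells
#' @return logical.
#' @export
acceptLax <- function(grid, cfg = acceptanceConfig()) {
  length(positiveCells(grid, cfg)) >= cfg$minPositiveLax
}

#' Stringent acceptance criterion
#'
#' Accepts only when the species is positive in both extraction
#' replicates: at least one positive A-cell and at least one positive
#' B-cell.
#'
#' @inheritParams positiveCells
#' @return logical.
#' @export
acceptStringent <- function(grid, cfg = acceptanceConfig()) {
  pos <- positiveCells(grid, cfg)
  any(startsWith(pos, "A.")) && any(startsWith(pos, "B."))
}

#' Read-count rule
#'
#' When only one marker yielded reads, its summed reads must reach
#' \code{minReadsPerMarker}; an assignment supported by two or more
#' markers is accepted even when individual markers fall below the
#' threshold.
#'
#' @inheritParams positiveCells
#' @return logical.
#' @export
readCountRule <- function(grid, cfg = acceptanceConfig()) {
  cn <- grid@counts
  marker <- vapply(strsplit(names(cn), ".", fixed = TRUE), `[`, "", 3L)
  perMarker <- vapply(split(cn, marker), function(x)
    sum(x, na.rm = TRUE), 0)
  withReads <- sum(perMarker > 0)
  if (withReads == 0L) return(FALSE)
  if (withReads >= 2L) return(TRUE)
  max(perMarker) >= cfg$minReadsPerMarker
}

#' Call detections over a set of replicate grids
#'
#' Evaluates both criteria side by side; an accepted detection must pass
#' the criterion and the read-count rule.
#'
#' @param grids list of \code{ReplicateGrid}.
#' @param cfg an \code{\link{acceptanceConfig}}.
#' @return data.frame with columns sample, species, stringent, lax,
#'   n_positive, markers, total_reads.
#' @export
callDetections <- function(grids, cfg = acceptanceConfig()) {
  rows <- lapply(grids, function(g) {
    pos <- positiveCells(g, cfg)
    rule <- readCountRule(g, cfg)
    mk <- unique(vapply(strsplit(pos, ".", fixed = TRUE), `[`, "", 3L))
    data.frame(sample = g@sample, species = g@species,
               stringent = acceptStringent(g, cfg) && rule,
               lax = acceptLax(g, cfg) && rule,
               n_positive = length(pos),
               markers = paste(sort(mk), collapse = ","),
               total_reads = sum(g@counts, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(sample = character(0), species = character(0),
                      stringent = logical(0), lax = logical(0),
                      n_positive = integer(0), markers = character(0),
                      total_reads = numeric(0), stringsAsFactors = FALSE)
  out
}

#' Per-species detection summary
#'
#' One row per species with the number of accepted detections under each
#' criterion, the change column (lax minus stringent) and a totals row
#' computed from the per-species sums. Accepts either detection calls
#' (logical \code{stringent}/\code{lax} columns, counted per species) or
#' an already-counted table (numeric columns, e.g.
#' \code{\link{exampleDetections}}; NA cells are parsed as 0).
#'
#' @param x detection calls or per-species count table.
#' @return data.frame species, stringent, lax, change + "Total" row.
#' @export
speciesSummary <- function(x) {
  if (nrow(x) == 0L) {
    out <- data.frame(species = "Total", stringent = 0, lax = 0,
                      change = 0, stringsAsFactors = FALSE)
    return(out)
  }
  if (is.logical(x$stringent)) {
    agg <- do.call(rbind, lapply(split(x, x$species), function(s)
      data.frame(species = s$species[1], stringent = sum(s$stringent),
                 lax = sum(s$lax), stringsAsFactors = FALSE)))
  } else {
    agg <- data.frame(species = x$species,
                      stringent = ifelse(is.na(x$stringent), 0,
                                         x$stringent),
                      lax = ifelse(is.na(x$lax), 0, x$lax),
                      stringsAsFactors = FALSE)
  }
  agg <- agg[order(agg$species), , drop = FALSE]
  agg$change <- agg$lax - agg$stringent
  tot <- data.frame(species = "Total", stringent = sum(agg$stringent),
                    lax = sum(agg$lax), change = sum(agg$change),
                    stringsAsFactors = FALSE)
  out <- rbind(agg, tot)
  rownames(out) <- NULL
  out
}

#' Closed-form acceptance probability
#'
#' Probability that a species truly amplifying with per-PCR detection
#' probability \code{p} is accepted, under the full 6 + 6 replicate
#' design: stringent \eqn{(1-(1-p)^{n_A})(1-(1-p)^{n_B})}; lax
#' \eqn{1-(1-p)^N - N p (1-p)^{N-1}} with \eqn{N = n_A + n_B}.
#'
#' @param p per-PCR detection probability (vectorised).
#' @param criterion "stringent" or "lax".
#' @param nA,nB replicates per extraction replicate (default 6 each).
#' @return numeric vector of acceptance probabilities.
#' @export
acceptanceProbability <- function(p, criterion = c("stringent", "lax"),
                                  nA = 6L, nB = 6L) {
  criterion <- match.arg(criterion)
  stopifnot(all(p >= 0 & p <= 1))
  if (criterion == "stringent") {
    (1 - (1 - p)^nA) * (1 - (1 - p)^nB)
  } else {
    N <- nA + nB
    1 - (1 - p)^N - N * p * (1 - p)^(N - 1)
  }
}

#' Acceptance probability by exhaustive enumeration
#'
#' Sums the probability of every positivity pattern of the \code{nA + nB}
#' replicate cells that the criterion accepts; the independent oracle for
#' the closed forms.
#'
#' @inheritParams acceptanceProbability
#' @return numeric vector of acceptance probabilities.
#' @export
enumerateAcceptance <- function(p, criterion = c("stringent", "lax"),
                                nA = 6L, nB = 6L) {
  criterion <- match.arg(criterion)
  N <- nA + nB
  pat <- as.matrix(expand.grid(rep(list(0:1), N)))
  acc <- if (criterion == "stringent")
    rowSums(pat[, seq_len(nA), drop = FALSE]) >= 1 &
      rowSums(pat[, nA + seq_len(nB), drop = FALSE]) >= 1
  else rowSums(pat) >= 2
  s <- rowSums(pat)
  vapply(p, function(pp)
    sum((pp^s * (1 - pp)^(N - s))[acc]), 0)
}

#' Monte-Carlo error-rate curves
#'
#' Simulates replicate grids at each true-detection probability in
#' \code{pDetect} (and false-amplification probability \code{pFalse}) and
#' reports, per criterion, the acceptance probability, the false-negative
#' rate (1 - acceptance when truly present) and the false-positive rate
#' (acceptance when truly absent), together with the closed-form values.
#'
#' @param pDetect numeric vector of per-PCR detection probabilities.
#' @param pFalse per-PCR false-amplification probability (default 0.05).
#' @param reps Monte-Carlo replicates per point (default 1e5).
#' @param seed RNG seed.
#' @param nA,nB design as in \code{\link{acceptanceProbability}}.
#' @return data.frame: p, criterion, acceptance, fn_rate, fp_rate,
#'   acceptance_closed, fp_closed, mc_se, method.
#' @export
simulateErrorRates <- function(pDetect, pFalse = 0.05, reps = 1e5L,
                               seed = 1L, nA = 6L, nB = 6L) {
  set.seed(seed)
  N <- nA + nB
  accept <- function(pat, criterion) {
    if (criterion == "stringent")
      rowSums(pat[, seq_len(nA), drop = FALSE]) >= 1 &
        rowSums(pat[, nA + seq_len(nB), drop = FALSE]) >= 1
    else rowSums(pat) >= 2
  }
  fpPat <- matrix(rbinom(reps * N, 1L, pFalse), reps, N)
  rows <- list()
  for (p in pDetect) {
    pat <- matrix(rbinom(reps * N, 1L, p), reps, N)
    for (cr in c("stringent", "lax")) {
      acc <- mean(accept(pat, cr))
      fp <- mean(accept(fpPat, cr))
      rows[[length(rows) + 1L]] <- data.frame(
        p = p, criterion = cr, acceptance = acc, fn_rate = 1 - acc,
        fp_rate = fp,
        acceptance_closed = acceptanceProbability(p, cr, nA, nB),
        fp_closed = acceptanceProbability(pFalse, cr, nA, nB),
        mc_se = sqrt(acc * (1 - acc) / reps),
        method = "monte_carlo", stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
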