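#' TagSet: a set of fixed-length sample/plate tags
#'
#' An S4 container for one level of a twin-tag scheme: an ordered set of
#' fixed-length nucleotide tags, one label per tag, an optional subset of
#' reserved labels (never assigned to samples, e.g. a control tag), and the
#' minimum pairwise Hamming distance the set is declared to satisfy.
#'
#' Validity requires all tags to have equal length, an A/C/G/T alphabet,
#' distinct sequences, and a minimum pairwise Hamming distance of at least
#' \code{dMin}. With \code{dMin >= 2*m + 1} every observed tag resolves to at
#' most one set member within \code{m} mismatches, so mismatch-tolerant
#' demultiplexing is unambiguous.
#'
#' @slot tags character vector of tag sequences, named by label.
#' @slot reserved character vector of reserved labels.
#' @slot dMin integer, declared minimum pairwise Hamming distance.
#' @export
setClass("TagSet", representation(
  tags = "character",
  reserved = "character",
  dMin = "integer"
))

setValidity("TagSet", function(object) {
  t <- object@tags
  if (length(t) < 1L) return("at least one tag required")
  if (is.null(names(t)) || anyNA(names(t)) || any(names(t) == ""))
    return("every tag must be labelled")
  if (anyDuplicated(names(t))) return("tag labels must be unique")
  if (length(unique(nchar(t))) != 1L) return("all tags must have equal length")
  if (any(grepl("[^ACGT]", t))) return("tags must contain only A,C,G,T")
  if (anyDuplicated(t)) return("duplicate tag sequences")
  if (!all(object@reserved %in% names(t)))
    return("reserved labels must be tag labels")
  if (length(t) >= 2L) {
    dmin <- minPairwiseDistance(t)
    if (dmin < object@dMin)
      return(sprintf("minimum pairwise distance %d < declared dMin %d",
                     dmin, object@dMin))
  }
  TRUE
})

#' Construct a TagSet
#'
#' @param tags character vector of equal-length A/C/G/T tag sequences.
#' @param labels one identifier per tag; defaults to \code{names(tags)}.
#' @param reserved labels excluded from sample assignment.
#' @param dMin declared minimum pairwise Hamming distance (default 3).
#' @return a validated \code{TagSet}.
#' @examples
#' ts <- tagSet(c(A = "TGCAT", B = "TCAGC"), dMin = 3)
#' @export
tagSet <- function(tags, labels = names(tags), reserved = character(0),
                   dMin = 3L) {
  force(labels)
  tags <- as.character(tags)
  names(tags) <- labels
  new("TagSet", tags = tags, reserved = as.character(reserved),
      dMin = as.integer(dMin))
}

setMethod("show", "TagSet", function(object) {
  cat(sprintf("TagSet of %d tags (length %d, dMin %d, %d reserved)\n",
              length(object@tags), nchar(object@tags[1]), object@dMin,
              length(object@reserved)))
})

#' @rdname tagSet
#' @param x a \code{TagSet}.
#' @export
tagSequences <- function(x) x@tags

#' @rdname tagSet
#' @export
tagLabels <- function(x) names(x@tags)

#' @rdname tagSet
#' @export
reservedLabels <- function(x) x@reserved

#' @rdname tagSet
#' @export
tagLength <- function(x) nchar(x@tags[[1]])

#' Hamming distance between two equal-length sequences
#'
#' @param a,b sequences of equal length.
#' @return integer count of mismatching positions.
#' @examples
#' hammingDistance("TGCAT", "TCAGC")  # 4
#' @export
hammingDistance <- function(a, b) {
  stopifnot_scalar_string(a, "a"); stopifnot_scalar_string(b, "b")
  if (nchar(a) != nchar(b))
    stop("hammingDistance: sequences have unequal lengths (", nchar(a),
         " vs ", nchar(b), ")", call. = FALSE)
  as.integer(.hamming1(a, b))
}

minPairwiseDistance <- function(tags) {
  raws <- lapply(tags, charToRaw)
  n <- length(raws)
  dmin <- nchar(tags[[1]])
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- sum(raws[[i]] != raws[[j]])
    if (d < dmin) dmin <- d
  }
  as.integer(dmin)
}

#' Validate a tag set against a minimum pairwise distance
#'
#' Computes the minimum Hamming distance over all unordered tag pairs and
#' raises an error when it falls below \code{dMin} (or when tags are
#' duplicated).
#'
#' @param ts a \code{TagSet} or a named character vector of tags.
#' @param dMin required minimum pairwise distance.
#' @return the minimum pairwise distance, invisibly validated.
#' @export
validateTagSet <- function(ts, dMin = 3L) {
  tags <- if (is(ts, "TagSet")) ts@tags else as.character(ts)
  if (length(tags) < 2L) stop("need at least 2 tags", call. = FALSE)
  if (anyDuplicated(tags)) stop("duplicate tag sequences", call. = FALSE)
  dmin <- minPairwiseDistance(tags)
  if (dmin < dMin)
    stop(sprintf("minimum pairwise distance %d is below required %d",
                 dmin, dMin), call. = FALSE)
  dmin
}

## Precompute the <=maxMismatch neighbourhood of every tag as a named lookup
## vector: neighbour sequence -> label. Distinct spheres are guaranteed when
## dMin >= 2*maxMismatch + 1; a collision therefore signals an invalid set.
tagIndex <- function(ts, maxMismatch = 1L) {
  tags <- ts@tags
  k <- nchar(tags[[1]])
  if (maxMismatch > (ts@dMin - 1L) %/% 2L)
    stop("maxMismatch ", maxMismatch, " is too large for dMin ", ts@dMin,
         ": assignment would be ambiguous", call. = FALSE)
  keys <- tags
  vals <- names(tags)
  if (maxMismatch >= 1L) {
    bases <- c("A", "C", "G", "T")
    for (i in seq_along(tags)) {
      tg <- strsplit(tags[[i]], "")[[1]]
      for (pos in seq_len(k)) for (b in bases[bases != tg[pos]]) {
        v <- tg; v[pos] <- b
        keys <- c(keys, paste(v, collapse = ""))
        vals <- c(vals, names(tags)[i])
      }
    }
  }
  if (anyDuplicated(keys)) {
    dup <- keys[duplicated(keys)][1]
    stop("ambiguous tag neighbourhoods (e.g. ", dup,
         "): tag set violates its distance invariant", call. = FALSE)
  }
  setNames(vals, keys)
}

#' Resolve an observed tag to a label
#'
#' Exact-then-mismatch lookup against a precomputed neighbourhood index.
#' Returns \code{NA} for tags that do not resolve within \code{maxMismatch}.
#'
#' @param observed character vector of observed tag sequences.
#' @param ts a \code{TagSet}.
#' @param maxMismatch maximum tolerated mismatches (default 1).
#' @return character vector of labels, \code{NA} where unassigned.
#' @export
matchTag <- function(observed, ts, maxMismatch = 1L) {
  idx <- tagIndex(ts, maxMismatch)
  unname(idx[observed])
}

#' Classify an observed forward/reverse tag pair
#'
#' Twin-tagged constructs carry the same tag on both mates; a resolvable
#' pair with differing labels is a tag jump, and a pair with an unresolvable
#' member is unassigned.
#'
#' @param fwdObs,revObs observed tag sequences (vectors of equal length).
#' @param ts a \code{TagSet}.
#' @param maxMismatch maximum tolerated mismatches per tag.
#' @return data.frame with columns \code{category} (twin/jump/unassigned),
#'   \code{label} (twin label or NA), \code{label_fwd}, \code{label_rev}.
#' @export
classifyTagPair <- function(fwdObs, revObs, ts, maxMismatch = 1L) {
  idx <- tagIndex(ts, maxMismatch)
  lf <- unname(idx[fwdObs])
  lr <- unname(idx[revObs])
  cat_ <- ifelse(is.na(lf) | is.na(lr), "unassigned",
                 ifelse(lf == lr, "twin", "jump"))
  data.frame(category = cat_,
             label = ifelse(cat_ == "twin", lf, NA_character_),
             label_fwd = lf, label_rev = lr,
             stringsAsFactors = FALSE)
}

#' TwinTagScheme: the full demultiplexing contract
#'
#' Couples the plate-level tag set (Tag 2, attached in the second PCR
#' round), the sample-level tag set (Tag 1, attached in the first round),
#' the marker amplicon definitions and the sample sheet mapping
#' (tag2 label, tag1 label, marker) to sample identifiers.
#'
#' @slot tag1 sample-level \code{TagSet}.
#' @slot tag2 plate/PCR-level \code{TagSet}.
#' @slot markers named list of \code{AmpliconDef}.
#' @slot sampleSheet data.frame with columns tag2_label, tag1_label, marker,
#'   sample_id (and optionally run).
#' @slot maxMismatch integer, per-tag mismatch tolerance.
#' @export
setClass("TwinTagScheme", representation(
  tag1 = "TagSet",
  tag2 = "TagSet",
  markers = "list",
  sampleSheet = "data.frame",
  maxMismatch = "integer"
))

setValidity("TwinTagScheme", function(object) {
  sh <- object@sampleSheet
  need <- c("tag2_label", "tag1_label", "marker", "sample_id")
  if (!all(need %in% names(sh)))
    return(paste("sample sheet must have columns",
                 paste(need, collapse = ", ")))
  if (!all(sh$tag1_label %in% tagLabels(object@tag1)))
    return("sample sheet references unknown Tag 1 labels")
  if (!all(sh$tag2_label %in% tagLabels(object@tag2)))
    return("sample sheet references unknown Tag 2 labels")
  if (any(sh$tag1_label %in% reservedLabels(object@tag1)))
    return("reserved Tag 1 labels must not be mapped to samples")
  if (length(object@markers) &&
      !all(sh$marker %in% names(object@markers)))
    return("sample sheet references unknown markers")
  for (ts in list(object@tag1, object@tag2))
    if (object@maxMismatch > (ts@dMin - 1L) %/% 2L)
      return("maxMismatch too large for tag set distance: ambiguous")
  key <- paste(sh$tag2_label, sh$tag1_label, sh$marker)
  if (anyDuplicated(key)) return("duplicate (tag2, tag1, marker) keys")
  TRUE
})

#' Construct a TwinTagScheme
#'
#' @param tag1 sample-level \code{TagSet} (first-round twin tags).
#' @param tag2 plate-level \code{TagSet} (second-round twin tags).
#' @param markers named list of \code{AmpliconDef} objects.
#' @param sampleSheet data.frame with columns tag2_label, tag1_label,
#'   marker, sample_id.
#' @param maxMismatch per-tag mismatch tolerance (default 1).
#' @return a validated \code{TwinTagScheme}.
#' @export
twinTagScheme <- function(tag1, tag2, markers = list(),
                          sampleSheet, maxMismatch = 1L) {
  sampleSheet <- as.data.frame(sampleSheet, stringsAsFactors = FALSE)
  new("TwinTagScheme", tag1 = tag1, tag2 = tag2, markers = markers,
      sampleSheet = sampleSheet, maxMismatch = as.integer(maxMismatch))
}

setMethod("show", "TwinTagScheme", function(object) {
  cat(sprintf(paste0("TwinTagScheme: %d Tag 1 (%d reserved) x %d Tag 2,",
                     " %d markers, %d sheet entries, capacity %d\n"),
              length(object@tag1@tags), length(object@tag1@reserved),
              length(object@tag2@tags), length(object@markers),
              nrow(object@sampleSheet), schemeCapacity(object)))
})

#' Sample capacity of a twin-tag scheme
#'
#' Usable Tag 1 count (excluding reserved labels) times the Tag 2 count:
#' the number of samples distinguishable in one pooled library preparation.
#'
#' @param scheme a \code{TwinTagScheme}.
#' @return integer capacity.
#' @export
schemeCapacity <- function(scheme) {
  n1 <- length(scheme@tag1@tags) - length(scheme@tag1@reserved)
  n1 * length(scheme@tag2@tags)
}
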