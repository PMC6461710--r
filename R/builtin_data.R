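#' The 25 printed sample-level twin tags (Tag 1)
#'
#' The published 5-nt sample tags used in the first PCR round of the
#' twin-tag scheme, one of which ("Tag Control") is reserved for controls
#' and never assigned to samples. The set has a minimum pairwise Hamming
#' distance of 3, so single-mismatch demultiplexing is unambiguous.
#'
#' @return a \code{TagSet} of 25 tags with "Tag Control" reserved.
#' @export
tag1TagSet <- function() {
  tags <- c(
    `Tag A` = "TGCAT", `Tag B` = "TCAGC", `Tag C` = "AAGCG",
    `Tag D` = "ACAAG", `Tag E` = "AGTGG", `Tag F` = "TTGAC",
    `Tag G` = "CCTAT", `Tag H` = "GGATG", `Tag I` = "CTAGG",
    `Tag K` = "CACCT", `Tag L` = "GTCAA", `Tag M` = "GAAGT",
    `Tag N` = "CGGTT", `Tag O` = "ACCGA", `Tag P` = "ACGTC",
    `Tag Q` = "AGACT", `Tag R` = "AGGAA", `Tag S` = "ATTCC",
    `Tag T` = "CAATC", `Tag V` = "CATGA", `Tag W` = "CCACA",
    `Tag X` = "GCTTA", `Tag Y` = "GGTAC", `Tag Z` = "AACAC",
    `Tag Control` = "ATCTG"
  )
  tagSet(tags, reserved = "Tag Control", dMin = 3L)
}

#' A default plate-level tag set (Tag 2)
#'
#' The plate-level tags of the original scheme are user-supplied and not
#' part of the published tag list; this accessor ships a documented default
#' of 20 synthetic 5-nt tags with minimum pairwise Hamming distance 3 so a
#' complete 24 x 20 = 480-sample scheme can be assembled out of the box.
#'
#' @return a \code{TagSet} of 20 tags, none reserved.
#' @export
tag2DefaultTagSet <- function() {
  tags <- c(
    P01 = "CGGAC", P02 = "GACTC", P03 = "GCGCG", P04 = "CAATG",
    P05 = "GTAAT", P06 = "CGCTA", P07 = "TCAGC", P08 = "GTGGC",
    P09 = "GGTAG", P10 = "GATGT", P11 = "TCGAT", P12 = "ACCAG",
    P13 = "TCTTA", P14 = "ATGCT", P15 = "TTCAC", P16 = "TTGTG",
    P17 = "AGTCC", P18 = "TGGGA", P19 = "CCAAA", P20 = "AAGTA"
  )
  tagSet(tags, reserved = character(0), dMin = 3L)
}

#' Bundled per-run demultiplexing accounting data
#'
#' Read accounting for the eight MiSeq runs of a large leech-iDNA tetrapod
#' screening campaign, as raw counts: total read pairs, reads with
#' matching (twin) and non-matching (jumped) Tag 2 pairs, and -- within the
#' Tag 2 twins -- reads with matching, non-matching and unidentifiable
#' Tag 1 pairs. The "IndexRun" row is a pooled-before-second-PCR experiment
#' whose Tag 2 demultiplexing was handled upstream (NA counts) and which is
#' excluded from the totals row; its tag-jump rate (>40%) is why pooling
#' before the second PCR round was abandoned. Feed to
#' \code{\link{demuxStatsTable}} to recompute the percentage columns.
#'
#' @return data.frame with one row per run and an \code{in_total} flag.
#' @export
exampleRunCounts <- function() {
  df <- data.frame(
    run = c("SeqRun01", "SeqRun02", "SeqRun03", "SeqRun04", "SeqRun05",
            "SeqRun06", "SeqRun07", "IndexRun"),
    total = c(18438517, 25385558, 14875796, 2027794, 18221504,
              20718202, 24604610, 10276093),
    tag2_twin = c(18102702, 24596380, 14393884, 1935149, 17500366,
                  19874913, 23746938, 10116808),
    tag2_jump = c(282419, 626245, 343528, 56077, 421588,
                  429048, 663730, NA),
    tag1_twin = c(17514515, 23426084, 13766187, 1806655, 16793851,
                  19317305, 22446187, 5841190),
    tag1_jump = c(451028, 612045, 426181, 88307, 482365,
                  371048, 497366, 4186688),
    tag1_unassigned = c(137159, 558251, 201516, 40187, 161458,
                        81422, 803385, 88930),
    in_total = c(rep(TRUE, 7), FALSE),
    stringsAsFactors = FALSE
  )
  df$tag2_unassigned <- df$total - df$tag2_twin - df$tag2_jump
  df
}

#' Bundled per-species detection counts under both acceptance criteria
#'
#' Accepted species assignments from the same leech-iDNA screening
#' campaign: the number of samples in which each vertebrate species was
#' accepted under the stringent criterion (positive in both extraction
#' replicates) and under the lax criterion (any two positive PCR
#' replicates). Blank cells of the source table are parsed as 0. Note that
#' the totals printed in the source (162/190) disagree by one with the
#' per-species column sums (163/191); \code{\link{speciesSummary}} reports
#' the computed sums.
#'
#' @return data.frame with columns species, stringent, lax.
#' @export
exampleDetections <- function() {
  data.frame(
    species = c(
      "Aonyx cinereus", "Arctictis binturong", "Bos javanicus",
      "Echinosorex gymnura", "Felis catus", "Helarctos malayanus",
      "Hemigalus derbyanus", "Hystrix brachyura",
      "Kalophrynus pleurostigma", "Macaca fascicularis",
      "Macaca nemestrina", "Macaca sp.", "Manis javanica",
      "Muntiacus atherodes", "Muntiacus muntjak", "Muntiacus sp.",
      "Mydaus javanensis", "Pongo pygmaeus", "Rusa unicolor",
      "Sus barbatus", "Tragulus javanicus", "Tragulus napu",
      "Trichys fasciculata", "Viverra tangalunga"),
    stringent = c(1, 1, 9, 5, 2, 5, 3, 4, 1, 0, 1, 0, 2, 6, 2, 10, 0, 5,
                  59, 17, 4, 10, 5, 11),
    lax = c(1, 1, 11, 6, 2, 6, 3, 5, 1, 1, 2, 3, 2, 6, 2, 10, 2, 5,
            67, 22, 6, 11, 5, 11),
    stringsAsFactors = FALSE
  )
}

#' Default full-capacity twin-tag scheme
#'
#' Assembles the printed Tag 1 set, the default Tag 2 set and the standard
#' marker definitions into a ready-to-use scheme. A sample sheet covering
#' the requested markers and plates is generated with systematic sample
#' identifiers unless one is supplied.
#'
#' @param markers marker names to include (default "16S").
#' @param nPlates number of Tag 2 plates to lay out (default 1).
#' @param sampleSheet optional explicit sample sheet.
#' @param maxMismatch per-tag mismatch tolerance (default 1).
#' @return a \code{TwinTagScheme}.
#' @export
defaultScheme <- function(markers = "16S", nPlates = 1L,
                          sampleSheet = NULL, maxMismatch = 1L) {
  t1 <- tag1TagSet()
  t2 <- tag2DefaultTagSet()
  defs <- markerAmplicons(markers)
  if (is.null(sampleSheet)) {
    usable <- setdiff(tagLabels(t1), reservedLabels(t1))
    plates <- tagLabels(t2)[seq_len(nPlates)]
    sampleSheet <- expand.grid(tag1_label = usable, tag2_label = plates,
                               marker = markers,
                               stringsAsFactors = FALSE)
    sampleSheet$sample_id <- sprintf(
      "S%s.%02d.%s", sampleSheet$tag2_label,
      match(sampleSheet$tag1_label, usable), sampleSheet$marker)
  }
  twinTagScheme(t1, t2, defs, sampleSheet, maxMismatch)
}
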