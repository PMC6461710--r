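#' Read a pair of FASTQ files into a read-pair data.frame
#'
#' @param file1,file2 paths to the forward and reverse FASTQ (optionally
#'   gzipped).
#' @return read-pair data.frame (see \code{\link{readPairs}}).
#' @export
readFastqPair <- function(file1, file2) {
  f <- Biostrings::readDNAStringSet(file1, format = "fastq",
                                    with.qualities = TRUE)
  r <- Biostrings::readDNAStringSet(file2, format = "fastq",
                                    with.qualities = TRUE)
  if (length(f) != length(r)) stop("mate files differ in read count")
  readPairs(sub(" .*", "", names(f)),
            as.character(f), as.character(r),
            as.character(S4Vectors::mcols(f)$qualities),
            as.character(S4Vectors::mcols(r)$qualities))
}

#' Write a read-pair data.frame as paired FASTQ
#'
#' @param reads read-pair data.frame.
#' @param file1,file2 output paths.
#' @return invisibly, the two paths.
#' @export
writeFastqPair <- function(reads, file1, file2) {
  wr <- function(seqs, quals, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(
      x, path, format = "fastq",
      qualities = Biostrings::BStringSet(quals))
  }
  wr(reads$seq_fwd, reads$qual_fwd, reads$id, file1)
  wr(reads$seq_rev, reads$qual_rev, reads$id, file2)
  invisible(c(file1, file2))
}

#' Write dereplicated inserts as size-annotated FASTA
#'
#' Headers follow the widely parsed \code{id;size=N} convention.
#'
#' @param derep data.frame with columns seq, size.
#' @param file output path.
#' @param idPrefix header prefix.
#' @return invisibly, the path.
#' @export
writeSizeFasta <- function(derep, file, idPrefix = "uniq") {
  x <- Biostrings::DNAStringSet(derep$seq)
  names(x) <- sprintf("%s%04d;size=%d", idPrefix, seq_len(nrow(derep)),
                      derep$size)
  Biostrings::writeXStringSet(x, file)
  invisible(file)
}

#' Read a size-annotated FASTA
#'
#' @param file path to a \code{;size=N} FASTA.
#' @return data.frame with columns id, seq, size.
#' @export
readSizeFasta <- function(file) {
  x <- Biostrings::readDNAStringSet(file)
  size <- suppressWarnings(
    as.integer(sub(".*;size=([0-9]+).*", "\\1", names(x))))
  data.frame(id = sub(";size=.*", "", names(x)),
             seq = as.character(x),
             size = ifelse(is.na(size), 1L, size),
             stringsAsFactors = FALSE)
}

#' Read a reference FASTA with Species_name_Accession headers
#'
#' @param file FASTA path.
#' @param marker marker name recorded in the db.
#' @param source provenance tag.
#' @return reference data.frame (see \code{\link{referenceDb}}).
#' @export
readReferenceFasta <- function(file, marker = "16S", source = "local") {
  x <- Biostrings::readDNAStringSet(file)
  referenceDb(names(x), as.character(x), marker, source)
}

#' Write a reference data.frame as FASTA
#'
#' @param db reference data.frame.
#' @param file output path.
#' @return invisibly, the path.
#' @export
writeReferenceFasta <- function(db, file) {
  x <- Biostrings::DNAStringSet(db$seq)
  names(x) <- refHeaders(db)
  Biostrings::writeXStringSet(x, file)
  invisible(file)
}

#' Read/write the flat tab-separated tables of the workflow
#'
#' Taxonomy tables (species, genus, family, order, class), synonym tables
#' (old_label, accepted_label), sample sheets (tag2_label, tag1_label,
#' marker, sample_id) and generic report tables are all plain TSV.
#'
#' @param file path.
#' @return data.frame.
#' @export
readTsv <- function(file) read.delim(file, stringsAsFactors = FALSE)

#' @rdname readTsv
#' @param x data.frame to write.
#' @return invisibly, the path.
#' @export
writeTsv <- function(x, file) {
  write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a tag-set configuration TSV
#'
#' Columns: label, sequence, and optionally reserved (TRUE/FALSE).
#'
#' @param file path.
#' @param dMin declared minimum pairwise distance.
#' @return a \code{TagSet}.
#' @export
readTagSetTsv <- function(file, dMin = 3L) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  reserved <- if ("reserved" %in% names(df))
    df$label[as.logical(df$reserved)] else character(0)
  tagSet(setNames(df$sequence, df$label), reserved = reserved,
         dMin = dMin)
}
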