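#' Reference databases
#'
#' Reference sequences travel as plain data.frames with columns
#' \code{accession}, \code{species} (underscored binomial label),
#' \code{marker}, \code{seq} and \code{source}; headers round-trip as
#' \code{Species_name_Accession}. This constructor parses such headers.
#'
#' @param headers character vector of \code{Genus_species_Accession}
#'   headers (the accession is the final underscore-separated token).
#' @param seqs sequences, same length as \code{headers}.
#' @param marker marker name.
#' @param source provenance tag (default "local").
#' @return reference data.frame.
#' @export
referenceDb <- function(headers, seqs, marker = "16S", source = "local") {
  parts <- strsplit(headers, "_", fixed = TRUE)
  acc <- vapply(parts, function(p) p[length(p)], "")
  sp <- vapply(parts, function(p) paste(p[-length(p)], collapse = "_"), "")
  data.frame(accession = acc, species = sp, marker = marker,
             seq = toupper(as.character(seqs)), source = source,
             stringsAsFactors = FALSE)
}

#' @rdname referenceDb
#' @param db a reference data.frame.
#' @export
refHeaders <- function(db) paste(db$species, db$accession, sep = "_")

.badTokens <- c("sp", "sp.", "cf", "cf.", "aff", "aff.")

#' Filter species labels to clean binomials
#'
#' Discards records whose label is not a clean binomial -- single-word
#' names, open nomenclature ("sp.", "cf.", "aff.") and labels containing
#' numerals -- and truncates trinomial (subspecies) labels to binomials.
#'
#' @param db reference data.frame.
#' @return list \code{kept} (relabelled db) and \code{discarded}
#'   (data.frame accession, species, reason).
#' @export
filterSpeciesLabels <- function(db) {
  toks <- strsplit(db$species, "_", fixed = TRUE)
  nt <- lengths(toks)
  bad <- vapply(toks, function(t)
    any(tolower(t) %in% .badTokens), TRUE)
  hasNum <- grepl("[0-9]", db$species)
  discard <- nt < 2L | bad | hasNum
  reason <- ifelse(nt < 2L, "not_binomial",
                   ifelse(bad, "open_nomenclature",
                          ifelse(hasNum, "numeral", NA)))
  kept <- db[!discard, , drop = FALSE]
  tok2 <- strsplit(kept$species, "_", fixed = TRUE)
  kept$species <- vapply(tok2, function(t)
    paste(t[1:2], collapse = "_"), "")
  rownames(kept) <- NULL
  list(kept = kept,
       discarded = data.frame(accession = db$accession[discard],
                              species = db$species[discard],
                              reason = reason[discard],
                              stringsAsFactors = FALSE))
}

#' Merge a primary and a supplementary reference set
#'
#' Accession-level union; on duplicated accessions the primary record wins.
#'
#' @param primary,extra reference data.frames.
#' @return merged reference data.frame.
#' @export
mergeSources <- function(primary, extra) {
  if (is.null(extra) || nrow(extra) == 0L) return(primary)
  out <- rbind(primary, extra[!extra$accession %in% primary$accession, ,
                              drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Amplicon extraction, primer stage
#'
#' Records in which both primer sites are found (substitutions only, up to
#' \code{maxMismatchPerPrimer} each) are trimmed to the insert between
#' them; all other records are passed to the similarity stage.
#'
#' @param db reference data.frame.
#' @param adef an \code{AmpliconDef}.
#' @param maxMismatchPerPrimer mismatch allowance per primer (default 2).
#' @return list \code{trimmed} and \code{remainder}.
#' @export
extractAmpliconPrimerStage <- function(db, adef, maxMismatchPerPrimer = 2L) {
  hit <- logical(nrow(db))
  ins <- character(nrow(db))
  fp <- adef@fwdPrimer
  rp <- revComp(adef@revPrimer)
  for (i in seq_len(nrow(db))) {
    f <- .findPrimer(db$seq[i], fp, maxMismatchPerPrimer)
    if (is.null(f)) next
    r <- .findPrimer(db$seq[i], rp, maxMismatchPerPrimer, fromEnd = TRUE)
    if (is.null(r) || r[1] <= f[2]) next
    hit[i] <- TRUE
    ins[i] <- substr(db$seq[i], f[2] + 1L, r[1] - 1L)
  }
  trimmed <- db[hit, , drop = FALSE]
  trimmed$seq <- ins[hit]
  rownames(trimmed) <- NULL
  list(trimmed = trimmed, remainder = db[!hit, , drop = FALSE])
}

#' Amplicon extraction, similarity stage
#'
#' Each remainder record is locally aligned against the primer-stage
#' inserts (match +1, mismatch -1, gap -2); when the best local alignment
#' covers at least \code{minLengthFrac} of the expected amplicon length,
#' the aligned subsequence is extracted, otherwise the record is discarded.
#'
#' @param remainder reference data.frame from the primer stage.
#' @param trimmedRefs primer-stage inserts used as alignment references.
#' @param adef an \code{AmpliconDef}.
#' @param maxRefs align against at most this many references (best hit
#'   reported; default all, deterministically ordered by accession).
#' @return list \code{recovered} (trimmed records) and \code{discarded}.
#' @export
extractAmpliconSimilarityStage <- function(remainder, trimmedRefs, adef,
                                           maxRefs = Inf) {
  if (nrow(trimmedRefs) == 0L) {
    ## no primer-bearing record anywhere: the input is judged already
    ## amplicon-trimmed (e.g. re-curation of a curated set) and records
    ## conforming to the amplicon length window pass through unchanged
    minLen <- ceiling(adef@minLengthFrac * adef@expectedLength)
    maxLen <- ceiling(1.1 * adef@expectedLength)
    ok <- nchar(remainder$seq) >= minLen & nchar(remainder$seq) <= maxLen
    if (any(!ok) || nrow(remainder) == 0L)
      warning("no primer-stage references: ", sum(!ok),
              " non-conforming records discarded")
    return(list(recovered = remainder[ok, , drop = FALSE],
                discarded = remainder[!ok, , drop = FALSE]))
  }
  ## ambiguity-free references only: the base-only scoring matrix is
  ## defined over A,C,G,T, and ambiguous records are discarded downstream
  refs <- trimmedRefs[!grepl("[^ACGT]", trimmedRefs$seq), , drop = FALSE]
  refs <- refs[order(refs$accession), , drop = FALSE]
  refs <- refs[seq_len(min(nrow(refs), maxRefs)), , drop = FALSE]
  if (nrow(refs) == 0L) {
    warning("similarity stage skipped: no unambiguous references")
    return(list(recovered = remainder[0, , drop = FALSE],
                discarded = remainder))
  }
  refSet <- Biostrings::DNAStringSet(refs$seq)
  minLen <- ceiling(adef@minLengthFrac * adef@expectedLength)
  keep <- logical(nrow(remainder))
  ins <- character(nrow(remainder))
  for (i in seq_len(nrow(remainder))) {
    if (grepl("[^ACGT]", remainder$seq[i])) next
    aln <- Biostrings::pairwiseAlignment(
      refSet, remainder$seq[i], type = "local",
      substitutionMatrix = .submat(), gapOpening = 0, gapExtension = 2)
    sc <- Biostrings::score(aln)
    b <- which.max(sc)
    subj <- Biostrings::subject(aln[b])
    s <- Biostrings::start(subj); e <- Biostrings::end(subj)
    if (e - s + 1L >= minLen) {
      keep[i] <- TRUE
      ins[i] <- substr(remainder$seq[i], s, e)
    }
  }
  recovered <- remainder[keep, , drop = FALSE]
  recovered$seq <- ins[keep]
  rownames(recovered) <- NULL
  list(recovered = recovered,
       discarded = remainder[!keep, , drop = FALSE])
}

## single-linkage connected components of an identity matrix at a
## threshold; returns integer component id per row
.singleLinkage <- function(idm, minIdentity) {
  n <- nrow(idm)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (idm[i, j] >= minIdentity && comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

## most basal rank at which the lineages of records i and j disagree
.conflictRank <- function(sub, i, j) {
  for (r in c("order", "family", "genus", "species"))
    if (sub[[r]][i] != sub[[r]][j]) return(r)
  "species"
}

.submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = TRUE)
}

#' Discard sequences with ambiguity codes
#'
#' @param db reference data.frame.
#' @return list \code{kept} and \code{discarded}.
#' @export
removeAmbiguous <- function(db) {
  amb <- grepl("[^ACGT]", db$seq)
  list(kept = db[!amb, , drop = FALSE],
       discarded = db[amb, , drop = FALSE])
}

#' Reconcile sequence labels against a reference taxonomy
#'
#' Labels found in the taxonomy keep their lineage (status
#' \code{accepted}). Labels found in the synonym table are relabelled to
#' the accepted name (status \code{synonym}; the original label is kept in
#' \code{original_label}). Unknown species whose genus exists in the
#' taxonomy are grafted in, borrowing the genus's higher ranks (status
#' \code{grafted}). Everything else is withheld on the orphan list.
#'
#' @param db reference data.frame.
#' @param taxonomy data.frame with columns species, genus, family, order,
#'   class (species as underscored binomials).
#' @param synonyms optional data.frame with columns old_label,
#'   accepted_label.
#' @return list \code{db} (with lineage + status columns), \code{taxonomy}
#'   (possibly extended by grafted species), \code{orphans} (withheld
#'   records).
#' @export
reconcileTaxonomy <- function(db, taxonomy, synonyms = NULL) {
  db$original_label <- db$species
  if (!is.null(synonyms) && nrow(synonyms)) {
    i <- match(db$species, synonyms$old_label)
    isSyn <- !is.na(i)
    db$species[isSyn] <- synonyms$accepted_label[i[isSyn]]
  } else isSyn <- rep(FALSE, nrow(db))
  ti <- match(db$species, taxonomy$species)
  known <- !is.na(ti)
  status <- ifelse(known & isSyn, "synonym",
                   ifelse(known, "accepted", NA))

  genusOf <- function(sp) vapply(strsplit(sp, "_", fixed = TRUE),
                                 `[`, "", 1L)
  unk <- which(!known)
  graftRows <- list()
  for (i in unk) {
    g <- genusOf(db$species[i])
    j <- which(taxonomy$genus == g)[1]
    if (!is.na(j)) {
      status[i] <- "grafted"
      if (!db$species[i] %in% vapply(graftRows, `[[`, "", "species"))
        graftRows[[length(graftRows) + 1L]] <-
          data.frame(species = db$species[i], genus = g,
                     family = taxonomy$family[j],
                     order = taxonomy$order[j],
                     class = taxonomy$class[j],
                     stringsAsFactors = FALSE)
    }
  }
  if (length(graftRows))
    taxonomy <- rbind(taxonomy, do.call(rbind, graftRows))
  ti <- match(db$species, taxonomy$species)
  resolved <- !is.na(status)
  out <- db[resolved, , drop = FALSE]
  tio <- ti[resolved]
  out$genus <- taxonomy$genus[tio]
  out$family <- taxonomy$family[tio]
  out$order <- taxonomy$order[tio]
  out$class <- taxonomy$class[tio]
  out$status <- status[resolved]
  rownames(out) <- NULL
  list(db = out, taxonomy = taxonomy,
       orphans = db[!resolved, , drop = FALSE])
}

#' Pairwise identity matrix of a sequence set
#'
#' Identity is the number of matching columns of the best local alignment
#' (match +1 / mismatch -1 / gap -2) divided by the length of the longer
#' sequence. Normalising by sequence length rather than by alignment
#' columns penalises short local hits, so divergent sequences score low
#' (a short perfect seed in two unrelated sequences does not masquerade
#' as high identity) while near-identical sequences still approach 1.
#' For sets of equal-length sequences a fast Hamming identity
#' (matches / length) is used, which coincides with the alignment
#' identity for the ungapped geometry such sets imply.
#'
#' @param seqs character vector of sequences.
#' @param method "auto", "hamming" or "alignment".
#' @return symmetric numeric identity matrix in [0, 1].
#' @export
pairwiseIdentity <- function(seqs, method = c("auto", "hamming",
                                              "alignment")) {
  method <- match.arg(method)
  n <- length(seqs)
  if (method == "auto")
    method <- if (length(unique(nchar(seqs))) == 1L) "hamming"
              else "alignment"
  m <- diag(1, n)
  if (n < 2L) return(m)
  if (method == "hamming") {
    raws <- lapply(seqs, charToRaw)
    L <- nchar(seqs[[1]])
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      m[i, j] <- m[j, i] <- sum(raws[[i]] == raws[[j]]) / L
  } else {
    set <- Biostrings::DNAStringSet(seqs)
    len <- nchar(seqs)
    for (i in seq_len(n - 1L)) {
      aln <- Biostrings::pairwiseAlignment(
        set[(i + 1L):n], set[[i]], type = "local",
        substitutionMatrix = .submat(), gapOpening = 0, gapExtension = 2)
      ident <- Biostrings::nmatch(aln) / pmax(len[(i + 1L):n], len[i])
      m[i, (i + 1L):n] <- m[(i + 1L):n, i] <- ident
    }
  }
  m
}

#' Flag putatively mislabelled references by neighbourhood consensus
#'
#' Leave-one-out k-nearest-neighbour screen: for every record the k most
#' similar other records (pairwise identity) vote at each rank, from order
#' down to species; when a consensus supported by at least
#' \code{minAgreement} of the neighbours disagrees with the record's own
#' taxon, the record is flagged at that rank (the most basal conflicting
#' rank) with the consensus lineage as the suggestion. Only neighbours
#' with identity of at least \code{minIdentity} are eligible to vote: a
#' label conflict is only evidence of mislabelling when the sequence sits
#' inside another taxon's cluster, and sole representatives of genuinely
#' novel species, far from every cluster, must not inherit a neighbour
#' consensus. Records with fewer than k eligible neighbours are left
#' unflagged. When a record has between 3 and k eligible neighbours, all
#' of them vote (clusters thinned by upstream filtering are still
#' screened); with fewer than 3 the evidence is judged insufficient.
#'
#' The screen iterates to a fixed point: records flagged in one round are
#' removed from the voter pool and the remaining records are re-screened,
#' so several mislabelled sequences sitting in the same cluster cannot
#' shield one another by voting for their shared wrong label.
#'
#' A second, cluster-level rule supplies the evidence a phylogenetic
#' label screen draws from non-monophyly: sequences are grouped into
#' single-linkage components at \code{minIdentity}, and records whose
#' label has its majority in a different component (a minority faction of
#' that label embedded in a cluster led by another species) are flagged
#' with the host cluster's leading label, even when colluding neighbours
#' defeat the local vote. Flags from both rules are merged.
#'
#' @param db reconciled reference data.frame (lineage columns present).
#' @param k number of neighbours (default 5).
#' @param minAgreement consensus support threshold (default 0.8).
#' @param minIdentity minimum identity for a neighbour to vote
#'   (default 0.9).
#' @param method similarity backend for \code{\link{pairwiseIdentity}}.
#' @return list \code{flags} (data.frame accession, species, rank,
#'   suggested lineage columns, confidence) and \code{rankCounts}.
#' @export
detectMislabels <- function(db, k = 5L, minAgreement = 0.8,
                            minIdentity = 0.9, method = "auto") {
  ranks <- c("order", "family", "genus", "species")
  flags <- list()
  for (mk in unique(db$marker)) {
    sub <- db[db$marker == mk, , drop = FALSE]
    if (nrow(sub) < k + 1L) {
      warning("marker ", mk, ": fewer than k+1 records, skipped")
      next
    }
    idm <- pairwiseIdentity(sub$seq, method)
    diag(idm) <- -Inf
    active <- rep(TRUE, nrow(sub))
    repeat {
      newFlags <- list()
      for (i in which(active)) {
        elig <- which(active & idm[i, ] >= minIdentity)
        if (length(elig) < 3L) next
        kEff <- min(k, length(elig))
        nb <- elig[order(idm[i, elig], decreasing = TRUE)][seq_len(kEff)]
        for (r in ranks) {
          tab <- sort(table(sub[[r]][nb]), decreasing = TRUE)
          support <- tab[1] / kEff
          cons <- names(tab)[1]
          if (support >= minAgreement && cons != sub[[r]][i]) {
            donor <- nb[sub[[r]][nb] == cons][1]
            newFlags[[length(newFlags) + 1L]] <- data.frame(
              accession = sub$accession[i], marker = mk,
              species = sub$species[i], rank = r,
              suggested_species = sub$species[donor],
              suggested_genus = sub$genus[donor],
              suggested_family = sub$family[donor],
              suggested_order = sub$order[donor],
              confidence = as.numeric(support),
              stringsAsFactors = FALSE)
            break
          }
          ## an agreeing consensus at this rank anchors the lineage;
          ## only look deeper among records that agree so far
          if (support >= minAgreement) next else break
        }
      }
      if (!length(newFlags)) break
      flags <- c(flags, newFlags)
      flaggedAcc <- vapply(newFlags, `[[`, "", "accession")
      active[sub$accession %in% flaggedAcc] <- FALSE
    }
    ## cluster-level minority-faction rule
    comp <- .singleLinkage(idm, minIdentity)
    labelTotals <- table(sub$species)
    for (cmp in split(seq_len(nrow(sub)), comp)) {
      labs <- table(sub$species[cmp])
      if (length(labs) < 2L) next
      ## the lead label is the one anchored in this component: largest
      ## fraction of its global records here, ties by local count
      inFracs <- vapply(names(labs), function(L)
        labs[[L]] / labelTotals[[L]], 0)
      ord <- order(-inFracs, -as.vector(labs), names(labs))
      lead <- names(labs)[ord[1]]
      for (L in setdiff(names(labs), lead)) {
        inFrac <- labs[[L]] / labelTotals[[L]]
        domFrac <- labs[[lead]] / length(cmp)
        if (inFrac <= 0.5 || domFrac >= minAgreement) {
          idx <- cmp[sub$species[cmp] == L]
          donor <- cmp[sub$species[cmp] == lead][1]
          for (i in idx) flags[[length(flags) + 1L]] <- data.frame(
            accession = sub$accession[i], marker = mk,
            species = sub$species[i], rank = .conflictRank(sub, i, donor),
            suggested_species = sub$species[donor],
            suggested_genus = sub$genus[donor],
            suggested_family = sub$family[donor],
            suggested_order = sub$order[donor],
            confidence = as.numeric(max(domFrac, 1 - inFrac)),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(flags)) {
    flags <- do.call(rbind, flags)
    flags <- flags[!duplicated(paste(flags$accession, flags$marker)), ,
                   drop = FALSE]
    rownames(flags) <- NULL
  }
  flags <- if (is.data.frame(flags)) flags
           else data.frame(accession = character(0), marker = character(0),
                           species = character(0), rank = character(0),
                           suggested_species = character(0),
                           suggested_genus = character(0),
                           suggested_family = character(0),
                           suggested_order = character(0),
                           confidence = numeric(0),
                           stringsAsFactors = FALSE)
  counts <- vapply(c("species", "genus", "family", "order"),
                   function(r) sum(flags$rank == r), 0L)
  list(flags = flags, rankCounts = counts)
}

#' Collapse identical haplotypes within species
#'
#' Per species and marker, exactly identical sequences collapse to a single
#' representative (zero differences allowed; unequal lengths never
#' collapse); the representative is the record with the lexicographically
#' smallest accession in its haplotype group. Sole representatives of a
#' species pass through automatically.
#'
#' @param db reference data.frame.
#' @return dereplicated reference data.frame.
#' @export
dereplicateHaplotypes <- function(db) {
  if (nrow(db) == 0L) return(db)
  key <- paste(db$species, db$marker, db$seq, sep = "\r")
  ord <- order(key, db$accession)
  db <- db[ord, , drop = FALSE]
  keep <- !duplicated(key[ord])
  out <- db[keep, , drop = FALSE]
  out <- out[order(out$marker, out$species, out$accession), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full curation chain on a raw reference set
#'
#' Chains the curation steps: species-label filtering, merging of
#' supplementary sequences, two-stage amplicon extraction, ambiguity
#' removal, taxonomy reconciliation, neighbourhood mislabel screening
#' (flagged records are discarded unless on the keep-list; relabel-list
#' entries are applied first), and within-species haplotype dereplication.
#' Every step appends to the curation log.
#'
#' @param db raw reference data.frame (headers already parsed).
#' @param taxonomy taxonomy data.frame (species, genus, family, order,
#'   class).
#' @param adef an \code{AmpliconDef}.
#' @param synonyms optional synonym table (old_label, accepted_label).
#' @param extra optional supplementary reference data.frame.
#' @param keepList accessions never discarded by the mislabel screen.
#' @param relabel optional data.frame (accession, species) of manual
#'   corrections applied before the mislabel screen.
#' @param k,minAgreement,similarityMethod mislabel-screen parameters.
#' @param maxMismatchPerPrimer primer-stage allowance.
#' @return list with \code{db} (final curated set), \code{taxonomy},
#'   \code{log} (per-step counts), \code{flags}, \code{orphans},
#'   \code{discards} (per-step discard records).
#' @export
curateReferenceDb <- function(db, taxonomy, adef, synonyms = NULL,
                              extra = NULL, keepList = character(0),
                              relabel = NULL, k = 5L, minAgreement = 0.8,
                              similarityMethod = "auto",
                              maxMismatchPerPrimer = 2L) {
  log <- data.frame(step = character(0), n_in = integer(0),
                    n_out = integer(0), stringsAsFactors = FALSE)
  note <- function(step, nIn, nOut)
    rbind(log, data.frame(step = step, n_in = nIn, n_out = nOut,
                          stringsAsFactors = FALSE))
  discards <- list()

  n0 <- nrow(db)
  fl <- filterSpeciesLabels(db)
  db <- fl$kept; discards$labels <- fl$discarded
  log <- note("label_filter", n0, nrow(db))

  n0 <- nrow(db)
  db <- mergeSources(db, extra)
  log <- note("add_extra", n0, nrow(db))

  n0 <- nrow(db)
  st1 <- extractAmpliconPrimerStage(db, adef, maxMismatchPerPrimer)
  st2 <- extractAmpliconSimilarityStage(st1$remainder, st1$trimmed, adef)
  db <- rbind(st1$trimmed, st2$recovered)
  discards$amplicon <- st2$discarded
  log <- note("amplicon_trim", n0, nrow(db))

  n0 <- nrow(db)
  shortLen <- !filterLength(db$seq, adef)
  discards$short <- db[shortLen, , drop = FALSE]
  db <- db[!shortLen, , drop = FALSE]
  amb <- removeAmbiguous(db)
  db <- amb$kept; discards$ambiguous <- amb$discarded
  log <- note("ambiguity_filter", n0, nrow(db))

  n0 <- nrow(db)
  rec <- reconcileTaxonomy(db, taxonomy, synonyms)
  db <- rec$db; taxonomy <- rec$taxonomy
  log <- note("taxonomy_reconcile", n0, nrow(db))

  if (!is.null(relabel) && nrow(relabel)) {
    i <- match(db$accession, relabel$accession)
    hit <- !is.na(i)
    db$species[hit] <- relabel$species[i[hit]]
    ti <- match(db$species, taxonomy$species)
    for (cc in c("genus", "family", "order", "class"))
      db[[cc]][hit] <- taxonomy[[cc]][ti[hit]]
  }

  n0 <- nrow(db)
  ml <- detectMislabels(db, k, minAgreement, method = similarityMethod)
  drop <- setdiff(ml$flags$accession, keepList)
  discards$mislabels <- db[db$accession %in% drop, , drop = FALSE]
  db <- db[!db$accession %in% drop, , drop = FALSE]
  log <- note("mislabel_screen", n0, nrow(db))

  n0 <- nrow(db)
  db <- dereplicateHaplotypes(db)
  log <- note("haplotype_derep", n0, nrow(db))

  log$loss_pct <- pct1(log$n_in - log$n_out, log$n_in)
  list(db = db, taxonomy = taxonomy, log = log, flags = ml$flags,
       orphans = rec$orphans, discards = discards)
}

#' Summaries of a curation run
#'
#' @param curated result of \code{\link{curateReferenceDb}}.
#' @return list with \code{losses} (per-step loss table),
#'   \code{haplotypesPerSpecies} (species x marker haplotype counts) and
#'   \code{coverage} (species in db vs species in taxonomy, per marker).
#' @export
curationReport <- function(curated) {
  db <- curated$db
  hps <- if (nrow(db)) as.data.frame(table(species = db$species,
                                           marker = db$marker),
                                     stringsAsFactors = FALSE)
         else data.frame(species = character(0), marker = character(0),
                         Freq = integer(0))
  hps <- hps[hps$Freq > 0, , drop = FALSE]
  names(hps)[3] <- "haplotypes"
  nTax <- nrow(curated$taxonomy)
  cov <- if (nrow(db))
    do.call(rbind, lapply(split(db, db$marker), function(s)
      data.frame(marker = s$marker[1],
                 species_covered = length(unique(s$species)),
                 species_total = nTax,
                 coverage_pct = pct1(length(unique(s$species)), nTax),
                 stringsAsFactors = FALSE)))
  else data.frame(marker = character(0), species_covered = integer(0),
                  species_total = integer(0), coverage_pct = numeric(0))
  rownames(cov) <- NULL
  list(losses = curated$log, haplotypesPerSpecies = hps, coverage = cov)
}
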