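#' Fixture specification
#'
#' Bundles every knob of the synthetic-data generator: taxonomy shape,
#' haplotype structure, divergences, planted-anomaly rates and read-set
#' parameters. Identical seeds give identical outputs. The defaults
#' emulate the statistical structure the workflow assumes: well-separated
#' species (expected inter-species divergence far above 10%) with tight
#' intra-species clusters (at most 1% divergence), GenBank-style
#' redundancy (several accessions per species sharing few haplotypes),
#' skewed per-species read counts, constant Q35 qualities and
#' substitution-only sequencing errors.
#'
#' @param seed RNG seed.
#' @param nOrders,familiesPerOrder,generaPerFamily,speciesPerGenus
#'   taxonomy shape (defaults 3, 2, 2, 3 = 36 species).
#' @param seqsPerSpecies reference accessions per species (default 8).
#' @param haplotypesPerSpecies distinct haplotypes per species
#'   (default 3).
#' @param intraDivergence per-site mutation rate within species
#'   (default 0.005, keeping intra-species divergence at or below 1%).
#' @param interDivergence per-site divergence of each species from its
#'   genus ancestor (default 0.2, giving pairwise inter-species
#'   divergence well above 10%).
#' @param subspeciesRate,ambiguityRate,synonymRate,mislabelRate,
#'   shortFragmentRate,graftRate,orphanRate planted-anomaly rates.
#' @param readsPerPcr reads per PCR replicate in read-set fixtures.
#' @param errorRate per-base substitution error rate of synthetic reads.
#' @param tagJumpRate fraction of reads given crossed Tag 1 pairs.
#' @param pDetect,pFalse per-PCR detection/false-amplification
#'   probabilities for replicate-grid fixtures.
#' @param speciesPerSample species mixed into each sample.
#' @param dirichletConcentration concentration of the per-sample species
#'   mix (small = skewed).
#' @return fixture spec list.
#' @export
fixtureSpec <- function(seed = 1L, nOrders = 3L, familiesPerOrder = 2L,
                        generaPerFamily = 2L, speciesPerGenus = 3L,
                        seqsPerSpecies = 8L, haplotypesPerSpecies = 3L,
                        intraDivergence = 0.005, interDivergence = 0.2,
                        subspeciesRate = 0, ambiguityRate = 0,
                        synonymRate = 0, mislabelRate = 0,
                        shortFragmentRate = 0, graftRate = 0,
                        orphanRate = 0, readsPerPcr = 500L,
                        errorRate = 0, tagJumpRate = 0,
                        pDetect = 0.8, pFalse = 0.01,
                        speciesPerSample = 3L,
                        dirichletConcentration = 1) {
  stopifnot(intraDivergence < interDivergence,
            all(c(subspeciesRate, ambiguityRate, synonymRate,
                  mislabelRate, shortFragmentRate, graftRate, orphanRate,
                  errorRate, tagJumpRate, pDetect, pFalse) >= 0),
            all(c(errorRate, tagJumpRate, pDetect, pFalse) <= 1))
  as.list(environment())
}

.lettersCode <- function(i) {
  ## deterministic two-letter code: 1 -> "aa", 2 -> "ab", ...
  i <- i - 1L
  paste0(letters[i %/% 26L + 1L], letters[i %% 26L + 1L])
}

#' Generate a balanced synthetic taxonomy
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @return taxonomy data.frame (species, genus, family, order, class)
#'   with clean binomial species labels.
#' @export
makeTaxonomy <- function(spec) {
  nSpecies <- spec$nOrders * spec$familiesPerOrder *
    spec$generaPerFamily * spec$speciesPerGenus
  if (nSpecies < 1L) stop("taxonomy shape yields zero species")
  rows <- list()
  gi <- 0L
  for (o in seq_len(spec$nOrders)) for (f in seq_len(spec$familiesPerOrder))
    for (g in seq_len(spec$generaPerFamily)) {
      gi <- gi + 1L
      genus <- paste0("Gen", .lettersCode(gi))
      for (s in seq_len(spec$speciesPerGenus))
        rows[[length(rows) + 1L]] <- data.frame(
          species = paste0(genus, "_tax", .lettersCode(s)),
          genus = genus,
          family = paste0("Fam", .lettersCode((o - 1L) *
                            spec$familiesPerOrder + f)),
          order = paste0("Ord", .lettersCode(o)),
          class = "Mammalia", stringsAsFactors = FALSE)
    }
  do.call(rbind, rows)
}

.randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

.mutate <- function(seq, rate, ambig = FALSE) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- if (ambig) "N" else sample(setdiff(c("A", "C", "G", "T"),
                                                ch[i]), 1)
  }
  paste(ch, collapse = "")
}

## substitute at exactly n positions (haplotype simulation: keeps the
## intra-species divergence bounded instead of Bernoulli-tailed)
.mutateN <- function(seq, n) {
  if (n <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  for (i in sample.int(length(ch), n)) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  }
  paste(ch, collapse = "")
}

#' Generate a reference database with planted anomalies
#'
#' Per species, haplotypes are simulated around a genus ancestor
#' (inter-species divergence) with tight within-species variation, then
#' embedded in primer context (random flanks + forward primer + insert +
#' reverse-complemented reverse primer) so both amplicon-extraction stages
#' are exercised; a fraction of records is emitted primerless (insert
#' only, 5' truncated) to exercise the similarity stage. Anomalies --
#' subspecies labels, ambiguity codes, synonym labels, cluster-
#' inconsistent mislabels, short fragments, graftable novel species and
#' orphan labels -- are planted at the spec rates and recorded in the
#' manifest together with the expected curated outcome.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param taxonomy taxonomy from \code{\link{makeTaxonomy}}.
#' @param adef marker \code{AmpliconDef}.
#' @param primerlessRate fraction of clean records emitted without primer
#'   context (default 0.1).
#' @return list with \code{db} (raw reference data.frame), \code{manifest}
#'   (per-accession ground truth), \code{synonyms} (synonym table),
#'   \code{haplotypes} (species -> distinct clean haplotype inserts).
#' @export
makeReferenceDb <- function(spec, taxonomy, adef, primerlessRate = 0.1) {
  set.seed(spec$seed)
  L <- adef@expectedLength
  fp <- adef@fwdPrimer
  rpc <- revComp(adef@revPrimer)
  genera <- unique(taxonomy$genus)
  ancestors <- setNames(lapply(genera, function(g) .randSeq(L)), genera)
  recs <- list(); mani <- list(); syns <- list()
  haps <- list()
  acc <- 0L
  nextAcc <- function() { acc <<- acc + 1L; sprintf("SYN%05d", acc) }
  embed <- function(insert) paste0(.randSeq(20L), fp, insert, rpc,
                                   .randSeq(20L))
  for (si in seq_len(nrow(taxonomy))) {
    sp <- taxonomy$species[si]
    base <- .mutate(ancestors[[taxonomy$genus[si]]],
                    spec$interDivergence)
    nMut <- max(1L, round(spec$intraDivergence * L))
    hp <- vapply(seq_len(spec$haplotypesPerSpecies), function(h)
      if (h == 1L) base else .mutateN(base, nMut), "")
    hp <- unique(hp)
    haps[[sp]] <- hp
    for (k in seq_len(spec$seqsPerSpecies)) {
      a <- nextAcc()
      insert <- hp[((k - 1L) %% length(hp)) + 1L]
      label <- sp
      anomaly <- "none"
      u <- runif(1)
      if (u < spec$mislabelRate) {
        ## sequence stays, label swapped to a congener (cluster-
        ## inconsistent at species rank) when one exists
        cong <- setdiff(taxonomy$species[taxonomy$genus ==
                                           taxonomy$genus[si]], sp)
        if (length(cong)) { label <- cong[1]; anomaly <- "mislabel" }
      } else if (u < spec$mislabelRate + spec$subspeciesRate) {
        label <- paste0(sp, "_ssp", .lettersCode(k))
        anomaly <- "subspecies"
      } else if (u < spec$mislabelRate + spec$subspeciesRate +
                 spec$synonymRate) {
        old <- paste0("Oldgen", .lettersCode(si), "_vet",
                      .lettersCode(k))
        syns[[length(syns) + 1L]] <- data.frame(
          old_label = old, accepted_label = sp, stringsAsFactors = FALSE)
        label <- old
        anomaly <- "synonym"
      } else if (u < spec$mislabelRate + spec$subspeciesRate +
                 spec$synonymRate + spec$ambiguityRate) {
        insert <- sub("[ACGT]", "N", insert)
        anomaly <- "ambiguity"
      } else if (u < spec$mislabelRate + spec$subspeciesRate +
                 spec$synonymRate + spec$ambiguityRate +
                 spec$shortFragmentRate) {
        insert <- substr(insert, 1L, floor(0.8 * L))
        anomaly <- "short"
      }
      primerless <- anomaly == "none" && runif(1) < primerlessRate
      if (primerless) {
        ## truncated, primer-free record: the similarity stage should
        ## recover exactly this subsequence
        insert <- substr(insert, sample(2:5, 1), nchar(insert))
        anomaly <- "primerless"
      }
      seqFull <- if (primerless) insert else embed(insert)
      recs[[length(recs) + 1L]] <- data.frame(
        accession = a, species = label, marker = adef@marker,
        seq = seqFull, source = "synthetic", stringsAsFactors = FALSE)
      mani[[length(mani) + 1L]] <- data.frame(
        accession = a, true_species = sp, label = label,
        anomaly = anomaly, insert = insert, stringsAsFactors = FALSE)
    }
  }
  ## graftable novel species: genus exists, species absent from taxonomy
  if (spec$graftRate > 0) {
    nGraft <- max(1L, round(spec$graftRate * nrow(taxonomy)))
    for (g in seq_len(nGraft)) {
      genus <- genera[((g - 1L) %% length(genera)) + 1L]
      sp <- paste0(genus, "_nov", .lettersCode(g))
      insert <- .mutate(ancestors[[genus]], spec$interDivergence)
      a <- nextAcc()
      recs[[length(recs) + 1L]] <- data.frame(
        accession = a, species = sp, marker = adef@marker,
        seq = embed(insert), source = "synthetic",
        stringsAsFactors = FALSE)
      mani[[length(mani) + 1L]] <- data.frame(
        accession = a, true_species = sp, label = sp, anomaly = "graft",
        insert = insert, stringsAsFactors = FALSE)
      haps[[sp]] <- insert
    }
  }
  ## orphans: neither species nor genus known to the taxonomy
  if (spec$orphanRate > 0) {
    nOrph <- max(1L, round(spec$orphanRate * nrow(taxonomy)))
    for (g in seq_len(nOrph)) {
      sp <- paste0("Zzygen", .lettersCode(g), "_ignota")
      a <- nextAcc()
      recs[[length(recs) + 1L]] <- data.frame(
        accession = a, species = sp, marker = adef@marker,
        seq = embed(.randSeq(L)), source = "synthetic",
        stringsAsFactors = FALSE)
      mani[[length(mani) + 1L]] <- data.frame(
        accession = a, true_species = NA_character_, label = sp,
        anomaly = "orphan", insert = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  list(db = do.call(rbind, recs), manifest = do.call(rbind, mani),
       synonyms = if (length(syns)) do.call(rbind, syns)
                  else data.frame(old_label = character(0),
                                  accepted_label = character(0),
                                  stringsAsFactors = FALSE),
       haplotypes = haps)
}

#' Generate a twin-tagged synthetic sequencing run
#'
#' Builds paired reads with the library layout the demultiplexer expects
#' (Tag 2 + Tag 1 + marker primer + insert on each mate, identical twin
#' tags on both mates), drawing each read's species from a skewed
#' per-sample mix over the fixture haplotypes. A stated fraction of reads
#' receives a crossed Tag 1 pair on the reverse mate (tag jump);
#' sequencing errors are substitutions at \code{errorRate}; qualities are
#' constant Q35. The truth table maps every read to its (sample, species,
#' jump) ground truth.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param scheme a \code{TwinTagScheme} (single marker).
#' @param haplotypes species -> insert haplotypes (from
#'   \code{\link{makeReferenceDb}}).
#' @param nReads total reads to generate.
#' @param readLength mate length (default 250; reads are truncated to
#'   this length).
#' @return list \code{reads} (read-pair data.frame) and \code{truth}
#'   (data.frame id, sample, species, tag2, tag1, jump).
#' @export
makeTaggedRun <- function(spec, scheme, haplotypes,
                          nReads = 1000L, readLength = 250L) {
  set.seed(spec$seed)
  sh <- scheme@sampleSheet
  marker <- sh$marker[1]
  adef <- scheme@markers[[marker]]
  t1 <- tagSequences(scheme@tag1)
  t2 <- tagSequences(scheme@tag2)
  spp <- names(haplotypes)
  ## per-sample skewed species mix
  mixes <- lapply(seq_len(nrow(sh)), function(i) {
    ms <- sample(spp, min(spec$speciesPerSample, length(spp)))
    w <- rgamma(length(ms), spec$dirichletConcentration)
    setNames(w / sum(w), ms)
  })
  rowIdx <- sample.int(nrow(sh), nReads, replace = TRUE)
  ids <- sprintf("read%06d", seq_len(nReads))
  truth <- data.frame(id = ids, sample = sh$sample_id[rowIdx],
                      species = NA_character_,
                      tag2 = sh$tag2_label[rowIdx],
                      tag1 = sh$tag1_label[rowIdx],
                      jump = runif(nReads) < spec$tagJumpRate,
                      stringsAsFactors = FALSE)
  usable <- setdiff(tagLabels(scheme@tag1), reservedLabels(scheme@tag1))
  ## species per read, drawn group-wise from each sample's mix
  for (g in split(seq_len(nReads), rowIdx)) {
    mix <- mixes[[rowIdx[g[1]]]]
    truth$species[g] <- sample(names(mix), length(g), replace = TRUE,
                               prob = mix)
  }
  ## haplotype per read, drawn group-wise per species
  insert <- character(nReads)
  for (g in split(seq_len(nReads), truth$species)) {
    hp <- haplotypes[[truth$species[g[1]]]]
    insert[g] <- hp[sample.int(length(hp), length(g), replace = TRUE)]
  }
  frag <- paste0(adef@fwdPrimer, insert, revComp(adef@revPrimer))
  tag1f <- unname(t1[truth$tag1])
  tag1r <- tag1f
  nj <- sum(truth$jump)
  if (nj) tag1r[truth$jump] <- unname(t1[vapply(
    which(truth$jump), function(i)
      sample(setdiff(usable, truth$tag1[i]), 1), "")])
  f <- paste0(unname(t2[truth$tag2]), tag1f, frag)
  r <- paste0(unname(t2[truth$tag2]), tag1r, revComp(frag))
  if (spec$errorRate > 0) {
    f <- vapply(f, .mutate, "", rate = spec$errorRate, USE.NAMES = FALSE)
    r <- vapply(r, .mutate, "", rate = spec$errorRate, USE.NAMES = FALSE)
  }
  list(reads = readPairs(ids, substr(f, 1L, readLength),
                         substr(r, 1L, readLength)),
       truth = truth)
}

#' Generate replicate grids with known detection probabilities
#'
#' For each truly present sample x species pair every one of the 12 cells
#' is positive independently with probability \code{pDetect}; species
#' absent from a sample turn positive with probability \code{pFalse}.
#' Positive cells draw a read count of at least the positive-cell
#' threshold (10 + Poisson-like noise via a geometric tail).
#'
#' @param presence data.frame with columns sample, species, present
#'   (logical).
#' @param pDetect,pFalse per-PCR probabilities.
#' @param seed RNG seed.
#' @param markers marker names.
#' @return list of \code{ReplicateGrid}.
#' @export
makeReplicateGrid <- function(presence, pDetect, pFalse = 0, seed = 1L,
                              markers = c("12S", "16S", "CytB")) {
  set.seed(seed)
  cells <- replicateCells(markers)
  lapply(seq_len(nrow(presence)), function(i) {
    p <- if (presence$present[i]) pDetect else pFalse
    pos <- rbinom(12L, 1L, p) == 1L
    counts <- setNames(ifelse(pos, 10 + rbinom(12L, 200L, 0.3), 0),
                       cells)
    replicateGrid(presence$sample[i], presence$species[i], counts,
                  markers)
  })
}
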