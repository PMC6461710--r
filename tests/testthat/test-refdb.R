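test_that("species labels are filtered to clean binomials", {
  db <- referenceDb(c("Panthera_pardus_AB123456",
                      "Panthera_sp._AB000001",
                      "Muntiacus_muntjak_vaginalis_X1",
                      "Gorilla_cf._beringei_Y2",
                      "Felis_B2_Z9",
                      "Incertae_A1"),
                    rep(strrep("ACGT", 25), 6))
  fl <- filterSpeciesLabels(db)
  expect_identical(fl$kept$accession, c("AB123456", "X1"))
  expect_identical(fl$kept$species[fl$kept$accession == "X1"],
                   "Muntiacus_muntjak")
  expect_setequal(fl$discarded$reason,
                  c("open_nomenclature", "numeral", "not_binomial"))
})

test_that("source merging deduplicates at accession level, primary wins", {
  a <- referenceDb("Pana_alpha_A1", "ACGT")
  b <- referenceDb(c("Pana_alpha_A1", "Pana_beta_B1"), c("TTTT", "GGGG"))
  m <- mergeSources(a, b)
  expect_identical(nrow(m), 2L)
  expect_identical(m$seq[m$accession == "A1"], "ACGT")
  expect_identical(mergeSources(a, NULL), a)
  expect_identical(nrow(mergeSources(a, b[0, ])), 1L)
})

test_that("amplicon extraction trims primer-bearing records and recovers the rest by similarity", {
  ad <- ad16S()
  ins <- vapply(1:6, function(i) seqOf(93L, 400 + i), "")
  withPrimers <- paste0("GG", ad@fwdPrimer, ins, revComp(ad@revPrimer),
                        "AA")
  db <- referenceDb(sprintf("Pana_alpha_P%02d", 1:6), withPrimers)
  # a record missing the primer regions entirely, but matching insert 1
  frag <- substr(ins[1], 3, 93)
  db2 <- rbind(db, referenceDb(c("Pana_beta_Q1", "Pana_beta_Q2"),
                               c(frag, seqOf(93L, 999))))
  st1 <- extractAmpliconPrimerStage(db2, ad)
  expect_identical(st1$trimmed$seq, ins)
  expect_identical(st1$remainder$accession, c("Q1", "Q2"))
  st2 <- extractAmpliconSimilarityStage(st1$remainder, st1$trimmed, ad)
  expect_identical(st2$recovered$accession, "Q1")
  expect_identical(st2$recovered$seq, frag)  # recovered identically
  expect_identical(st2$discarded$accession, "Q2")
  # one primer mismatch within the allowance still trims
  mm <- mutateAt(withPrimers[1], 4L,
                 if (substr(withPrimers[1], 4, 4) == "C") "G" else "C")
  stMM <- extractAmpliconPrimerStage(referenceDb("Pana_alpha_M1", mm),
                                     ad, maxMismatchPerPrimer = 2L)
  expect_identical(stMM$trimmed$seq, ins[1])
})

test_that("ambiguity codes are discarded", {
  db <- referenceDb(c("Pana_alpha_A1", "Pana_alpha_A2", "Pana_alpha_A3"),
                    c("ACGT", "ACNGT", "ACRGT"))
  ra <- removeAmbiguous(db)
  expect_identical(ra$kept$accession, "A1")
  expect_identical(ra$discarded$accession, c("A2", "A3"))
})

test_that("taxonomy reconciliation relabels synonyms, grafts novel congeners and withholds orphans", {
  tax <- toyTaxonomy()
  syn <- data.frame(old_label = "Felis_bengalensis",
                    accepted_label = "Pana_alpha",
                    stringsAsFactors = FALSE)
  db <- referenceDb(c("Pana_alpha_A1", "Felis_bengalensis_S1",
                      "Lutra_nova_G1", "Zzyzxus_nullus_O1"),
                    rep("ACGT", 4))
  rec <- reconcileTaxonomy(db, tax, syn)
  expect_identical(rec$db$status,
                   c("accepted", "synonym", "grafted"))
  expect_identical(rec$db$species[rec$db$accession == "S1"],
                   "Pana_alpha")
  expect_identical(rec$db$original_label[rec$db$accession == "S1"],
                   "Felis_bengalensis")
  graft <- rec$db[rec$db$accession == "G1", ]
  expect_identical(graft$family, "Lutridae")
  expect_true("Lutra_nova" %in% rec$taxonomy$species)
  expect_identical(rec$orphans$accession, "O1")
})

test_that("a record planted inside a foreign cluster is flagged at species rank", {
  tax <- toyTaxonomy()
  ins <- seqOf(93L, 50)
  # ten tight conspecific sequences of Pana_alpha
  cluster <- vapply(1:10, function(i)
    mutateAt(ins, i, if (substr(ins, i, i) == "A") "C" else "A"), "")
  db <- referenceDb(c(sprintf("Pana_alpha_C%02d", 1:10),
                      "Pana_beta_BAD1",
                      sprintf("Lutra_gamma_L%02d", 1:6)),
                    c(cluster, ins,
                      vapply(1:6, function(i)
                        mutateAt(seqOf(93L, 60), i, "A"), "")))
  rec <- reconcileTaxonomy(db, tax)
  ml <- detectMislabels(rec$db)
  expect_identical(ml$flags$accession, "BAD1")
  expect_identical(ml$flags$rank, "species")
  expect_identical(ml$flags$suggested_species, "Pana_alpha")
  expect_identical(unname(ml$rankCounts["species"]), 1L)
})

test_that("clean and ambiguous-evidence databases yield no flags", {
  spec <- fixtureSpec(seed = 61)
  tax <- makeTaxonomy(spec)
  ref <- makeReferenceDb(spec, tax, ad16S(), primerlessRate = 0)
  cur <- curateReferenceDb(ref$db, tax, ad16S())
  expect_identical(nrow(cur$flags), 0L)
  # a record far from every cluster (novel lineage) is not flagged
  tax2 <- toyTaxonomy()
  db <- referenceDb(c(sprintf("Pana_alpha_C%02d", 1:6), "Lutra_gamma_F1"),
                    c(vapply(1:6, function(i)
                      mutateAt(seqOf(93L, 70), i, "A"), ""),
                      seqOf(93L, 80)))
  ml <- detectMislabels(reconcileTaxonomy(db, tax2)$db)
  expect_identical(nrow(ml$flags), 0L)
})

test_that("haplotype dereplication is per species with smallest-accession representatives", {
  db <- referenceDb(c("Pana_alpha_A3", "Pana_alpha_A1", "Pana_alpha_A2",
                      "Pana_beta_B1", "Lutra_gamma_G1"),
                    c("AAAA", "AAAA", "TTTT", "CCCC", "CCCC"))
  d <- dereplicateHaplotypes(db)
  # species with {s1,s1,s2} keeps 2 representatives
  expect_identical(sum(d$species == "Pana_alpha"), 2L)
  expect_true("A1" %in% d$accession && !"A3" %in% d$accession)
  # sole representatives pass through; identical sequences in different
  # species are both retained
  expect_true(all(c("B1", "G1") %in% d$accession))
})

test_that("curation removes exactly the planted anomalies and is idempotent", {
  ad <- ad16S()
  spec <- fixtureSpec(seed = 23, subspeciesRate = 0.05,
                      ambiguityRate = 0.05, synonymRate = 0.05,
                      mislabelRate = 0.05, shortFragmentRate = 0.03,
                      graftRate = 0.05, orphanRate = 0.03)
  tax <- makeTaxonomy(spec)
  ref <- makeReferenceDb(spec, tax, ad)
  cur <- suppressWarnings(
    curateReferenceDb(ref$db, tax, ad, synonyms = ref$synonyms))
  m <- ref$manifest
  expect_setequal(cur$flags$accession,
                  m$accession[m$anomaly == "mislabel"])
  expect_setequal(cur$discards$ambiguous$accession,
                  m$accession[m$anomaly == "ambiguity"])
  expect_setequal(cur$discards$short$accession,
                  m$accession[m$anomaly == "short"])
  expect_setequal(cur$orphans$accession,
                  m$accession[m$anomaly == "orphan"])
  # synonyms relabelled to accepted names
  synAcc <- m$accession[m$anomaly == "synonym"]
  expect_identical(cur$db$species[match(intersect(synAcc,
                                                  cur$db$accession),
                                        cur$db$accession)],
                   m$true_species[match(intersect(synAcc,
                                                  cur$db$accession),
                                        m$accession)])
  # final database: exactly the distinct planted haplotypes per species
  kept <- m[!m$anomaly %in% c("ambiguity", "short", "mislabel",
                              "orphan"), ]
  expHap <- sum(vapply(split(kept, kept$true_species), function(s)
    length(unique(s$insert)), 0L))
  expect_identical(nrow(cur$db), expHap)
  # contract on the output: pure ACGT, length window, parseable headers
  expect_false(any(grepl("[^ACGT]", cur$db$seq)))
  expect_true(all(nchar(cur$db$seq) >= ceiling(0.9 * 93)))
  expect_true(all(cur$db$species %in% cur$taxonomy$species))
  # idempotence
  cur2 <- suppressWarnings(curateReferenceDb(
    cur$db[, c("accession", "species", "marker", "seq", "source")],
    cur$taxonomy, ad, synonyms = ref$synonyms))
  expect_identical(cur2$db$accession, cur$db$accession)
  expect_identical(cur2$db$seq, cur$db$seq)
  expect_identical(nrow(cur2$flags), 0L)
})

test_that("keep-lists shield flagged records and relabel-lists correct them", {
  tax <- toyTaxonomy()
  ins <- seqOf(93L, 50)
  cluster <- vapply(1:10, function(i)
    mutateAt(ins, i, if (substr(ins, i, i) == "A") "C" else "A"), "")
  mkdb <- function() {
    hdr <- c(sprintf("Pana_alpha_C%02d", 1:10), "Pana_beta_BAD1",
             sprintf("Lutra_gamma_L%02d", 1:6))
    sq <- c(paste0(ad16S()@fwdPrimer, c(cluster, ins),
                   revComp(ad16S()@revPrimer)),
            paste0(ad16S()@fwdPrimer,
                   vapply(1:6, function(i)
                     mutateAt(seqOf(93L, 60), i, "A"), ""),
                   revComp(ad16S()@revPrimer)))
    referenceDb(hdr, sq)
  }
  curKeep <- curateReferenceDb(mkdb(), tax, ad16S(), keepList = "BAD1")
  expect_true("BAD1" %in% curKeep$db$accession)
  curFix <- curateReferenceDb(mkdb(), tax, ad16S(),
                              relabel = data.frame(
                                accession = "BAD1",
                                species = "Pana_alpha"))
  expect_identical(nrow(curFix$flags), 0L)
})

test_that("curation reports reconcile counts, haplotypes and coverage", {
  spec <- fixtureSpec(seed = 71)
  tax <- makeTaxonomy(spec)
  ref <- makeReferenceDb(spec, tax, ad16S(), primerlessRate = 0)
  cur <- curateReferenceDb(ref$db, tax, ad16S())
  rep <- curationReport(cur)
  expect_identical(rep$losses$n_out[nrow(rep$losses)], nrow(cur$db))
  expect_identical(sum(rep$haplotypesPerSpecies$haplotypes),
                   nrow(cur$db))
  expect_identical(rep$coverage$species_covered,
                   length(unique(cur$db$species)))
  empty <- curationReport(list(db = cur$db[0, ], taxonomy = tax,
                               log = cur$log[0, ]))
  expect_identical(nrow(empty$haplotypesPerSpecies), 0L)
})
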