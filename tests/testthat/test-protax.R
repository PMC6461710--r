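test_that("sequence similarity is 1 for identical, 0.99 for one mismatch in 100, low for unrelated", {
  s <- seqOf(100L, 301)
  expect_equal(seqSimilarity(s, s), 1.0)
  s2 <- mutateAt(s, 50L, if (substr(s, 50, 50) == "A") "C" else "A")
  expect_equal(seqSimilarity(s, s2), 0.99)
  r <- vapply(1:5, function(i) seqOf(93L, 310 + i), "")
  sims <- seqSimilarity(seqOf(93L, 320), r, method = "alignment")
  expect_true(all(sims < 0.6))
})

test_that("candidate predictors encode reference presence, similarity and sibling margin", {
  tree <- toyTree()
  spNodes <- treeNodes(tree)[treeNodes(tree)$rank == "species", ]
  sims <- setNames(c(1.0, 0.9, 0.8, NA), as.character(spNodes$id))
  # at the genus parent of Pana: candidates alpha, beta + unknown
  genPana <- treeNodes(tree)$id[treeNodes(tree)$name == "Pana"]
  np <- nodePredictors(genPana, tree, sims)
  expect_identical(nrow(np$X), 3L)
  alphaRow <- which(np$candidates ==
                      spNodes$id[spNodes$name == "Pana_alpha"])
  expect_equal(unname(np$X[alphaRow, ]), c(1, 0, 1.0, 0.1))
  unknownRow <- which(is.na(np$candidates))
  expect_equal(unname(np$X[unknownRow, ]), c(1, 1, 0, -1.0))
  # a candidate with no references: x1 = 1, margin = -best sibling
  lutraDelta <- spNodes$id[spNodes$name == "Lutra_delta"]
  genLutra <- treeNodes(tree)$id[treeNodes(tree)$name == "Lutra"]
  np2 <- nodePredictors(genLutra, tree, sims)
  deltaRow <- which(np2$candidates == lutraDelta)
  expect_equal(unname(np2$X[deltaRow, ]), c(1, 1, 0, -0.8))
})

test_that("node posteriors mix a uniform component with a prior-weighted softmax", {
  X <- cbind(1, c(0, 0), c(1.0, 0.8), c(0.2, -0.2))
  # full mislabelling: uniform regardless of predictors
  expect_equal(nodePosterior(X, c(5, 5, 5, 5), 1), c(0.5, 0.5))
  # no signal, no mislabelling, uniform priors: uniform
  expect_equal(nodePosterior(X, rep(0, 4), 0), c(0.5, 0.5))
  # softmax arithmetic: e^10 vs e^8 -> 1/(1+e^-2)
  p <- nodePosterior(X, c(0, 0, 10, 0), 0)
  expect_equal(p, c(1 / (1 + exp(-2)), exp(-2) / (1 + exp(-2))),
               tolerance = 1e-9)
  expect_equal(round(p[1], 3), 0.881)
  expect_error(nodePosterior(X[0, , drop = FALSE], rep(0, 4), 0),
               "no candidates")
})

test_that("posteriors sum to one at every node for random parameters", {
  set.seed(5)
  for (i in 1:20) {
    K <- sample(2:7, 1)
    X <- cbind(1, rbinom(K, 1, 0.3), runif(K), runif(K, -1, 1))
    p <- nodePosterior(X, rnorm(4, 0, 3), runif(1),
                       prior = runif(K, 0.1, 1))
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("raising a candidate's similarity never lowers its posterior when beta2 > 0", {
  beta <- c(0, -1, 3, 1.5)
  base <- cbind(1, c(0, 0, 1), c(0.7, 0.9, 0), c(0, 0.2, -0.9))
  p0 <- nodePosterior(base, beta, 0.05)
  up <- base; up[1, 3] <- 0.95
  p1 <- nodePosterior(up, beta, 0.05)
  expect_gt(p1[1], p0[1])
})

test_that("species priors split the expected and remaining mass", {
  spp <- sprintf("S%04d", 1:1000)
  pri <- speciesPriors(spp, spp[1:103])
  expect_equal(unname(pri[1]), 0.9 / 103)
  expect_equal(unname(pri[999]), 0.1 / 897)
  expect_equal(sum(pri), 1)
  expect_equal(unname(speciesPriors(spp)[5]), 1 / 1000)
  expect_equal(unname(speciesPriors(spp, spp)[5]), 1 / 1000)
})

test_that("training sets split scenarios reproducibly and refuse oversampling", {
  tree <- toyTree(10L)  # 40 reference sequences
  ts <- buildTrainingSet(tree, n = 24L, nKnown = 20L, nNovel = 4L,
                         seed = 7)
  expect_length(ts, 24L)
  sc <- table(vapply(ts, `[[`, "", "scenario"))
  expect_identical(as.integer(sc[c("novel_species", "novel_genus",
                                   "novel_family", "novel_order")]),
                   rep(1L, 4))
  expect_identical(as.integer(sum(sc[c("known_with_refs",
                                       "known_without_refs")])), 20L)
  ts2 <- buildTrainingSet(tree, n = 24L, nKnown = 20L, nNovel = 4L,
                          seed = 7)
  expect_identical(ts, ts2)
  expect_error(buildTrainingSet(tree, n = 100L, nKnown = 96L,
                                nNovel = 4L, seed = 1), "exceeds")
  expect_error(buildTrainingSet(tree, n = 10L, nKnown = 7L, nNovel = 3L,
                                seed = 1), "divisible")
})

test_that("MAP fitting recovers simulated parameters", {
  bstar <- c(0, -1, 3, 1.5)
  estar <- 0.1
  cs <- simulateTrainingCases(5000L, bstar, estar, seed = 11)
  f <- fitMap(cs)
  expect_true(f$converged)
  expect_lt(max(abs(f$beta - bstar)), 0.3)
  expect_lt(abs(f$eps - estar), 0.05)
  # separable data with no mislabelling pushes eps to the floor
  cs0 <- simulateTrainingCases(2000L, c(0, -1, 8, 4), 0, seed = 12)
  f0 <- fitMap(cs0)
  expect_lte(f0$eps, 0.02)
  expect_error(fitMap(list()), "empty")
})

test_that("degenerate single-candidate designs return start values with a warning", {
  cs <- lapply(1:10, function(i)
    list(X = cbind(1, 0, 1, 0), prior = 1, trueIdx = 1L))
  expect_warning(f <- fitMap(cs), "unidentifiable")
  expect_identical(f$eps, 0.01)
})

test_that("a query identical to a unique reference is assigned its species", {
  tree <- toyTree()
  mdl <- protaxModel(matrix(rep(c(0, -2, 8, 4), 4), 4, 4, byrow = TRUE),
                     rep(0, 4))
  db <- toyRefDb(1L)
  a <- protaxClassify(db$seq[1], mdl, tree)
  expect_identical(a$name[a$rank == "species"], "Pana_alpha")
  expect_gt(a$probability[a$rank == "species"], 0.99)
  expect_equal(a$best_similarity[a$rank == "species"], 1.0)
  expect_identical(a$path[4], "Carnivora;Panidae;Pana;Pana_alpha")
  # rank nodes chain parent -> child
  nd <- treeNodes(tree)
  expect_identical(nd$parent[match(a$node_id[4], nd$id)], a$node_id[3])
})

test_that("queries from reference-free genera land on the unknown species branch", {
  tree <- toyTree()
  # strip references from Lutra_delta and classify something Lutra-like
  db <- toyRefDb(1L)
  db <- db[db$species != "Lutra_delta", ]
  tree <- attachReferences(buildTaxonomyTree(toyTaxonomy()), db)
  mdl <- protaxModel(matrix(rep(c(0, -2, 8, 4), 4), 4, 4, byrow = TRUE),
                     rep(0, 4))
  # a query 3 mutations away from the Lutra_gamma reference
  q <- db$seq[db$species == "Lutra_gamma"][1]
  for (i in c(5L, 25L, 45L))
    q <- mutateAt(q, i, if (substr(q, i, i) == "A") "C" else "A")
  a <- protaxClassify(q, mdl, tree)
  expect_identical(a$name[a$rank == "genus"], "Lutra")
  expect_true(a$name[a$rank == "species"] %in%
                c("unknown", "Lutra_gamma"))
})

test_that("prior weighting breaks ties between reference-identical species", {
  tax <- toyTaxonomy()
  ins <- seqOf(93L, 900)
  db <- referenceDb(c("Pana_alpha_A1", "Pana_beta_B1"), c(ins, ins))
  tree <- attachReferences(buildTaxonomyTree(tax), db)
  mdl <- protaxModel(matrix(rep(c(0, -2, 8, 4), 4), 4, 4, byrow = TRUE),
                     rep(0, 4))
  spn <- treeNodes(tree)$name[treeNodes(tree)$rank == "species"]
  even <- protaxClassify(ins, mdl, tree, speciesPriors(spn))
  pA <- protaxClassify(ins, mdl, tree,
                       speciesPriors(spn, "Pana_alpha", 0.9))
  pB <- protaxClassify(ins, mdl, tree,
                       speciesPriors(spn, "Pana_beta", 0.9))
  # equal priors: a coin-flip flagged by low probability at similarity 1
  expect_lt(even$probability[even$rank == "species"], 0.6)
  expect_equal(even$best_similarity[even$rank == "species"], 1.0)
  expect_identical(pA$name[pA$rank == "species"], "Pana_alpha")
  expect_identical(pB$name[pB$rank == "species"], "Pana_beta")
  expect_gt(pA$probability[pA$rank == "species"],
            even$probability[even$rank == "species"])
})

test_that("an end-to-end fit on fixture references classifies its own sequences", {
  spec <- fixtureSpec(seed = 81)
  tax <- makeTaxonomy(spec)
  ref <- makeReferenceDb(spec, tax, ad16S(), primerlessRate = 0)
  cur <- curateReferenceDb(ref$db, tax, ad16S())
  tree <- attachReferences(buildTaxonomyTree(cur$taxonomy), cur$db)
  items <- buildTrainingSet(tree, n = 48L, nKnown = 44L, nNovel = 4L,
                            seed = 2)
  mdl <- fitProtax(items, tree)
  a <- protaxClassify(cur$db$seq[5], mdl, tree)
  expect_identical(a$name[a$rank == "species"], cur$db$species[5])
  expect_true(all(a$probability >= 0 & a$probability <= 1))
  expect_true(all(diff(a$probability) <= 1e-9))  # cumulative never grows
})

test_that("models round-trip through their TSV serialisation", {
  mdl <- protaxModel(matrix(rnorm(16), 4, 4), c(0.1, 0.2, 0.05, 0))
  path <- tempfile(fileext = ".tsv")
  writeProtaxModel(mdl, path)
  back <- readProtaxModel(path)
  expect_equal(back@beta, mdl@beta, tolerance = 1e-12)
  expect_equal(back@eps, mdl@eps, tolerance = 1e-12)
})
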