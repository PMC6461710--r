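cfg <- acceptanceConfig()

gridOf <- function(cells, sample = "s1", species = "sp1") {
  replicateGrid(sample, species, cells)
}

test_that("positive cells respect the threshold and absent libraries", {
  expect_length(positiveCells(gridOf(numeric(0)), cfg), 0L)
  expect_identical(positiveCells(gridOf(c(A.1.12S = 5)), cfg),
                   "A.1.12S")
  g <- gridOf(c(A.1.12S = 5, A.1.16S = NA, A.2.16S = NA, B.1.16S = NA,
                B.2.16S = NA))
  expect_identical(positiveCells(g, cfg), "A.1.12S")
})

test_that("lax accepts any two positives, stringent needs both extractions", {
  bothA <- gridOf(c(A.1.12S = 3, A.2.12S = 4))
  expect_true(acceptLax(bothA, cfg))
  expect_false(acceptStringent(bothA, cfg))
  expect_false(acceptLax(gridOf(c(A.1.12S = 9)), cfg))
  crossM <- gridOf(c(A.1.16S = 2, B.2.CytB = 2))
  expect_true(acceptLax(crossM, cfg))
  expect_true(acceptStringent(crossM, cfg))
  expect_true(acceptStringent(gridOf(c(A.1.16S = 1, B.1.16S = 1)), cfg))
  expect_false(acceptStringent(gridOf(numeric(0)), cfg))
})

test_that("the read-count rule needs 10 reads for single-marker, any reads for multi-marker", {
  expect_false(readCountRule(gridOf(c(A.1.12S = 9)), cfg))
  expect_true(readCountRule(gridOf(c(A.1.12S = 12)), cfg))
  expect_true(readCountRule(gridOf(c(A.1.12S = 5, A.2.12S = 7)), cfg))
  # two markers below 10 each are still accepted
  expect_true(readCountRule(gridOf(c(A.1.12S = 6, A.1.16S = 4)), cfg))
  expect_false(readCountRule(gridOf(numeric(0)), cfg))
})

test_that("detection calls combine criterion and read rule", {
  gs <- list(gridOf(c(A.1.12S = 20, B.1.12S = 15), species = "both"),
             gridOf(c(A.1.12S = 20, A.2.12S = 15), species = "laxonly"),
             gridOf(c(A.1.12S = 4, B.1.12S = 4), species = "lowreads"))
  calls <- callDetections(gs, cfg)
  expect_identical(calls$stringent, c(TRUE, FALSE, FALSE))
  expect_identical(calls$lax, c(TRUE, TRUE, FALSE))
  # stringent acceptance implies lax acceptance
  expect_true(all(!calls$stringent | calls$lax))
})

test_that("stringent implies lax over every positivity pattern", {
  pat <- as.matrix(expand.grid(rep(list(0:1), 12)))
  str <- rowSums(pat[, 1:6]) >= 1 & rowSums(pat[, 7:12]) >= 1
  lax <- rowSums(pat) >= 2
  expect_identical(nrow(pat), 4096L)
  expect_true(all(!str | lax))
  # the same property through the grid interface on a sample of patterns
  cells <- replicateCells()
  aCells <- grep("^A", cells, value = TRUE)
  bCells <- grep("^B", cells, value = TRUE)
  for (i in seq(1, 4096, by = 409)) {
    counts <- setNames(as.numeric(pat[i, ]), c(aCells, bCells))
    g <- replicateGrid("s", "x", counts)
    expect_true(!acceptStringent(g, cfg) || acceptLax(g, cfg))
  }
})

test_that("closed-form acceptance equals exhaustive enumeration", {
  p <- seq(0, 1, by = 0.1)
  for (cr in c("stringent", "lax")) {
    expect_equal(acceptanceProbability(p, cr), enumerateAcceptance(p, cr),
                 tolerance = 1e-12)
  }
  # and for asymmetric designs
  for (nA in c(2L, 4L)) for (nB in c(3L, 6L))
    expect_equal(acceptanceProbability(p, "stringent", nA, nB),
                 enumerateAcceptance(p, "stringent", nA, nB),
                 tolerance = 1e-12)
  expect_equal(acceptanceProbability(0, "lax"), 0)
  expect_equal(acceptanceProbability(1, "stringent"), 1)
  # frozen enumeration values at p = 0.5
  expect_equal(acceptanceProbability(0.5, "stringent"), 0.96899414,
               tolerance = 1e-7)
  expect_equal(acceptanceProbability(0.5, "lax"), 0.99682617,
               tolerance = 1e-7)
})

test_that("the criteria order error rates as the design intends", {
  p <- seq(0, 1, by = 0.05)
  accS <- acceptanceProbability(p, "stringent")
  accL <- acceptanceProbability(p, "lax")
  expect_true(all(accS <= accL + 1e-12))
  # hence FN_stringent >= FN_lax and FP_stringent <= FP_lax everywhere
  expect_true(all((1 - accS) >= (1 - accL) - 1e-12))
})

test_that("Monte-Carlo error rates agree with the closed forms", {
  sim <- simulateErrorRates(c(0.3, 0.7), pFalse = 0.05, reps = 20000L,
                            seed = 4)
  expect_true(all(abs(sim$acceptance - sim$acceptance_closed) <=
                    3 * pmax(sim$mc_se, 1e-4)))
  expect_true(all(sim$fn_rate == 1 - sim$acceptance))
  z <- simulateErrorRates(1, pFalse = 0, reps = 5000L, seed = 5)
  expect_true(all(z$fn_rate == 0))
  expect_true(all(z$fp_rate == 0))
})

test_that("the per-species summary reproduces the published change column", {
  s <- speciesSummary(exampleDetections())
  tot <- s[s$species == "Total", ]
  expect_identical(tot$change, 28)
  # the per-species columns sum to one more than the published totals
  # (162/190); the computed sums are reported
  expect_identical(tot$stringent, 163)
  expect_identical(tot$lax, 191)
  expect_identical(s$change[s$species == "Rusa unicolor"], 8)
  # from logical calls
  calls <- data.frame(sample = c("a", "b"), species = "x",
                      stringent = c(TRUE, FALSE), lax = c(TRUE, TRUE))
  s2 <- speciesSummary(calls)
  expect_identical(s2$stringent[1], 1L)
  expect_identical(s2$lax[1], 2L)
  expect_identical(s2$change[1], 1L)
  s0 <- speciesSummary(calls[0, ])
  expect_identical(s0$lax, 0)
})

test_that("simulated replicate grids hit the closed-form acceptance rate", {
  presence <- data.frame(sample = sprintf("s%04d", 1:1500),
                         species = "sp", present = TRUE)
  grids <- makeReplicateGrid(presence, pDetect = 0.5, seed = 10)
  calls <- callDetections(grids, cfg)
  accS <- mean(calls$stringent)
  expected <- acceptanceProbability(0.5, "stringent")
  se <- sqrt(expected * (1 - expected) / nrow(presence))
  expect_lt(abs(accS - expected), 3 * se + 1e-9)
  # extremes
  g1 <- makeReplicateGrid(presence[1:50, ], pDetect = 1, seed = 1)
  expect_true(all(callDetections(g1, cfg)$stringent))
  absent <- data.frame(sample = "s", species = "none", present = FALSE)
  g0 <- makeReplicateGrid(absent[rep(1, 50), ], pDetect = 1, pFalse = 0,
                          seed = 2)
  expect_false(any(callDetections(g0, cfg)$lax))
})
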