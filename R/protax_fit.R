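#' Build a training set for the placement model
#'
#' Draws \code{n} training queries from the attached reference database.
#' \code{nKnown} of them represent known species -- split (default 50/50)
#' between species whose conspecific references are retained and species
#' whose conspecific references are masked, simulating species missing
#' from the database -- and \code{nNovel} represent previously unknown
#' lineages, distributed evenly across the four ranks by masking the
#' query's species, genus, family or order node (and every reference
#' beneath it), so the true answer at the masked rank is the unknown
#' branch. Reproducible under \code{seed}.
#'
#' @param tree a \code{TaxonomyTree} with references attached.
#' @param n total training size (default 5000).
#' @param nKnown known-species items (default 4500).
#' @param nNovel novel-lineage items (default 500; must be divisible by 4).
#' @param knownWithRefsFrac fraction of known items keeping their
#'   conspecific references (default 0.5).
#' @param seed RNG seed.
#' @return list of training items; each has \code{query},
#'   \code{queryAccession}, \code{scenario}, \code{maskedAccessions},
#'   \code{maskedNodes} and \code{truePath} (named node ids per rank,
#'   NA where the truth is the unknown branch).
#' @export
buildTrainingSet <- function(tree, n = 5000L, nKnown = 4500L,
                             nNovel = 500L, knownWithRefsFrac = 0.5,
                             seed = 1L) {
  if (nKnown + nNovel != n) stop("nKnown + nNovel must equal n")
  if (nNovel %% 4L != 0L) stop("nNovel must be divisible by 4")
  if (n > nrow(tree@refdb))
    stop("training size ", n, " exceeds database size ",
         nrow(tree@refdb), call. = FALSE)
  set.seed(seed)
  nd <- tree@nodes
  pick <- sample.int(nrow(tree@refdb), n)
  scen <- c(rep("known_with_refs", round(nKnown * knownWithRefsFrac)),
            rep("known_without_refs",
                nKnown - round(nKnown * knownWithRefsFrac)),
            rep(c("novel_species", "novel_genus", "novel_family",
                  "novel_order"), each = nNovel / 4L))
  scen <- sample(scen)

  spNodes <- nd[nd$rank == "species", ]
  items <- vector("list", n)
  for (i in seq_len(n)) {
    ri <- pick[i]
    sp <- tree@refdb$species[ri]
    sid <- spNodes$id[match(sp, spNodes$name)]
    path <- .pathToRoot(tree, sid)  # named: order, family, genus, species
    sc <- scen[i]
    maskedNodes <- integer(0)
    maskedAcc <- character(0)
    truePath <- path
    if (sc == "known_without_refs") {
      maskedAcc <- tree@refdb$accession[tree@refs[[as.character(sid)]]]
    } else if (sc != "known_with_refs") {
      novelRank <- sub("novel_", "", sc)
      mNode <- path[[novelRank]]
      maskedNodes <- mNode
      below <- speciesBelow(tree, mNode)
      maskedAcc <- tree@refdb$accession[
        unlist(tree@refs[as.character(below)], use.names = FALSE)]
      rks <- c("order", "family", "genus", "species")
      truePath[rks[seq(match(novelRank, rks), 4L)]] <- NA_integer_
    } else {
      ## with-refs: the query itself stays out of its own evidence
      maskedAcc <- tree@refdb$accession[ri]
    }
    items[[i]] <- list(query = tree@refdb$seq[ri],
                       queryAccession = tree@refdb$accession[ri],
                       scenario = sc,
                       maskedAccessions = maskedAcc,
                       maskedNodes = maskedNodes,
                       truePath = truePath)
  }
  attr(items, "seed") <- seed
  items
}

.pathToRoot <- function(tree, sid) {
  nd <- tree@nodes
  path <- integer(0)
  id <- sid
  while (!is.na(id) && id != 0L) {
    r <- match(id, nd$id)
    path[nd$rank[r]] <- id
    id <- nd$parent[r]
  }
  path[c("order", "family", "genus", "species")]
}

#' Per-rank design data of a training set
#'
#' For each item, evaluates the candidate predictors at the parent implied
#' by the item's true path at the requested rank (teacher forcing), giving
#' the predictor matrix, candidate priors and the index of the true
#' candidate (the unknown branch for novel-at-rank items).
#'
#' @param items training items from \code{\link{buildTrainingSet}}.
#' @param tree a \code{TaxonomyTree} with references attached.
#' @param rank "order", "family", "genus" or "species".
#' @param spPrior named per-species prior (uniform when NULL).
#' @param method similarity backend.
#' @param simsList optional precomputed per-item species-similarity
#'   vectors (one \code{.speciesSims} result per item), reused across
#'   ranks.
#' @return list of cases, each with \code{X}, \code{prior},
#'   \code{trueIdx}; items whose truth is undefined at this rank's parent
#'   are skipped.
#' @export
trainingDesign <- function(items, tree, rank, spPrior = NULL,
                           method = "auto", simsList = NULL) {
  rks <- c("order", "family", "genus", "species")
  up <- c(order = "root", family = "order", genus = "family",
          species = "genus")
  if (is.null(spPrior)) {
    spn <- tree@nodes$name[tree@nodes$rank == "species"]
    spPrior <- speciesPriors(spn)
  }
  cases <- list()
  for (ii in seq_along(items)) {
    it <- items[[ii]]
    parent <- if (rank == "order") 0L else it$truePath[[up[[rank]]]]
    if (is.na(parent)) next  # lineage novel above this rank
    spSims <- if (is.null(simsList))
      .speciesSims(it$query, tree, it$maskedAccessions, method)
    else simsList[[ii]]
    np <- nodePredictors(parent, tree, spSims, it$maskedNodes)
    trueNode <- it$truePath[[rank]]
    trueIdx <- if (is.na(trueNode)) length(np$candidates)
               else match(trueNode, np$candidates)
    if (is.na(trueIdx)) next
    pri <- .candidatePriors(tree, np$candidates, spPrior)
    cases[[length(cases) + 1L]] <- list(X = np$X, prior = pri,
                                        trueIdx = trueIdx)
  }
  cases
}

#' MAP fit of one rank's placement parameters
#'
#' Maximises the log posterior of the per-node candidate model --
#' \eqn{\sum_i \log p(c_i^{true})} plus independent Gaussian(0, 10^2)
#' priors on the coefficients and a Beta(1, 10) prior on the mislabelling
#' probability -- by deterministic quasi-Newton ascent (BFGS with analytic
#' gradients) from the fixed start beta = 0, eps = 0.01. Convergence is
#' declared when the gradient norm drops below \code{tol} (checked after
#' the optimiser returns); degenerate designs in which every case has a
#' single candidate leave eps unidentifiable and return the start value
#' with a warning.
#'
#' @param cases training cases from \code{\link{trainingDesign}} (or
#'   simulated cases of the same shape).
#' @param betaSd Gaussian prior sd on coefficients (default 10).
#' @param epsShape Beta prior on eps (default c(1, 10)).
#' @param tol gradient-norm convergence tolerance (default 1e-6).
#' @param maxit iteration cap (default 10000).
#' @return list with \code{beta}, \code{eps}, \code{converged},
#'   \code{logPosterior}, \code{gradNorm}.
#' @export
fitMap <- function(cases, betaSd = 10, epsShape = c(1, 10), tol = 1e-6,
                   maxit = 10000L) {
  if (!length(cases)) stop("empty training set", call. = FALSE)
  Ks <- vapply(cases, function(cs) nrow(cs$X), 0L)
  if (all(Ks == 1L)) {
    warning("all cases have a single candidate: parameters unidentifiable",
            "; returning start values")
    return(list(beta = rep(0, 4), eps = 0.01, converged = FALSE,
                logPosterior = NA_real_, gradNorm = NA_real_))
  }
  Xall <- do.call(rbind, lapply(cases, `[[`, "X"))
  logPri <- log(pmax(unlist(lapply(cases, `[[`, "prior")), 1e-300))
  grp <- rep(seq_along(cases), Ks)
  trueRow <- cumsum(Ks) - Ks + vapply(cases, `[[`, 0L, "trueIdx")
  Kvec <- Ks
  nI <- length(cases)

  negLogPost <- function(par) {
    beta <- par[1:4]; eps <- par[5]
    z <- as.vector(Xall %*% beta) + logPri
    zmax <- vapply(split(z, grp), max, 0)
    ez <- exp(z - zmax[grp])
    den <- vapply(split(ez, grp), sum, 0)
    s <- ez / den[grp]
    pTrue <- eps / Kvec + (1 - eps) * s[trueRow]
    ll <- sum(log(pmax(pTrue, 1e-300)))
    lp <- sum(dnorm(beta, 0, betaSd, log = TRUE)) +
      dbeta(eps, epsShape[1], epsShape[2], log = TRUE)
    -(ll + lp)
  }
  gradNegLogPost <- function(par) {
    beta <- par[1:4]; eps <- par[5]
    z <- as.vector(Xall %*% beta) + logPri
    zmax <- vapply(split(z, grp), max, 0)
    ez <- exp(z - zmax[grp])
    den <- vapply(split(ez, grp), sum, 0)
    s <- ez / den[grp]
    pTrue <- pmax(eps / Kvec + (1 - eps) * s[trueRow], 1e-300)
    w <- (1 - eps) * s[trueRow] / pTrue        # per item
    ## d log pTrue / d beta = w * (x_true - sum_c s_c x_c)
    sx <- rowsum(s * Xall, grp)
    gBeta <- colSums(w * (Xall[trueRow, , drop = FALSE] - sx)) -
      beta / betaSd^2
    gEps <- sum((1 / Kvec - s[trueRow]) / pTrue) +
      (epsShape[1] - 1) / eps - (epsShape[2] - 1) / (1 - eps)
    -c(gBeta, gEps)
  }
  start <- c(rep(0, 4), 0.01)
  fit <- optim(start, negLogPost, gradNegLogPost, method = "L-BFGS-B",
               lower = c(rep(-Inf, 4), 1e-6),
               upper = c(rep(Inf, 4), 1 - 1e-6),
               control = list(maxit = maxit, factr = 1e4))
  g <- gradNegLogPost(fit$par)
  list(beta = fit$par[1:4], eps = fit$par[5],
       converged = fit$convergence == 0 || sqrt(sum(g^2)) < tol,
       logPosterior = -fit$value, gradNorm = sqrt(sum(g^2)))
}

#' Simulate training cases from known model parameters
#'
#' Draws candidate sets with independent predictor variation -- a
#' no-reference indicator, a best-similarity predictor spread over [0, 1]
#' (zero for reference-free candidates) and an independent margin
#' component -- and samples each case's outcome from the node-posterior
#' model at the supplied true parameters. The simulation-recovery oracle
#' for \code{\link{fitMap}}: fitting these cases must return the true
#' parameters up to sampling error. Independent covariate variation keeps
#' the design informative, so the 5 parameters are estimable from a few
#' thousand cases.
#'
#' @param n number of cases.
#' @param beta true coefficient vector (the shared intercept is not
#'   identifiable in a softmax over candidates; use 0).
#' @param eps true mislabelling probability.
#' @param seed RNG seed.
#' @param Kmin,Kmax candidate-set size range (defaults 3 and 6).
#' @return list of cases with \code{X}, \code{prior}, \code{trueIdx}.
#' @export
simulateTrainingCases <- function(n, beta = c(0, -1, 3, 1.5), eps = 0.1,
                                  seed = 1L, Kmin = 3L, Kmax = 6L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    K <- sample(seq.int(Kmin, Kmax), 1)
    x1 <- as.numeric(runif(K) < 0.3)
    x2 <- ifelse(x1 == 1, 0, runif(K))
    x3 <- runif(K, -0.5, 0.5)
    X <- cbind(x0 = 1, x1 = x1, x2 = x2, x3 = x3)
    pri <- rep(1 / K, K)
    p <- nodePosterior(X, beta, eps, pri)
    list(X = X, prior = pri, trueIdx = sample.int(K, 1, prob = p))
  })
}

#' Fit the full four-rank model
#'
#' Builds the per-rank designs from one training set and fits each rank
#' independently.
#'
#' @param items training items.
#' @param tree a \code{TaxonomyTree} with references attached.
#' @param spPrior named per-species prior (uniform when NULL).
#' @param method similarity backend.
#' @param ... passed to \code{\link{fitMap}}.
#' @return a \code{ProtaxModel}.
#' @export
fitProtax <- function(items, tree, spPrior = NULL, method = "auto", ...) {
  rks <- c("order", "family", "genus", "species")
  beta <- matrix(0, 4, 4)
  eps <- numeric(4)
  conv <- logical(4)
  simsList <- lapply(items, function(it)
    .speciesSims(it$query, tree, it$maskedAccessions, method))
  for (i in seq_along(rks)) {
    cases <- trainingDesign(items, tree, rks[i], spPrior, method,
                            simsList)
    f <- fitMap(cases, ...)
    beta[i, ] <- f$beta
    eps[i] <- f$eps
    conv[i] <- f$converged
  }
  protaxModel(beta, eps,
              meta = list(seed = attr(items, "seed"),
                          trainingSize = length(items),
                          converged = conv))
}

#' Classify a query sequence
#'
#' Greedy root-to-leaf traversal: at each rank the candidate posteriors
#' (children of the current node plus the unknown branch) are computed
#' with that rank's parameters and the best candidate is taken, its
#' posterior multiplying the cumulative placement probability. Once the
#' unknown branch wins, deeper ranks are reported as unknown at the same
#' cumulative probability. The best reference similarity of the assigned
#' species (or of the assigned genus when the species is unknown) is
#' attached for flagging conflicting-signal assignments.
#'
#' @param query query sequence.
#' @param model a \code{ProtaxModel}.
#' @param tree a \code{TaxonomyTree} with references attached.
#' @param spPrior named per-species prior (uniform when NULL).
#' @param method similarity backend.
#' @param queryId,size identifier and dereplication size carried into the
#'   output.
#' @return data.frame with one row per rank: query_id, size, rank,
#'   node_id, name, probability (cumulative), best_similarity, path.
#' @export
protaxClassify <- function(query, model, tree, spPrior = NULL,
                           method = "auto", queryId = "query", size = 1L) {
  rks <- c("order", "family", "genus", "species")
  if (is.null(spPrior)) {
    spn <- tree@nodes$name[tree@nodes$rank == "species"]
    spPrior <- speciesPriors(spn)
  }
  spSims <- .speciesSims(query, tree, character(0), method)
  cur <- 0L
  cum <- 1
  unknownFrom <- NA_integer_
  rows <- list()
  pathParts <- character(0)
  for (i in seq_along(rks)) {
    if (!is.na(unknownFrom)) {
      pathParts <- c(pathParts, "unknown")
      rows[[i]] <- data.frame(query_id = queryId, size = size,
                              rank = rks[i], node_id = NA_integer_,
                              name = "unknown", probability = cum,
                              best_similarity = NA_real_,
                              path = paste(pathParts, collapse = ";"),
                              stringsAsFactors = FALSE)
      next
    }
    np <- nodePredictors(cur, tree, spSims)
    pri <- .candidatePriors(tree, np$candidates, spPrior)
    p <- nodePosterior(np$X, model@beta[rks[i], ], model@eps[[rks[i]]],
                       pri)
    b <- which.max(p)
    cum <- cum * p[b]
    if (is.na(np$candidates[b])) {
      unknownFrom <- i
      pathParts <- c(pathParts, "unknown")
      rows[[i]] <- data.frame(query_id = queryId, size = size,
                              rank = rks[i], node_id = NA_integer_,
                              name = "unknown", probability = cum,
                              best_similarity = NA_real_,
                              path = paste(pathParts, collapse = ";"),
                              stringsAsFactors = FALSE)
    } else {
      cur <- np$candidates[b]
      nm <- tree@nodes$name[match(cur, tree@nodes$id)]
      pathParts <- c(pathParts, nm)
      sp <- speciesBelow(tree, cur)
      v <- spSims[as.character(sp)]
      bs <- if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
      rows[[i]] <- data.frame(query_id = queryId, size = size,
                              rank = rks[i], node_id = cur, name = nm,
                              probability = cum, best_similarity = bs,
                              path = paste(pathParts, collapse = ";"),
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Classify a dereplicated sample
#'
#' @param derep data.frame with columns seq, size (see
#'   \code{\link{dereplicateSample}}), or a named character vector.
#' @param model,tree,spPrior,method as in \code{\link{protaxClassify}}.
#' @param idPrefix prefix for generated query ids.
#' @return row-bound assignment data.frame, one row per rank per read.
#' @export
classifySample <- function(derep, model, tree, spPrior = NULL,
                           method = "auto", idPrefix = "uniq") {
  if (!nrow(derep)) return(protaxClassify("A", model, tree)[0, ])
  out <- lapply(seq_len(nrow(derep)), function(i)
    protaxClassify(derep$seq[i], model, tree, spPrior, method,
                   queryId = sprintf("%s%04d;size=%d", idPrefix, i,
                                     derep$size[i]),
                   size = derep$size[i]))
  do.call(rbind, out)
}
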