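#' TaxonomyTree: the four-rank assignment hierarchy
#'
#' A rooted tree over the ranks root, order, family, genus, species, built
#' from a flat taxonomy table. Node ids are integers with the root fixed
#' at 0; each node knows its parent, rank and name. Reference sequences
#' attach to species nodes via \code{\link{attachReferences}}.
#'
#' @slot nodes data.frame with columns id, parent, rank, name.
#' @slot children list mapping node id (as character) to child ids.
#' @slot refs list mapping species node id (as character) to indices into
#'   the attached reference db.
#' @slot refdb attached reference data.frame (possibly empty).
#' @export
setClass("TaxonomyTree", representation(
  nodes = "data.frame",
  children = "list",
  refs = "list",
  refdb = "data.frame"
))

setValidity("TaxonomyTree", function(object) {
  nd <- object@nodes
  if (sum(nd$rank == "root") != 1L) return("exactly one root required")
  rk <- c(root = 0L, order = 1L, family = 2L, genus = 3L, species = 4L)
  if (!all(nd$rank %in% names(rk))) return("unknown rank")
  pid <- match(nd$parent, nd$id)
  nonroot <- nd$rank != "root"
  if (anyNA(pid[nonroot])) return("dangling parent id")
  if (!all(rk[nd$rank[nonroot]] == rk[nd$rank[pid[nonroot]]] + 1L))
    return("ranks must increase by one along every edge")
  TRUE
})

#' Build a TaxonomyTree from a flat taxonomy table
#'
#' @param taxonomy data.frame with columns species, genus, family, order
#'   (class is ignored: the assignment hierarchy spans order to species).
#' @return a \code{TaxonomyTree}.
#' @export
buildTaxonomyTree <- function(taxonomy) {
  nodes <- data.frame(id = 0L, parent = NA_integer_, rank = "root",
                      name = "root", stringsAsFactors = FALSE)
  nextId <- 1L
  addLevel <- function(nodes, keys, parents, rank) {
    uk <- !duplicated(keys)
    ids <- seq.int(nextId, length.out = sum(uk))
    nextId <<- nextId + sum(uk)
    nodes <- rbind(nodes, data.frame(
      id = ids, parent = parents[uk], rank = rank,
      name = keys[uk], stringsAsFactors = FALSE))
    list(nodes = nodes, idOf = setNames(ids, keys[uk]))
  }
  o <- addLevel(nodes, taxonomy$order, rep(0L, nrow(taxonomy)), "order")
  f <- addLevel(o$nodes, paste(taxonomy$order, taxonomy$family, sep = "|"),
                unname(o$idOf[taxonomy$order]), "family")
  fkey <- paste(taxonomy$order, taxonomy$family, sep = "|")
  g <- addLevel(f$nodes, paste(fkey, taxonomy$genus, sep = "|"),
                unname(f$idOf[fkey]), "genus")
  gkey <- paste(fkey, taxonomy$genus, sep = "|")
  s <- addLevel(g$nodes, taxonomy$species, unname(g$idOf[gkey]), "species")
  nodes <- s$nodes
  ## display name = last path component
  nodes$name <- vapply(strsplit(nodes$name, "|", fixed = TRUE),
                       function(p) p[length(p)], "")
  ch <- split(nodes$id[-1L], as.character(nodes$parent[-1L]))
  new("TaxonomyTree", nodes = nodes, children = ch, refs = list(),
      refdb = data.frame())
}

setMethod("show", "TaxonomyTree", function(object) {
  nd <- object@nodes
  cat(sprintf(paste0("TaxonomyTree: %d orders, %d families, %d genera,",
                     " %d species; %d reference sequences\n"),
              sum(nd$rank == "order"), sum(nd$rank == "family"),
              sum(nd$rank == "genus"), sum(nd$rank == "species"),
              nrow(object@refdb)))
})

#' Attach curated reference sequences to a taxonomy tree
#'
#' @param tree a \code{TaxonomyTree}.
#' @param db curated reference data.frame (species labels must exist in
#'   the tree).
#' @return the tree with references attached.
#' @export
attachReferences <- function(tree, db) {
  spNodes <- tree@nodes[tree@nodes$rank == "species", ]
  sid <- spNodes$id[match(db$species, spNodes$name)]
  if (anyNA(sid))
    stop("reference species not in taxonomy: ",
         paste(unique(db$species[is.na(sid)]), collapse = ", "),
         call. = FALSE)
  tree@refs <- split(seq_len(nrow(db)), as.character(sid))
  tree@refdb <- db
  tree
}

#' @rdname buildTaxonomyTree
#' @param tree a \code{TaxonomyTree}.
#' @export
treeNodes <- function(tree) tree@nodes

childrenOf <- function(tree, id) {
  ch <- tree@children[[as.character(id)]]
  if (is.null(ch)) integer(0) else ch
}

## species node ids below an arbitrary node
speciesBelow <- function(tree, id) {
  rk <- tree@nodes$rank[match(id, tree@nodes$id)]
  if (rk == "species") return(id)
  out <- integer(0)
  stack <- childrenOf(tree, id)
  while (length(stack)) {
    x <- stack[[1]]; stack <- stack[-1]
    if (tree@nodes$rank[match(x, tree@nodes$id)] == "species")
      out <- c(out, x)
    else stack <- c(stack, childrenOf(tree, x))
  }
  out
}

#' Export the tree as a node table
#'
#' Four-level node table (node_id, parent_id, rank, name), root row first,
#' the interchange format between the curation and assignment steps.
#'
#' @param tree a \code{TaxonomyTree}.
#' @param file optional path; when given the table is written as TSV.
#' @return the node table data.frame (invisibly when written).
#' @export
exportTaxonomyNodes <- function(tree, file = NULL) {
  nd <- tree@nodes[order(tree@nodes$id), ]
  out <- data.frame(node_id = nd$id, parent_id = nd$parent,
                    rank = nd$rank, name = nd$name,
                    stringsAsFactors = FALSE)
  if (!is.null(file)) {
    write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Pairwise sequence similarity
#'
#' Identity in [0, 1] between a query and reference sequences: matching
#' columns of the best local alignment (match +1, mismatch -1, gap -2)
#' divided by the longer sequence length (so short local seeds in
#' unrelated sequences score low), or Hamming identity for equal-length
#' sets under the "auto" method. Identical sequences score 1.
#'
#' @param query a single query sequence.
#' @param refs character vector of reference sequences.
#' @param method "auto", "hamming" or "alignment".
#' @return numeric vector of identities, one per reference.
#' @export
seqSimilarity <- function(query, refs, method = c("auto", "alignment",
                                                  "hamming")) {
  method <- match.arg(method)
  if (!length(refs)) return(numeric(0))
  eq <- nchar(refs) == nchar(query)
  if (method == "hamming" || (method == "auto" && all(eq))) {
    if (!all(eq)) stop("hamming similarity needs equal lengths")
    qr <- charToRaw(query)
    return(vapply(refs, function(s) sum(charToRaw(s) == qr), 0,
                  USE.NAMES = FALSE) / nchar(query))
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(refs), query, type = "local",
    substitutionMatrix = .submat(), gapOpening = 0, gapExtension = 2)
  Biostrings::nmatch(aln) / pmax(nchar(refs), nchar(query))
}

## best similarity of a query to the references of every species node,
## honouring masked accessions; returns named vector by species node id
.speciesSims <- function(query, tree, masked = character(0),
                         method = "auto") {
  out <- numeric(0)
  for (sid in names(tree@refs)) {
    idx <- tree@refs[[sid]]
    acc <- tree@refdb$accession[idx]
    idx <- idx[!acc %in% masked]
    out[sid] <- if (length(idx))
      max(seqSimilarity(query, tree@refdb$seq[idx], method)) else NA_real_
  }
  out
}

#' Candidate predictor vectors at a parent node
#'
#' For each candidate child of \code{parent} plus the unknown branch,
#' builds the 4-vector (intercept; no-reference indicator; best similarity
#' of the query to references beneath the candidate; margin of that
#' similarity over the best sibling). The unknown branch has no
#' references by construction.
#'
#' @param parent parent node id.
#' @param tree a \code{TaxonomyTree} with references attached.
#' @param spSims named vector of per-species best similarities (from
#'   masked or unmasked reference sets); pass a precomputed vector to
#'   avoid recomputation across ranks.
#' @param maskedNodes node ids treated as absent (novel-lineage
#'   simulation).
#' @return list with \code{candidates} (child ids and NA for unknown),
#'   \code{X} (matrix, one row per candidate) and \code{hasRefs}.
#' @export
nodePredictors <- function(parent, tree, spSims,
                           maskedNodes = integer(0)) {
  kids <- setdiff(childrenOf(tree, parent), maskedNodes)
  if (!length(kids))
    stop("node ", parent, " has no candidate children", call. = FALSE)
  best <- vapply(kids, function(k) {
    sp <- setdiff(speciesBelow(tree, k), maskedNodes)
    v <- spSims[as.character(sp)]
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  }, 0)
  hasRefs <- !is.na(best)
  sim <- ifelse(hasRefs, best, 0)
  nC <- length(kids) + 1L
  x2 <- c(sim, 0)
  x1 <- c(as.numeric(!hasRefs), 1)
  x3 <- vapply(seq_len(nC), function(i) {
    sib <- x2[-i]
    x2[i] - if (length(sib)) max(sib) else 0
  }, 0)
  X <- cbind(1, x1, x2, x3)
  colnames(X) <- c("x0", "x1", "x2", "x3")
  list(candidates = c(kids, NA_integer_), X = X,
       hasRefs = c(hasRefs, FALSE))
}

#' Posterior over the candidates of one node
#'
#' Mixes a uniform mislabelling component with a prior-weighted
#' multinomial regression:
#' \deqn{p(c) = \epsilon / K + (1 - \epsilon)\,
#'   \mathrm{softmax}_c(\beta^T x_c + \log \pi_c)}
#' so the probabilities always sum to one over the K candidates (the
#' node's children plus the unknown branch).
#'
#' @param X predictor matrix (one row per candidate).
#' @param beta numeric vector of 4 regression coefficients.
#' @param eps mislabelling probability in [0, 1].
#' @param prior candidate prior probabilities (uniform when NULL).
#' @return numeric vector of posterior probabilities.
#' @export
nodePosterior <- function(X, beta, eps, prior = NULL) {
  K <- nrow(X)
  if (K < 1L) stop("no candidates", call. = FALSE)
  if (is.null(prior)) prior <- rep(1 / K, K)
  prior <- prior / sum(prior)
  s <- softmax(as.vector(X %*% beta) + log(pmax(prior, 1e-300)))
  eps / K + (1 - eps) * s
}

#' Species prior weights
#'
#' Splits a total prior mass between an expected-species list and all
#' other species: each expected species receives
#' \code{massExpected/|expected|} and each remaining species shares the
#' complement. With an empty expected list (or when every species is
#' expected) the prior is uniform.
#'
#' @param speciesNames character vector of all species in the taxonomy.
#' @param expected character vector of expected species.
#' @param massExpected prior mass given to the expected set (default 0.9).
#' @return named numeric vector of per-species priors summing to 1.
#' @export
speciesPriors <- function(speciesNames, expected = character(0),
                          massExpected = 0.9) {
  expected <- intersect(expected, speciesNames)
  n <- length(speciesNames)
  others <- setdiff(speciesNames, expected)
  if (!length(expected) || !length(others))
    return(setNames(rep(1 / n, n), speciesNames))
  p <- setNames(rep((1 - massExpected) / length(others), n), speciesNames)
  p[expected] <- massExpected / length(expected)
  p
}

## candidate priors at a parent: children get their summed descendant
## species mass; the unknown branch gets the mean child mass (neutral
## share), then the vector is renormalised
.candidatePriors <- function(tree, candidates, spPrior) {
  kids <- candidates[!is.na(candidates)]
  mass <- vapply(kids, function(k) {
    sp <- speciesBelow(tree, k)
    nm <- tree@nodes$name[match(sp, tree@nodes$id)]
    sum(spPrior[nm], na.rm = TRUE)
  }, 0)
  if (all(mass == 0)) mass <- rep(1, length(kids))
  pri <- c(mass, mean(mass))
  pri / sum(pri)
}

#' ProtaxModel: fitted per-rank placement parameters
#'
#' Four regression coefficients and a mislabelling probability per rank
#' (order, family, genus, species), 5 parameters per rank.
#'
#' @slot beta 4 x 4 numeric matrix, rows = ranks, columns = coefficients.
#' @slot eps named numeric vector of per-rank mislabelling probabilities.
#' @slot meta list of fitting metadata (seed, training size, convergence).
#' @export
setClass("ProtaxModel", representation(
  beta = "matrix", eps = "numeric", meta = "list"
))

setValidity("ProtaxModel", function(object) {
  rks <- c("order", "family", "genus", "species")
  if (!identical(rownames(object@beta), rks)) return("beta rows != ranks")
  if (ncol(object@beta) != 4L) return("beta must have 4 columns")
  if (!identical(names(object@eps), rks)) return("eps names != ranks")
  if (any(object@eps < 0 | object@eps > 1)) return("eps outside [0,1]")
  TRUE
})

#' Construct a ProtaxModel
#'
#' @param beta 4 x 4 matrix of coefficients (rows order, family, genus,
#'   species).
#' @param eps per-rank mislabelling probabilities.
#' @param meta metadata list.
#' @return a validated \code{ProtaxModel}.
#' @export
protaxModel <- function(beta, eps, meta = list()) {
  rks <- c("order", "family", "genus", "species")
  beta <- matrix(as.numeric(beta), nrow = 4, ncol = 4,
                 dimnames = list(rks, c("b0", "b1", "b2", "b3")))
  new("ProtaxModel", beta = beta, eps = setNames(as.numeric(eps), rks),
      meta = meta)
}

setMethod("show", "ProtaxModel", function(object) {
  cat("ProtaxModel (4 ranks x [4 coefficients + mislabelling prob]):\n")
  m <- cbind(object@beta, eps = object@eps)
  print(round(m, 4))
})

#' Write/read a fitted model as TSV
#'
#' @param model a \code{ProtaxModel}.
#' @param file path.
#' @return \code{readProtaxModel} returns a \code{ProtaxModel}.
#' @export
writeProtaxModel <- function(model, file) {
  df <- data.frame(rank = rownames(model@beta), model@beta,
                   eps = model@eps, stringsAsFactors = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeProtaxModel
#' @export
readProtaxModel <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  protaxModel(as.matrix(df[, c("b0", "b1", "b2", "b3")]), df$eps)
}
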