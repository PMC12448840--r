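# Synthetic generators: community-structured interaction graphs (stochastic
# block model), random protein sequences, embeddings with planted
# within-block correlation, and scenario pathway collections spanning
# overlap-driven and interaction-driven enrichment regimes. Every generator
# is a pure function of its parameters and seed, so fixtures are built in
# code at any scale.

#' Block (community) assignment for synthetic proteins
#'
#' Deterministic identifiers \code{P0001, P0002, ...} split into
#' \code{nCommunities} contiguous blocks of near-equal size.
#'
#' @param nNodes number of proteins.
#' @param nCommunities number of blocks.
#' @return named integer vector: identifier -> block index.
#' @export
communityBlocks <- function(nNodes, nCommunities) {
  nNodes <- as.integer(nNodes)
  nCommunities <- as.integer(nCommunities)
  if (nNodes < nCommunities) stop("need at least one node per community")
  sizes <- rep(nNodes %/% nCommunities, nCommunities)
  extra <- nNodes %% nCommunities
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  stats::setNames(rep(seq_len(nCommunities), sizes),
                  sprintf("P%04d", seq_len(nNodes)))
}

#' Generate a stochastic block model interaction graph
#'
#' Undirected simple graph with within-community edge probability \code{pIn}
#' and cross-community probability \code{pOut} (\code{pOut <= pIn}), via
#' \code{igraph::sample_sbm}. Node identifiers and block assignment follow
#' [communityBlocks()].
#'
#' @param nNodes,nCommunities graph size and number of communities.
#' @param pIn,pOut edge probabilities, \code{0 <= pOut <= pIn <= 1}.
#' @param seed RNG seed.
#' @param score combined score attached to every edge.
#' @return A [PPIEdges-class]; the block assignment is attached as
#'   attribute \code{"blocks"}.
#' @export
generateSBMGraph <- function(nNodes, nCommunities, pIn, pOut, seed = 1L,
                             score = 900) {
  if (!(pOut >= 0 && pOut <= pIn && pIn <= 1)) {
    stop("need 0 <= pOut <= pIn <= 1")
  }
  blocks <- communityBlocks(nNodes, nCommunities)
  sizes <- as.integer(table(blocks))
  pref <- matrix(pOut, nCommunities, nCommunities)
  diag(pref) <- pIn
  g <- .withSeed(seed,
    igraph::sample_sbm(nNodes, pref.matrix = pref, block.sizes = sizes)
  )
  el <- igraph::as_edgelist(g, names = FALSE)
  ids <- names(blocks)
  edges <- if (nrow(el)) {
    PPIEdges(ids[el[, 1L]], ids[el[, 2L]], rep(score, nrow(el)))
  } else {
    new("PPIEdges", protA = character(), protB = character(),
        score = numeric())
  }
  attr(edges, "blocks") <- blocks
  edges
}

#' Generate random amino-acid sequences
#'
#' Residues uniform over the 20-letter canonical alphabet; lengths uniform
#' in \code{[minLen, maxLen]}; identifiers \code{P0001...}.
#'
#' @param n number of sequences.
#' @param minLen,maxLen length range.
#' @param seed RNG seed.
#' @return named character vector of sequences.
#' @export
generateSequences <- function(n, minLen = 50L, maxLen = 200L, seed = 1L) {
  if (minLen < 1L || maxLen < minLen) stop("need 1 <= minLen <= maxLen")
  .withSeed(seed, {
    lens <- minLen + sample.int(maxLen - minLen + 1L, n,
                                replace = TRUE) - 1L
    seqs <- vapply(lens, function(L) {
      paste(sample(.AA_ALPHABET, L, replace = TRUE), collapse = "")
    }, "")
    stats::setNames(seqs, sprintf("P%04d", seq_len(n)))
  })
}

#' Generate embeddings with planted within-block correlation
#'
#' Each protein's vector is \code{sqrt(rho) * g_block + sqrt(1 - rho) * e},
#' with the shared block vector \code{g_block} and the idiosyncratic noise
#' \code{e} both standard normal, so the expected within-block pairwise
#' Pearson correlation is \code{rho} and cross-block correlation is 0.
#'
#' @param blocks named integer vector (identifier -> block), e.g. from
#'   [communityBlocks()].
#' @param dim embedding dimension, >= 3.
#' @param rho target within-block correlation in [0, 1).
#' @param seed RNG seed.
#' @return A [ProteinEmbeddings-class].
#' @export
generatePlantedEmbeddings <- function(blocks, dim = 64L, rho = 0.9,
                                      seed = 1L) {
  dim <- as.integer(dim)
  if (dim < 3L) stop("dim must be at least 3")
  if (!(rho >= 0 && rho < 1)) stop("rho must lie in [0, 1)")
  stopifnot(!is.null(names(blocks)))
  .withSeed(seed, {
    shared <- matrix(stats::rnorm(max(blocks) * dim), max(blocks), dim)
    noise <- matrix(stats::rnorm(length(blocks) * dim), length(blocks), dim)
    m <- sqrt(rho) * shared[blocks, , drop = FALSE] +
      sqrt(1 - rho) * noise
    rownames(m) <- names(blocks)
    ProteinEmbeddings(m)
  })
}

#' Generate a scenario pathway collection and matching query
#'
#' Builds a query from block 1 and one pathway per requested scenario:
#' \describe{
#'   \item{overlap_rich}{shares \code{shareFraction} of the query's members,
#'     padded with cross-block proteins.}
#'   \item{overlap_free_linked}{disjoint from the query but drawn from the
#'     query's block, so under correlated (or trained) embeddings it is
#'     detectable purely through interaction-driven correlation.}
#'   \item{unrelated}{disjoint and drawn from other blocks.}
#' }
#'
#' @param blocks named integer vector (identifier -> block).
#' @param scenarios character subset of the three scenario names; one
#'   pathway per entry.
#' @param querySize number of query identifiers.
#' @param pathwaySize members per generated pathway.
#' @param shareFraction fraction of the query copied into the overlap_rich
#'   pathway.
#' @param seed RNG seed.
#' @return list with elements \code{query} ([GeneQuery-class]) and
#'   \code{collection} ([PathwayCollection-class]).
#' @export
generateScenarioCollection <- function(blocks,
                                       scenarios = c("overlap_rich",
                                                     "overlap_free_linked",
                                                     "unrelated"),
                                       querySize = 10L, pathwaySize = 10L,
                                       shareFraction = 0.5, seed = 1L) {
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  ids1 <- names(blocks)[blocks == 1L]
  others <- names(blocks)[blocks != 1L]
  if (length(ids1) < querySize + pathwaySize) {
    stop("block 1 too small for a disjoint linked pathway")
  }
  if (length(others) < 2L * pathwaySize) {
    stop("not enough cross-block proteins")
  }
  .withSeed(seed, {
    qids <- sample(ids1, querySize)
    linkedPool <- setdiff(ids1, qids)
    sets <- list()
    usedOther <- character()
    for (sc in scenarios) {
      sets[[sc]] <- switch(sc,
        overlap_rich = {
          nShare <- ceiling(shareFraction * querySize)
          fill <- sample(setdiff(others, usedOther),
                         pathwaySize - nShare)
          usedOther <- c(usedOther, fill)
          c(sample(qids, nShare), fill)
        },
        overlap_free_linked = sample(linkedPool, pathwaySize),
        unrelated = {
          mem <- sample(setdiff(others, usedOther), pathwaySize)
          usedOther <- c(usedOther, mem)
          mem
        })
    }
    list(query = GeneQuery(qids, label = "synthetic-query"),
         collection = PathwayCollection("scenarios", names(sets), sets,
                                        descriptions = names(sets)))
  })
}
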