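# Permutation-based significance: an empirical null of random same-size
# gene lists scored against each pathway, empirical p-values, and
# Benjamini-Hochberg FDR control. The same random lists are reused across
# all pathways of a run; null scores depend on beta and the filtration
# threshold and are recomputed per configuration.

#' Null distribution settings
#'
#' @param nPermutations number of random lists. The reference analysis uses
#'   100000 (minimal attainable p-value 1e-5); note the null cost scales as
#'   permutations x pathways, so small studies and test suites typically use
#'   a few hundred.
#' @param seed RNG seed for the list sampling.
#' @return validated list of class \code{null_config}.
#' @export
nullConfig <- function(nPermutations = 100000L, seed = 1L) {
  nPermutations <- as.integer(nPermutations)
  if (is.na(nPermutations) || nPermutations < 1L) {
    stop("nPermutations must be a positive integer")
  }
  structure(list(nPermutations = nPermutations, seed = as.integer(seed)),
            class = "null_config")
}

#' Sample random query lists from a universe
#'
#' Each list is an independent uniform without-replacement sample of
#' \code{size} identifiers; reproducible under a fixed seed. One sampled
#' batch is meant to be reused across every pathway of a run.
#'
#' @param universe character identifiers to sample from (typically the
#'   proteins with embeddings).
#' @param size list size (the number of encoded query proteins).
#' @param n number of lists.
#' @param seed RNG seed.
#' @return list of \code{n} character vectors.
#' @export
sampleNullQueries <- function(universe, size, n, seed = 1L) {
  universe <- as.character(universe)
  if (size > length(universe)) {
    stop("size (", size, ") exceeds universe size (", length(universe), ")")
  }
  if (n < 1L) stop("n must be at least 1")
  .withSeed(seed, lapply(seq_len(n), function(i) sample(universe, size)))
}

#' Empirical exceedance p-value
#'
#' \code{p = min(1, (b + 1) / n)} with \code{b} the number of null scores
#' greater than or equal to the observed score. The add-one numerator keeps
#' p strictly positive; the minimal attainable value is \code{1/n} (1e-5 at
#' 100000 permutations).
#'
#' @param observed observed score.
#' @param nullScores numeric vector of null scores.
#' @return p-value in (0, 1].
#' @examples
#' empiricalPvalue(0.25, c(0.1, 0.2, 0.3))  # (1 + 1) / 3
#' @export
empiricalPvalue <- function(observed, nullScores) {
  if (!length(nullScores)) stop("nullScores must be non-empty")
  min(1, (sum(nullScores >= observed) + 1) / length(nullScores))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH adjusted p-values (via [stats::p.adjust()]) with input
#' validation: every p must lie in (0, 1].
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return adjusted p-values, in the input order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bhAdjust <- function(pvalues) {
  if (!length(pvalues)) stop("pvalues must be non-empty")
  if (any(!is.finite(pvalues)) || any(pvalues <= 0 | pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

# Fast indexed scorer used for the permutation null. `filtFull` is the
# already-filtered universe-by-pathway correlation matrix; a query is a row
# subset, after which overlap masking, beta weighting and the row-max mean
# are applied exactly as in scoreQueryAgainstPathway().
.scoreSubset <- function(filtFull, rows, listIds, pathwayIds, beta) {
  sub <- filtFull[rows, , drop = FALSE]
  k <- match(pathwayIds, listIds)
  ov <- which(!is.na(k))
  if (length(ov)) {
    sub[, ov] <- 0
    sub[cbind(k[ov], ov)] <- beta
  }
  mx <- sub[cbind(seq_along(rows), max.col(sub, ties.method = "first"))]
  mean(pmax(mx, 0))
}

#' Assess significance of enrichment results
#'
#' Samples \code{nPermutations} random lists of the same size as the encoded
#' query from the embedding universe, scores every list against every
#' (non-skipped) pathway under the same scoring configuration, and fills in
#' empirical p-values and BH-adjusted p-values. The BH family is the set of
#' non-skipped pathways in the collection (per-database correction); skipped
#' pathways keep NA.
#'
#' @param results an [EnrichmentTable-class] from [enrich()].
#' @param collection the [PathwayCollection-class] that produced it.
#' @param embeddings the [ProteinEmbeddings-class] used for scoring.
#' @param config the same [scoringConfig()] used by [enrich()] (a beta or
#'   threshold mismatch is an error: null distributions depend on both).
#' @param null a [nullConfig()].
#' @return the [EnrichmentTable-class] with \code{pvalue} and \code{bh}
#'   filled in and \code{nPermutations} recorded.
#' @export
assessSignificance <- function(results, collection, embeddings,
                               config = scoringConfig(),
                               null = nullConfig()) {
  stopifnot(is(results, "EnrichmentTable"),
            is(collection, "PathwayCollection"),
            is(embeddings, "ProteinEmbeddings"),
            inherits(config, "scoring_config"),
            inherits(null, "null_config"))
  if (results@beta != config$beta) {
    stop("beta mismatch: results were scored at beta = ", results@beta,
         ", config has ", config$beta)
  }
  if (results@corrThreshold != config$corrThreshold) {
    stop("corrThreshold mismatch between results and config")
  }
  tab <- results@table
  if (!all(tab$pathway_id %in% collection@pathwayIds)) {
    stop("results contain pathways absent from the collection")
  }
  universe <- rownames(embeddings@embeddings)
  size <- results@nQuery
  lists <- sampleNullQueries(universe, size, null$nPermutations, null$seed)
  rowsOf <- lapply(lists, match, universe)

  Z <- .standardizeRows(embeddings@embeddings)
  members <- stats::setNames(collection@members, collection@pathwayIds)
  active <- which(!tab$skipped)
  for (i in active) {
    mem <- members[[tab$pathway_id[i]]]
    pids <- mem[mem %in% universe]
    filtFull <- filterCorrelations(
      .clampCor(tcrossprod(Z, Z[pids, , drop = FALSE])),
      config$corrThreshold
    )
    nullScores <- vapply(seq_along(lists), function(j) {
      .scoreSubset(filtFull, rowsOf[[j]], lists[[j]], pids, config$beta)
    }, 0)
    tab$pvalue[i] <- empiricalPvalue(tab$score[i], nullScores)
  }
  if (length(active)) {
    tab$bh[active] <- bhAdjust(tab$pvalue[active])
  }
  new("EnrichmentTable", table = tab, beta = results@beta,
      corrThreshold = results@corrThreshold, nQuery = results@nQuery,
      queryLabel = results@queryLabel,
      nPermutations = null$nPermutations)
}
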