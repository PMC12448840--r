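# Enrichment scoring: query-by-pathway embedding correlation matrix,
# filtration, overlap masking, decomposition into overlap/interaction parts
# and the (weighted) enrichment score.
#
# Pipeline order (fixed): Pearson correlations -> filtration (strict >
# threshold) -> overlap masking by identifier equality -> decomposition ->
# beta weighting -> per-query-row maxima -> mean.

#' Scoring settings
#'
#' @param beta overlap weight, >= 1. At 1 the score is the plain enrichment
#'   score (ES); larger values progressively up-weight exact gene overlaps
#'   relative to interaction-driven correlations. Default 10, the trade-off
#'   value between the two regimes.
#' @param corrThreshold filtration threshold in (0, 1); correlations not
#'   strictly above it are zeroed. Default 0.9.
#' @param missingAsZero if TRUE, query identifiers absent from the embedding
#'   table count as all-zero rows in the score's mean (denominator = full
#'   query size); if FALSE (default) they are dropped and the mean runs over
#'   encoded query proteins only.
#' @return validated list of class \code{scoring_config}.
#' @export
scoringConfig <- function(beta = 10, corrThreshold = 0.9,
                          missingAsZero = FALSE) {
  if (!is.numeric(beta) || length(beta) != 1L || beta < 1) {
    stop("beta must be a single number >= 1")
  }
  if (!(corrThreshold > 0 && corrThreshold < 1)) {
    stop("corrThreshold must lie strictly between 0 and 1")
  }
  structure(list(beta = as.numeric(beta),
                 corrThreshold = as.numeric(corrThreshold),
                 missingAsZero = isTRUE(missingAsZero)),
            class = "scoring_config")
}

#' Pearson correlation with a zero-variance convention
#'
#' Standard Pearson correlation between two coordinate vectors; if either
#' vector has zero variance the correlation is defined as 0 (a degenerate
#' embedding can never pass the filtration threshold).
#'
#' @param u,v numeric vectors of equal length >= 3.
#' @return correlation in [-1, 1].
#' @examples
#' pearsonCor(c(1, 2, 3), c(1, 1, 2))  # sqrt(3)/2
#' pearsonCor(c(1, 2, 3), c(5, 5, 5))  # 0 by convention
#' @export
pearsonCor <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  if (length(u) < 3L) stop("vectors must have length at least 3")
  if (stats::sd(u) == 0 || stats::sd(v) == 0) return(0)
  .clampCor(stats::cor(u, v))
}

#' Encode an identifier list as a matrix of embedding rows
#'
#' Looks up each identifier in the embedding table, preserving order;
#' identifiers without an embedding are recorded in \code{dropped} (and
#' warned about).
#'
#' @param embeddings a [ProteinEmbeddings-class].
#' @param ids character identifiers.
#' @param warn warn about dropped identifiers.
#' @return list with \code{ids} (retained, in order), \code{matrix} (rows =
#'   embedding vectors) and \code{dropped}.
#' @export
encodeSet <- function(embeddings, ids, warn = TRUE) {
  stopifnot(is(embeddings, "ProteinEmbeddings"))
  ids <- as.character(ids)
  have <- ids %in% rownames(embeddings@embeddings)
  if (warn && !all(have)) {
    warning(sum(!have), " identifier(s) absent from the embedding table: ",
            paste(utils::head(ids[!have], 5L), collapse = ", "))
  }
  keep <- ids[have]
  list(ids = keep,
       matrix = embeddings@embeddings[keep, , drop = FALSE],
       dropped = ids[!have])
}

#' Raw query-by-pathway correlation matrix
#'
#' Entry (k, l) is the Pearson correlation between the k-th query embedding
#' and the l-th pathway embedding ([pearsonCor()] semantics, including the
#' zero-variance convention).
#'
#' @param queryMat,pathwayMat numeric matrices of embedding rows sharing the
#'   same column dimension (>= 3).
#' @return numeric matrix (query rows x pathway rows).
#' @export
correlationMatrix <- function(queryMat, pathwayMat) {
  if (ncol(queryMat) != ncol(pathwayMat)) {
    stop("embedding dimension mismatch: ", ncol(queryMat), " vs ",
         ncol(pathwayMat))
  }
  .clampCor(tcrossprod(.standardizeRows(queryMat),
                       .standardizeRows(pathwayMat)))
}

#' Zero out weak correlations
#'
#' Entries not strictly above the threshold are set to 0 (an entry exactly
#' equal to the threshold is zeroed).
#'
#' @param mat correlation matrix.
#' @param corrThreshold threshold in (0, 1).
#' @return filtered matrix.
#' @export
filterCorrelations <- function(mat, corrThreshold = 0.9) {
  if (!(corrThreshold > 0 && corrThreshold < 1)) {
    stop("corrThreshold must lie strictly between 0 and 1")
  }
  mat[mat <= corrThreshold] <- 0
  mat
}

#' Mask overlap columns
#'
#' Overlap pairs are detected by identifier equality (the robust realization
#' of "correlation equal to 1 means the same gene"): for each pathway
#' protein also present in the query, its matrix entry against itself is set
#' to exactly 1 and every other entry in that column is set to 0, so exact
#' overlaps cannot also contribute spurious interaction signal.
#'
#' @param filtered filtered correlation matrix.
#' @param queryIds,pathwayIds identifiers of the rows/columns.
#' @return list with \code{matrix} (masked) and \code{overlapPairs}
#'   (two-column character matrix of matched identifiers).
#' @export
maskOverlaps <- function(filtered, queryIds, pathwayIds) {
  stopifnot(nrow(filtered) == length(queryIds),
            ncol(filtered) == length(pathwayIds))
  cols <- which(pathwayIds %in% queryIds)
  pairs <- matrix(character(), 0L, 2L,
                  dimnames = list(NULL, c("query", "pathway")))
  for (l in cols) {
    k <- match(pathwayIds[l], queryIds)
    filtered[, l] <- 0
    filtered[k, l] <- 1
    pairs <- rbind(pairs, c(queryIds[k], pathwayIds[l]))
  }
  list(matrix = filtered, overlapPairs = pairs)
}

#' Decompose a masked matrix into overlap and interaction parts
#'
#' \code{overlap} is a binary matrix with 1 exactly at the overlap pairs;
#' \code{interaction = masked - overlap}, so the two parts reconstruct the
#' masked matrix entrywise.
#'
#' @param masked masked matrix from [maskOverlaps()].
#' @param queryIds,pathwayIds row/column identifiers.
#' @param overlapPairs the pair matrix from [maskOverlaps()].
#' @return list with matrices \code{overlap} and \code{interaction}.
#' @export
decomposeCorrelations <- function(masked, queryIds, pathwayIds,
                                  overlapPairs) {
  ov <- matrix(0, nrow(masked), ncol(masked))
  if (nrow(overlapPairs)) {
    ov[cbind(match(overlapPairs[, 1L], queryIds),
             match(overlapPairs[, 2L], pathwayIds))] <- 1
  }
  list(overlap = ov, interaction = masked - ov)
}

#' Beta-weighted enrichment score
#'
#' Weights the overlap part by beta, takes the maximum of each query row of
#' \code{interaction + beta * overlap} and averages: the weighted enrichment
#' score (WES; the plain ES at beta = 1). All-zero rows contribute 0. An
#' empty matrix scores 0 with \code{empty = TRUE}.
#'
#' @param overlap,interaction matrices from [decomposeCorrelations()].
#' @param beta overlap weight >= 1.
#' @param nDenom denominator of the mean; defaults to the number of rows
#'   (set it to the full query size to count unencoded query genes as zero
#'   rows).
#' @return list with \code{maxC} (per-row maxima), \code{score} and
#'   \code{empty}.
#' @examples
#' ov <- matrix(c(1, 0, 0, 0), 2, 2)
#' it <- matrix(c(0, 0, 0.95, 0.92), 2, 2)
#' weightedScore(ov, it, beta = 10)$score  # (10 + 0.92) / 2
#' @export
weightedScore <- function(overlap, interaction, beta = 10, nDenom = NULL) {
  stopifnot(identical(dim(overlap), dim(interaction)))
  if (beta < 1) stop("beta must be >= 1")
  if (nrow(overlap) == 0L || ncol(overlap) == 0L) {
    return(list(maxC = numeric(nrow(overlap)), score = 0, empty = TRUE))
  }
  weighted <- interaction + beta * overlap
  maxC <- pmax(apply(weighted, 1L, max), 0)
  if (is.null(nDenom)) nDenom <- nrow(overlap)
  list(maxC = maxC, score = sum(maxC) / nDenom, empty = FALSE)
}

#' Score one query against one pathway
#'
#' Runs the full scoring pipeline for a single query/pathway pair and
#' returns every intermediate as a [ScoreBreakdown-class].
#'
#' @param embeddings a [ProteinEmbeddings-class].
#' @param queryIds,pathwayIds identifier vectors.
#' @param config a [scoringConfig()].
#' @param warn warn about identifiers without embeddings.
#' @return A [ScoreBreakdown-class].
#' @export
scoreQueryAgainstPathway <- function(embeddings, queryIds, pathwayIds,
                                     config = scoringConfig(),
                                     warn = FALSE) {
  stopifnot(inherits(config, "scoring_config"))
  q <- encodeSet(embeddings, queryIds, warn = warn)
  p <- encodeSet(embeddings, pathwayIds, warn = warn)
  if (!length(q$ids)) stop("no encodable query identifiers")
  if (!length(p$ids)) {
    empty <- matrix(0, length(q$ids), 0L)
    return(new("ScoreBreakdown", corr = empty, overlap = empty,
               interaction = empty, maxC = numeric(length(q$ids)),
               score = 0, beta = config$beta,
               corrThreshold = config$corrThreshold, queryIds = q$ids,
               pathwayIds = character(), droppedQuery = q$dropped,
               droppedPathway = p$dropped))
  }
  raw <- correlationMatrix(q$matrix, p$matrix)
  filt <- filterCorrelations(raw, config$corrThreshold)
  mk <- maskOverlaps(filt, q$ids, p$ids)
  parts <- decomposeCorrelations(mk$matrix, q$ids, p$ids, mk$overlapPairs)
  nDenom <- if (config$missingAsZero) length(queryIds) else NULL
  ws <- weightedScore(parts$overlap, parts$interaction, config$beta, nDenom)
  new("ScoreBreakdown", corr = mk$matrix, overlap = parts$overlap,
      interaction = parts$interaction, maxC = ws$maxC, score = ws$score,
      beta = config$beta, corrThreshold = config$corrThreshold,
      queryIds = q$ids, pathwayIds = p$ids, droppedQuery = q$dropped,
      droppedPathway = p$dropped)
}

#' Count query-pathway PPI edges
#'
#' Number of undirected interaction edges with one endpoint in the query and
#' the other in the pathway, each unordered pair counted once.
#'
#' @param queryIds,pathwayIds identifier vectors.
#' @param edges a [PPIEdges-class].
#' @return integer count.
#' @export
countInteractions <- function(queryIds, pathwayIds, edges) {
  stopifnot(is(edges, "PPIEdges"))
  aq <- edges@protA %in% queryIds
  bq <- edges@protB %in% queryIds
  ap <- edges@protA %in% pathwayIds
  bp <- edges@protB %in% pathwayIds
  sum((aq & bp) | (bq & ap))
}

#' Enrich a query against a pathway collection
#'
#' Scores every pathway in the collection against the query (scores only;
#' p-values are filled in by [assessSignificance()]). Pathways with no
#' encodable member are emitted with score 0 and flagged \code{skipped};
#' they are excluded from the multiple-testing family later.
#'
#' @param query a [GeneQuery-class].
#' @param collection a [PathwayCollection-class].
#' @param embeddings a [ProteinEmbeddings-class].
#' @param config a [scoringConfig()].
#' @param edges optional [PPIEdges-class]; when supplied, the per-pathway
#'   count of query-pathway PPI edges is reported (otherwise NA).
#' @return An [EnrichmentTable-class] with \code{pvalue}/\code{bh} set to NA.
#' @export
enrich <- function(query, collection, embeddings,
                   config = scoringConfig(), edges = NULL) {
  stopifnot(is(query, "GeneQuery"), is(collection, "PathwayCollection"),
            is(embeddings, "ProteinEmbeddings"),
            inherits(config, "scoring_config"))
  qids <- query@identifiers
  qEnc <- encodeSet(embeddings, qids, warn = TRUE)
  if (!length(qEnc$ids)) {
    stop("no query identifier has an embedding; cannot score")
  }
  ids <- collection@pathwayIds
  n <- length(ids)
  res <- data.frame(
    pathway_id = ids,
    pathway_size = lengths(collection@members),
    overlap = NA_integer_, coverage = NA_real_,
    interactions = NA_integer_, corr_entries = NA_integer_,
    score = NA_real_, pvalue = NA_real_, bh = NA_real_,
    skipped = FALSE, stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    mem <- collection@members[[i]]
    res$overlap[i] <- length(intersect(qids, mem))
    res$coverage[i] <- res$overlap[i] / length(mem)
    if (!is.null(edges)) {
      res$interactions[i] <- countInteractions(qids, mem, edges)
    }
    bd <- scoreQueryAgainstPathway(embeddings, qids, mem, config)
    res$score[i] <- bd@score
    res$corr_entries[i] <- sum(bd@interaction > 0)
    res$skipped[i] <- length(bd@pathwayIds) == 0L
  }
  if (any(res$skipped)) {
    warning(sum(res$skipped), " pathway(s) had no member with an ",
            "embedding and were skipped: ",
            paste(utils::head(res$pathway_id[res$skipped], 5L),
                  collapse = ", "))
  }
  new("EnrichmentTable", table = res, beta = config$beta,
      corrThreshold = config$corrThreshold,
      nQuery = length(qEnc$ids), queryLabel = query@label,
      nPermutations = NA_integer_)
}
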