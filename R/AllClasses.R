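#' @import methods
NULL

#' PathwayCollection: a named collection of pathway gene sets
#'
#' Container for a gene-set collection as read from a GMT file: each pathway
#' has a unique identifier, a free-text description and an ordered list of
#' unique member gene/protein identifiers.
#'
#' @slot name single character, the collection (database) name.
#' @slot pathwayIds character vector of unique pathway identifiers.
#' @slot descriptions character vector parallel to \code{pathwayIds}.
#' @slot members list of character vectors (the member identifiers of each
#'   pathway), parallel to \code{pathwayIds}.
#'
#' @seealso [readGMT()], [pathwayIds()], [pathwayMembers()]
#' @export
setClass("PathwayCollection",
  slots = c(
    name = "character",
    pathwayIds = "character",
    descriptions = "character",
    members = "list"
  )
)

setValidity("PathwayCollection", function(object) {
  msg <- character()
  if (length(object@name) != 1L)
    msg <- c(msg, "'name' must be a single string")
  n <- length(object@pathwayIds)
  if (length(object@descriptions) != n || length(object@members) != n)
    msg <- c(msg, "pathwayIds, descriptions and members must be parallel")
  if (anyDuplicated(object@pathwayIds))
    msg <- c(msg, "pathway identifiers must be unique within a collection")
  if (n > 0L) {
    sizes <- lengths(object@members)
    if (any(sizes == 0L))
      msg <- c(msg, "every pathway must have at least one member")
    if (any(vapply(object@members, anyDuplicated, 0L) > 0L))
      msg <- c(msg, "member lists must not contain duplicates")
  }
  if (length(msg)) msg else TRUE
})

#' PathwayCollection constructor
#'
#' @param name collection name.
#' @param pathwayIds character vector of unique pathway identifiers.
#' @param members list of character member vectors, one per pathway.
#' @param descriptions optional character vector of descriptions.
#' @return A [PathwayCollection-class] object.
#' @examples
#' pc <- PathwayCollection("toy", c("P1", "P2"),
#'                         list(c("G1", "G2"), c("G2", "G3")))
#' pathwayIds(pc)
#' @export
PathwayCollection <- function(name, pathwayIds, members,
                              descriptions = rep("", length(pathwayIds))) {
  new("PathwayCollection",
      name = as.character(name),
      pathwayIds = as.character(pathwayIds),
      descriptions = as.character(descriptions),
      members = lapply(members, as.character))
}

#' GeneQuery: an ordered list of query gene/protein identifiers
#'
#' @slot identifiers character vector, unique, non-empty.
#' @slot label single character label for the query.
#' @seealso [readQueryList()], [enrich()]
#' @export
setClass("GeneQuery",
  slots = c(identifiers = "character", label = "character")
)

setValidity("GeneQuery", function(object) {
  msg <- character()
  if (length(object@identifiers) == 0L)
    msg <- c(msg, "query must contain at least one identifier")
  if (anyDuplicated(object@identifiers))
    msg <- c(msg, "query identifiers must be unique")
  if (length(object@label) != 1L)
    msg <- c(msg, "'label' must be a single string")
  if (length(msg)) msg else TRUE
})

#' GeneQuery constructor
#'
#' @param identifiers character vector of gene/protein identifiers.
#' @param label query label.
#' @return A [GeneQuery-class] object.
#' @examples
#' q <- GeneQuery(c("TP53", "ATM"), label = "toy")
#' @export
GeneQuery <- function(identifiers, label = "query") {
  new("GeneQuery", identifiers = as.character(identifiers),
      label = as.character(label))
}

#' PPIEdges: an undirected protein-protein interaction edge list
#'
#' Edges are stored in canonical order (\code{protA < protB} lexicographically)
#' with no self-loops and no duplicate pairs, matching the undirected semantics
#' of STRING-style interaction tables.
#'
#' @slot protA character vector of first endpoints (canonical order).
#' @slot protB character vector of second endpoints.
#' @slot score numeric combined scores in [0, 1000].
#' @seealso [readStringEdges()], [countInteractions()]
#' @export
setClass("PPIEdges",
  slots = c(protA = "character", protB = "character", score = "numeric")
)

setValidity("PPIEdges", function(object) {
  msg <- character()
  n <- length(object@protA)
  if (length(object@protB) != n || length(object@score) != n)
    msg <- c(msg, "protA, protB and score must be parallel")
  if (n > 0L) {
    if (any(object@protA == object@protB))
      msg <- c(msg, "self-loops are not allowed")
    if (any(object@protA > object@protB))
      msg <- c(msg, "edges must be stored in canonical (protA < protB) order")
    if (anyDuplicated(paste(object@protA, object@protB, sep = "\r")))
      msg <- c(msg, "duplicate edges are not allowed")
    if (any(object@score < 0 | object@score > 1000))
      msg <- c(msg, "scores must lie in [0, 1000]")
  }
  if (length(msg)) msg else TRUE
})

#' PPIEdges constructor
#'
#' Symmetric duplicates are merged (keeping the maximum score) and self-loops
#' dropped, so any raw pair list is accepted.
#'
#' @param protA,protB character endpoint vectors.
#' @param score numeric scores in [0, 1000]; defaults to 900 for all edges.
#' @return A [PPIEdges-class] object.
#' @examples
#' e <- PPIEdges(c("A", "B"), c("B", "A"), c(900, 700))
#' edgeCount(e)  # 1: symmetric duplicate merged, max score kept
#' @export
PPIEdges <- function(protA, protB, score = rep(900, length(protA))) {
  protA <- as.character(protA)
  protB <- as.character(protB)
  score <- as.numeric(score)
  keep <- protA != protB
  a <- pmin(protA[keep], protB[keep])
  b <- pmax(protA[keep], protB[keep])
  s <- score[keep]
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    s <- vapply(split(s, key), max, 0)
    ab <- strsplit(names(s), "\r", fixed = TRUE)
    a <- vapply(ab, `[`, "", 1L)
    b <- vapply(ab, `[`, "", 2L)
  }
  o <- order(a, b)
  new("PPIEdges", protA = a[o], protB = b[o], score = as.numeric(s)[o])
}

#' ProteinEmbeddings: per-protein embedding vectors
#'
#' Wraps a numeric matrix whose rows are the fixed-length embedding vectors
#' (one per protein identifier). All downstream correlation scoring operates
#' on this container.
#'
#' @slot embeddings numeric matrix with unique rownames (protein identifiers)
#'   and at least 3 columns (Pearson correlation over fewer than 3 coordinates
#'   is degenerate).
#' @seealso [readEmbeddingTable()], [encodeProteins()], [enrich()]
#' @export
setClass("ProteinEmbeddings", slots = c(embeddings = "matrix"))

setValidity("ProteinEmbeddings", function(object) {
  m <- object@embeddings
  msg <- character()
  if (!is.numeric(m))
    msg <- c(msg, "embeddings must be numeric")
  if (nrow(m) == 0L)
    msg <- c(msg, "embedding table must be non-empty")
  if (ncol(m) < 3L)
    msg <- c(msg, "embedding dimension must be at least 3")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    msg <- c(msg, "rows must carry unique protein identifiers")
  if (length(m) && !all(is.finite(m)))
    msg <- c(msg, "embedding values must be finite")
  if (length(msg)) msg else TRUE
})

#' ProteinEmbeddings constructor
#'
#' @param embeddings numeric matrix, rows named by protein identifier,
#'   ncol >= 3.
#' @return A [ProteinEmbeddings-class] object.
#' @examples
#' m <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("P", 1:4), NULL))
#' emb <- ProteinEmbeddings(m)
#' embeddingDim(emb)
#' @export
ProteinEmbeddings <- function(embeddings) {
  new("ProteinEmbeddings", embeddings = as.matrix(embeddings))
}

#' PPIGraph: a featured interaction graph ready for encoder training
#'
#' @slot nodes character vector of node identifiers, sorted.
#' @slot edgeIdx two-column integer matrix of node indices (i < j), one row
#'   per undirected edge.
#' @slot features numeric matrix of per-node input features, rows parallel
#'   to \code{nodes}.
#' @seealso [buildGraph()], [trainEncoder()]
#' @export
setClass("PPIGraph",
  slots = c(nodes = "character", edgeIdx = "matrix",
            features = "matrix")
)

setValidity("PPIGraph", function(object) {
  msg <- character()
  n <- length(object@nodes)
  if (is.unsorted(object@nodes))
    msg <- c(msg, "nodes must be sorted")
  if (nrow(object@features) != n)
    msg <- c(msg, "features must have one row per node")
  e <- object@edgeIdx
  if (ncol(e) != 2L)
    msg <- c(msg, "edgeIdx must have two columns")
  if (nrow(e) > 0L) {
    if (any(e < 1L) || any(e > n))
      msg <- c(msg, "edge endpoints must index nodes")
    if (any(e[, 1L] == e[, 2L]))
      msg <- c(msg, "self-loops are not allowed")
    if (any(e[, 1L] > e[, 2L]))
      msg <- c(msg, "edges must be stored with i < j")
    if (anyDuplicated(paste(e[, 1L], e[, 2L])))
      msg <- c(msg, "duplicate edges are not allowed")
  }
  if (length(msg)) msg else TRUE
})

#' EncoderModel: a trained (or initialized) graph encoder
#'
#' @slot params list of layer weight matrices and bias vectors.
#' @slot config the [encoderConfig()] list used for training.
#' @slot history data.frame with one row per epoch (loss, validation AUC).
#' @slot split list with train/test edge index matrices.
#' @slot featureCenter,featureScale numeric vectors used to standardize node
#'   features before the first layer.
#' @seealso [trainEncoder()], [encodeProteins()]
#' @export
setClass("EncoderModel",
  slots = c(params = "list", config = "list", history = "data.frame",
                 split = "list", featureCenter = "numeric",
                 featureScale = "numeric")
)

#' ScoreBreakdown: the filtered, masked correlation matrix and its parts
#'
#' Holds the query-by-pathway correlation matrix after filtration and overlap
#' masking, its decomposition into an overlap indicator part and an
#' interaction part, the per-query-row maxima of the beta-weighted matrix and
#' the resulting enrichment score.
#'
#' @slot corr numeric matrix (filtered, masked correlations).
#' @slot overlap binary matrix: 1 exactly at overlap (same-identifier) pairs.
#' @slot interaction numeric matrix: \code{corr - overlap} entrywise.
#' @slot maxC per-query-row maxima of \code{interaction + beta * overlap}.
#' @slot score the (weighted) enrichment score: mean of \code{maxC}.
#' @slot beta,corrThreshold scoring parameters used.
#' @slot queryIds,pathwayIds row/column identifiers of the encoded sets.
#' @slot droppedQuery,droppedPathway identifiers absent from the embedding
#'   table.
#' @seealso [scoreQueryAgainstPathway()]
#' @export
setClass("ScoreBreakdown",
  slots = c(corr = "matrix", overlap = "matrix", interaction = "matrix",
                 maxC = "numeric", score = "numeric", beta = "numeric",
                 corrThreshold = "numeric", queryIds = "character",
                 pathwayIds = "character", droppedQuery = "character",
                 droppedPathway = "character")
)

#' EnrichmentTable: per-pathway enrichment results
#'
#' One row per pathway: weighted enrichment score, overlap and interaction
#' counts, coverage, and (after [assessSignificance()]) empirical p-value and
#' BH-adjusted p-value.
#'
#' @slot table data.frame with columns pathway_id, pathway_size, overlap,
#'   coverage, interactions, corr_entries, score, pvalue, bh, skipped.
#' @slot beta,corrThreshold scoring parameters the scores were computed with.
#' @slot nQuery number of encoded query proteins (rows of the correlation
#'   matrix, i.e. the N of the score's mean).
#' @slot queryLabel label of the scored query.
#' @slot nPermutations permutations used for the null (NA before assessment).
#' @seealso [enrich()], [assessSignificance()], [writeEnrichmentResults()]
#' @export
setClass("EnrichmentTable",
  slots = c(table = "data.frame", beta = "numeric",
                 corrThreshold = "numeric", nQuery = "integer",
                 queryLabel = "character", nPermutations = "integer")
)
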