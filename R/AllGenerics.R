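#' Accessor generics
#'
#' Small accessor generics for the package's S4 containers, so user code never
#' touches slots directly.
#'
#' @param x an object of the matching class.
#' @name accessors
NULL

#' @rdname accessors
#' @return `pathwayIds`: character vector of pathway identifiers.
#' @export
setGeneric("pathwayIds", function(x) standardGeneric("pathwayIds"))

#' @rdname accessors
#' @return `pathwayMembers`: named list of member identifier vectors.
#' @export
setGeneric("pathwayMembers", function(x) standardGeneric("pathwayMembers"))

#' @rdname accessors
#' @return `pathwayDescriptions`: named character vector of descriptions.
#' @export
setGeneric("pathwayDescriptions",
           function(x) standardGeneric("pathwayDescriptions"))

#' @rdname accessors
#' @return `collectionName`: the collection name.
#' @export
setGeneric("collectionName", function(x) standardGeneric("collectionName"))

#' @rdname accessors
#' @return `queryIds`: character vector of query identifiers.
#' @export
setGeneric("queryIds", function(x) standardGeneric("queryIds"))

#' @rdname accessors
#' @return `queryLabel`: the query label.
#' @export
setGeneric("queryLabel", function(x) standardGeneric("queryLabel"))

#' @rdname accessors
#' @return `edgeCount`: number of undirected edges.
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))

#' @rdname accessors
#' @return `edgeTable`: data.frame with columns protein1, protein2,
#'   combined_score.
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname accessors
#' @return `embeddingMatrix`: the numeric embedding matrix (rows = proteins).
#' @export
setGeneric("embeddingMatrix", function(x) standardGeneric("embeddingMatrix"))

#' @rdname accessors
#' @return `embeddingDim`: the embedding dimension.
#' @export
setGeneric("embeddingDim", function(x) standardGeneric("embeddingDim"))

#' @rdname accessors
#' @return `proteinIds`: character vector of protein identifiers.
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))

#' @rdname accessors
#' @return `graphNodes`: sorted node identifiers of a graph.
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))

#' @rdname accessors
#' @return `graphEdges`: two-column character matrix of edge endpoints.
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' @rdname accessors
#' @return `nodeFeatures`: per-node feature matrix.
#' @export
setGeneric("nodeFeatures", function(x) standardGeneric("nodeFeatures"))

#' @rdname accessors
#' @return `trainingHistory`: per-epoch data.frame (loss, validation AUC).
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))

#' @rdname accessors
#' @return `enrichmentScore`: the (weighted) enrichment score of a
#'   [ScoreBreakdown-class].
#' @export
setGeneric("enrichmentScore", function(x) standardGeneric("enrichmentScore"))
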