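# Accessor and show methods for the S4 containers.

#' @rdname accessors
#' @aliases pathwayIds,PathwayCollection-method
#' @export
setMethod("pathwayIds", "PathwayCollection", function(x) x@pathwayIds)

#' @rdname accessors
#' @export
setMethod("pathwayMembers", "PathwayCollection", function(x) {
  stats::setNames(x@members, x@pathwayIds)
})

#' @rdname accessors
#' @export
setMethod("pathwayDescriptions", "PathwayCollection", function(x) {
  stats::setNames(x@descriptions, x@pathwayIds)
})

#' @rdname accessors
#' @export
setMethod("collectionName", "PathwayCollection", function(x) x@name)

#' Number of pathways in a collection
#' @param x a [PathwayCollection-class].
#' @return integer.
#' @export
setMethod("length", "PathwayCollection", function(x) length(x@pathwayIds))

setMethod("show", "PathwayCollection", function(object) {
  cat("PathwayCollection '", object@name, "' with ",
      length(object@pathwayIds), " pathway(s)\n", sep = "")
  if (length(object@pathwayIds)) {
    sizes <- lengths(object@members)
    cat("  sizes: min ", min(sizes), ", median ", stats::median(sizes),
        ", max ", max(sizes), "\n", sep = "")
  }
})

#' @rdname accessors
#' @export
setMethod("queryIds", "GeneQuery", function(x) x@identifiers)

#' @rdname accessors
#' @export
setMethod("queryLabel", "GeneQuery", function(x) x@label)

#' Number of identifiers in a query
#' @param x a [GeneQuery-class].
#' @return integer.
#' @export
setMethod("length", "GeneQuery", function(x) length(x@identifiers))

setMethod("show", "GeneQuery", function(object) {
  cat("GeneQuery '", object@label, "': ", length(object@identifiers),
      " identifier(s)\n", sep = "")
})

#' @rdname accessors
#' @export
setMethod("edgeCount", "PPIEdges", function(x) length(x@protA))

#' @rdname accessors
#' @export
setMethod("edgeTable", "PPIEdges", function(x) {
  data.frame(protein1 = x@protA, protein2 = x@protB,
             combined_score = x@score, stringsAsFactors = FALSE)
})

setMethod("show", "PPIEdges", function(object) {
  cat("PPIEdges: ", length(object@protA), " undirected edge(s) among ",
      length(unique(c(object@protA, object@protB))), " protein(s)\n",
      sep = "")
})

#' @rdname accessors
#' @export
setMethod("embeddingMatrix", "ProteinEmbeddings", function(x) x@embeddings)

#' @rdname accessors
#' @export
setMethod("embeddingDim", "ProteinEmbeddings", function(x) ncol(x@embeddings))

#' @rdname accessors
#' @export
setMethod("proteinIds", "ProteinEmbeddings", function(x) rownames(x@embeddings))

setMethod("show", "ProteinEmbeddings", function(object) {
  cat("ProteinEmbeddings: ", nrow(object@embeddings), " protein(s), dim ",
      ncol(object@embeddings), "\n", sep = "")
})

#' @rdname accessors
#' @export
setMethod("graphNodes", "PPIGraph", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("graphEdges", "PPIGraph", function(x) {
  cbind(x@nodes[x@edgeIdx[, 1L]], x@nodes[x@edgeIdx[, 2L]])
})

#' @rdname accessors
#' @export
setMethod("nodeFeatures", "PPIGraph", function(x) x@features)

#' @rdname accessors
#' @export
setMethod("edgeCount", "PPIGraph", function(x) nrow(x@edgeIdx))

setMethod("show", "PPIGraph", function(object) {
  cat("PPIGraph: ", length(object@nodes), " node(s), ",
      nrow(object@edgeIdx), " edge(s), ", ncol(object@features),
      " feature(s)/node\n", sep = "")
})

#' @rdname accessors
#' @export
setMethod("trainingHistory", "EncoderModel", function(x) x@history)

setMethod("show", "EncoderModel", function(object) {
  cat("EncoderModel: dim ", object@config$embeddingDim, ", ",
      object@config$convLayers, " graph layer(s), ",
      nrow(object@history), " epoch(s) trained", sep = "")
  if (nrow(object@history)) {
    last <- object@history[nrow(object@history), ]
    cat(sprintf(" (final loss %.4f, val AUC %.3f)", last$loss, last$val_auc))
  }
  cat("\n")
})

#' @rdname accessors
#' @export
setMethod("enrichmentScore", "ScoreBreakdown", function(x) x@score)

setMethod("show", "ScoreBreakdown", function(object) {
  cat("ScoreBreakdown: ", nrow(object@corr), " query x ", ncol(object@corr),
      " pathway protein(s); beta ", object@beta, ", threshold ",
      object@corrThreshold, "\n  score ", format(object@score),
      " (overlap pairs: ", sum(object@overlap), ")\n", sep = "")
})

#' Coerce an EnrichmentTable to a data.frame
#'
#' @param x an [EnrichmentTable-class].
#' @param row.names,optional,... passed for S3 compatibility, unused.
#' @return the underlying data.frame (one row per pathway).
#' @export
as.data.frame.EnrichmentTable <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  x@table
}

setMethod("show", "EnrichmentTable", function(object) {
  tab <- object@table
  cat("EnrichmentTable for query '", object@queryLabel, "' (",
      object@nQuery, " encoded protein(s)): ", nrow(tab),
      " pathway(s), beta ", object@beta, "\n", sep = "")
  if (!is.na(object@nPermutations)) {
    cat("  significance: ", object@nPermutations, " permutation(s); ",
        sum(tab$bh < 0.05, na.rm = TRUE), " pathway(s) at BH < 0.05\n",
        sep = "")
  } else {
    cat("  significance: not assessed\n")
  }
  print(utils::head(tab[order(-tab$score), , drop = FALSE], 5L))
})

#' Number of pathway rows in an enrichment table
#' @param x an [EnrichmentTable-class].
#' @return integer.
#' @export
setMethod("length", "EnrichmentTable", function(x) nrow(x@table))
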