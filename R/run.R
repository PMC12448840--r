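# Workflow orchestration: YAML run configuration with strict key checking,
# a documented global-seed fan-out, and the encode -> score -> assess ->
# report pipeline behind the command-line front end
# (inst/scripts/ppienrich.R).

.RUN_DEFAULTS <- list(
  seed = 1L,
  encoder = list(embeddingDim = 64L, convLayers = 2L,
                 sequencePool = "mean-composition", learningRate = 0.01,
                 epochs = 200L, negativeRatio = 1, trainFraction = 0.8),
  scoring = list(beta = 10, corrThreshold = 0.9, missingAsZero = FALSE),
  permutations = list(nPermutations = 100000L),
  io = list(minScore = 0)
)

.mergeSection <- function(defaults, user, section) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s) in '", section, "': ",
         paste(unknown, collapse = ", "))
  }
  utils::modifyList(defaults, user)
}

#' Read and validate a run configuration
#'
#' YAML with the optional sections \code{encoder}, \code{scoring},
#' \code{permutations}, \code{io} and a global \code{seed}; unknown keys are
#' rejected. Missing values take the package defaults. The global seed fans
#' out deterministically to the encoder, null-sampling and fixture
#' sub-seeds via fixed offsets, so one seed reproduces a full run.
#'
#' @param path path to a YAML file, or NULL for pure defaults.
#' @return nested configuration list of class \code{run_config}, with the
#'   derived sub-seeds under \code{$seeds}.
#' @export
readRunConfig <- function(path = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  unknown <- setdiff(names(user), names(.RUN_DEFAULTS))
  if (length(unknown)) {
    stop("unknown configuration section(s): ",
         paste(unknown, collapse = ", "))
  }
  cfg <- .RUN_DEFAULTS
  if (!is.null(user$seed)) cfg$seed <- as.integer(user$seed)
  for (s in c("encoder", "scoring", "permutations", "io")) {
    cfg[[s]] <- .mergeSection(.RUN_DEFAULTS[[s]], user[[s]], s)
  }
  cfg$seeds <- .deriveSeeds(cfg$seed)
  structure(cfg, class = "run_config")
}

# One-line provenance log: effective seed, config hash and input checksums.
.logRun <- function(step, config, files = character()) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(unclass(config)), tmp)
  hash <- unname(tools::md5sum(tmp))
  message(sprintf("[%s] seed=%d config=%s", step, config$seed,
                  substr(hash, 1L, 8L)))
  files <- files[file.exists(files)]
  if (length(files)) {
    sums <- tools::md5sum(files)
    for (f in names(sums)) {
      message(sprintf("[%s] input %s md5=%s", step, basename(f),
                      substr(sums[[f]], 1L, 8L)))
    }
  }
}

#' Encode proteins from an edge list and sequences
#'
#' Reads the interaction edges and FASTA sequences, builds node features
#' (per \code{encoder$sequencePool}), trains the graph encoder by link
#' prediction and writes the embedding table. Edge endpoints without a
#' sequence are dropped with a warning.
#'
#' @param edgesFile STRING-style edge list path.
#' @param fastaFile FASTA path.
#' @param outFile output embedding TSV path.
#' @param config a [readRunConfig()] configuration.
#' @param seed optional override of the global seed.
#' @return the [ProteinEmbeddings-class], invisibly.
#' @export
runEncode <- function(edgesFile, fastaFile, outFile,
                      config = readRunConfig(), seed = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
    config$seeds <- .deriveSeeds(config$seed)
  }
  .logRun("encode", config, c(edgesFile, fastaFile))
  edges <- readStringEdges(edgesFile, minScore = config$io$minScore)
  seqs <- readFastaSequences(fastaFile)
  feats <- if (config$encoder$sequencePool == "conv1d") {
    convFeatures(seqs, seed = config$seeds$encoder)
  } else {
    compositionFeatures(seqs)
  }
  graph <- buildGraph(edges, feats)
  enc <- encoderConfig(
    embeddingDim = config$encoder$embeddingDim,
    convLayers = config$encoder$convLayers,
    sequencePool = config$encoder$sequencePool,
    learningRate = config$encoder$learningRate,
    epochs = config$encoder$epochs,
    negativeRatio = config$encoder$negativeRatio,
    trainFraction = config$encoder$trainFraction,
    seed = config$seeds$encoder
  )
  model <- trainEncoder(graph, enc)
  h <- model@history
  if (nrow(h)) {
    message(sprintf("[encode] final loss %.4f, validation AUC %.3f",
                    h$loss[nrow(h)], h$val_auc[nrow(h)]))
  }
  table <- encodeProteins(model, graph)
  writeEmbeddingTable(table, outFile)
  message("[encode] wrote ", nrow(embeddingMatrix(table)),
          " embeddings to ", outFile)
  invisible(table)
}

#' Run enrichment with significance assessment
#'
#' Scores the query against every pathway, assesses significance with the
#' permutation null and (optionally) writes the sorted results TSV.
#'
#' @param queryFile query list path.
#' @param gmtFile GMT collection path.
#' @param embeddingsFile embedding table path.
#' @param edgesFile optional edge list path (enables the per-pathway
#'   interaction count column).
#' @param outFile optional results TSV path.
#' @param config a [readRunConfig()] configuration.
#' @param beta,corrThreshold,nPermutations,seed optional overrides of the
#'   corresponding configuration values.
#' @return the assessed [EnrichmentTable-class], invisibly.
#' @export
runEnrich <- function(queryFile, gmtFile, embeddingsFile,
                      edgesFile = NULL, outFile = NULL,
                      config = readRunConfig(), beta = NULL,
                      corrThreshold = NULL, nPermutations = NULL,
                      seed = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
    config$seeds <- .deriveSeeds(config$seed)
  }
  if (!is.null(beta)) config$scoring$beta <- beta
  if (!is.null(corrThreshold)) config$scoring$corrThreshold <- corrThreshold
  if (!is.null(nPermutations)) config$permutations$nPermutations <- nPermutations
  .logRun("enrich", config,
          c(queryFile, gmtFile, embeddingsFile, edgesFile))
  query <- readQueryList(queryFile)
  collection <- readGMT(gmtFile)
  embeddings <- readEmbeddingTable(embeddingsFile)
  edges <- if (!is.null(edgesFile)) readStringEdges(edgesFile)
  sc <- scoringConfig(beta = config$scoring$beta,
                      corrThreshold = config$scoring$corrThreshold,
                      missingAsZero = config$scoring$missingAsZero)
  nc <- nullConfig(nPermutations = config$permutations$nPermutations,
                   seed = config$seeds$null)
  res <- enrich(query, collection, embeddings, sc, edges)
  res <- assessSignificance(res, collection, embeddings, sc, nc)
  if (!is.null(outFile)) {
    writeEnrichmentResults(res, outFile)
    message("[enrich] wrote ", length(res), " pathway rows to ", outFile)
  }
  invisible(res)
}

#' Scan the overlap weight beta
#'
#' Re-scores and re-assesses the query at each beta (null scores are
#' recomputed per beta from the same random lists) and returns the
#' long-format table behind per-beta heatmaps.
#'
#' @inheritParams runEnrich
#' @param betas numeric vector of beta values, all >= 1.
#' @return data.frame with columns pathway_id, beta, score, pvalue, bh
#'   (one block per beta), invisibly if \code{outFile} is given.
#' @export
runBetaScan <- function(queryFile, gmtFile, embeddingsFile,
                        edgesFile = NULL, outFile = NULL, betas = c(1, 10, 40),
                        config = readRunConfig(), nPermutations = NULL,
                        seed = NULL) {
  if (!length(betas) || any(betas < 1)) {
    stop("betas must be non-empty with every value >= 1")
  }
  out <- do.call(rbind, lapply(betas, function(b) {
    res <- runEnrich(queryFile, gmtFile, embeddingsFile, edgesFile,
                     outFile = NULL, config = config, beta = b,
                     nPermutations = nPermutations, seed = seed)
    tab <- as.data.frame(res)
    data.frame(pathway_id = tab$pathway_id, beta = b, score = tab$score,
               pvalue = tab$pvalue, bh = tab$bh, stringsAsFactors = FALSE)
  }))
  if (!is.null(outFile)) {
    utils::write.table(out, outFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    message("[beta-scan] wrote ", nrow(out), " rows to ", outFile)
    return(invisible(out))
  }
  out
}

#' Write a complete synthetic fixture set
#'
#' Generates a community-structured interaction graph, random sequences,
#' planted embeddings, a scenario pathway collection and a matching query,
#' and writes them in the standard formats (edge TSV, FASTA, embedding TSV,
#' GMT, query text) so they double as worked input examples.
#'
#' @param dir output directory (created if needed).
#' @param nNodes,nCommunities,pIn,pOut graph parameters.
#' @param rho planted within-block embedding correlation.
#' @param dim embedding dimension.
#' @param seed global seed (fanned out per generator).
#' @return named character vector of the file paths written.
#' @export
makeFixtures <- function(dir, nNodes = 120L, nCommunities = 4L,
                         pIn = 0.3, pOut = 0.01, rho = 0.9, dim = 64L,
                         seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- .deriveSeeds(seed)
  blocks <- communityBlocks(nNodes, nCommunities)
  edges <- generateSBMGraph(nNodes, nCommunities, pIn, pOut,
                            seed = seeds$fixtures)
  seqs <- generateSequences(nNodes, seed = seeds$fixtures + 1L)
  emb <- generatePlantedEmbeddings(blocks, dim = dim, rho = rho,
                                   seed = seeds$fixtures + 2L)
  scen <- generateScenarioCollection(blocks, seed = seeds$fixtures + 3L)

  paths <- c(edges = file.path(dir, "edges.tsv"),
             fasta = file.path(dir, "proteins.fasta"),
             embeddings = file.path(dir, "embeddings.tsv"),
             gmt = file.path(dir, "pathways.gmt"),
             query = file.path(dir, "query.txt"))
  et <- edgeTable(edges)
  writeLines(c("protein1 protein2 combined_score",
               sprintf("%s %s %d", et$protein1, et$protein2,
                       as.integer(et$combined_score))),
             paths[["edges"]])
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs),
                              paths[["fasta"]])
  writeEmbeddingTable(emb, paths[["embeddings"]])
  writeGMT(scen$collection, paths[["gmt"]])
  writeLines(c("# synthetic query", queryIds(scen$query)),
             paths[["query"]])
  paths
}
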