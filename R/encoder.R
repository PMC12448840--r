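# Graph encoder: learns per-protein embedding vectors from the PPI graph by
# link prediction. Architecture: node input features (composition or pooled
# convolutional sequence features) followed by GIN-style sum-aggregation
# graph layers; pairwise edge probability = logistic(inner product of the
# two endpoint embeddings). Trained with binary cross-entropy against
# uniformly resampled non-edges, by full-batch gradient descent (Adam) with
# hand-derived gradients. Everything is seeded and deterministic.

#' Encoder training settings
#'
#' @param embeddingDim output embedding dimension (hP), >= 3.
#' @param convLayers number of graph convolution layers.
#' @param sequencePool node-feature front end: \code{"mean-composition"}
#'   (20-dim residue frequencies) or \code{"conv1d"} (random filter bank,
#'   see [convFeatures()]).
#' @param learningRate Adam step size.
#' @param epochs training epochs; 0 returns the initialized model.
#' @param negativeRatio sampled non-edges per train edge.
#' @param trainFraction fraction of edges used for training (rest held out
#'   for validation).
#' @param seed RNG seed governing initialization, the edge split and
#'   negative sampling.
#' @return validated list of class \code{encoder_config}.
#' @export
encoderConfig <- function(embeddingDim = 64L, convLayers = 2L,
                          sequencePool = c("mean-composition", "conv1d"),
                          learningRate = 0.01, epochs = 200L,
                          negativeRatio = 1, trainFraction = 0.8,
                          seed = 1L) {
  embeddingDim <- as.integer(embeddingDim)
  convLayers <- as.integer(convLayers)
  epochs <- as.integer(epochs)
  if (is.na(embeddingDim) || embeddingDim < 3L) {
    stop("embeddingDim must be at least 3")
  }
  if (is.na(convLayers) || convLayers < 1L) {
    stop("convLayers must be a positive integer")
  }
  if (!(trainFraction > 0 && trainFraction < 1)) {
    stop("trainFraction must lie strictly between 0 and 1")
  }
  if (negativeRatio <= 0) stop("negativeRatio must be positive")
  if (is.na(epochs) || epochs < 0L) stop("epochs must be >= 0")
  structure(list(embeddingDim = embeddingDim, convLayers = convLayers,
                 sequencePool = match.arg(sequencePool),
                 learningRate = learningRate, epochs = epochs,
                 negativeRatio = negativeRatio,
                 trainFraction = trainFraction, seed = as.integer(seed)),
            class = "encoder_config")
}

#' Build a featured PPI graph
#'
#' Assembles a [PPIGraph-class] from an edge list and per-node features.
#' Edges with an endpoint lacking a feature entry are dropped with a
#' warning; node order is deterministic (sorted identifiers).
#'
#' @param edges a [PPIEdges-class].
#' @param features numeric matrix with rownames (one row of input features
#'   per protein), e.g. from [compositionFeatures()] or [convFeatures()].
#' @return A [PPIGraph-class].
#' @export
buildGraph <- function(edges, features) {
  stopifnot(is(edges, "PPIEdges"), is.matrix(features),
            !is.null(rownames(features)))
  have <- rownames(features)
  ok <- edges@protA %in% have & edges@protB %in% have
  if (!all(ok)) {
    missing <- setdiff(c(edges@protA[!ok], edges@protB[!ok]), have)
    warning("dropped ", sum(!ok), " edge(s) with endpoint(s) lacking ",
            "features: ", paste(utils::head(missing, 5L), collapse = ", "))
  }
  a <- edges@protA[ok]
  b <- edges@protB[ok]
  if (!length(a)) stop("no usable edges: every edge lost an endpoint")
  nodes <- sort(unique(c(a, b)))
  i <- match(a, nodes)
  j <- match(b, nodes)
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  o <- order(lo, hi)
  new("PPIGraph", nodes = nodes,
      edgeIdx = cbind(lo, hi)[o, , drop = FALSE],
      features = features[nodes, , drop = FALSE])
}

#' Split graph edges into train and test sets
#'
#' Uniform random split: \code{round(trainFraction * |E|)} edges train, the
#' rest test; disjoint with union equal to all edges; reproducible under a
#' fixed seed. Nodes isolated in the train set are permitted but reported.
#'
#' @param graph a [PPIGraph-class] with at least 5 edges.
#' @param trainFraction fraction in (0, 1).
#' @param seed RNG seed.
#' @return list with integer edge-row indices \code{train} and \code{test}.
#' @export
splitEdges <- function(graph, trainFraction = 0.8, seed = 1L) {
  stopifnot(is(graph, "PPIGraph"))
  nE <- nrow(graph@edgeIdx)
  if (nE < 5L) stop("graph must have at least 5 edges to split")
  if (!(trainFraction > 0 && trainFraction < 1)) {
    stop("trainFraction must lie strictly between 0 and 1")
  }
  nTrain <- round(trainFraction * nE)
  nTrain <- max(1L, min(nE - 1L, nTrain))
  train <- sort(.withSeed(seed, sample.int(nE, nTrain)))
  test <- setdiff(seq_len(nE), train)
  deg <- tabulate(graph@edgeIdx[train, ], nbins = length(graph@nodes))
  if (any(deg == 0L)) {
    message(sum(deg == 0L), " node(s) isolated in the train split")
  }
  list(train = train, test = test)
}

# --- internal numerics ------------------------------------------------------

# Aggregation operator of the GIN-style layer: S = A + I (sum over
# neighbours plus the node itself), built from a chosen edge subset.
.aggMatrix <- function(n, edgeIdx) {
  S <- diag(n)
  if (nrow(edgeIdx)) {
    S[edgeIdx] <- S[edgeIdx] + 1
    S[edgeIdx[, c(2L, 1L), drop = FALSE]] <-
      S[edgeIdx[, c(2L, 1L), drop = FALSE]] + 1
  }
  S
}

.initParams <- function(dims) {
  # Xavier/Glorot uniform initialization; called inside a seeded context.
  W <- vector("list", length(dims) - 1L)
  b <- vector("list", length(dims) - 1L)
  for (l in seq_along(W)) {
    lim <- sqrt(6 / (dims[l] + dims[l + 1L]))
    W[[l]] <- matrix(stats::runif(dims[l] * dims[l + 1L], -lim, lim),
                     dims[l], dims[l + 1L])
    b[[l]] <- numeric(dims[l + 1L])
  }
  list(W = W, b = b)
}

# Forward pass. Returns the final embeddings and (optionally) the
# intermediates needed by the backward pass.
.forward <- function(X, S, params, keepCache = FALSE) {
  L <- length(params$W)
  M <- X
  Zs <- if (keepCache) vector("list", L)
  Ms <- if (keepCache) vector("list", L + 1L)
  if (keepCache) Ms[[1L]] <- M
  for (l in seq_len(L)) {
    Z <- S %*% M %*% params$W[[l]]
    Z <- sweep(Z, 2L, params$b[[l]], "+")
    M <- if (l < L) pmax(Z, 0) else Z
    if (keepCache) {
      Zs[[l]] <- Z
      Ms[[l + 1L]] <- M
    }
  }
  if (keepCache) list(H = M, Zs = Zs, Ms = Ms) else list(H = M)
}

# Pairwise logistic edge scores for rows u, v of H. The logit is the inner
# product scaled by 1/sqrt(d) to keep it in the responsive range of the
# sigmoid at initialization.
.pairProb <- function(H, u, v) {
  s <- rowSums(H[u, , drop = FALSE] * H[v, , drop = FALSE]) / sqrt(ncol(H))
  1 / (1 + exp(-s))
}

# Sample `n` non-edges (i < j) uniformly, rejecting existing edges; uses the
# current RNG stream.
.sampleNonEdges <- function(nNodes, edgeKeys, n) {
  out_i <- integer(0)
  out_j <- integer(0)
  guard <- 0L
  while (length(out_i) < n && guard < 60L) {
    m <- 2L * (n - length(out_i)) + 10L
    i <- sample.int(nNodes, m, replace = TRUE)
    j <- sample.int(nNodes, m, replace = TRUE)
    lo <- pmin(i, j)
    hi <- pmax(i, j)
    ok <- lo != hi & !(paste(lo, hi) %in% edgeKeys)
    out_i <- c(out_i, lo[ok])
    out_j <- c(out_j, hi[ok])
    guard <- guard + 1L
  }
  if (length(out_i) < n) stop("could not sample enough non-edges")
  cbind(out_i[seq_len(n)], out_j[seq_len(n)])
}

#' Train the graph encoder by link prediction
#'
#' Minimizes binary cross-entropy between logistic inner-product edge scores
#' and the train-edge labels, against non-edges resampled every epoch at
#' \code{negativeRatio} per positive edge. Message passing during training
#' uses the train edges only; held-out edges provide the per-epoch
#' validation AUC against a fixed sample of validation non-edges. Node
#' features are column-standardized before the first layer. With
#' \code{epochs = 0} the returned model carries the initialized parameters.
#'
#' @param graph a [PPIGraph-class].
#' @param config an [encoderConfig()].
#' @return An [EncoderModel-class] with per-epoch \code{loss} and
#'   \code{val_auc} history.
#' @export
trainEncoder <- function(graph, config = encoderConfig()) {
  stopifnot(is(graph, "PPIGraph"), inherits(config, "encoder_config"))
  n <- length(graph@nodes)
  ctr <- colMeans(graph@features)
  scl <- apply(graph@features, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  X <- sweep(sweep(graph@features, 2L, ctr), 2L, scl, "/")

  split <- splitEdges(graph, config$trainFraction, seed = config$seed)
  trainE <- graph@edgeIdx[split$train, , drop = FALSE]
  testE <- graph@edgeIdx[split$test, , drop = FALSE]
  allKeys <- paste(graph@edgeIdx[, 1L], graph@edgeIdx[, 2L])
  S <- .aggMatrix(n, trainE)

  dims <- c(ncol(X), rep(config$embeddingDim, config$convLayers))
  nNeg <- max(1L, round(config$negativeRatio * nrow(trainE)))

  .withSeed(config$seed, {
    params <- .initParams(dims)
    valNeg <- if (nrow(testE)) {
      .sampleNonEdges(n, allKeys, nrow(testE))
    } else {
      matrix(integer(), 0L, 2L)
    }

    nL <- length(params$W)
    mW <- lapply(params$W, function(w) w * 0)
    vW <- mW
    mB <- lapply(params$b, function(b) b * 0)
    vB <- mB
    beta1 <- 0.9; beta2 <- 0.999; epsA <- 1e-8
    wd <- 1e-3  # L2 regularization against memorizing train edges
    hist <- data.frame(epoch = integer(), loss = numeric(),
                       val_auc = numeric())
    bestAUC <- -Inf
    bestParams <- params

    for (epoch in seq_len(config$epochs)) {
      neg <- .sampleNonEdges(n, allKeys, nNeg)
      u <- c(trainE[, 1L], neg[, 1L])
      v <- c(trainE[, 2L], neg[, 2L])
      y <- c(rep(1, nrow(trainE)), rep(0, nrow(neg)))

      fw <- .forward(X, S, params, keepCache = TRUE)
      H <- fw$H
      p <- .pairProb(H, u, v)
      loss <- -mean(y * log(pmax(p, 1e-12)) +
                    (1 - y) * log(pmax(1 - p, 1e-12)))
      if (!is.finite(loss)) {
        stop("non-finite training loss at epoch ", epoch,
             "; reduce learningRate")
      }

      # gradient of the loss w.r.t. the final embeddings (the 1/sqrt(d)
      # logit scaling propagates into the pair gradient)
      g <- (p - y) / length(y) / sqrt(ncol(H))
      gu <- H[v, , drop = FALSE] * g
      gv <- H[u, , drop = FALSE] * g
      agg <- rowsum(rbind(gu, gv), group = c(u, v))
      G <- matrix(0, n, ncol(H))
      G[as.integer(rownames(agg)), ] <- agg

      # backward through the graph layers
      D <- G
      dW <- vector("list", nL)
      dB <- vector("list", nL)
      for (l in rev(seq_len(nL))) {
        SM <- S %*% fw$Ms[[l]]
        dW[[l]] <- crossprod(SM, D) + wd * params$W[[l]]
        dB[[l]] <- colSums(D)
        if (l > 1L) {
          D <- (S %*% (D %*% t(params$W[[l]]))) *
            (fw$Zs[[l - 1L]] > 0)
        }
      }

      # Adam update
      for (l in seq_len(nL)) {
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * dW[[l]]
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * dW[[l]]^2
        mB[[l]] <- beta1 * mB[[l]] + (1 - beta1) * dB[[l]]
        vB[[l]] <- beta2 * vB[[l]] + (1 - beta2) * dB[[l]]^2
        mhW <- mW[[l]] / (1 - beta1^epoch)
        vhW <- vW[[l]] / (1 - beta2^epoch)
        mhB <- mB[[l]] / (1 - beta1^epoch)
        vhB <- vB[[l]] / (1 - beta2^epoch)
        params$W[[l]] <- params$W[[l]] -
          config$learningRate * mhW / (sqrt(vhW) + epsA)
        params$b[[l]] <- params$b[[l]] -
          config$learningRate * mhB / (sqrt(vhB) + epsA)
      }

      valAUC <- if (nrow(testE)) {
        Hv <- .forward(X, S, params)$H
        .rankAUC(.pairProb(Hv, testE[, 1L], testE[, 2L]),
                 .pairProb(Hv, valNeg[, 1L], valNeg[, 2L]))
      } else {
        NA_real_
      }
      hist <- rbind(hist, data.frame(epoch = epoch, loss = loss,
                                     val_auc = valAUC))
      if (!is.na(valAUC) && valAUC > bestAUC) {
        bestAUC <- valAUC
        bestParams <- params
      }
    }

    # keep the checkpoint with the best validation AUC (link prediction on
    # small graphs overfits quickly; selection on the held-out edges is the
    # same criterion the dimension grid search uses)
    if (is.finite(bestAUC)) params <- bestParams

    new("EncoderModel", params = params, config = unclass(config),
        history = hist, split = split, featureCenter = ctr,
        featureScale = scl)
  })
}

#' Held-out link-prediction AUC of a model
#'
#' Scores the model's held-out (test) edges against an equal-sized seeded
#' sample of non-edges, with message passing restricted to the train edges
#' (so held-out pairs stay unseen), and returns the rank-based AUC.
#'
#' @param model an [EncoderModel-class].
#' @param graph the [PPIGraph-class] the model was trained on.
#' @param seed RNG seed for the non-edge sample.
#' @return AUC in [0, 1].
#' @export
validationAUC <- function(model, graph, seed = 1L) {
  stopifnot(is(model, "EncoderModel"), is(graph, "PPIGraph"))
  n <- length(graph@nodes)
  testE <- graph@edgeIdx[model@split$test, , drop = FALSE]
  if (!nrow(testE)) stop("model has no held-out edges")
  trainE <- graph@edgeIdx[model@split$train, , drop = FALSE]
  X <- sweep(sweep(graph@features, 2L, model@featureCenter), 2L,
             model@featureScale, "/")
  H <- .forward(X, .aggMatrix(n, trainE), model@params)$H
  allKeys <- paste(graph@edgeIdx[, 1L], graph@edgeIdx[, 2L])
  neg <- .withSeed(seed, .sampleNonEdges(n, allKeys, nrow(testE)))
  .rankAUC(.pairProb(H, testE[, 1L], testE[, 2L]),
           .pairProb(H, neg[, 1L], neg[, 2L]))
}

#' Encode all graph proteins with a trained model
#'
#' Runs the forward pass with message passing over the full edge set (the
#' train/test split matters only for fitting) and returns one embedding
#' vector per node.
#'
#' @param model an [EncoderModel-class].
#' @param graph a [PPIGraph-class] with the same feature dimensionality the
#'   model was trained on.
#' @return A [ProteinEmbeddings-class] with one row per graph node.
#' @export
encodeProteins <- function(model, graph) {
  stopifnot(is(model, "EncoderModel"), is(graph, "PPIGraph"))
  if (ncol(graph@features) != nrow(model@params$W[[1L]])) {
    stop("feature dimensionality mismatch: model expects ",
         nrow(model@params$W[[1L]]), ", graph has ", ncol(graph@features))
  }
  X <- sweep(sweep(graph@features, 2L, model@featureCenter), 2L,
             model@featureScale, "/")
  S <- .aggMatrix(length(graph@nodes), graph@edgeIdx)
  H <- .forward(X, S, model@params)$H
  rownames(H) <- graph@nodes
  ProteinEmbeddings(H)
}

#' Choose the embedding dimension by validation AUC
#'
#' Grid search over candidate dimensions: trains one encoder per candidate
#' and returns the configuration with the highest final validation AUC,
#' breaking ties in favour of the smaller dimension.
#'
#' @param graph a [PPIGraph-class].
#' @param candidateDims integer vector of dimensions, all >= 3.
#' @param config base [encoderConfig()]; its \code{embeddingDim} is
#'   overridden per candidate.
#' @return the winning \code{encoder_config}, with attribute
#'   \code{"aucByDim"} recording the grid.
#' @export
tuneEmbeddingDim <- function(graph, candidateDims, config = encoderConfig()) {
  candidateDims <- sort(unique(as.integer(candidateDims)))
  if (!length(candidateDims)) stop("candidateDims must be non-empty")
  if (any(candidateDims < 3L)) stop("all candidate dimensions must be >= 3")
  aucs <- vapply(candidateDims, function(d) {
    cfg <- config
    cfg$embeddingDim <- d
    model <- trainEncoder(graph, cfg)
    h <- model@history
    if (nrow(h)) h$val_auc[nrow(h)] else 0.5
  }, 0)
  best <- candidateDims[which.max(aucs)]  # first max = smallest dim on ties
  out <- config
  out$embeddingDim <- best
  attr(out, "aucByDim") <- stats::setNames(aucs, candidateDims)
  out
}
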