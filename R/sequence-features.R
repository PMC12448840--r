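# Per-residue sequence featurization: the raw node features that seed the
# graph encoder. Each residue contributes a 20-channel one-hot plus a
# 7-channel physicochemical-class indicator; sequences are truncated or
# zero-padded to a fixed length with an accompanying mask.

# The classic 7-class physicochemical grouping; the groups partition the 20
# canonical residues.
.AA_GROUPS <- list(
  aliphatic = c("A", "G", "I", "L", "M", "V"),
  aromatic = c("F", "W", "Y"),
  positive = c("H", "K", "R"),
  negative = c("D", "E"),
  polar_uncharged = c("N", "Q", "S", "T"),
  cysteine = "C",
  proline = "P"
)

#' Residue featurization settings
#'
#' @param maxLength truncation/padding target length (residues). Longer
#'   sequences keep their N-terminal prefix.
#' @param propertyGroups ordered named list of amino-acid classes; must
#'   partition the 20 canonical residues. Default: the classic 7-class
#'   grouping (aliphatic, aromatic, positive, negative, polar-uncharged,
#'   cysteine, proline).
#' @param includeOneHot include the 20 one-hot residue channels.
#' @return validated list of class \code{residue_feature_config}.
#' @export
residueFeatureConfig <- function(maxLength = 512L,
                                 propertyGroups = .AA_GROUPS,
                                 includeOneHot = TRUE) {
  maxLength <- as.integer(maxLength)
  if (is.na(maxLength) || maxLength < 1L) {
    stop("maxLength must be a positive integer")
  }
  all20 <- sort(unlist(propertyGroups, use.names = FALSE))
  if (!identical(all20, sort(.AA_ALPHABET))) {
    stop("propertyGroups must partition the 20 canonical residues")
  }
  structure(list(maxLength = maxLength, propertyGroups = propertyGroups,
                 includeOneHot = isTRUE(includeOneHot)),
            class = "residue_feature_config")
}

#' Featurize an amino-acid sequence
#'
#' Produces a \code{maxLength x 27} matrix: 20 one-hot residue channels
#' followed by 7 physicochemical-group channels, plus a logical mask of real
#' (unpadded) positions. Each unpadded row of a canonical residue sums to
#' exactly 2; \code{X} rows and padding rows are all-zero. Output shape
#' depends only on the configuration, never on the sequence.
#'
#' @param seq amino-acid sequence (20 canonical residues plus \code{X}).
#' @param config a [residueFeatureConfig()].
#' @param identifier optional identifier carried along.
#' @return list of class \code{protein_features} with elements
#'   \code{matrix}, \code{mask}, \code{identifier}.
#' @examples
#' pf <- featurizeSequence("MKV", residueFeatureConfig(maxLength = 8))
#' rowSums(pf$matrix)[1:3]  # each encoded residue row sums to 2
#' @export
featurizeSequence <- function(seq, config = residueFeatureConfig(),
                              identifier = NA_character_) {
  stopifnot(inherits(config, "residue_feature_config"))
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    stop("sequence must be a single non-empty string")
  }
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  ok <- chars %in% c(.AA_ALPHABET, "X")
  if (!all(ok)) {
    stop("unknown residue(s): ", paste(unique(chars[!ok]), collapse = ", "))
  }
  groups <- config$propertyGroups
  nOne <- if (config$includeOneHot) 20L else 0L
  ncols <- nOne + length(groups)
  m <- matrix(0, nrow = config$maxLength, ncol = ncols)
  colnames(m) <- c(if (config$includeOneHot) .AA_ALPHABET,
                   names(groups))
  L <- min(length(chars), config$maxLength)
  use <- chars[seq_len(L)]
  if (config$includeOneHot) {
    hit <- match(use, .AA_ALPHABET)  # NA for X
    real <- which(!is.na(hit))
    m[cbind(real, hit[real])] <- 1
  }
  grpOf <- stats::setNames(
    rep(seq_along(groups), lengths(groups)),
    unlist(groups, use.names = FALSE)
  )
  g <- grpOf[use]  # NA for X
  real <- which(!is.na(g))
  m[cbind(real, nOne + g[real])] <- 1
  mask <- c(rep(TRUE, L), rep(FALSE, config$maxLength - L))
  structure(list(matrix = m, mask = mask, identifier = identifier),
            class = "protein_features")
}

#' @export
print.protein_features <- function(x, ...) {
  cat("protein_features", if (!is.na(x$identifier)) paste0("'", x$identifier, "'"),
      ": ", sum(x$mask), "/", length(x$mask), " positions, ",
      ncol(x$matrix), " channels\n", sep = "")
  invisible(x)
}

#' Amino-acid composition vector
#'
#' Relative frequency of each canonical residue; \code{X} is excluded from
#' both numerator and denominator, so the vector sums to 1 over the residues
#' present.
#'
#' @param seq amino-acid sequence.
#' @return named numeric vector of length 20 summing to 1.
#' @examples
#' compositionVector("AXC")  # A and C at 0.5 each; X ignored
#' @export
compositionVector <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    stop("sequence must be a single non-empty string")
  }
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  ok <- chars %in% c(.AA_ALPHABET, "X")
  if (!all(ok)) {
    stop("unknown residue(s): ", paste(unique(chars[!ok]), collapse = ", "))
  }
  chars <- chars[chars != "X"]
  if (!length(chars)) stop("no canonical residues in sequence")
  counts <- table(factor(chars, levels = .AA_ALPHABET))
  stats::setNames(as.numeric(counts) / length(chars), .AA_ALPHABET)
}

#' Composition feature matrix for a set of sequences
#'
#' Stacks [compositionVector()] over a named sequence vector; the default
#' (cheap, convolution-free) node-feature front end for the graph encoder.
#'
#' @param seqs named character vector of sequences.
#' @return numeric matrix (sequences x 20) with rownames.
#' @export
compositionFeatures <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  m <- t(vapply(seqs, compositionVector, numeric(20L)))
  rownames(m) <- names(seqs)
  m
}

#' Convolutional sequence features (fixed random filter bank)
#'
#' Projects each residue feature matrix through a seeded, fixed bank of 1D
#' convolution filters followed by ReLU and global average pooling over real
#' positions. The filters are random projections (not trained); the
#' trainable graph layers sit on top of them.
#'
#' @param seqs named character vector of sequences.
#' @param nFilters number of filters (output feature dimension).
#' @param width filter width in residues.
#' @param config a [residueFeatureConfig()].
#' @param seed RNG seed for the filter bank.
#' @return numeric matrix (sequences x nFilters) with rownames.
#' @export
convFeatures <- function(seqs, nFilters = 32L, width = 9L,
                         config = residueFeatureConfig(), seed = 1L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  nFilters <- as.integer(nFilters)
  width <- as.integer(width)
  nChan <- (if (config$includeOneHot) 20L else 0L) +
    length(config$propertyGroups)
  W <- .withSeed(seed, matrix(stats::rnorm(width * nChan * nFilters,
                                           sd = 1 / sqrt(width * nChan)),
                              width * nChan, nFilters))
  out <- matrix(0, length(seqs), nFilters,
                dimnames = list(names(seqs), NULL))
  for (i in seq_along(seqs)) {
    pf <- featurizeSequence(seqs[[i]], config, names(seqs)[i])
    L <- sum(pf$mask)
    nPos <- max(L - width + 1L, 1L)
    # sliding windows as rows of a (nPos x width*nChan) matrix
    win <- matrix(0, nPos, width * nChan)
    for (t in seq_len(nPos)) {
      rows <- t:min(t + width - 1L, L)
      block <- matrix(0, width, nChan)
      block[seq_along(rows), ] <- pf$matrix[rows, , drop = FALSE]
      win[t, ] <- as.vector(block)
    }
    z <- win %*% W
    z[z < 0] <- 0
    out[i, ] <- colMeans(z)
  }
  out
}
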