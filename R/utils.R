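# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
.withSeed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  code
}

# Rank-based (Mann-Whitney) AUC for link prediction: probability that a
# positive pair outscores a negative pair, ties counted 1/2.
.rankAUC <- function(pos, neg) {
  if (!length(pos) || !length(neg)) {
    stop("AUC needs both positive and negative scores")
  }
  r <- rank(c(pos, neg))
  np <- length(pos)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * length(neg))
}

# Standardize matrix rows so that tcrossprod() of the result gives the
# Pearson correlation between rows. Rows with zero variance map to the zero
# vector, which realizes the r = 0 convention for degenerate vectors.
.standardizeRows <- function(m) {
  d <- ncol(m)
  if (d < 3L) stop("embedding dimension must be at least 3")
  ctr <- m - rowMeans(m)
  ss <- sqrt(rowSums(ctr^2))
  ss[ss == 0] <- Inf
  ctr / ss
}

# Clamp numerical correlation values into [-1, 1].
.clampCor <- function(m) {
  m[m > 1] <- 1
  m[m < -1] <- -1
  m
}

# Derive per-stage sub-seeds from one global seed (documented fan-out, kept
# below .Machine$integer.max).
.deriveSeeds <- function(seed) {
  seed <- as.integer(seed) %% 1000000000L
  list(encoder = seed + 101L,
       null = seed + 202L,
       fixtures = seed + 303L,
       scan = seed + 404L)
}
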