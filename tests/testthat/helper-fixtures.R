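# Shared fixture builders; everything is generated in code.

# Random embedding table over ids Q01..., unstructured.
randomEmbeddings <- function(n, d, seed = 1L, prefix = "G") {
  set.seed(seed)
  m <- matrix(rnorm(n * d), n, d,
              dimnames = list(sprintf("%s%03d", prefix, seq_len(n)), NULL))
  ProteinEmbeddings(m)
}

# Embeddings where a subset of ids is nearly collinear (pairwise r close to
# 1), so interaction-driven entries pass the 0.9 filter.
correlatedEmbeddings <- function(ids, d = 16L, rho = 0.97, seed = 1L,
                                 extraIds = character()) {
  set.seed(seed)
  base <- rnorm(d)
  m <- t(vapply(seq_along(ids), function(i) {
    sqrt(rho) * base + sqrt(1 - rho) * rnorm(d)
  }, numeric(d)))
  if (length(extraIds)) {
    m <- rbind(m, matrix(rnorm(length(extraIds) * d), ncol = d))
  }
  rownames(m) <- c(ids, extraIds)
  ProteinEmbeddings(m)
}

writeTempLines <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# Small trained-encoder fixture shared by encoder tests (computed once).
sbmTestGraph <- function(seed = 7L) {
  edges <- generateSBMGraph(120, 4, 0.3, 0.01, seed = seed)
  seqs <- generateSequences(120, seed = seed + 1L)
  g <- buildGraph(edges, compositionFeatures(seqs))
  attr(g, "blocks") <- attr(edges, "blocks")
  g
}
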