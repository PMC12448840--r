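# Straight-line brute-force re-implementation of the scoring pipeline:
# nested loops, no matrix operations. Used as the independent oracle the
# vectorized pipeline is checked against.

oraclePearson <- function(u, v) {
  n <- length(u)
  mu <- sum(u) / n
  mv <- sum(v) / n
  num <- 0
  du <- 0
  dv <- 0
  for (i in seq_len(n)) {
    num <- num + (u[i] - mu) * (v[i] - mv)
    du <- du + (u[i] - mu)^2
    dv <- dv + (v[i] - mv)^2
  }
  if (du == 0 || dv == 0) return(0)
  r <- num / sqrt(du * dv)
  max(-1, min(1, r))
}

# Full pipeline by hand: correlations, strict filtration, overlap masking by
# identifier equality, beta weighting, row maxima, mean over query rows.
oracleScore <- function(embMat, queryIds, pathwayIds, beta = 1,
                        threshold = 0.9) {
  qk <- queryIds[queryIds %in% rownames(embMat)]
  pk <- pathwayIds[pathwayIds %in% rownames(embMat)]
  if (length(qk) == 0L) stop("no encodable query ids")
  if (length(pk) == 0L) return(0)
  N <- length(qk)
  M <- length(pk)
  C <- matrix(0, N, M)
  ov <- matrix(0, N, M)
  for (k in seq_len(N)) {
    for (l in seq_len(M)) {
      r <- oraclePearson(embMat[qk[k], ], embMat[pk[l], ])
      C[k, l] <- if (r > threshold) r else 0
    }
  }
  for (l in seq_len(M)) {
    if (pk[l] %in% qk) {
      for (k in seq_len(N)) C[k, l] <- 0
      k0 <- which(qk == pk[l])
      C[k0, l] <- 1
      ov[k0, l] <- 1
    }
  }
  total <- 0
  for (k in seq_len(N)) {
    best <- 0
    for (l in seq_len(M)) {
      w <- (C[k, l] - ov[k, l]) + beta * ov[k, l]
      if (w > best) best <- w
    }
    total <- total + best
  }
  total / N
}

# Hand step-up BH: independent of stats::p.adjust.
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) {
    if (m == 1L) break
    q[i] <- min(q[i], q[i + 1L])
  }
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}
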