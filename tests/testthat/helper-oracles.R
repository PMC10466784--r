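## Independent, deliberately slow reference implementations used to check
## the vectorised package code. Everything here is literal loops.

## GCN propagation evaluated element by element.
oracleGCN <- function(S, H, Q) {
  N <- nrow(S)
  S2 <- S + diag(N)
  deg <- rowSums(S2)
  P <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N))
    P[i, j] <- S2[i, j] / sqrt(deg[i] * deg[j])
  Z <- matrix(0, N, ncol(Q))
  for (i in seq_len(N)) for (f in seq_len(ncol(Q)))
    for (j in seq_len(N)) for (g in seq_len(ncol(H)))
      Z[i, f] <- Z[i, f] + P[i, j] * H[j, g] * Q[g, f]
  pmax(Z, 0)
}

## Multi-head attention evaluated node by node.
oracleGAT <- function(S, H, layer) {
  N <- nrow(S)
  K <- length(layer$W)
  Fo <- ncol(layer$W[[1]])
  lrelu <- function(z) if (z > 0) z else layer$slope * z
  acc <- matrix(0, N, Fo)
  for (k in seq_len(K)) {
    W <- layer$W[[k]]
    av <- layer$a[[k]]
    a1 <- av[seq_len(Fo)]; a2 <- av[Fo + seq_len(Fo)]; a3 <- av[2 * Fo + 1]
    Ht <- H %*% W
    for (i in seq_len(N)) {
      nbr <- sort(unique(c(i, which(S[i, ] > 0))))
      logits <- vapply(nbr, function(j)
        lrelu(sum(a1 * Ht[i, ]) + sum(a2 * Ht[j, ]) +
                a3 * layer$B[[k]] * S[i, j]), numeric(1))
      w <- exp(logits - max(logits))
      phi <- w / sum(w)
      for (t in seq_along(nbr))
        acc[i, ] <- acc[i, ] + phi[t] * Ht[nbr[t], ]
    }
  }
  pmax(acc / K, 0)
}

## 1-D two-channel convolution with same padding, sliding-window loops.
oracleCNN <- function(H1, H3, kernel, bias) {
  w <- ncol(kernel)
  left <- (w - 1) %/% 2
  Fdim <- ncol(H1)
  X <- matrix(0, nrow(H1), Fdim)
  for (n in seq_len(nrow(H1))) for (f in seq_len(Fdim)) {
    acc <- bias
    for (t in seq_len(w)) {
      src <- f + t - 1 - left
      if (src >= 1 && src <= Fdim)
        acc <- acc + kernel[1, t] * H1[n, src] + kernel[2, t] * H3[n, src]
    }
    X[n, f] <- acc
  }
  t(X)
}

## Ancestor contributions by exhaustive path enumeration (DAGs <= 8 nodes):
## the contribution of ancestor t is max over all directed child->parent
## paths of decay^length.
oracleContributions <- function(term, edges, decay) {
  contrib <- c(1)
  names(contrib) <- term
  paths <- list(list(node = term, len = 0))
  while (length(paths)) {
    p <- paths[[1]]
    paths <- paths[-1]
    parents <- edges$parent[edges$child == p$node]
    for (q in parents) {
      val <- decay^(p$len + 1)
      if (is.na(contrib[q]) || val > contrib[[q]]) contrib[q] <- val
      paths[[length(paths) + 1]] <- list(node = q, len = p$len + 1)
    }
  }
  contrib
}

oracleSemanticSim <- function(ontology, d1, d2, decay) {
  edges <- parentEdges(ontology)
  S1 <- oracleContributions(d1, edges, decay)
  S2 <- oracleContributions(d2, edges, decay)
  shared <- intersect(names(S1), names(S2))
  if (!length(shared)) return(0)
  (sum(S1[shared]) + sum(S2[shared])) / (sum(S1) + sum(S2))
}

## AUC by concordant-pair counting (ties count one half).
oracleAUC <- function(scores, labels) {
  ps <- scores[labels == 1]
  ns <- scores[labels == 0]
  tot <- 0
  for (p in ps) for (q in ns)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(ps) * length(ns))
}

## AUPR by explicit threshold walk (step integration, no trapezoids).
oracleAUPR <- function(scores, labels) {
  nPos <- sum(labels == 1)
  thr <- sort(unique(scores), decreasing = TRUE)
  area <- 0
  prevRec <- 0
  for (th in thr) {
    sel <- scores >= th
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / nPos
    area <- area + prec * (rec - prevRec)
    prevRec <- rec
  }
  area
}

## Exhaustive scan over every feature and threshold; returns the best gain
## and evaluates the gain formula by direct summation.
oracleSplitGain <- function(g, h, left, lambda) {
  GL <- sum(g[left]); HL <- sum(h[left])
  GR <- sum(g[!left]); HR <- sum(h[!left])
  0.5 * (GL^2 / (HL + lambda) + GR^2 / (HR + lambda) -
           sum(g)^2 / (sum(h) + lambda))
}

oracleBestGain <- function(x, g, h, lambda) {
  best <- -Inf
  for (f in seq_len(ncol(x))) {
    for (v in sort(unique(x[, f]))[-length(unique(x[, f]))]) {
      left <- x[, f] <= v
      gain <- oracleSplitGain(g, h, left, lambda)
      if (gain > best) best <- gain
    }
  }
  best
}

## Small planted fixture shared by several end-to-end tests.
tinyPlanted <- function(n = 14, m = 18, seed = 5)
  generateNetwork(n, m, rank = 2, density = 0.2, noise = 0, seed = seed)

## Fast pipeline configuration for smoke/determinism tests (reduced sizes;
## the full defaults are exercised by the recovery test).
fastEncoder <- function(seed = 1L)
  encoderConfig(embeddingDim = 8L, epochs = 40L, seed = seed)
fastDNN <- list(hidden = c(16L), epochs = 80L, learningRate = 1e-2)
fastGBM <- list(nTrees = 20L, maxLeaves = 8L)
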