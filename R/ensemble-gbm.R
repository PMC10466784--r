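## Second-order gradient-boosted regression trees, implemented from the
## additive-model equations: per round the logistic loss is expanded to
## second order (g_i = p_i - y_i, h_i = p_i (1 - p_i)), trees are grown
## leaf-wise by maximising the split gain
##   G = 1/2 [ GL^2/(HL+lambda) + GR^2/(HR+lambda) - G^2/(H+lambda) ]
## and each leaf takes its Newton-optimal weight w* = -G/(H+lambda).
## Splits are exact greedy scans over raw feature values (no histogram
## binning) -- the tables here are desk-scale.

#' Newton-optimal leaf weight and split gain
#'
#' For per-sample first/second-order gradients g and h, the optimal leaf
#' weight is \eqn{w^* = -\sum g / (\sum h + \lambda)}. When \code{left}
#' marks a candidate left/right partition, the returned gain is
#' \deqn{\frac12\left[\frac{G_L^2}{H_L+\lambda} + \frac{G_R^2}{H_R+\lambda}
#'   - \frac{G^2}{H+\lambda}\right].}
#'
#' @param g,h numeric vectors of first- and second-order gradients.
#' @param lambda L2 regularisation on leaf weights (>= 0).
#' @param left optional logical/integer index of the left partition.
#' @return list with \code{weight} (the full-set leaf weight) and
#'   \code{gain} (\code{NA} when no partition is given).
#' @export
leafWeightAndGain <- function(g, h, lambda = 0, left = NULL) {
  G <- sum(g)
  H <- sum(h)
  if (H + lambda <= 0) stop("sum(h) + lambda must be positive")
  weight <- -G / (H + lambda)
  gain <- NA_real_
  if (!is.null(left)) {
    if (is.logical(left)) left <- which(left)
    GL <- sum(g[left]); HL <- sum(h[left])
    GR <- G - GL; HR <- H - HL
    if (HL + lambda <= 0 || HR + lambda <= 0)
      stop("each side needs sum(h) + lambda > 0")
    gain <- 0.5 * (GL^2 / (HL + lambda) + GR^2 / (HR + lambda) -
                     G^2 / (H + lambda))
  }
  list(weight = weight, gain = gain)
}

## Best exact split of one node: scan every feature, thresholds at
## midpoints between consecutive distinct sorted values. Deterministic
## tie-break: first feature (ascending), then lowest threshold, by virtue
## of strict improvement checks.
.bestSplit <- function(x, g, h, idx, lambda) {
  G <- sum(g[idx]); H <- sum(h[idx])
  parent <- G^2 / (H + lambda)
  best <- NULL
  for (f in seq_len(ncol(x))) {
    v <- x[idx, f]
    o <- order(v)
    vs <- v[o]
    gs <- cumsum(g[idx][o])
    hs <- cumsum(h[idx][o])
    nIdx <- length(idx)
    cut <- which(vs[-nIdx] < vs[-1L]) # split after position cut
    if (!length(cut)) next
    GL <- gs[cut]; HL <- hs[cut]
    GR <- G - GL; HR <- H - HL
    gains <- 0.5 * (GL^2 / (HL + lambda) + GR^2 / (HR + lambda) - parent)
    kBest <- which.max(gains)
    if (is.null(best) || gains[kBest] > best$gain + 1e-12) {
      thr <- (vs[cut[kBest]] + vs[cut[kBest] + 1L]) / 2
      best <- list(feature = f, threshold = thr, gain = gains[kBest],
                   leftIdx = idx[o[seq_len(cut[kBest])]],
                   rightIdx = idx[o[seq(cut[kBest] + 1L, nIdx)]])
    }
  }
  best
}

## Grow one tree leaf-wise until maxLeaves or no positive gain.
.growTree <- function(x, g, h, maxLeaves, lambda) {
  nodes <- list(list(leaf = TRUE, idx = seq_len(nrow(x)), value = NA_real_))
  cand <- list(if (maxLeaves > 1L)
    .bestSplit(x, g, h, seq_len(nrow(x)), lambda) else NULL)
  nLeaves <- 1L
  while (nLeaves < maxLeaves) {
    gains <- vapply(seq_along(nodes), function(i) {
      if (isTRUE(nodes[[i]]$leaf) && !is.null(cand[[i]]))
        cand[[i]]$gain else -Inf
    }, numeric(1))
    pick <- which.max(gains)
    if (!is.finite(gains[pick]) || gains[pick] <= 0) break
    sp <- cand[[pick]]
    li <- length(nodes) + 1L
    ri <- length(nodes) + 2L
    nodes[[pick]] <- list(leaf = FALSE, feature = sp$feature,
                          threshold = sp$threshold, left = li, right = ri)
    nodes[[li]] <- list(leaf = TRUE, idx = sp$leftIdx, value = NA_real_)
    nodes[[ri]] <- list(leaf = TRUE, idx = sp$rightIdx, value = NA_real_)
    ## single-bracket list assignment so NULL entries keep their slot
    cand[pick] <- list(NULL) # gain consumed
    cand[li] <- list(if (length(sp$leftIdx) > 1L)
      .bestSplit(x, g, h, sp$leftIdx, lambda) else NULL)
    cand[ri] <- list(if (length(sp$rightIdx) > 1L)
      .bestSplit(x, g, h, sp$rightIdx, lambda) else NULL)
    nLeaves <- nLeaves + 1L
  }
  for (i in seq_along(nodes)) {
    if (isTRUE(nodes[[i]]$leaf)) {
      idx <- nodes[[i]]$idx
      nodes[[i]]$value <- leafWeightAndGain(g[idx], h[idx], lambda)$weight
      nodes[[i]]$idx <- NULL
    }
  }
  nodes
}

.treePredict <- function(nodes, x) {
  out <- numeric(nrow(x))
  assign_node <- function(i, idx) {
    nd <- nodes[[i]]
    if (isTRUE(nd$leaf)) {
      out[idx] <<- nd$value
      return(invisible())
    }
    goLeft <- x[idx, nd$feature] <= nd$threshold
    if (any(goLeft)) assign_node(nd$left, idx[goLeft])
    if (any(!goLeft)) assign_node(nd$right, idx[!goLeft])
  }
  if (nrow(x)) assign_node(1L, seq_len(nrow(x)))
  out
}

#' Train the second-order boosted-tree classifier
#'
#' Builds an additive model \eqn{F_t = F_{t-1} + \nu f_t} of regression
#' trees fitted to the second-order expansion of the logistic loss: at each
#' round \eqn{g_i = p_i - y_i} and \eqn{h_i = p_i(1-p_i)} with
#' \eqn{p_i = \sigma(F_{t-1}(x_i))}. Trees grow leaf-wise, always splitting
#' the leaf with the largest gain, and stop at \code{maxLeaves} leaves or
#' when no split has positive gain. The initial score is 0 (p = 0.5).
#'
#' @param x numeric feature matrix.
#' @param labels binary 0/1 vector; both classes must be present.
#' @param nTrees number of boosting rounds T (default 100).
#' @param maxLeaves leaf budget per tree (default 31).
#' @param lambda L2 leaf regularisation (default 1).
#' @param shrinkage learning rate \eqn{\nu} (default 0.1).
#' @param seed recorded for provenance; the exact greedy trainer is
#'   deterministic.
#' @return a list of class \code{ldaGBM}.
#' @export
trainGBM <- function(x, labels, nTrees = 100L, maxLeaves = 31L, lambda = 1,
                     shrinkage = 0.1, seed = 1L) {
  x <- as.matrix(x)
  y <- as.numeric(labels)
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class")
  pred <- numeric(nrow(x))
  trees <- vector("list", nTrees)
  for (t in seq_len(nTrees)) {
    p <- .sigmoid(pred)
    g <- p - y
    h <- p * (1 - p)
    tree <- .growTree(x, g, h, maxLeaves, lambda)
    trees[[t]] <- tree
    pred <- pred + shrinkage * .treePredict(tree, x)
  }
  structure(list(trees = trees, nFeatures = ncol(x),
                 config = list(nTrees = nTrees, maxLeaves = maxLeaves,
                               lambda = lambda, shrinkage = shrinkage,
                               seed = seed)),
            class = "ldaGBM")
}

#' Score pairs with the boosted-tree classifier
#'
#' Logistic of the shrinkage-scaled sum of leaf outputs over all trees; an
#' empty model (no trees) scores 0.5 everywhere.
#'
#' @param model an object of class \code{ldaGBM}.
#' @param x feature matrix.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predictGBM <- function(model, x) {
  x <- as.matrix(x)
  if (!is.null(model$nFeatures) && ncol(x) != model$nFeatures)
    stop("feature length does not match the model")
  pred <- numeric(nrow(x))
  for (tree in model$trees)
    pred <- pred + model$config$shrinkage * .treePredict(tree, x)
  .sigmoid(pred)
}
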