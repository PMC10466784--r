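## Graph-encoder layers. The encoder stacks GCN -> GAT -> GCN on each
## similarity graph, combines the first and third layer outputs with a
## one-dimensional convolution along the feature axis, and scores all
## lncRNA-disease pairs with the preference matrix U = t(Xc) %*% Xd.

## Symmetric-normalised propagation operator: with S' = I + S and
## A = diag(rowSums(S')), P = A^{-1/2} S' A^{-1/2}. S' has diagonal >= 1,
## so degrees are always positive.
.gcnPropagator <- function(S) {
  S2 <- S + diag(nrow(S))
  dinv <- 1 / sqrt(rowSums(S2))
  S2 * outer(dinv, dinv)
}

#' Graph-convolution layer forward pass
#'
#' Computes \eqn{\sigma(A^{-1/2} S' A^{-1/2} H Q)} with \eqn{S' = I + S},
#' \eqn{A} the degree matrix of \eqn{S'}, and \eqn{\sigma} the rectifier.
#'
#' @param S square symmetric non-negative adjacency (a similarity matrix).
#' @param H node feature matrix, one row per node.
#' @param Q trainable weight matrix (\code{ncol(H)} x output dim).
#' @return node feature matrix, \code{nrow(H)} x \code{ncol(Q)}.
#' @export
gcnForward <- function(S, H, Q) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S)) stop("S must be square")
  if (nrow(H) != nrow(S)) stop("H rows must match S")
  if (ncol(H) != nrow(Q)) stop("H/Q dimension mismatch")
  .relu(.gcnPropagator(S) %*% H %*% Q)
}

#' Construct a multi-head graph-attention layer
#'
#' Per head k the layer holds a feature transform \code{W_k} (F x F'), an
#' attention vector \code{a_k} of length \code{2F' + 1} (the extra slot
#' weights the edge value \code{B_k * S_ij}), and a trainable edge-weight
#' scalar \code{B_k} initialised to 1. Heads are combined by averaging.
#'
#' @param inDim,outDim input / output feature dimensions.
#' @param heads number of attention heads K (>= 1).
#' @param negativeSlope slope of the LeakyReLU applied to attention logits.
#' @return a list of class \code{gatLayer}.
#' @export
gatLayer <- function(inDim, outDim, heads = 2L, negativeSlope = 0.2) {
  stopifnot(heads >= 1L)
  hd <- paste0("h", seq_len(heads))
  W <- lapply(seq_len(heads), function(k) .glorot(inDim, outDim))
  a <- lapply(seq_len(heads), function(k)
    stats::runif(2L * outDim + 1L, -0.1, 0.1))
  names(W) <- hd
  names(a) <- hd
  structure(list(W = W, a = a, B = rep(1, heads), slope = negativeSlope),
            class = "gatLayer")
}

## Per-head attention forward with cache for backprop. Neighbourhoods are
## all j with S[i, j] > 0 plus the node itself.
.gatForwardCached <- function(S, H, layer) {
  K <- length(layer$W)
  N <- nrow(S)
  mask <- S > 0
  diag(mask) <- TRUE
  acc <- matrix(0, N, ncol(layer$W[[1]]))
  heads <- vector("list", K)
  for (k in seq_len(K)) {
    W <- layer$W[[k]]
    Fo <- ncol(W)
    av <- layer$a[[k]]
    a1 <- av[seq_len(Fo)]
    a2 <- av[Fo + seq_len(Fo)]
    a3 <- av[2L * Fo + 1L]
    Ht <- H %*% W
    raw <- outer(drop(Ht %*% a1), drop(Ht %*% a2), "+") +
      a3 * layer$B[[k]] * S
    act <- .leakyRelu(raw, layer$slope)
    act[!mask] <- -Inf
    act <- act - apply(act, 1, max) # row-wise stabilisation
    ex <- exp(act)
    ex[!mask] <- 0
    phi <- ex / rowSums(ex)
    acc <- acc + phi %*% Ht
    heads[[k]] <- list(Ht = Ht, raw = raw, phi = phi)
  }
  pre <- acc / K
  list(out = .relu(pre), pre = pre, heads = heads, mask = mask)
}

#' Multi-head graph-attention layer forward pass
#'
#' Attention logits for an edge (i, j) are
#' \eqn{f(a_k^T [W_k H_i \| W_k H_j \| B_k S_{ij}])} with \eqn{f} a
#' LeakyReLU; coefficients \eqn{\phi_{ij}^k} are the softmax over node i's
#' neighbourhood (\eqn{S_{ij} > 0} plus self). The output of node i is the
#' rectified head-average \eqn{\sigma((1/K)\sum_k \sum_j \phi_{ij}^k W_k H_j)}.
#'
#' @param S square symmetric adjacency (similarity matrix).
#' @param H node feature matrix.
#' @param layer a [gatLayer()].
#' @param returnAttention when TRUE, attach the per-head coefficient
#'   matrices as attribute \code{"attention"}.
#' @return node feature matrix.
#' @export
gatForward <- function(S, H, layer, returnAttention = FALSE) {
  fw <- .gatForwardCached(as.matrix(S), H, layer)
  out <- fw$out
  if (returnAttention)
    attr(out, "attention") <- lapply(fw$heads, `[[`, "phi")
  out
}

## 1-D convolution along the feature axis with two input channels (H1, H3),
## one output channel, same padding. Linear output (no activation), so a
## width-1 kernel of 0.5/0.5 reduces to the plain average of H1 and H3.
.cnnForward <- function(H1, H3, kernel, bias) {
  w <- ncol(kernel)
  Fdim <- ncol(H1)
  left <- (w - 1L) %/% 2L
  X <- matrix(bias, nrow(H1), Fdim)
  for (t in seq_len(w)) {
    s <- t - 1L - left
    lo <- max(1L, 1L - s)
    hi <- min(Fdim, Fdim - s)
    if (lo > hi) next
    cols <- lo:hi
    X[, cols] <- X[, cols] + kernel[1, t] * H1[, cols + s] +
      kernel[2, t] * H3[, cols + s]
  }
  X
}

.cnnBackward <- function(dX, H1, H3, kernel) {
  w <- ncol(kernel)
  Fdim <- ncol(H1)
  left <- (w - 1L) %/% 2L
  dH1 <- matrix(0, nrow(H1), Fdim)
  dH3 <- matrix(0, nrow(H1), Fdim)
  dK <- matrix(0, 2, w)
  for (t in seq_len(w)) {
    s <- t - 1L - left
    lo <- max(1L, 1L - s)
    hi <- min(Fdim, Fdim - s)
    if (lo > hi) next
    cols <- lo:hi
    dH1[, cols + s] <- dH1[, cols + s] + kernel[1, t] * dX[, cols]
    dH3[, cols + s] <- dH3[, cols + s] + kernel[2, t] * dX[, cols]
    dK[1, t] <- sum(dX[, cols] * H1[, cols + s])
    dK[2, t] <- sum(dX[, cols] * H3[, cols + s])
  }
  list(dH1 = dH1, dH3 = dH3, dK = dK, db = sum(dX))
}

#' Combine two layer outputs with a one-dimensional convolution
#'
#' Stacks H1 and H3 as two channels and applies a 1-D convolution of the
#' given kernel along the feature axis (same padding, two input channels to
#' one output channel, linear). The result is transposed to F x N so that
#' the preference matrix can be formed as \code{t(Xc) \%*\% Xd}.
#'
#' @param H1,H3 node feature matrices of identical shape (N x F).
#' @param kernel 2 x width numeric matrix (channel weights).
#' @param bias scalar bias (default 0).
#' @return embedding matrix, F x N.
#' @export
combineCNN <- function(H1, H3, kernel, bias = 0) {
  if (!all(dim(H1) == dim(H3))) stop("H1 and H3 must have the same shape")
  if (nrow(kernel) != 2L) stop("kernel must have two channel rows")
  t(.cnnForward(H1, H3, kernel, bias))
}

#' Preference matrix from paired embeddings
#'
#' \eqn{U = X_c^T X_d}: entry (i, j) is the inner-product affinity of
#' lncRNA i and disease j. During training, \code{sigmoid(U)} is matched to
#' the association matrix with binary cross-entropy.
#'
#' @param Xc lncRNA embeddings, F x n.
#' @param Xd disease embeddings, F x m.
#' @return n x m numeric matrix.
#' @export
preferenceMatrix <- function(Xc, Xd) {
  if (nrow(Xc) != nrow(Xd)) stop("embedding dimensions must match")
  crossprod(Xc, Xd)
}
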