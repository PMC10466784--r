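## Encoder assembly and training. Gradients are derived by hand (reverse
## mode through GCN -> GAT -> GCN -> CNN -> U -> BCE) and checked against
## numerical differentiation in the test suite.

#' Encoder configuration
#'
#' @param embeddingDim embedding dimension F (default 32).
#' @param heads number of attention heads K (default 2).
#' @param epochs training epochs (default 200).
#' @param learningRate Adam step size (default 1e-3).
#' @param cnnKernelWidth width of the 1-D combiner convolution (default 3).
#' @param negativeSlope LeakyReLU slope in attention logits (default 0.2).
#' @param seed RNG seed controlling all initialisation.
#' @return a named list of class \code{encoderConfig}.
#' @export
encoderConfig <- function(embeddingDim = 32L, heads = 2L, epochs = 200L,
                          learningRate = 1e-3, cnnKernelWidth = 3L,
                          negativeSlope = 0.2, seed = 1L) {
  stopifnot(embeddingDim >= 1L, heads >= 1L, epochs >= 1L,
            learningRate > 0, cnnKernelWidth >= 1L)
  structure(list(embeddingDim = as.integer(embeddingDim),
                 heads = as.integer(heads), epochs = as.integer(epochs),
                 learningRate = learningRate,
                 cnnKernelWidth = as.integer(cnnKernelWidth),
                 negativeSlope = negativeSlope, seed = as.integer(seed)),
            class = "encoderConfig")
}

## One graph's trainable parameters. Initial node features are the
## similarity rows themselves (H0 = S), so Q1 maps N -> F.
.initGraphParams <- function(N, Fdim, config) {
  list(
    Q1 = .glorot(N, Fdim),
    gat = unclass(gatLayer(Fdim, Fdim, config$heads, config$negativeSlope)),
    Q2 = .glorot(Fdim, Fdim),
    convW = matrix(stats::runif(2L * config$cnnKernelWidth, -0.5, 0.5),
                   2L, config$cnnKernelWidth),
    convB = 0
  )
}

.initEncoderParams <- function(n, m, config) {
  set.seed(config$seed)
  list(c = .initGraphParams(n, config$embeddingDim, config),
      d = .initGraphParams(m, config$embeddingDim, config))
}

## Forward pass over one graph with caches for reverse mode.
.graphForward <- function(S, pg) {
  P <- .gcnPropagator(S)
  H0 <- S
  Z1 <- P %*% H0 %*% pg$Q1
  H1 <- .relu(Z1)
  gat <- .gatForwardCached(S, H1, pg$gat)
  H2 <- gat$out
  Z3 <- P %*% H2 %*% pg$Q2
  H3 <- .relu(Z3)
  X <- t(.cnnForward(H1, H3, pg$convW, pg$convB))
  list(P = P, H0 = H0, Z1 = Z1, H1 = H1, gat = gat, H2 = H2, Z3 = Z3,
       H3 = H3, X = X, S = S)
}

## Reverse pass: dX is the loss gradient w.r.t. X (F x N).
.graphBackward <- function(dX, fw, pg) {
  K <- length(pg$gat$W)
  cnn <- .cnnBackward(t(dX), fw$H1, fw$H3, pg$convW)
  dH3 <- cnn$dH3
  dZ3 <- dH3 * (fw$Z3 > 0)
  PH2 <- fw$P %*% fw$H2
  dQ2 <- crossprod(PH2, dZ3)
  dH2 <- fw$P %*% dZ3 %*% t(pg$Q2) # P is symmetric
  dPre <- dH2 * (fw$gat$pre > 0) / K
  dH1 <- cnn$dH1
  gatGrads <- list(W = vector("list", K), a = vector("list", K),
                   B = numeric(K))
  names(gatGrads$W) <- names(pg$gat$W)
  names(gatGrads$a) <- names(pg$gat$a)
  for (k in seq_len(K)) {
    hd <- fw$gat$heads[[k]]
    W <- pg$gat$W[[k]]
    Fo <- ncol(W)
    av <- pg$gat$a[[k]]
    a1 <- av[seq_len(Fo)]
    a2 <- av[Fo + seq_len(Fo)]
    a3 <- av[2L * Fo + 1L]
    dPhi <- dPre %*% t(hd$Ht)
    dHt <- crossprod(hd$phi, dPre)
    ## softmax backward, row-wise; phi is zero outside the neighbourhood
    dLogit <- hd$phi * (dPhi - rowSums(hd$phi * dPhi))
    dRaw <- dLogit * ifelse(hd$raw > 0, 1, pg$gat$slope)
    de1 <- rowSums(dRaw)
    de2 <- colSums(dRaw)
    da3 <- sum(dRaw * pg$gat$B[[k]] * fw$S)
    dB <- sum(dRaw * a3 * fw$S)
    dHt <- dHt + outer(de1, a1) + outer(de2, a2)
    da1 <- drop(crossprod(hd$Ht, de1))
    da2 <- drop(crossprod(hd$Ht, de2))
    gatGrads$W[[k]] <- crossprod(fw$H1, dHt)
    gatGrads$a[[k]] <- c(da1, da2, da3)
    gatGrads$B[[k]] <- dB
    dH1 <- dH1 + dHt %*% t(W)
  }
  dZ1 <- dH1 * (fw$Z1 > 0)
  PH0 <- fw$P %*% fw$H0
  dQ1 <- crossprod(PH0, dZ1)
  list(Q1 = dQ1,
       gat = list(W = gatGrads$W, a = gatGrads$a, B = gatGrads$B,
                  slope = 0),
       Q2 = dQ2, convW = cnn$dK, convB = cnn$db)
}

.encoderLossGrad <- function(params, Sc, Sd, Y) {
  fc <- .graphForward(Sc, params$c)
  fd <- .graphForward(Sd, params$d)
  U <- crossprod(fc$X, fd$X)
  p <- .sigmoid(U)
  loss <- .bce(p, Y)
  dU <- (p - Y) / length(Y)
  dXc <- fd$X %*% t(dU)
  dXd <- fc$X %*% dU
  grads <- list(c = .graphBackward(dXc, fc, params$c),
                d = .graphBackward(dXd, fd, params$d))
  list(loss = loss, grads = grads, fc = fc, fd = fd, U = U)
}

.stateFromForward <- function(fc, fd, U, lossHistory, config, params) {
  new("EncoderState",
      Hc = list(fc$H0, fc$H1, fc$H2, fc$H3),
      Hd = list(fd$H0, fd$H1, fd$H2, fd$H3),
      Xc = fc$X, Xd = fd$X, U = U,
      lossHistory = lossHistory, config = unclass(config), params = params)
}

#' Untrained encoder forward pass
#'
#' Runs the stacked GCN -> GAT -> GCN encoder plus the convolutional
#' combiner once, with freshly initialised (seeded) parameters, over the
#' lncRNA similarity graph C and the disease similarity graph D. Initial
#' node features are the similarity rows themselves.
#'
#' @param C,D [SimilarityMatrix-class] objects (lncRNA / disease side).
#' @param config an [encoderConfig()].
#' @param params optional pre-built parameter list (used internally).
#' @return an [EncoderState-class].
#' @export
encodeNetwork <- function(C, D, config = encoderConfig(), params = NULL) {
  Sc <- simMatrix(C)
  Sd <- simMatrix(D)
  if (is.null(params))
    params <- .initEncoderParams(nrow(Sc), nrow(Sd), config)
  fc <- .graphForward(Sc, params$c)
  fd <- .graphForward(Sd, params$d)
  U <- crossprod(fc$X, fd$X)
  st <- .stateFromForward(fc, fd, U, numeric(), config, params)
  colnames(st@Xc) <- entityNames(C)
  colnames(st@Xd) <- entityNames(D)
  dimnames(st@U) <- list(entityNames(C), entityNames(D))
  st
}

#' Train the graph encoder against the association matrix
#'
#' Minimises the mean binary cross-entropy between \code{sigmoid(U)} with
#' \code{U = t(Xc) \%*\% Xd} and the binary association matrix Y by Adam
#' over all trainable parameters (both GCN weight matrices, every attention
#' head's transform/attention vector/edge scalar, and the combiner
#' convolution, separately per graph).
#'
#' @param C,D [SimilarityMatrix-class] objects.
#' @param network an [AssociationNetwork-class] (or a binary matrix) whose
#'   Y supervises training; its row/column order must match C and D.
#' @param config an [encoderConfig()].
#' @return a trained [EncoderState-class] with the per-epoch loss history.
#' @export
trainEncoder <- function(C, D, network, config = encoderConfig()) {
  Y <- if (is(network, "AssociationNetwork")) assocMatrix(network)
       else as.matrix(network)
  Sc <- simMatrix(C)
  Sd <- simMatrix(D)
  if (nrow(Y) != nrow(Sc) || ncol(Y) != nrow(Sd))
    stop("Y dimensions must match the similarity graphs")
  params <- .initEncoderParams(nrow(Sc), nrow(Sd), config)
  flat <- .flattenParams(params)
  adam <- .adamInit(flat)
  losses <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    lg <- .encoderLossGrad(params, Sc, Sd, Y)
    if (!is.finite(lg$loss))
      stop("encoder training diverged at epoch ", epoch)
    losses[epoch] <- lg$loss
    gflat <- .flattenParams(lg$grads)
    upd <- .adamStep(flat, gflat[names(flat)], adam, config$learningRate)
    flat <- upd$params
    adam <- upd$state
    params <- .unflattenParams(flat, params)
    params$c$gat$slope <- config$negativeSlope
    params$d$gat$slope <- config$negativeSlope
  }
  fc <- .graphForward(Sc, params$c)
  fd <- .graphForward(Sd, params$d)
  U <- crossprod(fc$X, fd$X)
  st <- .stateFromForward(fc, fd, U, losses, config, params)
  colnames(st@Xc) <- entityNames(C)
  colnames(st@Xd) <- entityNames(D)
  dimnames(st@U) <- list(entityNames(C), entityNames(D))
  st
}
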