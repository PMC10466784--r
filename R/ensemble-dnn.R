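## Feed-forward classifier half of the ensemble: rectified hidden layers,
## logistic output, binary cross-entropy loss, Adam, full-batch training.

.dnnForward <- function(model, x) {
  A <- x
  caches <- list()
  L <- length(model$W)
  for (l in seq_len(L)) {
    Z <- sweep(A %*% model$W[[l]], 2, model$b[[l]], "+")
    A_new <- if (l < L) .relu(Z) else .sigmoid(Z)
    caches[[l]] <- list(A_prev = A, Z = Z)
    A <- A_new
  }
  list(out = A, caches = caches)
}

#' Train the feed-forward network
#'
#' Hidden layers compute \eqn{h_j = \sum_i w_i x_i + b_j} followed by a
#' rectifier; the output layer applies the logistic function
#' \eqn{\sigma(h) = 1/(1+e^{-h})}. Trained full-batch with Adam on binary
#' cross-entropy.
#'
#' @param x numeric feature matrix, one row per lncRNA-disease pair.
#' @param labels binary vector (0/1); both classes must be present.
#' @param hidden integer vector of hidden-layer sizes (default c(128, 64)).
#' @param epochs training epochs (default 200).
#' @param learningRate Adam step size (default 1e-3).
#' @param seed RNG seed for the weight initialisation.
#' @return a list of class \code{ldaDNN} with weights, biases and the loss
#'   history.
#' @export
trainDNN <- function(x, labels, hidden = c(128L, 64L), epochs = 200L,
                     learningRate = 1e-3, seed = 1L) {
  x <- as.matrix(x)
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2L)
    stop("training labels contain a single class")
  set.seed(seed)
  sizes <- c(ncol(x), hidden, 1L)
  L <- length(sizes) - 1L
  W <- lapply(seq_len(L), function(l) .glorot(sizes[l], sizes[l + 1L]))
  b <- lapply(seq_len(L), function(l) rep(0, sizes[l + 1L]))
  names(W) <- names(b) <- paste0("l", seq_len(L))
  model <- list(W = W, b = b)
  flat <- .flattenParams(model)
  adam <- .adamInit(flat)
  y <- matrix(labels, ncol = 1)
  losses <- numeric(epochs)
  nObs <- nrow(x)
  for (epoch in seq_len(epochs)) {
    fw <- .dnnForward(model, x)
    p <- fw$out
    loss <- .bce(p, y)
    if (!is.finite(loss)) stop("DNN training diverged at epoch ", epoch)
    losses[epoch] <- loss
    dZ <- (p - y) / nObs # logistic + BCE
    grads <- list(W = vector("list", L), b = vector("list", L))
    names(grads$W) <- names(grads$b) <- names(W)
    for (l in rev(seq_len(L))) {
      cache <- fw$caches[[l]]
      grads$W[[l]] <- crossprod(cache$A_prev, dZ)
      grads$b[[l]] <- colSums(dZ)
      if (l > 1L) {
        dA <- dZ %*% t(model$W[[l]])
        dZ <- dA * (fw$caches[[l - 1L]]$Z > 0)
      }
    }
    gflat <- .flattenParams(grads)
    upd <- .adamStep(flat, gflat[names(flat)], adam, learningRate)
    flat <- upd$params
    adam <- upd$state
    model <- .unflattenParams(flat, model)
  }
  structure(list(W = model$W, b = model$b, lossHistory = losses,
                 config = list(hidden = hidden, epochs = epochs,
                               learningRate = learningRate, seed = seed)),
            class = "ldaDNN")
}

#' Score pairs with a trained feed-forward network
#'
#' @param model an object of class \code{ldaDNN}.
#' @param x feature matrix with the same number of columns as in training.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predictDNN <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != nrow(model$W[[1]]))
    stop("feature length does not match the model")
  drop(.dnnForward(model, x)$out)
}
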