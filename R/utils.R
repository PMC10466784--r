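## Internal numerical helpers shared across the encoder and the ensemble.

.relu <- function(x) pmax(x, 0)

.sigmoid <- function(x) 1 / (1 + exp(-x))

.leakyRelu <- function(x, slope) ifelse(x > 0, x, slope * x)

## Binary cross-entropy, mean over entries, clamped away from log(0).
.bce <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

## Glorot-uniform initialisation; draws from the active RNG stream.
.glorot <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

## Deterministic fan-out of one master seed into per-repeat, per-stage
## streams; kept strictly below 2^31 - 1.
.stageSeed <- function(seed, rep = 0L, stage = 0L) {
  s <- (as.numeric(seed) %% 2147483647) + 7919 * rep + 104729 * stage
  as.integer(s %% 2147483646) + 1L
}

## Adam update for a flat list of numeric arrays. `state` carries first and
## second moments plus the step counter; created lazily on first call.
.adamInit <- function(params) {
  list(
    m = lapply(params, function(p) array(0, dim = if (is.null(dim(p))) length(p) else dim(p))),
    v = lapply(params, function(p) array(0, dim = if (is.null(dim(p))) length(p) else dim(p))),
    t = 0L
  )
}

.adamStep <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    g <- grads[[i]]
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g^2
    mhat <- state$m[[i]] / corr1
    vhat <- state$v[[i]] / corr2
    params[[i]] <- params[[i]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## Flatten / unflatten a nested parameter list while preserving shapes,
## used so one Adam state can drive every trainable tensor of the encoder.
.flattenParams <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(x[[nm]])) out <- c(out, .flattenParams(x[[nm]], key))
    else out[[key]] <- x[[nm]]
  }
  out
}

.unflattenParams <- function(flat, skeleton, prefix = "") {
  for (nm in names(skeleton)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(skeleton[[nm]]))
      skeleton[[nm]] <- .unflattenParams(flat, skeleton[[nm]], key)
    else skeleton[[nm]] <- flat[[key]]
  }
  skeleton
}
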