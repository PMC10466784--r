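## Pair-level classification: concatenated embeddings in, soft-voted
## association probabilities out.

#' Build pair feature vectors from encoder embeddings
#'
#' The feature vector of pair (i, j) is the concatenation of column i of
#' the lncRNA embeddings and column j of the disease embeddings, length 2F.
#'
#' @param state an [EncoderState-class].
#' @param pairs two-column integer matrix (or data.frame) of (lncRNA index,
#'   disease index).
#' @param labels optional 0/1 vector, one per pair.
#' @return a list of class \code{pairFeatures} with elements \code{x}
#'   (feature matrix), \code{pairs}, \code{labels}, \code{lncrna},
#'   \code{disease}.
#' @export
buildPairFeatures <- function(state, pairs, labels = NULL) {
  pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  Xc <- lncrnaEmbeddings(state)
  Xd <- diseaseEmbeddings(state)
  if (any(pairs[, 1] < 1 | pairs[, 1] > ncol(Xc)) ||
      any(pairs[, 2] < 1 | pairs[, 2] > ncol(Xd)))
    stop("pair index out of range")
  x <- cbind(t(Xc)[pairs[, 1], , drop = FALSE],
             t(Xd)[pairs[, 2], , drop = FALSE])
  colnames(x) <- c(paste0("c", seq_len(nrow(Xc))),
                   paste0("d", seq_len(nrow(Xd))))
  structure(list(x = x, pairs = pairs, labels = labels,
                 lncrna = colnames(Xc)[pairs[, 1]],
                 disease = colnames(Xd)[pairs[, 2]]),
            class = "pairFeatures")
}

#' Soft-voting combination of the two classifier scores
#'
#' \eqn{Score = \alpha C_{DNN} + \beta C_{GBM}} with default weights 0.4 and
#' 0.6; a pair is labelled positive iff its score is strictly greater than
#' the threshold (0.5), so a tie at exactly 0.5 is negative.
#'
#' @param cDnn,cGbm numeric score vectors in [0, 1], equal length.
#' @param alpha,beta non-negative voting weights summing to 1.
#' @param threshold decision cut in (0, 1).
#' @return list with \code{score} and integer \code{label}.
#' @export
softVote <- function(cDnn, cGbm, alpha = 0.4, beta = 0.6, threshold = 0.5) {
  if (length(cDnn) != length(cGbm)) stop("score vectors differ in length")
  if (alpha < 0 || beta < 0 || abs(alpha + beta - 1) > 1e-9)
    stop("weights must be non-negative and sum to 1")
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly in (0, 1)")
  if (any(cDnn < 0 | cDnn > 1 | cGbm < 0 | cGbm > 1))
    stop("scores must lie in [0, 1]")
  score <- alpha * cDnn + beta * cGbm
  list(score = score, label = as.integer(score > threshold))
}

#' Train the full association-prediction model
#'
#' End-to-end convenience wrapper: builds the fused similarity matrices,
#' trains the graph encoder against Y, samples unknown pairs as negatives
#' (1:1 by default), trains the feed-forward network and the boosted trees
#' on the concatenated pair embeddings, and stores the soft-voting weights.
#'
#' @param network an [AssociationNetwork-class].
#' @param ontology optional [DiseaseOntology-class].
#' @param encoder an [encoderConfig()].
#' @param dnn list of [trainDNN()] settings (hidden, epochs, learningRate).
#' @param gbm list of [trainGBM()] settings (nTrees, maxLeaves, lambda,
#'   shrinkage).
#' @param alpha,beta soft-voting weights (default 0.4 / 0.6).
#' @param threshold decision threshold (default 0.5).
#' @param negativeRatio negatives per positive for classifier training.
#' @param gammaPrime,decay similarity parameters.
#' @param seed master seed; every stage derives its own stream from it.
#' @return a list of class \code{ldaModel}.
#' @export
trainLDAModel <- function(network, ontology = NULL,
                          encoder = encoderConfig(),
                          dnn = list(), gbm = list(),
                          alpha = 0.4, beta = 0.6, threshold = 0.5,
                          negativeRatio = 1, gammaPrime = 1, decay = 0.5,
                          seed = 1L) {
  sims <- computeSimilarities(network, ontology, gammaPrime, decay)
  encoder$seed <- .stageSeed(seed, 0L, 1L)
  state <- trainEncoder(sims$C, sims$D, network, encoder)
  Y <- assocMatrix(network)
  pos <- which(Y == 1, arr.ind = TRUE)
  neg <- sampleNegatives(network, negativeRatio, .stageSeed(seed, 0L, 2L))
  pairs <- rbind(unname(pos), as.matrix(neg))
  labels <- c(rep(1, nrow(pos)), rep(0, nrow(neg)))
  feats <- buildPairFeatures(state, pairs, labels)
  dnnArgs <- utils::modifyList(
    list(hidden = c(128L, 64L), epochs = 200L, learningRate = 1e-3), dnn)
  gbmArgs <- utils::modifyList(
    list(nTrees = 100L, maxLeaves = 31L, lambda = 1, shrinkage = 0.1), gbm)
  dnnModel <- trainDNN(feats$x, labels, hidden = dnnArgs$hidden,
                       epochs = dnnArgs$epochs,
                       learningRate = dnnArgs$learningRate,
                       seed = .stageSeed(seed, 0L, 3L))
  gbmModel <- trainGBM(feats$x, labels, nTrees = gbmArgs$nTrees,
                       maxLeaves = gbmArgs$maxLeaves,
                       lambda = gbmArgs$lambda,
                       shrinkage = gbmArgs$shrinkage,
                       seed = .stageSeed(seed, 0L, 4L))
  structure(list(network = network, similarities = sims, encoder = state,
                 dnn = dnnModel, gbm = gbmModel,
                 weights = c(alpha = alpha, beta = beta),
                 threshold = threshold, seed = seed),
            class = "ldaModel")
}

#' Score lncRNA-disease pairs with a trained model
#'
#' @param model an object of class \code{ldaModel} from [trainLDAModel()].
#' @param pairs optional two-column matrix of (lncRNA index, disease index);
#'   default: all n x m pairs.
#' @param member one of \code{"ensemble"} (soft vote, default),
#'   \code{"dnn"}, \code{"gbm"} — the single-model modes support ablation.
#' @return data.frame with columns \code{lncrna}, \code{disease},
#'   \code{score}, \code{predictedLabel}, \code{knownLabel}.
#' @export
predictPairs <- function(model, pairs = NULL,
                         member = c("ensemble", "dnn", "gbm")) {
  member <- match.arg(member)
  Y <- assocMatrix(model$network)
  if (is.null(pairs))
    pairs <- as.matrix(expand.grid(seq_len(nrow(Y)), seq_len(ncol(Y))))
  feats <- buildPairFeatures(model$encoder, pairs)
  cDnn <- predictDNN(model$dnn, feats$x)
  cGbm <- predictGBM(model$gbm, feats$x)
  vote <- switch(member,
    ensemble = softVote(cDnn, cGbm, model$weights[["alpha"]],
                        model$weights[["beta"]], model$threshold),
    dnn = list(score = cDnn, label = as.integer(cDnn > model$threshold)),
    gbm = list(score = cGbm, label = as.integer(cGbm > model$threshold)))
  data.frame(lncrna = feats$lncrna, disease = feats$disease,
             score = vote$score, predictedLabel = vote$label,
             knownLabel = Y[pairs])
}

#' Rank candidate lncRNAs for one disease
#'
#' Scores every lncRNA against the given disease, removes known positives,
#' and returns the top candidates by score (ties broken by lncRNA id).
#'
#' @param model a trained \code{ldaModel}.
#' @param disease disease identifier.
#' @param top number of candidates to keep (default 20).
#' @param member ensemble member to score with (see [predictPairs()]).
#' @return data.frame with columns \code{rank}, \code{lncrna}, \code{score}.
#' @export
rankCandidates <- function(model, disease, top = 20L,
                           member = "ensemble") {
  j <- match(disease, diseaseNames(model$network))
  if (is.na(j)) stop("unknown disease: ", disease)
  n <- length(lncrnaNames(model$network))
  tab <- predictPairs(model, cbind(seq_len(n), j), member = member)
  tab <- tab[tab$knownLabel != 1, , drop = FALSE]
  tab <- tab[order(-tab$score, tab$lncrna), , drop = FALSE]
  tab <- tab[seq_len(min(top, nrow(tab))), , drop = FALSE]
  data.frame(rank = seq_len(nrow(tab)), lncrna = tab$lncrna,
             score = tab$score)
}

#' @export
print.ldaModel <- function(x, ...) {
  cat("ldaModel: trained on", length(lncrnaNames(x$network)), "lncRNAs x",
      length(diseaseNames(x$network)), "diseases; voting weights",
      x$weights[["alpha"]], "/", x$weights[["beta"]], "\n")
  invisible(x)
}

#' @export
print.ldaDNN <- function(x, ...) {
  cat("ldaDNN:", length(x$W) - 1L, "hidden layer(s), final BCE",
      sprintf("%.4f", utils::tail(x$lossHistory, 1)), "\n")
  invisible(x)
}

#' @export
print.ldaGBM <- function(x, ...) {
  cat("ldaGBM:", length(x$trees), "trees, shrinkage",
      x$config$shrinkage, "\n")
  invisible(x)
}
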