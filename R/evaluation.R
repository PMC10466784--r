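## Negative sampling, the three cross-validation protocols (lncRNA-wise,
## disease-wise, pair-wise), metric computation and repeat aggregation.

#' Sample unknown pairs as negatives
#'
#' Uniform sample without replacement from the pairs with \eqn{y_{ij} = 0};
#' the count is \code{round(ratio * number of positives)}.
#'
#' @param network an [AssociationNetwork-class].
#' @param ratio negatives per positive (default 1).
#' @param seed RNG seed.
#' @return two-column integer matrix of (lncRNA index, disease index).
#' @export
sampleNegatives <- function(network, ratio = 1, seed = 1L) {
  Y <- assocMatrix(network)
  zero <- which(Y == 0)
  want <- round(ratio * sum(Y))
  if (want > length(zero))
    stop("not enough unknown pairs for the requested ratio")
  set.seed(seed)
  pick <- sample(zero, want)
  cbind(row(Y)[pick], col(Y)[pick])
}

#' Split labelled pairs for one cross-validation repeat
#'
#' CV1 partitions the lncRNAs (80/20 by default): every labelled pair whose
#' lncRNA is held out goes to the test set, emulating prediction for a new
#' lncRNA. CV2 does the same over diseases; CV3 partitions the labelled
#' pair list itself. A split that leaves zero positives in train or test is
#' resampled (with the retry count reported via \code{message()}).
#'
#' @param network an [AssociationNetwork-class].
#' @param negatives two-column matrix from [sampleNegatives()].
#' @param scheme \code{"CV1"}, \code{"CV2"} or \code{"CV3"}.
#' @param trainFraction fraction of entities/pairs in training (default 0.8).
#' @param seed RNG seed.
#' @return list with \code{scheme}, \code{train} and \code{test} (each a
#'   data.frame with columns \code{i}, \code{j}, \code{label}) and, for
#'   CV1/CV2, \code{testEntities} (integer indices of held-out entities).
#' @export
cvSplit <- function(network, negatives, scheme = c("CV3", "CV1", "CV2"),
                    trainFraction = 0.8, seed = 1L) {
  scheme <- match.arg(scheme)
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must lie strictly in (0, 1)")
  Y <- assocMatrix(network)
  pos <- which(Y == 1, arr.ind = TRUE)
  pairs <- data.frame(i = c(pos[, 1], negatives[, 1]),
                      j = c(pos[, 2], negatives[, 2]),
                      label = c(rep(1L, nrow(pos)),
                                rep(0L, nrow(negatives))))
  set.seed(seed)
  for (try in seq_len(100L)) {
    if (scheme == "CV3") {
      nTrain <- round(trainFraction * nrow(pairs))
      ord <- sample.int(nrow(pairs))
      trainIdx <- ord[seq_len(nTrain)]
      inTrain <- seq_len(nrow(pairs)) %in% trainIdx
      testEntities <- integer()
    } else {
      nEnt <- if (scheme == "CV1") nrow(Y) else ncol(Y)
      nTrain <- round(trainFraction * nEnt)
      ord <- sample.int(nEnt)
      trainEnt <- ord[seq_len(nTrain)]
      ent <- if (scheme == "CV1") pairs$i else pairs$j
      inTrain <- ent %in% trainEnt
      testEntities <- sort(ord[-seq_len(nTrain)])
    }
    train <- pairs[inTrain, , drop = FALSE]
    test <- pairs[!inTrain, , drop = FALSE]
    ok <- sum(train$label) > 0 && sum(test$label) > 0 &&
      any(train$label == 0) && any(test$label == 0)
    if (ok) {
      if (try > 1L) message("cvSplit: resampled ", try - 1L, " time(s)")
      return(list(scheme = scheme, train = train, test = test,
                  testEntities = testEntities))
    }
  }
  stop("could not produce a split with positives in both folds")
}

#' Zero the test-side associations out of Y
#'
#' Produces the masked network used for similarity computation and encoder
#' training: under CV1 every association of a held-out lncRNA is removed
#' (CV2: held-out disease), so a new entity contributes no association
#' signal anywhere upstream; under CV3 exactly the held-out positive pairs
#' are removed.
#'
#' @param network an [AssociationNetwork-class].
#' @param split a split from [cvSplit()].
#' @return an [AssociationNetwork-class] with the masked Y.
#' @export
maskTestAssociations <- function(network, split) {
  Y <- assocMatrix(network)
  if (split$scheme == "CV1") {
    Y[split$testEntities, ] <- 0
  } else if (split$scheme == "CV2") {
    Y[, split$testEntities] <- 0
  } else {
    tp <- split$test[split$test$label == 1, , drop = FALSE]
    Y[cbind(tp$i, tp$j)] <- 0
  }
  AssociationNetwork(Y, lncrnaNames(network), diseaseNames(network))
}

## Tie-aware rank AUC (equivalent to the Wilcoxon statistic).
.aucRank <- function(scores, labels) {
  nPos <- sum(labels == 1)
  nNeg <- sum(labels == 0)
  r <- rank(scores) # average ranks on ties
  (sum(r[labels == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

## Step-wise area under the precision-recall curve: walk distinct score
## thresholds from high to low, accumulate P(k) * (R(k) - R(k-1)).
.auprStep <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  keep <- c(s[-length(s)] > s[-1L], TRUE) # last index of each tie group
  tp <- tp[keep]
  fp <- fp[keep]
  nPos <- sum(labels == 1)
  recall <- tp / nPos
  precision <- tp / (tp + fp)
  sum(precision * diff(c(0, recall)))
}

#' Threshold and ranking metrics for one score vector
#'
#' Computes precision, recall, accuracy and F1 at the given threshold
#' (strict inequality; ties at the threshold are negative) plus tie-aware
#' rank AUC and step-interpolated AUPR.
#'
#' @param scores numeric vector.
#' @param labels 0/1 vector; at least one of each class.
#' @param threshold decision cut (default 0.5).
#' @return named numeric vector with elements \code{precision},
#'   \code{recall}, \code{accuracy}, \code{f1}, \code{auc}, \code{aupr}.
#' @export
computeMetrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  if (!any(labels == 1) || !any(labels == 0))
    stop("need at least one positive and one negative label")
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- tp / (tp + fn)
  accuracy <- mean(pred == labels)
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, accuracy = accuracy, f1 = f1,
    auc = .aucRank(scores, labels), aupr = .auprStep(scores, labels))
}

#' Run one cross-validation experiment
#'
#' For each repeat: sample negatives, split per the scheme, zero the
#' held-out associations out of Y, rebuild the similarity matrices from the
#' masked network (the ontology-based semantic part is association-free and
#' stays intact), train the encoder and both classifiers on the training
#' pairs only, score the test pairs with the soft vote, and compute the six
#' metrics. Everything is driven by per-repeat, per-stage seeds derived
#' from the master seed.
#'
#' @param network an [AssociationNetwork-class].
#' @param ontology optional [DiseaseOntology-class].
#' @param scheme \code{"CV1"}, \code{"CV2"} or \code{"CV3"}.
#' @param repeats number of repeats (default 10).
#' @param trainFraction training fraction (default 0.8).
#' @param negativeRatio negatives per positive (default 1).
#' @param encoder an [encoderConfig()].
#' @param dnn,gbm classifier settings, as in [trainLDAModel()].
#' @param alpha,beta,threshold soft-voting parameters.
#' @param gammaPrime,decay similarity parameters.
#' @param member \code{"ensemble"} (default), \code{"dnn"} or \code{"gbm"}:
#'   score test pairs with the soft vote or with a single member model (the
#'   single-model ablation design).
#' @param seed master seed.
#' @return an [EvaluationReport-class].
#' @export
runExperiment <- function(network, ontology = NULL,
                          scheme = c("CV3", "CV1", "CV2"), repeats = 10L,
                          trainFraction = 0.8, negativeRatio = 1,
                          encoder = encoderConfig(), dnn = list(),
                          gbm = list(), alpha = 0.4, beta = 0.6,
                          threshold = 0.5, gammaPrime = 1, decay = 0.5,
                          member = c("ensemble", "dnn", "gbm"),
                          seed = 1L) {
  scheme <- match.arg(scheme)
  member <- match.arg(member)
  dnnArgs <- utils::modifyList(
    list(hidden = c(128L, 64L), epochs = 200L, learningRate = 1e-3), dnn)
  gbmArgs <- utils::modifyList(
    list(nTrees = 100L, maxLeaves = 31L, lambda = 1, shrinkage = 0.1), gbm)
  rows <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    negs <- sampleNegatives(network, negativeRatio, .stageSeed(seed, r, 1L))
    split <- cvSplit(network, negs, scheme, trainFraction,
                     .stageSeed(seed, r, 2L))
    masked <- maskTestAssociations(network, split)
    sims <- computeSimilarities(masked, ontology, gammaPrime, decay)
    encCfg <- encoder
    encCfg$seed <- .stageSeed(seed, r, 3L)
    state <- trainEncoder(sims$C, sims$D, masked, encCfg)
    trFeats <- buildPairFeatures(state,
                                 cbind(split$train$i, split$train$j),
                                 split$train$label)
    teFeats <- buildPairFeatures(state, cbind(split$test$i, split$test$j),
                                 split$test$label)
    dnnModel <- trainDNN(trFeats$x, split$train$label,
                         hidden = dnnArgs$hidden, epochs = dnnArgs$epochs,
                         learningRate = dnnArgs$learningRate,
                         seed = .stageSeed(seed, r, 4L))
    gbmModel <- trainGBM(trFeats$x, split$train$label,
                         nTrees = gbmArgs$nTrees,
                         maxLeaves = gbmArgs$maxLeaves,
                         lambda = gbmArgs$lambda,
                         shrinkage = gbmArgs$shrinkage,
                         seed = .stageSeed(seed, r, 5L))
    cDnn <- predictDNN(dnnModel, teFeats$x)
    cGbm <- predictGBM(gbmModel, teFeats$x)
    vote <- switch(member,
      ensemble = softVote(cDnn, cGbm, alpha, beta, threshold),
      dnn = list(score = cDnn, label = as.integer(cDnn > threshold)),
      gbm = list(score = cGbm, label = as.integer(cGbm > threshold)))
    rows[[r]] <- c(repeat_ = r,
                   computeMetrics(vote$score, split$test$label, threshold))
  }
  perRepeat <- as.data.frame(do.call(rbind, rows))
  metrics <- c("precision", "recall", "accuracy", "f1", "auc", "aupr")
  aggregate <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(mm) mean(perRepeat[[mm]]), numeric(1)),
    sd = vapply(metrics, function(mm) stats::sd(perRepeat[[mm]]), numeric(1))
  )
  rownames(aggregate) <- NULL
  new("EvaluationReport", perRepeat = perRepeat, aggregate = aggregate,
      scheme = scheme,
      config = list(repeats = repeats, trainFraction = trainFraction,
                    negativeRatio = negativeRatio,
                    encoder = unclass(encoder), dnn = dnnArgs,
                    gbm = gbmArgs, alpha = alpha, beta = beta,
                    threshold = threshold, gammaPrime = gammaPrime,
                    decay = decay, member = member, seed = seed))
}

#' Write an evaluation report to TSV (per-repeat) and JSON-like summary
#'
#' @param report an [EvaluationReport-class].
#' @param prefix output path prefix; writes \code{<prefix>_repeats.tsv} and
#'   \code{<prefix>_summary.tsv}.
#' @return invisible character vector of the written paths.
#' @export
writeReport <- function(report, prefix) {
  p1 <- paste0(prefix, "_repeats.tsv")
  p2 <- paste0(prefix, "_summary.tsv")
  utils::write.table(perRepeat(report), p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(aggregated(report), p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(p1, p2))
}
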