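test_that("negative sampling draws unknown pairs at the requested ratio", {
  Y <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("l1", "l2"),
                                                   c("d1", "d2")))
  net <- AssociationNetwork(Y)
  neg <- sampleNegatives(net, ratio = 1, seed = 2)
  expect_equal(nrow(neg), 2) # forced: both unknown pairs
  expect_true(all(Y[neg] == 0))

  pn <- tinyPlanted()
  n1 <- sampleNegatives(pn$network, 1, seed = 5)
  expect_equal(nrow(n1), sum(assocMatrix(pn$network)))
  expect_identical(n1, sampleNegatives(pn$network, 1, seed = 5))
  expect_false(identical(n1, sampleNegatives(pn$network, 1, seed = 6)))
  expect_error(sampleNegatives(net, ratio = 50), "not enough")
})

test_that("CV1 holds out 20% of lncRNAs with no leakage into training", {
  pn <- generateNetwork(10, 12, 2, 0.25, 0, seed = 4)
  neg <- sampleNegatives(pn$network, 1, seed = 1)
  sp <- cvSplit(pn$network, neg, "CV1", seed = 3)
  expect_equal(length(sp$testEntities), 2) # 10 lncRNAs -> 8/2
  expect_false(any(sp$train$i %in% sp$testEntities))
  expect_true(all(sp$test$i %in% sp$testEntities))
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(neg) * 2)

  masked <- maskTestAssociations(pn$network, sp)
  expect_true(all(assocMatrix(masked)[sp$testEntities, ] == 0))
  keep <- setdiff(seq_len(10), sp$testEntities)
  expect_identical(assocMatrix(masked)[keep, ],
                   assocMatrix(pn$network)[keep, ])
})

test_that("CV2 and CV3 partition diseases and pairs respectively", {
  pn <- generateNetwork(10, 20, 2, 0.25, 0, seed = 4)
  neg <- sampleNegatives(pn$network, 1, seed = 1)
  sp2 <- cvSplit(pn$network, neg, "CV2", seed = 3)
  expect_equal(length(sp2$testEntities), 4) # 20 diseases -> 16/4
  expect_false(any(sp2$train$j %in% sp2$testEntities))

  nLab <- sum(assocMatrix(pn$network)) + nrow(neg)
  sp3 <- cvSplit(pn$network, neg, "CV3", seed = 3)
  expect_equal(nrow(sp3$train), round(0.8 * nLab))
  expect_equal(nrow(sp3$test), nLab - round(0.8 * nLab))
  ## disjoint pair sets
  key <- function(d) paste(d$i, d$j, d$label)
  expect_length(intersect(key(sp3$train), key(sp3$test)), 0)
  masked3 <- maskTestAssociations(pn$network, sp3)
  tp <- sp3$test[sp3$test$label == 1, ]
  expect_true(all(assocMatrix(masked3)[cbind(tp$i, tp$j)] == 0))
})

test_that("threshold metrics behave on the worked examples", {
  m <- computeMetrics(c(0.9, 0.8, 0.4, 0.1), c(1, 1, 0, 0))
  expect_equal(unname(m), rep(1, 6)) # perfect separation

  m2 <- computeMetrics(c(0.9, 0.4, 0.8, 0.1), c(1, 1, 0, 0))
  expect_equal(m2[["auc"]], 3 / 4)

  m3 <- computeMetrics(c(0.5, 0.5), c(1, 0))
  expect_equal(m3[["auc"]], 0.5) # tie-average

  expect_error(computeMetrics(c(0.1, 0.2), c(1, 1)), "negative")
})

test_that("rank metrics equal brute-force oracles, including ties", {
  set.seed(12)
  for (rep in 1:30) {
    n <- sample(4:50, 1)
    scores <- round(runif(n), 1) # coarse grid forces ties
    labels <- rbinom(n, 1, 0.4)
    if (!any(labels == 1)) labels[1] <- 1
    if (!any(labels == 0)) labels[2] <- 0
    m <- computeMetrics(scores, labels)
    expect_equal(m[["auc"]], oracleAUC(scores, labels), tolerance = 1e-12)
    expect_equal(m[["aupr"]], oracleAUPR(scores, labels),
                 tolerance = 1e-12)
    ## bounds and the F1 harmonic identity
    expect_true(all(m >= 0 & m <= 1))
    if (m[["precision"]] + m[["recall"]] > 0)
      expect_equal(m[["f1"]],
                   2 * m[["precision"]] * m[["recall"]] /
                     (m[["precision"]] + m[["recall"]]))
  }
})

test_that("rank AUC agrees with the pROC reference implementation", {
  library(pROC)
  set.seed(9)
  for (rep in 1:5) {
    scores <- round(runif(40), 2)
    labels <- rbinom(40, 1, 0.5)
    if (!any(labels == 1)) labels[1] <- 1
    if (!any(labels == 0)) labels[2] <- 0
    ref <- as.numeric(pROC::auc(labels, scores, quiet = TRUE,
                                direction = "<"))
    expect_equal(computeMetrics(scores, labels)[["auc"]], ref,
                 tolerance = 1e-12)
  }
})

test_that("experiment reports have the right shape and beat a degree baseline", {
  pn <- tinyPlanted(seed = 12)
  rep5 <- runExperiment(pn$network, scheme = "CV3", repeats = 3,
                        encoder = fastEncoder(), dnn = fastDNN,
                        gbm = fastGBM, seed = 31)
  expect_s4_class(rep5, "EvaluationReport")
  expect_equal(nrow(perRepeat(rep5)), 3)
  expect_equal(nrow(aggregated(rep5)), 6)
  expect_true(validObject(rep5))

  ## degenerate baseline: score a test pair by its lncRNA training degree
  neg <- sampleNegatives(pn$network, 1, seed = 31)
  sp <- cvSplit(pn$network, neg, "CV3", seed = 31)
  masked <- maskTestAssociations(pn$network, sp)
  deg <- rowSums(assocMatrix(masked))
  base <- computeMetrics(deg[sp$test$i] / max(deg), sp$test$label)[["auc"]]
  meanAUC <- aggregated(rep5)$mean[aggregated(rep5)$metric == "auc"]
  expect_gt(meanAUC, base)
})

test_that("single-member ablation scores with one model only", {
  pn <- tinyPlanted(seed = 4)
  base <- list(scheme = "CV3", repeats = 2, encoder = fastEncoder(),
               dnn = fastDNN, gbm = fastGBM, seed = 11)
  ens <- do.call(runExperiment, c(list(pn$network), base))
  dnnOnly <- do.call(runExperiment,
                     c(list(pn$network), base, member = "dnn"))
  gbmOnly <- do.call(runExperiment,
                     c(list(pn$network), base, member = "gbm"))
  expect_false(identical(perRepeat(ens)$auc, perRepeat(dnnOnly)$auc))
  expect_false(identical(perRepeat(dnnOnly)$auc, perRepeat(gbmOnly)$auc))
  ## identical seeds -> identical splits, so the scores differ only by
  ## the member model used
  expect_identical(ens@config$member, "ensemble")
  expect_identical(dnnOnly@config$member, "dnn")
  for (rp in list(ens, dnnOnly, gbmOnly)) expect_true(validObject(rp))
})

test_that("report writer emits per-repeat and summary tables", {
  pn <- tinyPlanted(seed = 2)
  rep1 <- runExperiment(pn$network, scheme = "CV3", repeats = 2,
                        encoder = fastEncoder(), dnn = fastDNN,
                        gbm = fastGBM, seed = 1)
  pre <- withr::local_tempfile()
  paths <- writeReport(rep1, pre)
  expect_true(all(file.exists(paths)))
  back <- read.delim(paths[1])
  expect_equal(nrow(back), 2)
  expect_equal(back$auc, perRepeat(rep1)$auc)
})
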