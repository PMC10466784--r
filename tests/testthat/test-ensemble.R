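test_that("pair features concatenate the two embedding columns", {
  st <- new("EncoderState",
            Hc = rep(list(matrix(0)), 4), Hd = rep(list(matrix(0)), 4),
            Xc = matrix(c(1, 2, 5, 6), 2,
                        dimnames = list(NULL, c("l1", "l2"))),
            Xd = matrix(c(3, 4, 7, 8), 2,
                        dimnames = list(NULL, c("d1", "d2"))),
            U = crossprod(matrix(c(1, 2, 5, 6), 2),
                          matrix(c(3, 4, 7, 8), 2)),
            lossHistory = numeric(), config = list(), params = list())
  ft <- buildPairFeatures(st, rbind(c(1, 1), c(1, 1), c(2, 2)))
  expect_equal(unname(ft$x[1, ]), c(1, 2, 3, 4))
  expect_identical(ft$x[1, ], ft$x[2, ]) # same pair -> identical rows
  expect_equal(ncol(ft$x), 4)
  all4 <- buildPairFeatures(st, as.matrix(expand.grid(1:2, 1:2)))
  expect_equal(nrow(all4$x), 4)
  expect_error(buildPairFeatures(st, rbind(c(3, 1))), "out of range")
})

test_that("an all-zero network outputs one half before training", {
  model <- structure(list(W = list(matrix(0, 3, 4), matrix(0, 4, 1)),
                          b = list(rep(0, 4), 0)), class = "ldaDNN")
  expect_equal(predictDNN(model, matrix(rnorm(15), 5, 3)), rep(0.5, 5))
})

test_that("a hand-set single-unit network evaluates the logistic chain", {
  ## h = ReLU(1*1 + 0) = 1; sigma(1) = 1/(1+exp(-1))
  model <- structure(list(W = list(matrix(1, 1, 1), matrix(1, 1, 1)),
                          b = list(0, 0)), class = "ldaDNN")
  expect_equal(predictDNN(model, matrix(1, 1, 1)), 1 / (1 + exp(-1)))
  expect_error(predictDNN(model, matrix(1, 1, 2)), "feature length")
})

test_that("the network learns a linearly separable fixture perfectly", {
  set.seed(42)
  n <- 60
  x <- cbind(rnorm(n), rnorm(n))
  y <- as.integer(x[, 1] + x[, 2] > 0)
  y[abs(x[, 1] + x[, 2]) < 0.2] <- NA # enforce a margin
  keep <- !is.na(y)
  x <- x[keep, ]; y <- y[keep]
  model <- trainDNN(x, y, hidden = c(16), epochs = 500,
                    learningRate = 1e-2, seed = 3)
  acc <- mean(as.integer(predictDNN(model, x) > 0.5) == y)
  expect_equal(acc, 1.0)
  expect_lt(model$lossHistory[500], model$lossHistory[1])
  model2 <- trainDNN(x, y, hidden = c(16), epochs = 500,
                     learningRate = 1e-2, seed = 3)
  expect_identical(model$W, model2$W) # same seed -> identical weights
  expect_error(trainDNN(x, rep(1, length(y))), "single class")
})

test_that("leaf weight and split gain follow the closed forms", {
  ## w* = -sum(g)/(sum(h)+lambda)
  expect_equal(leafWeightAndGain(c(1, 1), c(1, 1), 0)$weight, -1)
  ## split separating +1,+1 from -1,-1 with h = 1: gain = 2
  res <- leafWeightAndGain(c(1, 1, -1, -1), rep(1, 4), 0, left = 1:2)
  expect_equal(res$gain, 2)
  ## heavy regularisation kills both weight and gain
  resL <- leafWeightAndGain(c(1, 1, -1, -1), rep(1, 4), 1e9, left = 1:2)
  expect_lt(abs(resL$weight), 1e-8)
  expect_lt(abs(resL$gain), 1e-7)
  expect_error(leafWeightAndGain(1, -2, 1), "positive")
})

test_that("gain computation matches the exhaustive scan oracle", {
  set.seed(17)
  for (rep in 1:8) {
    n <- sample(5:20, 1)
    x <- matrix(round(rnorm(n * 3), 1), n, 3)
    p <- runif(n, 0.1, 0.9)
    y <- rbinom(n, 1, 0.5)
    g <- p - y
    h <- p * (1 - p)
    lam <- sample(c(0, 0.5, 1), 1)
    best <- ldaEnsemble:::.bestSplit(x, g, h, seq_len(n), lam)
    if (is.null(best)) next
    expect_equal(best$gain, oracleBestGain(x, g, h, lam), tolerance = 1e-10)
    ## leafWeightAndGain agrees with direct summation on the chosen split
    lw <- leafWeightAndGain(g, h, lam, left = best$leftIdx)
    expect_equal(lw$gain,
                 oracleSplitGain(g, h, seq_len(n) %in% best$leftIdx, lam),
                 tolerance = 1e-12)
  }
})

test_that("a single-leaf single-tree model is the Newton intercept step", {
  set.seed(4)
  y <- rbinom(20, 1, 0.7)
  x <- matrix(rnorm(40), 20, 2)
  model <- trainGBM(x, y, nTrees = 1, maxLeaves = 1, lambda = 0,
                    shrinkage = 1)
  leaf <- model$trees[[1]][[1]]
  expect_true(leaf$leaf)
  ## g_i = 0.5 - y_i, h_i = 0.25 at the p = 0.5 start
  expect_equal(leaf$value, -sum(0.5 - y) / (0.25 * length(y)))
  expect_equal(unique(predictGBM(model, x)),
               1 / (1 + exp(-leaf$value)))
})

test_that("boosting separates a separable fixture and is deterministic", {
  set.seed(23)
  n <- 50
  x <- cbind(rnorm(n), rnorm(n))
  y <- as.integer(x[, 1] > 0.1 | x[, 2] > 1)
  if (length(unique(y)) < 2) y[1] <- 1 - y[1]
  m1 <- trainGBM(x, y, nTrees = 20, maxLeaves = 8)
  expect_equal(computeMetrics(predictGBM(m1, x), y)[["auc"]], 1.0)
  m2 <- trainGBM(x, y, nTrees = 20, maxLeaves = 8)
  expect_identical(m1$trees, m2$trees)
  expect_error(trainGBM(x, rep(0, n)), "single class")
})

test_that("empty and manual stump models route predictions correctly", {
  empty <- structure(list(trees = list(), nFeatures = 2,
                          config = list(shrinkage = 0.1)), class = "ldaGBM")
  expect_equal(predictGBM(empty, matrix(0, 3, 2)), rep(0.5, 3))
  stump <- structure(list(
    trees = list(list(
      list(leaf = FALSE, feature = 1, threshold = 0.5, left = 2, right = 3),
      list(leaf = TRUE, value = -2),
      list(leaf = TRUE, value = 3))),
    nFeatures = 1, config = list(shrinkage = 0.5)), class = "ldaGBM")
  got <- predictGBM(stump, matrix(c(0, 1), 2, 1))
  expect_equal(got, 1 / (1 + exp(-0.5 * c(-2, 3))))
  dup <- predictGBM(stump, matrix(c(0, 0), 2, 1))
  expect_identical(dup[1], dup[2])
})

test_that("soft voting is the stated convex combination with strict cut", {
  v <- softVote(c(1, 0.2, 0.5), c(1, 0.9, 0.5))
  expect_equal(v$score, c(1, 0.4 * 0.2 + 0.6 * 0.9, 0.5))
  expect_equal(v$label, c(1L, 1L, 0L)) # exactly 0.5 is negative
  set.seed(8)
  a <- runif(200); b <- runif(200)
  vv <- softVote(a, b)
  expect_true(all(vv$score >= pmin(a, b) - 1e-12 &
                    vv$score <= pmax(a, b) + 1e-12))
  expect_error(softVote(a, b[-1]), "length")
  expect_error(softVote(a, b, alpha = 0.5, beta = 0.6), "sum to 1")
  expect_error(softVote(c(1.2), c(0.1)), "0, 1")
})

test_that("the from-scratch booster matches the reference backend on AUC", {
  library(xgboost)
  set.seed(77)
  n <- 300
  x <- matrix(rnorm(n * 6), n, 6)
  logit <- 1.2 * x[, 1] - 0.8 * x[, 2] + 0.5 * x[, 3] * x[, 4]
  y <- rbinom(n, 1, 1 / (1 + exp(-logit)))
  tr <- 1:200; te <- 201:n
  ours <- trainGBM(x[tr, ], y[tr], nTrees = 40, maxLeaves = 15, lambda = 1,
                   shrinkage = 0.1)
  aucOurs <- computeMetrics(predictGBM(ours, x[te, ]), y[te])[["auc"]]
  dtrain <- xgboost::xgb.DMatrix(x[tr, ], label = y[tr])
  bst <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", eta = 0.1, lambda = 1,
                  max_depth = 0, max_leaves = 15,
                  grow_policy = "lossguide", tree_method = "hist",
                  min_child_weight = 0, gamma = 0, base_score = 0.5),
    data = dtrain, nrounds = 40, verbose = 0)
  aucRef <- computeMetrics(
    predict(bst, xgboost::xgb.DMatrix(x[te, ])), y[te])[["auc"]]
  expect_lt(abs(aucOurs - aucRef), 0.05)
})
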