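test_that("Gaussian kernel matches hand evaluation and its invariants", {
  K <- gaussianKernelSimilarity(rbind(l1 = c(1, 0), l2 = c(0, 1)))
  ## mean squared profile norm 1 -> gamma = 1 -> K12 = exp(-2)
  expect_equal(simMatrix(K)[1, 2], exp(-2))
  expect_equal(simMatrix(K)[2, 1], exp(-2))
  expect_equal(diag(simMatrix(K)), c(l1 = 1, l2 = 1))

  ## identical profiles -> similarity 1
  K2 <- gaussianKernelSimilarity(rbind(a = c(1, 1, 0), b = c(1, 1, 0)))
  expect_equal(simMatrix(K2)[1, 2], 1)

  expect_error(gaussianKernelSimilarity(matrix(0, 3, 4)), "all profiles")
  expect_error(gaussianKernelSimilarity(rbind(c(1, 0), c(0, 1)),
                                        gammaPrime = 0), "positive")
})

test_that("Gaussian kernel is invariant to column permutation", {
  set.seed(31)
  for (k in 1:10) {
    P <- matrix(rbinom(6 * 9, 1, 0.3), 6, 9)
    if (all(rowSums(P) == 0)) P[1, 1] <- 1
    perm <- sample(ncol(P))
    K1 <- simMatrix(gaussianKernelSimilarity(P, entityIds = letters[1:6]))
    K2 <- simMatrix(gaussianKernelSimilarity(P[, perm],
                                             entityIds = letters[1:6]))
    expect_equal(K1, K2)
    expect_true(max(abs(K1 - t(K1))) < 1e-12)
    expect_true(all(K1 >= 0 & K1 <= 1))
  }
})

test_that("semantic similarity reproduces the sibling worked example", {
  onto <- DiseaseOntology(c("d1", "d2", "p"),
                          data.frame(child = c("d1", "d2"),
                                     parent = c("p", "p")))
  S <- diseaseSemanticSimilarity(onto, c("d1", "d2"), decay = 0.5)
  ## each sibling: self 1, parent 0.5 -> sim = (0.5+0.5)/(1.5+1.5) = 1/3
  expect_equal(simMatrix(S)[1, 2], 1 / 3)
  expect_equal(diag(simMatrix(S)), c(d1 = 1, d2 = 1))
  expect_error(diseaseSemanticSimilarity(onto, c("d1", "d2"), decay = 1),
               "decay")
})

test_that("disjoint ancestor sets give zero; absent diseases stay diagonal", {
  onto <- DiseaseOntology(c("a", "b", "pa", "pb"),
                          data.frame(child = c("a", "b"),
                                     parent = c("pa", "pb")))
  S <- simMatrix(diseaseSemanticSimilarity(onto, c("a", "b", "zzz"), 0.5))
  expect_equal(S[1, 2], 0)
  expect_equal(unname(S[, 3]), c(0, 0, 1)) # zzz absent from the ontology
  expect_equal(ontologyCoverage(onto, c("a", "zzz")), c(TRUE, FALSE))
})

test_that("semantic similarity agrees with path-enumeration oracle", {
  for (seed in 1:25) {
    onto <- generateOntology(nTerms = sample(3:8, 1), branching = 2,
                             depth = 3, seed = seed)
    terms <- ontologyTerms(onto)
    dd <- sample(terms, min(4, length(terms)))
    S <- simMatrix(diseaseSemanticSimilarity(onto, dd, 0.5))
    for (i in seq_along(dd)) for (j in seq_along(dd)) {
      if (i == j) next
      expect_equal(S[i, j], oracleSemanticSim(onto, dd[i], dd[j], 0.5),
                   tolerance = 1e-9)
    }
  }
})

test_that("adding a shared ancestor never decreases semantic similarity", {
  for (seed in 1:10) {
    onto <- generateOntology(nTerms = 7, branching = 2, depth = 3,
                             seed = seed)
    terms <- ontologyTerms(onto)
    set.seed(seed)
    dd <- sample(terms, 2)
    before <- simMatrix(diseaseSemanticSimilarity(onto, dd, 0.5))[1, 2]
    onto2 <- DiseaseOntology(
      c(terms, "sharedAnc"),
      rbind(parentEdges(onto),
            data.frame(child = dd, parent = "sharedAnc")))
    after <- simMatrix(diseaseSemanticSimilarity(onto2, dd, 0.5))[1, 2]
    expect_gte(after, before - 1e-12)
  }
})

test_that("functional similarity follows best-match averaging", {
  Y <- matrix(0, 3, 3, dimnames = list(c("l1", "l2", "l3"),
                                       c("d1", "d2", "d3")))
  Y[1, 1] <- 1; Y[2, 2] <- 1; Y[3, 3] <- 1
  ## lncRNAs sharing one identical associated disease -> similarity 1
  Y2 <- Y; Y2[2, ] <- c(1, 0, 0)
  net2 <- AssociationNetwork(Y2)
  Dsim <- SimilarityMatrix(diag(3), c("d1", "d2", "d3"))
  FS2 <- simMatrix(lncrnaFunctionalSimilarity(net2, Dsim))
  expect_equal(FS2[1, 2], 1)

  ## A = {d1}, B = {d2}, sim(d1, d2) = 1/3 -> FS = 1/3
  M <- diag(3); M[1, 2] <- M[2, 1] <- 1 / 3
  DsimB <- SimilarityMatrix(M, c("d1", "d2", "d3"))
  FS <- simMatrix(lncrnaFunctionalSimilarity(AssociationNetwork(Y), DsimB))
  expect_equal(FS[1, 2], 1 / 3)

  ## association-free lncRNA: 0 off-diagonal, 1 on the diagonal
  Y3 <- Y; Y3[3, ] <- 0
  FS3 <- simMatrix(lncrnaFunctionalSimilarity(AssociationNetwork(Y3), Dsim))
  expect_equal(FS3[3, ], c(l1 = 0, l2 = 0, l3 = 1))
})

test_that("fusion averages where defined and falls back elsewhere", {
  ids <- c("a", "b", "c")
  A <- SimilarityMatrix(matrix(c(1, .2, .4, .2, 1, .6, .4, .6, 1), 3), ids)
  B <- SimilarityMatrix(matrix(c(1, .6, .2, .6, 1, .0, .2, 0, 1), 3), ids)
  fused <- simMatrix(fuseSimilarity(A, B, defined = c(TRUE, TRUE, FALSE)))
  expect_equal(fused["a", "b"], (0.2 + 0.6) / 2)
  expect_equal(fused["a", "c"], 0.4) # c undefined in B -> fallback
  expect_equal(diag(fused), c(a = 1, b = 1, c = 1))

  nowhere <- simMatrix(fuseSimilarity(A, B, defined = rep(FALSE, 3)))
  expect_equal(nowhere, simMatrix(A))
  expect_error(fuseSimilarity(A, SimilarityMatrix(diag(2), c("a", "b"))),
               "ordering")
})

test_that("every pipeline similarity matrix passes its invariants", {
  pn <- tinyPlanted()
  onto <- generateOntology(nTerms = 10, seed = 3,
                           terms = c("t_root",
                                     diseaseNames(pn$network)[1:9]))
  sims <- computeSimilarities(pn$network, onto)
  for (S in list(sims$C, sims$D)) {
    M <- simMatrix(S)
    expect_true(max(abs(M - t(M))) < 1e-9)
    expect_true(all(M >= 0 & M <= 1))
    expect_equal(max(abs(diag(M) - 1)), 0)
    expect_true(validObject(S))
  }
})
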