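## Similarity construction: Gaussian interaction-profile kernels on the
## rows/columns of Y, DAG-based disease semantic similarity, best-match
## average lncRNA functional similarity, and the fusion rule that yields
## the lncRNA matrix C and the disease matrix D.

#' Gaussian interaction-profile kernel similarity
#'
#' Computes \eqn{K(i,j) = \exp(-\gamma \|p_i - p_j\|^2)} over binary
#' interaction profiles (one row per entity), with the bandwidth normalised
#' by network density: \eqn{\gamma = \gamma' / \mathrm{mean}_i \|p_i\|^2}.
#' This is the standard interaction-profile kernel for bipartite
#' association networks; for lncRNAs the profiles are the rows of Y, for
#' diseases the columns.
#'
#' @param profiles binary matrix, one row per entity; rownames used as ids.
#' @param gammaPrime positive bandwidth multiplier (default 1).
#' @param entityIds optional identifier registry overriding rownames.
#' @return a [SimilarityMatrix-class].
#' @examples
#' K <- gaussianKernelSimilarity(rbind(l1 = c(1, 0), l2 = c(0, 1)))
#' simMatrix(K)[1, 2]  # exp(-2)
#' @export
gaussianKernelSimilarity <- function(profiles, gammaPrime = 1,
                                     entityIds = rownames(profiles)) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2L) stop("need at least 2 profiles")
  if (gammaPrime <= 0) stop("gammaPrime must be positive")
  norms2 <- rowSums(profiles^2)
  if (all(norms2 == 0))
    stop("all profiles are zero; kernel bandwidth undefined")
  gamma <- gammaPrime / mean(norms2)
  G <- tcrossprod(profiles)
  d2 <- outer(norms2, norms2, "+") - 2 * G
  d2[d2 < 0] <- 0
  K <- exp(-gamma * d2)
  if (is.null(entityIds)) entityIds <- paste0("e", seq_len(nrow(K)))
  SimilarityMatrix(K, entityIds)
}

## Ancestor contributions for one term: itself 1, each ancestor the best
## (max over paths) decay^depth. Relaxation over the child->parent DAG.
.ancestorContributions <- function(term, parentsOf, decay) {
  contrib <- c(1)
  names(contrib) <- term
  queue <- term
  while (length(queue)) {
    t0 <- queue[[1L]]
    queue <- queue[-1L]
    for (p in parentsOf[[t0]]) {
      cand <- decay * contrib[[t0]]
      if (is.na(contrib[p]) || cand > contrib[[p]]) {
        contrib[p] <- cand
        queue <- c(queue, p)
      }
    }
  }
  contrib
}

#' DAG-based disease semantic similarity
#'
#' Each disease contributes 1 to itself and \eqn{\Delta^{depth}} (best path)
#' to every ancestor in the ontology DAG; the similarity of two diseases is
#' the sum of both contribution values over shared terms, divided by the sum
#' of all contributions of the two diseases. Diseases absent from the
#' ontology get similarity defined only on the diagonal (off-diagonal 0, and
#' flagged undefined for fusion, see [ontologyCoverage()]).
#'
#' @param ontology a [DiseaseOntology-class].
#' @param diseases character vector of disease ids (defines output order).
#' @param decay contribution decay per edge, in (0, 1); default 0.5.
#' @return a [SimilarityMatrix-class].
#' @export
diseaseSemanticSimilarity <- function(ontology, diseases, decay = 0.5) {
  if (decay <= 0 || decay >= 1) stop("decay must lie strictly in (0, 1)")
  ed <- parentEdges(ontology)
  parentsOf <- split(ed$parent, factor(ed$child, levels = ontologyTerms(ontology)))
  present <- diseases %in% ontologyTerms(ontology)
  contribs <- vector("list", length(diseases))
  for (k in which(present))
    contribs[[k]] <- .ancestorContributions(diseases[[k]], parentsOf, decay)
  m <- length(diseases)
  M <- diag(1, m)
  for (i in seq_len(m - 1)) {
    if (!present[i]) next
    Si <- contribs[[i]]
    for (j in seq(i + 1, m)) {
      if (!present[j]) next
      Sj <- contribs[[j]]
      shared <- intersect(names(Si), names(Sj))
      if (length(shared))
        M[i, j] <- M[j, i] <-
          (sum(Si[shared]) + sum(Sj[shared])) / (sum(Si) + sum(Sj))
    }
  }
  SimilarityMatrix(M, diseases)
}

#' Which diseases are covered by the ontology
#'
#' @param ontology a [DiseaseOntology-class].
#' @param diseases character vector of disease ids.
#' @return logical vector: TRUE where semantic similarity is defined.
#' @export
ontologyCoverage <- function(ontology, diseases)
  diseases %in% ontologyTerms(ontology)

#' Best-match-average lncRNA functional similarity
#'
#' Two lncRNAs are functionally similar when their associated disease sets
#' are similar: with disease sets A and B,
#' \deqn{FS = \frac{\sum_{a \in A} \max_{b \in B} s(a,b) +
#'                  \sum_{b \in B} \max_{a \in A} s(a,b)}{|A| + |B|}.}
#' lncRNAs without any association get similarity 0 off-diagonal and 1 on
#' the diagonal (and are flagged undefined for fusion).
#'
#' @param network an [AssociationNetwork-class].
#' @param diseaseSim a [SimilarityMatrix-class] over the network's diseases.
#' @return a [SimilarityMatrix-class] over the network's lncRNAs.
#' @export
lncrnaFunctionalSimilarity <- function(network, diseaseSim) {
  Y <- assocMatrix(network)
  if (!identical(diseaseNames(network), entityNames(diseaseSim)))
    stop("diseaseSim must be indexed by the network's diseases")
  S <- simMatrix(diseaseSim)
  n <- nrow(Y)
  sets <- lapply(seq_len(n), function(i) which(Y[i, ] == 1))
  M <- diag(1, n)
  for (i in seq_len(n - 1)) {
    A <- sets[[i]]
    if (!length(A)) next
    for (j in seq(i + 1, n)) {
      B <- sets[[j]]
      if (!length(B)) next
      sub <- S[A, B, drop = FALSE]
      M[i, j] <- M[j, i] <-
        (sum(apply(sub, 1, max)) + sum(apply(sub, 2, max))) /
        (length(A) + length(B))
    }
  }
  SimilarityMatrix(M, lncrnaNames(network))
}

#' Fuse two similarity matrices
#'
#' Arithmetic mean where the second similarity is defined, first-matrix
#' fallback elsewhere. "Defined" is given per entity: a pair (i, j) uses the
#' mean only when both entities are flagged defined (the diagonal is always
#' defined).
#'
#' @param a,b [SimilarityMatrix-class] objects over the same entities.
#' @param defined logical vector over entities (default: all defined) or a
#'   logical matrix over pairs.
#' @return a [SimilarityMatrix-class].
#' @export
fuseSimilarity <- function(a, b, defined = NULL) {
  if (!identical(entityNames(a), entityNames(b)))
    stop("similarity matrices must share the same entity ordering")
  A <- simMatrix(a)
  B <- simMatrix(b)
  if (is.null(defined)) defined <- rep(TRUE, nrow(A))
  D <- if (is.matrix(defined)) defined else outer(defined, defined, "&")
  diag(D) <- TRUE
  M <- ifelse(D, (A + B) / 2, A)
  SimilarityMatrix(M, entityNames(a))
}

#' Build the fused lncRNA and disease similarity matrices
#'
#' Convenience wrapper producing the pair (C, D) the graph encoder consumes:
#' disease side D = Gaussian kernel on the columns of Y fused with DAG
#' semantic similarity (where the ontology covers the disease); lncRNA side
#' C = Gaussian kernel on the rows of Y fused with best-match functional
#' similarity computed against D (where the lncRNA has at least one
#' association).
#'
#' @param network an [AssociationNetwork-class].
#' @param ontology optional [DiseaseOntology-class]; when absent, D is the
#'   Gaussian kernel alone.
#' @param gammaPrime kernel bandwidth multiplier.
#' @param decay semantic-similarity decay.
#' @return list with elements \code{C} and \code{D}
#'   ([SimilarityMatrix-class]).
#' @export
computeSimilarities <- function(network, ontology = NULL, gammaPrime = 1,
                                decay = 0.5) {
  Y <- assocMatrix(network)
  Dg <- gaussianKernelSimilarity(t(Y), gammaPrime, diseaseNames(network))
  if (!is.null(ontology)) {
    Ds <- diseaseSemanticSimilarity(ontology, diseaseNames(network), decay)
    covered <- ontologyCoverage(ontology, diseaseNames(network))
    D <- fuseSimilarity(Dg, Ds, covered)
  } else D <- Dg
  Cg <- gaussianKernelSimilarity(Y, gammaPrime, lncrnaNames(network))
  Cf <- lncrnaFunctionalSimilarity(network, D)
  hasAssoc <- rowSums(Y) > 0
  C <- fuseSimilarity(Cg, Cf, hasAssoc)
  list(C = C, D = D)
}
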