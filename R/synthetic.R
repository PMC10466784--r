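## Seeded synthetic fixtures: bipartite association networks with planted
## low-rank latent structure, and small random disease-term DAGs. These
## drive every end-to-end test without any external download.

#' Generate an association network with planted low-rank structure
#'
#' Draws non-negative latent factors \code{L} (n x r) and \code{Dm} (m x r)
#' as absolute Gaussians, forms the score matrix \code{L \%*\% t(Dm)}, sets
#' the top \code{round(density * n * m)} entries to 1 (a quantile
#' threshold), then flips each entry independently with probability
#' \code{noise}. Non-negative factors make the planted structure visible to
#' the Gaussian interaction-profile kernels, so encoder recovery is
#' testable.
#'
#' @param n,m numbers of lncRNAs / diseases.
#' @param rank latent rank r, between 1 and min(n, m).
#' @param density target positive fraction in (0, 1).
#' @param noise independent flip probability in [0, 0.5).
#' @param seed RNG seed; regeneration with the same arguments is
#'   bit-identical.
#' @return a list of class \code{plantedNetwork} with elements
#'   \code{network} ([AssociationNetwork-class]), \code{latentL},
#'   \code{latentD} and \code{params}.
#' @export
generateNetwork <- function(n = 40L, m = 60L, rank = 3L, density = 0.1,
                            noise = 0, seed = 1L) {
  if (rank < 1L || rank > min(n, m))
    stop("rank must lie between 1 and min(n, m)")
  if (density <= 0 || density >= 1)
    stop("density must lie strictly in (0, 1)")
  if (noise < 0 || noise >= 0.5)
    stop("noise must lie in [0, 0.5)")
  set.seed(seed)
  L <- abs(matrix(stats::rnorm(n * rank), n, rank))
  Dm <- abs(matrix(stats::rnorm(m * rank), m, rank))
  scores <- L %*% t(Dm)
  k <- round(density * n * m)
  Y <- matrix(0, n, m)
  Y[order(scores, decreasing = TRUE)[seq_len(k)]] <- 1
  if (noise > 0) {
    flip <- matrix(stats::runif(n * m) < noise, n, m)
    Y[flip] <- 1 - Y[flip]
  }
  dimnames(Y) <- list(paste0("l", seq_len(n)), paste0("d", seq_len(m)))
  structure(list(network = AssociationNetwork(Y), latentL = L,
                 latentD = Dm,
                 params = list(n = n, m = m, rank = rank,
                               density = density, noise = noise,
                               seed = seed)),
            class = "plantedNetwork")
}

#' @export
print.plantedNetwork <- function(x, ...) {
  p <- x$params
  cat("plantedNetwork:", p$n, "x", p$m, "rank", p$rank, "density",
      p$density, "noise", p$noise, "seed", p$seed, "\n")
  invisible(x)
}

#' Generate a random rooted disease-term DAG
#'
#' Terms are assigned to levels 1..depth under a single root (level 0);
#' each term receives one to \code{branching} parents drawn from strictly
#' lower levels, so the result is acyclic by construction. With
#' \code{depth = 1} the ontology is a star around the root.
#'
#' @param nTerms total number of terms including the root.
#' @param branching maximum number of parents per term.
#' @param depth number of levels below the root.
#' @param seed RNG seed.
#' @param terms optional term names (length \code{nTerms}); defaults to
#'   \code{t1..tN} with \code{t1} the root.
#' @return a [DiseaseOntology-class].
#' @export
generateOntology <- function(nTerms = 30L, branching = 2L, depth = 3L,
                             seed = 1L, terms = NULL) {
  if (nTerms < 1L) stop("nTerms must be at least 1")
  if (is.null(terms)) terms <- paste0("t", seq_len(nTerms))
  if (length(terms) != nTerms) stop("terms must have length nTerms")
  set.seed(seed)
  if (nTerms == 1L) return(DiseaseOntology(terms))
  level <- c(0L, sort(sample.int(depth, nTerms - 1L, replace = TRUE)))
  child <- character()
  parent <- character()
  for (k in seq(2L, nTerms)) {
    lower <- which(level < level[k])
    nPar <- sample.int(min(branching, length(lower)), 1L)
    pk <- if (length(lower) == 1L) lower else sample(lower, nPar)
    child <- c(child, rep(terms[k], length(pk)))
    parent <- c(parent, terms[pk])
  }
  DiseaseOntology(terms, data.frame(child = child, parent = parent))
}
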