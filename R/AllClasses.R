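#' @import methods
NULL

#' Bipartite lncRNA-disease association network
#'
#' Holds the binary association matrix Y (lncRNAs in rows, diseases in
#' columns) together with the two identifier registries. \code{Y[i, j] = 1}
#' records a curated association between lncRNA \code{i} and disease
#' \code{j}; 0 means unknown (not negative).
#'
#' @slot lncrnaIds character vector of unique lncRNA identifiers (row order).
#' @slot diseaseIds character vector of unique disease identifiers (column
#'   order).
#' @slot assoc numeric matrix with entries in \{0, 1\}, dimension
#'   \code{length(lncrnaIds) x length(diseaseIds)}.
#'
#' @seealso [AssociationNetwork()], [readEdgeList()]
#' @exportClass AssociationNetwork
setClass("AssociationNetwork",
  representation(
    lncrnaIds = "character",
    diseaseIds = "character",
    assoc = "matrix"
  )
)

setValidity("AssociationNetwork", function(object) {
  msg <- character()
  Y <- object@assoc
  if (anyDuplicated(object@lncrnaIds))
    msg <- c(msg, "lncRNA identifiers must be unique")
  if (anyDuplicated(object@diseaseIds))
    msg <- c(msg, "disease identifiers must be unique")
  if (nrow(Y) != length(object@lncrnaIds) ||
      ncol(Y) != length(object@diseaseIds))
    msg <- c(msg, "assoc dimensions must match identifier registries")
  if (nrow(Y) < 2L || ncol(Y) < 2L)
    msg <- c(msg, "need at least 2 lncRNAs and 2 diseases")
  if (!all(Y %in% c(0, 1)))
    msg <- c(msg, "assoc entries must be 0 or 1")
  if (sum(Y) < 1)
    msg <- c(msg, "network must contain at least one association")
  if (length(msg)) msg else TRUE
})

#' Disease ontology as a parent-child DAG
#'
#' A rooted directed acyclic graph over disease terms, used by the semantic
#' similarity. Edges point child -> parent; roots are terms with no parent.
#'
#' @slot terms character vector of unique term identifiers.
#' @slot parentEdges data.frame with columns \code{child}, \code{parent};
#'   every endpoint is a registered term and the relation is acyclic.
#'
#' @seealso [DiseaseOntology()], [readOntology()], [diseaseSemanticSimilarity()]
#' @exportClass DiseaseOntology
setClass("DiseaseOntology",
  representation(
    terms = "character",
    parentEdges = "data.frame"
  )
)

.findCycle <- function(terms, child, parent) {
  ## Iterative depth-first search over child->parent edges; returns NULL
  ## when the relation is acyclic, otherwise one offending path.
  nTerm <- length(terms)
  idx <- seq_len(nTerm)
  names(idx) <- terms
  adj <- split(idx[parent], factor(child, levels = terms))
  color <- integer(nTerm) # 0 white, 1 on stack, 2 done
  for (s in seq_len(nTerm)) {
    if (color[s] != 0L) next
    stack <- list(list(v = s, nexti = 1L))
    color[s] <- 1L
    while (length(stack)) {
      top <- stack[[length(stack)]]
      nbrs <- adj[[top$v]]
      if (top$nexti > length(nbrs)) {
        color[top$v] <- 2L
        stack[[length(stack)]] <- NULL
        next
      }
      w <- nbrs[[top$nexti]]
      stack[[length(stack)]]$nexti <- top$nexti + 1L
      if (color[w] == 1L) {
        onstack <- vapply(stack, function(e) e$v, integer(1))
        from <- match(w, onstack)
        return(terms[c(onstack[from:length(onstack)], w)])
      }
      if (color[w] == 0L) {
        color[w] <- 1L
        stack[[length(stack) + 1L]] <- list(v = w, nexti = 1L)
      }
    }
  }
  NULL
}

setValidity("DiseaseOntology", function(object) {
  msg <- character()
  ed <- object@parentEdges
  if (!all(c("child", "parent") %in% names(ed)))
    msg <- c(msg, "parentEdges needs columns 'child' and 'parent'")
  if (anyDuplicated(object@terms))
    msg <- c(msg, "terms must be unique")
  if (nrow(ed)) {
    if (!all(ed$child %in% object@terms) || !all(ed$parent %in% object@terms))
      msg <- c(msg, "every edge endpoint must be a registered term")
    if (any(ed$child == ed$parent))
      msg <- c(msg, "self-loop detected")
    else if (length(msg) == 0L) {
      cyc <- .findCycle(object@terms, ed$child, ed$parent)
      if (!is.null(cyc))
        msg <- c(msg, paste0("cycle detected: ",
                             paste(cyc, collapse = " -> ")))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Square similarity matrix over one entity type
#'
#' Symmetric matrix of pairwise similarities in [0, 1] with unit diagonal,
#' indexed by an ordered identifier registry. One instance describes either
#' the lncRNA side (C) or the disease side (D) of the model.
#'
#' @slot entityIds character vector of unique identifiers.
#' @slot sim numeric square matrix; symmetric within 1e-9, entries in [0, 1],
#'   diagonal exactly 1.
#'
#' @seealso [SimilarityMatrix()], [gaussianKernelSimilarity()]
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix",
  representation(
    entityIds = "character",
    sim = "matrix"
  )
)

setValidity("SimilarityMatrix", function(object) {
  msg <- character()
  M <- object@sim
  if (nrow(M) != ncol(M)) msg <- c(msg, "matrix must be square")
  if (nrow(M) != length(object@entityIds))
    msg <- c(msg, "dimension must match entityIds")
  if (anyDuplicated(object@entityIds))
    msg <- c(msg, "entityIds must be unique")
  if (nrow(M) == ncol(M) && nrow(M) > 0) {
    if (max(abs(M - t(M))) > 1e-9) msg <- c(msg, "matrix must be symmetric")
    if (min(M) < -1e-9 || max(M) > 1 + 1e-9)
      msg <- c(msg, "entries must lie in [0, 1]")
    if (max(abs(diag(M) - 1)) > 1e-9)
      msg <- c(msg, "diagonal entries must equal 1")
  }
  if (length(msg)) msg else TRUE
})

#' Graph-encoder state
#'
#' Layer outputs and embeddings produced by the stacked GCN-GAT-GCN encoder:
#' per-graph feature matrices H0..H3, the convolution-combined embeddings
#' \code{Xc} (F x n, lncRNAs) and \code{Xd} (F x m, diseases), and the
#' preference matrix \code{U = t(Xc) \%*\% Xd} used as the training signal.
#'
#' @slot Hc list of four matrices: lncRNA-graph layer outputs H0..H3.
#' @slot Hd list of four matrices: disease-graph layer outputs H0..H3.
#' @slot Xc numeric matrix, embedding dimension x n.
#' @slot Xd numeric matrix, embedding dimension x m.
#' @slot U numeric n x m preference matrix.
#' @slot lossHistory numeric vector of per-epoch training losses (empty for
#'   an untrained forward pass).
#' @slot config list echoing the [encoderConfig()] used.
#' @slot params list of trained layer parameters (both graphs).
#'
#' @exportClass EncoderState
setClass("EncoderState",
  representation(
    Hc = "list",
    Hd = "list",
    Xc = "matrix",
    Xd = "matrix",
    U = "matrix",
    lossHistory = "numeric",
    config = "list",
    params = "list"
  )
)

setValidity("EncoderState", function(object) {
  msg <- character()
  n <- ncol(object@Xc)
  m <- ncol(object@Xd)
  if (nrow(object@Xc) != nrow(object@Xd))
    msg <- c(msg, "Xc and Xd must share the embedding dimension")
  if (!all(dim(object@U) == c(n, m)))
    msg <- c(msg, "U must be n x m")
  else if (max(abs(object@U - crossprod(object@Xc, object@Xd))) > 1e-8)
    msg <- c(msg, "U must equal t(Xc) %*% Xd")
  if (length(object@Hc) != 4L || length(object@Hd) != 4L)
    msg <- c(msg, "need layer outputs H0..H3 for each graph")
  if (length(msg)) msg else TRUE
})

#' Cross-validation evaluation report
#'
#' Per-repeat and aggregated classification metrics for one cross-validation
#' scheme (lncRNA-wise CV1, disease-wise CV2, or pair-wise CV3).
#'
#' @slot perRepeat data.frame with one row per repeat and columns
#'   \code{repeat_}, \code{precision}, \code{recall}, \code{accuracy},
#'   \code{f1}, \code{auc}, \code{aupr}.
#' @slot aggregate data.frame with columns \code{metric}, \code{mean},
#'   \code{sd}.
#' @slot scheme character, one of \code{"CV1"}, \code{"CV2"}, \code{"CV3"}.
#' @slot config list echoing the experiment configuration and seeds.
#'
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  representation(
    perRepeat = "data.frame",
    aggregate = "data.frame",
    scheme = "character",
    config = "list"
  )
)

setValidity("EvaluationReport", function(object) {
  msg <- character()
  metrics <- c("precision", "recall", "accuracy", "f1", "auc", "aupr")
  pr <- object@perRepeat
  if (!all(metrics %in% names(pr)))
    msg <- c(msg, "perRepeat must contain the six metric columns")
  else {
    vals <- as.matrix(pr[metrics])
    if (any(vals < -1e-12 | vals > 1 + 1e-12, na.rm = TRUE))
      msg <- c(msg, "metrics must lie in [0, 1]")
    agg <- object@aggregate
    for (k in seq_len(nrow(agg))) {
      v <- pr[[agg$metric[k]]]
      if (abs(mean(v) - agg$mean[k]) > 1e-8)
        msg <- c(msg, "aggregate means must match per-repeat values")
    }
  }
  if (!object@scheme %in% c("CV1", "CV2", "CV3"))
    msg <- c(msg, "scheme must be CV1, CV2 or CV3")
  if (length(msg)) msg else TRUE
})
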