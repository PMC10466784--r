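#' Construct an association network
#'
#' @param assoc binary matrix (lncRNAs x diseases) with entries in \{0, 1\}.
#' @param lncrnaIds,diseaseIds identifier registries; default to the
#'   dimnames of \code{assoc}.
#' @return an [AssociationNetwork-class] object.
#' @examples
#' Y <- matrix(c(1, 0, 1, 1), 2, 2,
#'             dimnames = list(c("l1", "l2"), c("d1", "d2")))
#' net <- AssociationNetwork(Y)
#' assocMatrix(net)
#' @export
AssociationNetwork <- function(assoc,
                               lncrnaIds = rownames(assoc),
                               diseaseIds = colnames(assoc)) {
  if (is.null(lncrnaIds) || is.null(diseaseIds))
    stop("identifier registries required (supply ids or dimnames)")
  assoc <- as.matrix(assoc)
  storage.mode(assoc) <- "double"
  dimnames(assoc) <- list(lncrnaIds, diseaseIds)
  new("AssociationNetwork", lncrnaIds = as.character(lncrnaIds),
      diseaseIds = as.character(diseaseIds), assoc = assoc)
}

#' Construct a disease ontology
#'
#' @param terms character vector of term identifiers.
#' @param parentEdges data.frame with columns \code{child}, \code{parent}.
#' @return a [DiseaseOntology-class] object.
#' @export
DiseaseOntology <- function(terms, parentEdges = data.frame(
                              child = character(), parent = character())) {
  parentEdges <- data.frame(child = as.character(parentEdges$child),
                            parent = as.character(parentEdges$parent),
                            stringsAsFactors = FALSE)
  new("DiseaseOntology", terms = as.character(terms),
      parentEdges = parentEdges)
}

#' Construct a similarity matrix
#'
#' @param sim square numeric matrix; symmetric, entries in [0, 1], unit
#'   diagonal.
#' @param entityIds identifier registry; defaults to rownames.
#' @return a [SimilarityMatrix-class] object.
#' @export
SimilarityMatrix <- function(sim, entityIds = rownames(sim)) {
  if (is.null(entityIds))
    stop("entity identifiers required (supply ids or rownames)")
  sim <- as.matrix(sim)
  ## snap floating-point dust so downstream validity checks stay meaningful
  sim <- (sim + t(sim)) / 2
  sim[sim < 0 & sim > -1e-9] <- 0
  sim[sim > 1 & sim < 1 + 1e-9] <- 1
  dimnames(sim) <- list(entityIds, entityIds)
  new("SimilarityMatrix", entityIds = as.character(entityIds), sim = sim)
}

#' @rdname AssociationNetwork
#' @param object,x an object.
#' @export
setGeneric("lncrnaNames", function(x) standardGeneric("lncrnaNames"))

#' @rdname AssociationNetwork
#' @export
setGeneric("diseaseNames", function(x) standardGeneric("diseaseNames"))

#' @rdname AssociationNetwork
#' @export
setGeneric("assocMatrix", function(x) standardGeneric("assocMatrix"))

#' @rdname SimilarityMatrix
#' @param x an object.
#' @export
setGeneric("entityNames", function(x) standardGeneric("entityNames"))

#' @rdname SimilarityMatrix
#' @export
setGeneric("simMatrix", function(x) standardGeneric("simMatrix"))

#' @rdname EncoderState-class
#' @param x an object.
#' @export
setGeneric("lncrnaEmbeddings", function(x) standardGeneric("lncrnaEmbeddings"))

#' @rdname EncoderState-class
#' @export
setGeneric("diseaseEmbeddings", function(x) standardGeneric("diseaseEmbeddings"))

#' @rdname EncoderState-class
#' @export
setGeneric("preferenceScores", function(x) standardGeneric("preferenceScores"))

#' @rdname EncoderState-class
#' @export
setGeneric("lossHistory", function(x) standardGeneric("lossHistory"))

#' @rdname EvaluationReport-class
#' @param x an object.
#' @export
setGeneric("perRepeat", function(x) standardGeneric("perRepeat"))

#' @rdname EvaluationReport-class
#' @export
setGeneric("aggregated", function(x) standardGeneric("aggregated"))

#' @rdname AssociationNetwork
#' @export
setMethod("lncrnaNames", "AssociationNetwork", function(x) x@lncrnaIds)

#' @rdname AssociationNetwork
#' @export
setMethod("diseaseNames", "AssociationNetwork", function(x) x@diseaseIds)

#' @rdname AssociationNetwork
#' @export
setMethod("assocMatrix", "AssociationNetwork", function(x) x@assoc)

#' @rdname SimilarityMatrix
#' @export
setMethod("entityNames", "SimilarityMatrix", function(x) x@entityIds)

#' @rdname SimilarityMatrix
#' @export
setMethod("simMatrix", "SimilarityMatrix", function(x) x@sim)

#' @rdname DiseaseOntology
#' @param x an object.
#' @export
setGeneric("ontologyTerms", function(x) standardGeneric("ontologyTerms"))

#' @rdname DiseaseOntology
#' @export
setGeneric("parentEdges", function(x) standardGeneric("parentEdges"))

#' @rdname DiseaseOntology
#' @export
setMethod("ontologyTerms", "DiseaseOntology", function(x) x@terms)

#' @rdname DiseaseOntology
#' @export
setMethod("parentEdges", "DiseaseOntology", function(x) x@parentEdges)

#' @rdname EncoderState-class
#' @export
setMethod("lncrnaEmbeddings", "EncoderState", function(x) x@Xc)

#' @rdname EncoderState-class
#' @export
setMethod("diseaseEmbeddings", "EncoderState", function(x) x@Xd)

#' @rdname EncoderState-class
#' @export
setMethod("preferenceScores", "EncoderState", function(x) x@U)

#' @rdname EncoderState-class
#' @export
setMethod("lossHistory", "EncoderState", function(x) x@lossHistory)

#' @rdname EvaluationReport-class
#' @export
setMethod("perRepeat", "EvaluationReport", function(x) x@perRepeat)

#' @rdname EvaluationReport-class
#' @export
setMethod("aggregated", "EvaluationReport", function(x) x@aggregate)

setMethod("show", "AssociationNetwork", function(object) {
  Y <- object@assoc
  cat("AssociationNetwork:", nrow(Y), "lncRNAs x", ncol(Y), "diseases,",
      sum(Y), "associations (density",
      sprintf("%.3f", mean(Y)), ")\n")
})

setMethod("show", "DiseaseOntology", function(object) {
  roots <- setdiff(object@terms, object@parentEdges$child)
  cat("DiseaseOntology:", length(object@terms), "terms,",
      nrow(object@parentEdges), "child->parent edges,",
      length(roots), "root(s)\n")
})

setMethod("show", "SimilarityMatrix", function(object) {
  M <- object@sim
  off <- M[upper.tri(M)]
  cat("SimilarityMatrix:", nrow(M), "entities; off-diagonal mean",
      sprintf("%.3f", if (length(off)) mean(off) else NA_real_), "\n")
})

setMethod("show", "EncoderState", function(object) {
  cat("EncoderState: F =", nrow(object@Xc), ", n =", ncol(object@Xc),
      ", m =", ncol(object@Xd), "\n")
  if (length(object@lossHistory))
    cat("  trained", length(object@lossHistory), "epochs; final BCE",
        sprintf("%.4f", utils::tail(object@lossHistory, 1)), "\n")
  else cat("  untrained forward pass\n")
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport (", object@scheme, ", ",
      nrow(object@perRepeat), " repeats)\n", sep = "")
  agg <- object@aggregate
  for (k in seq_len(nrow(agg)))
    cat(sprintf("  %-9s %.4f +/- %.4f\n", agg$metric[k], agg$mean[k],
                agg$sd[k]))
})
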