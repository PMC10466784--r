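## Readers and writers for edge lists, association matrices, ontologies
## and prediction tables. All formats are plain text (TSV/CSV).

.detectSep <- function(line) if (grepl("\t", line, fixed = TRUE)) "\t" else ","

.looksLikeHeader <- function(fields) {
  f1 <- tolower(fields[[1]])
  f2 <- tolower(fields[[2]])
  grepl("lnc|rna", f1) && grepl("dis|doid|mesh", f2)
}

#' Read an lncRNA-disease edge list
#'
#' Reads a two-column TSV/CSV of (lncRNA id, disease id) pairs into a binary
#' association network. The separator and an optional header row are
#' auto-detected; duplicated pairs collapse to a single association (the
#' number collapsed is reported via \code{message()}). Identifier order is
#' first appearance in the file unless registries are supplied, in which
#' case rows/columns follow the registries and unlisted entities get
#' all-zero profiles.
#'
#' @param path file path.
#' @param knownLncrnas,knownDiseases optional identifier registries; ids in
#'   the file that are absent from a supplied registry raise an error.
#' @return an [AssociationNetwork-class].
#' @export
readEdgeList <- function(path, knownLncrnas = NULL, knownDiseases = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty edge-list file: ", path)
  sep <- .detectSep(lines[[1]])
  parts <- strsplit(lines, sep, fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop("row ", bad[[1]], " has fewer than 2 fields")
  if (.looksLikeHeader(trimws(parts[[1]]))) parts <- parts[-1L]
  if (!length(parts)) stop("edge list contains only a header row")
  lnc <- trimws(vapply(parts, `[[`, "", 1L))
  dis <- trimws(vapply(parts, `[[`, "", 2L))
  if (!is.null(knownLncrnas)) {
    miss <- setdiff(unique(lnc), knownLncrnas)
    if (length(miss))
      stop("lncRNA id(s) not in supplied registry: ",
           paste(utils::head(miss, 5), collapse = ", "))
    lncIds <- as.character(knownLncrnas)
  } else lncIds <- unique(lnc)
  if (!is.null(knownDiseases)) {
    miss <- setdiff(unique(dis), knownDiseases)
    if (length(miss))
      stop("disease id(s) not in supplied registry: ",
           paste(utils::head(miss, 5), collapse = ", "))
    disIds <- as.character(knownDiseases)
  } else disIds <- unique(dis)
  Y <- matrix(0, length(lncIds), length(disIds),
              dimnames = list(lncIds, disIds))
  dup <- duplicated(paste(lnc, dis, sep = "\r"))
  if (any(dup))
    message("collapsed ", sum(dup), " duplicated edge(s)")
  Y[cbind(match(lnc, lncIds), match(dis, disIds))] <- 1
  AssociationNetwork(Y)
}

#' Write an association network as an edge list
#'
#' One row per association, TSV with header \code{lncrna\tdisease}.
#' @param network an [AssociationNetwork-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeEdgeList <- function(network, path) {
  Y <- assocMatrix(network)
  idx <- which(Y == 1, arr.ind = TRUE)
  df <- data.frame(lncrna = lncrnaNames(network)[idx[, 1]],
                   disease = diseaseNames(network)[idx[, 2]])
  df <- df[order(df$lncrna, df$disease), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export / import the full binary matrix as CSV with headers
#'
#' Unlike the edge list, the matrix form preserves entities without any
#' association, so write-then-read reproduces Y bit-exactly.
#' @param network an [AssociationNetwork-class].
#' @param path file path.
#' @return `writeAssociationMatrix`: the path invisibly;
#'   `readAssociationMatrix`: an [AssociationNetwork-class].
#' @export
writeAssociationMatrix <- function(network, path) {
  utils::write.csv(assocMatrix(network), path, quote = FALSE)
  invisible(path)
}

#' @rdname writeAssociationMatrix
#' @export
readAssociationMatrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  AssociationNetwork(as.matrix(df))
}

#' Read a disease ontology from a child-parent TSV
#'
#' Expects two columns (child, parent). The term registry is the union of
#' all endpoints; acyclicity is verified and a violation is reported with
#' one offending path.
#'
#' @param path file path.
#' @return a [DiseaseOntology-class].
#' @export
readOntology <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty ontology file: ", path)
  sep <- .detectSep(lines[[1]])
  parts <- strsplit(lines, sep, fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) stop("row ", bad[[1]], " has fewer than 2 fields")
  if (tolower(trimws(parts[[1]][1])) == "child") parts <- parts[-1L]
  child <- trimws(vapply(parts, `[[`, "", 1L))
  parent <- trimws(vapply(parts, `[[`, "", 2L))
  terms <- unique(c(child, parent))
  DiseaseOntology(terms, data.frame(child = child, parent = parent))
}

#' @rdname readOntology
#' @param ontology a [DiseaseOntology-class].
#' @export
writeOntology <- function(ontology, path) {
  utils::write.table(parentEdges(ontology), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a prediction table, optionally keeping the top k per disease
#'
#' Emits a TSV with columns \code{disease}, \code{rank}, \code{lncrna},
#' \code{score}, sorted by score descending within each disease (ties broken
#' by lncRNA id, lexicographic). When \code{topK} is given, pairs whose
#' known label is positive are removed first — the candidate-ranking mode
#' used to propose novel biomarkers — and only the first \code{topK} rows
#' per disease are written.
#'
#' @param table data.frame with columns \code{lncrna}, \code{disease},
#'   \code{score} and optionally \code{knownLabel}.
#' @param path output file path.
#' @param topK optional positive integer.
#' @return the written data.frame, invisibly.
#' @export
writePredictions <- function(table, path, topK = NULL) {
  if (!nrow(table)) stop("prediction table is empty")
  tab <- as.data.frame(table)
  if (!is.null(topK)) {
    if (!is.null(tab$knownLabel))
      tab <- tab[is.na(tab$knownLabel) | tab$knownLabel != 1, , drop = FALSE]
  }
  tab <- tab[order(tab$disease, -tab$score, tab$lncrna), , drop = FALSE]
  out <- do.call(rbind, lapply(split(tab, tab$disease), function(d) {
    d$rank <- seq_len(nrow(d))
    if (!is.null(topK)) d <- d[seq_len(min(topK, nrow(d))), , drop = FALSE]
    d
  }))
  out <- out[, c("disease", "rank", "lncrna", "score")]
  rownames(out) <- NULL
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
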