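#' ProteinSet: protein sequences with optional secondary structure
#'
#' Container for a set of protein sequences (20 canonical residues plus the
#' IUPAC ambiguity codes B/Z/X/J and the rare residues U/O) together with an
#' optional per-protein three-state secondary-structure string over
#' \{H, E, C\} (helix, sheet, coil). Secondary structure may be `NA` for any
#' protein; when present it must have the same length as the sequence.
#'
#' @slot seqs named character vector of amino-acid sequences (names = ids).
#' @slot ss named character vector of secondary-structure strings, `NA`
#'   where unavailable; parallel to `seqs`.
#' @export
setClass("ProteinSet", representation(seqs = "character", ss = "character"))

setValidity("ProteinSet", function(object) {
  s <- object@seqs
  if (length(s) == 0) return(TRUE)
  if (is.null(names(s)) || anyNA(names(s)) || any(names(s) == ""))
    return("all sequences must be named with protein ids")
  if (anyDuplicated(names(s))) return("duplicate protein ids")
  if (any(nchar(s) == 0)) return("empty sequence")
  if (length(object@ss) != length(s))
    return("ss must be parallel to seqs")
  ok <- is.na(object@ss) | nchar(object@ss) == nchar(s)
  if (!all(ok))
    return(sprintf("ss length mismatch for '%s'", names(s)[which(!ok)[1]]))
  TRUE
})

#' Construct a ProteinSet
#'
#' @param seqs named character vector of sequences (uppercased on input).
#' @param ss optional named/unnamed character vector of H/E/C strings,
#'   `NA` allowed; recycled to `NA` if omitted.
#' @return a [ProteinSet-class] object.
#' @export
ProteinSet <- function(seqs, ss = NULL) {
  seqs <- toupper(seqs)
  for (i in seq_along(seqs)) validateSequence(seqs[i], names(seqs)[i])
  if (is.null(ss)) ss <- rep(NA_character_, length(seqs))
  ss <- toupper(ss)
  for (i in seq_along(ss))
    if (!is.na(ss[i])) validateSequence(ss[i], names(seqs)[i], SS3)
  names(ss) <- names(seqs)
  new("ProteinSet", seqs = seqs, ss = ss)
}

#' @describeIn ProteinSet number of proteins
#' @param x a ProteinSet
#' @export
setMethod("length", "ProteinSet", function(x) length(x@seqs))

#' Accessors for ProteinSet
#'
#' `proteinIds` returns the ids, `sequences` the named sequence vector,
#' `ssStrings` the named secondary-structure vector (`NA` where absent).
#'
#' @param x a [ProteinSet-class]
#' @return character vectors.
#' @export
proteinIds <- function(x) names(x@seqs)

#' @rdname proteinIds
#' @export
sequences <- function(x) x@seqs

#' @rdname proteinIds
#' @export
ssStrings <- function(x) x@ss

#' Subset a ProteinSet by ids or indices
#' @param x a ProteinSet
#' @param i index vector (ids, positions or logical)
#' @param j,drop,... ignored
#' @export
setMethod("[", "ProteinSet", function(x, i, j, ..., drop = FALSE) {
  new("ProteinSet", seqs = x@seqs[i], ss = x@ss[i])
})

setMethod("show", "ProteinSet", function(object) {
  n <- length(object)
  cat(sprintf("ProteinSet with %d sequence%s", n, if (n == 1) "" else "s"))
  if (n > 0)
    cat(sprintf(", lengths %d-%d, %d with secondary structure",
                min(nchar(object@seqs)), max(nchar(object@seqs)),
                sum(!is.na(object@ss))))
  cat("\n")
})

#' GoDag: directed acyclic graph of GO terms with a slim subset
#'
#' Term graph over `is_a` edges, split into the three GO namespaces, with a
#' marked subset of slim terms (the categories under study).
#'
#' @slot terms character vector of term ids (GO:NNNNNNN).
#' @slot termName named character, term id -> human-readable name.
#' @slot namespace named character, term id -> one of
#'   `molecular_function`, `cellular_component`, `biological_process`.
#' @slot parents named list, term id -> character vector of parent term ids.
#' @slot slim character vector of slim term ids (subset of `terms`).
#' @export
setClass("GoDag", representation(terms = "character", termName = "character",
                                 namespace = "character", parents = "list",
                                 slim = "character"))

setValidity("GoDag", function(object) {
  tm <- object@terms
  if (anyDuplicated(tm)) return("duplicate term ids")
  if (!all(names(object@parents) == tm)) return("parents misaligned")
  pp <- unlist(object@parents, use.names = FALSE)
  if (length(pp) && !all(pp %in% tm)) {
    miss <- setdiff(pp, tm)
    return(sprintf("dangling is_a target '%s'", miss[1]))
  }
  if (!all(object@slim %in% tm)) return("slim terms not all in DAG")
  # acyclicity by Kahn's algorithm
  nkids <- setNames(integer(length(tm)), tm)
  for (p in pp) nkids[p] <- nkids[p] + 1L
  queue <- tm[nkids == 0L]
  seen <- 0L
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    for (p in object@parents[[t]]) {
      nkids[p] <- nkids[p] - 1L
      if (nkids[p] == 0L) queue <- c(queue, p)
    }
  }
  if (seen < length(tm)) return("cycle detected in is_a graph")
  TRUE
})

#' Construct a GoDag
#'
#' @param terms term ids.
#' @param parents list parallel to `terms` of parent-id character vectors.
#' @param namespace namespace per term (recycled if length 1).
#' @param name human-readable names per term (defaults to the ids).
#' @param slim character vector marking the slim subset.
#' @return a [GoDag-class]
#' @export
GoDag <- function(terms, parents, namespace = "biological_process",
                  name = terms, slim = character()) {
  if (length(namespace) == 1) namespace <- rep(namespace, length(terms))
  parents <- lapply(parents, as.character)
  names(parents) <- terms
  new("GoDag", terms = terms,
      termName = setNames(name, terms),
      namespace = setNames(namespace, terms),
      parents = parents, slim = slim)
}

#' @rdname proteinIds
#' @export
slimTerms <- function(x) x@slim

#' @rdname proteinIds
#' @export
dagTerms <- function(x) x@terms

setMethod("show", "GoDag", function(object) {
  cat(sprintf("GoDag with %d terms (%d slim) over namespaces: %s\n",
              length(object@terms), length(object@slim),
              paste(unique(object@namespace), collapse = ", ")))
})

#' LabelMatrix: proteins x slim-terms binary membership
#'
#' Rows are proteins, columns slim terms; cells are 0/1 membership. A column
#' is flagged *incomplete* when the term has at least one slim descendant,
#' i.e. its positive set deliberately excludes the subtrees captured by
#' descendant slim categories (rendered with a trailing asterisk in reports).
#'
#' @slot labels integer matrix in \{0,1\} with protein-id rownames and
#'   term-id colnames.
#' @slot incomplete named logical per column.
#' @export
setClass("LabelMatrix", representation(labels = "matrix",
                                       incomplete = "logical"))

setValidity("LabelMatrix", function(object) {
  m <- object@labels
  if (!all(m %in% c(0L, 1L))) return("labels must be 0/1")
  if (ncol(m) > 0 && is.null(colnames(m))) return("missing term colnames")
  if (nrow(m) > 0 && is.null(rownames(m))) return("missing protein rownames")
  if (length(object@incomplete) != ncol(m))
    return("incomplete flag must be per column")
  TRUE
})

#' Construct a LabelMatrix
#' @param labels 0/1 matrix, rownames = protein ids, colnames = term ids.
#' @param incomplete logical per column (default all FALSE).
#' @return a [LabelMatrix-class]
#' @export
LabelMatrix <- function(labels, incomplete = NULL) {
  mode(labels) <- "integer"
  if (is.null(incomplete)) incomplete <- rep(FALSE, ncol(labels))
  names(incomplete) <- colnames(labels)
  new("LabelMatrix", labels = labels, incomplete = incomplete)
}

#' @rdname proteinIds
#' @export
labelValues <- function(x) x@labels

#' @rdname proteinIds
#' @export
incompleteFlags <- function(x) x@incomplete

setMethod("show", "LabelMatrix", function(object) {
  cat(sprintf("LabelMatrix: %d proteins x %d terms (%d incomplete)\n",
              nrow(object@labels), ncol(object@labels),
              sum(object@incomplete)))
  if (ncol(object@labels) > 0) {
    np <- colSums(object@labels)
    cat(sprintf("  positives per term: %d-%d (median %g)\n",
                min(np), max(np), stats::median(np)))
  }
})

#' FeatureClustering: partition of features from Ward clustering
#'
#' @slot k number of clusters.
#' @slot assignment named integer, feature name -> cluster id (1..k).
#' @slot linkage the `hclust` merge record (list with `merge`, `height`,
#'   `labels`, `method`).
#' @export
setClass("FeatureClustering", representation(k = "numeric",
                                             assignment = "integer",
                                             linkage = "list"))

setValidity("FeatureClustering", function(object) {
  a <- object@assignment
  if (is.null(names(a))) return("assignment must be named by feature")
  if (length(a) && (min(a) < 1 || max(a) > object@k))
    return("cluster ids out of range")
  TRUE
})

#' @rdname proteinIds
#' @export
clusterAssignment <- function(x) x@assignment

setMethod("show", "FeatureClustering", function(object) {
  cat(sprintf("FeatureClustering: %d features in %d clusters (sizes %s)\n",
              length(object@assignment), object@k,
              paste(tabulate(object@assignment, object@k), collapse = ", ")))
})

#' ZScoreState: fitted per-feature normalization parameters
#'
#' @slot center named numeric of feature means (fitting subset).
#' @slot scale named numeric of feature sample standard deviations.
#' @slot zeroVar named logical flagging zero-variance features (mapped to 0).
#' @export
setClass("ZScoreState", representation(center = "numeric", scale = "numeric",
                                       zeroVar = "logical"))

setMethod("show", "ZScoreState", function(object) {
  cat(sprintf("ZScoreState over %d features (%d zero-variance)\n",
              length(object@center), sum(object@zeroVar)))
})
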