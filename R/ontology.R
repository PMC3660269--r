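#' Ancestors of a GO term
#'
#' Transitive closure over `is_a` parent edges, excluding the term itself.
#' Under the GO propagation (true-path) principle an annotation to a term
#' implies annotation to every ancestor.
#'
#' @param term a term id in `dag`.
#' @param dag a [GoDag-class]
#' @return character vector of ancestor ids (empty for a root).
#' @export
goAncestors <- function(term, dag) {
  if (!(term %in% dag@terms)) stopf("unknown term '%s'", term)
  out <- character(); frontier <- dag@parents[[term]]
  while (length(frontier)) {
    out <- union(out, frontier)
    frontier <- setdiff(unique(unlist(dag@parents[frontier])), out)
  }
  out
}

#' Descendants of a GO term
#' @inheritParams goAncestors
#' @return character vector of descendant ids (excluding `term`).
#' @export
goDescendants <- function(term, dag) {
  kids <- childMap(dag)
  out <- character(); frontier <- kids[[term]]
  while (length(frontier)) {
    out <- union(out, frontier)
    frontier <- setdiff(unique(unlist(kids[frontier])), out)
  }
  out
}

## parent -> children adjacency
childMap <- function(dag) {
  kids <- setNames(vector("list", length(dag@terms)), dag@terms)
  for (t in dag@terms)
    for (p in dag@parents[[t]]) kids[[p]] <- c(kids[[p]], t)
  kids
}

#' Terms whose annotations contribute positives to a slim category
#'
#' For a slim term T the positive set is built from annotations to T or any
#' of its descendants, *except* the subtrees captured by descendant slim
#' categories: walking down from T, the walk never enters another slim term.
#' A descendant with multiple parents is therefore kept iff at least one
#' downward path from T reaches it while avoiding every slim descendant
#' (path-sensitive exclusion).
#'
#' @param slimTerm a term id in `slimTerms(dag)`.
#' @param dag a [GoDag-class]
#' @return character vector of contributing term ids (always contains
#'   `slimTerm`).
#' @export
contributingTerms <- function(slimTerm, dag) {
  if (!(slimTerm %in% dag@slim))
    stopf("'%s' is not a slim term", slimTerm)
  kids <- childMap(dag)
  blocked <- setdiff(dag@slim, slimTerm)
  out <- slimTerm
  frontier <- setdiff(kids[[slimTerm]], blocked)
  while (length(frontier)) {
    out <- union(out, frontier)
    nxt <- unique(unlist(kids[frontier]))
    frontier <- setdiff(nxt, c(out, blocked))
  }
  out
}

#' Build the proteins x slim-terms label matrix
#'
#' A protein is positive for slim term T iff it carries at least one
#' annotation to a term in [contributingTerms]`(T, dag)`; every other
#' protein in the table is a negative for T. Proteins passed via `proteins`
#' appear as rows even if they have no usable annotation (all-negative
#' rows), mirroring per-namespace universes where an unannotated protein is
#' a universal negative. A term is flagged *incomplete* iff it has at least
#' one slim descendant.
#'
#' @param ann annotation data.frame (`protein`, `term`, ...columns) as from
#'   [readAnnotations].
#' @param dag a [GoDag-class] with a non-empty slim set.
#' @param proteins optional character vector fixing the row universe.
#' @return a [LabelMatrix-class]
#' @export
buildLabelMatrix <- function(ann, dag, proteins = NULL) {
  if (is.null(proteins)) proteins <- unique(ann$protein)
  unknown <- setdiff(unique(ann$term), dag@terms)
  if (length(unknown)) {
    warnf("skipping %d annotation(s) to unknown term(s)",
          sum(ann$term %in% unknown))
    ann <- ann[!(ann$term %in% unknown), , drop = FALSE]
  }
  slim <- dag@slim
  m <- matrix(0L, nrow = length(proteins), ncol = length(slim),
              dimnames = list(proteins, slim))
  byTerm <- split(ann$protein, ann$term)
  incomplete <- setNames(logical(length(slim)), slim)
  for (s in slim) {
    contrib <- contributingTerms(s, dag)
    pos <- unique(unlist(byTerm[intersect(contrib, names(byTerm))]))
    m[intersect(pos, proteins), s] <- 1L
    incomplete[s] <- length(intersect(goDescendants(s, dag), slim)) > 0
  }
  LabelMatrix(m, incomplete)
}

#' Drop slim categories with too few positive samples
#'
#' Categories with fewer than `minSize` positives are discarded as too small
#' to train a statistically reliable classifier (default threshold 30).
#' The row set is unchanged.
#'
#' @param labels a [LabelMatrix-class]
#' @param minSize minimum number of positives (default 30).
#' @return a [LabelMatrix-class] with a (possibly empty) subset of columns.
#' @export
filterMinSize <- function(labels, minSize = 30) {
  m <- labelValues(labels)
  keep <- colSums(m) >= minSize
  LabelMatrix(m[, keep, drop = FALSE], incompleteFlags(labels)[keep])
}

#' Propagate per-term predictions up the ontology
#'
#' After propagation a protein is positive for slim term T iff it is
#' predicted positive for T or for any slim term below T: categories then
#' include all their descendants and the incomplete (asterisk) marking no
#' longer applies. The operation is idempotent and enforces true-path
#' consistency (positives(parent) is a superset of positives(child)).
#'
#' @param pred a [LabelMatrix-class] whose columns are slim terms of `dag`.
#' @param dag a [GoDag-class]
#' @return a [LabelMatrix-class] with all incomplete flags cleared.
#' @export
propagatePredictions <- function(pred, dag) {
  m <- labelValues(pred)
  terms <- colnames(m)
  if (is.null(terms)) terms <- character()
  stopifnot(all(terms %in% dag@slim))
  out <- m
  for (t in terms) {
    below <- intersect(goDescendants(t, dag), terms)
    if (length(below))
      out[, t] <- pmax(m[, t], apply(m[, below, drop = FALSE], 1, max))
  }
  LabelMatrix(out, rep(FALSE, ncol(out)))
}

#' Bundled plant GO-slim category list
#'
#' The 75 plant GO-slim categories used in the study (14 molecular function,
#' 20 cellular component, 41 biological process), with the acronyms used in
#' reports and the positive-set sizes at the 30% identity cutoff.
#'
#' @return data.frame with columns `class`, `acronym`, `ontology`, `size`,
#'   `incomplete` (the asterisk flag).
#' @export
plantSlimClasses <- function() {
  path <- system.file("extdata", "plant_slim_classes.tsv",
                      package = "GOSlimPred", mustWork = TRUE)
  df <- read.table(path, sep = "\t", header = TRUE, quote = "",
                   stringsAsFactors = FALSE)
  df$incomplete <- as.logical(df$incomplete)
  df
}
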