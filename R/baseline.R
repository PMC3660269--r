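#' Best local-alignment hit in a database
#'
#' Smith-Waterman local alignment (BLOSUM62, gap opening 11 / extension 1)
#' of the query against every database sequence; the highest raw score wins,
#' ties broken by database id (lexicographic). Hits scoring below
#' `threshold` are reported as absent — the query then transfers no labels.
#'
#' @param query an amino-acid sequence string.
#' @param db a [ProteinSet-class] to search.
#' @param threshold minimum raw alignment score (default 50).
#' @return list `hit` (db id or NA), `score`; `hit` is NA when nothing
#'   reaches the threshold.
#' @export
bestHit <- function(query, db, threshold = 50) {
  if (length(db) == 0) stopf("empty database")
  subj <- sequences(db)
  scores <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(canonicalizeForAlignment(subj)),
    canonicalizeForAlignment(query),
    substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1,
    type = "local", scoreOnly = TRUE)
  ord <- order(-scores, names(subj))
  best <- ord[1]
  if (scores[best] < threshold)
    return(list(hit = NA_character_, score = scores[best]))
  list(hit = names(subj)[best], score = scores[best])
}

#' Alignment-transfer baseline under the shared CV protocol
#'
#' Nearest-neighbour annotation transfer in the style of BLASTP-based
#' function assignment, evaluated with the *same* fold assignment as the
#' SVM pipeline (pass the identical seed): per fold, each held-out protein
#' receives the complete slim-label row of its best-scoring training hit;
#' with no hit above threshold it is predicted all-negative. Per-term
#' sensitivity/specificity/G-mean are computed per fold.
#'
#' @param x a [ProteinSet-class]
#' @param labels a [LabelMatrix-class] on the same proteins.
#' @param nFolds folds (default 5).
#' @param seed fold seed — must match the classifier run for a paired
#'   comparison.
#' @param stratifyTerm term whose labels stratify the folds (default:
#'   first column), again to mirror the classifier protocol.
#' @param threshold minimum alignment score for a transfer.
#' @param folds explicit fold assignment overriding the seeded
#'   stratification (use the `folds` element returned by [evaluateTerm]
#'   for a byte-identical paired comparison).
#' @return list `results` (long data.frame term/fold metrics), `folds`,
#'   `hits` (data.frame query, hit, score).
#' @export
transferEvaluate <- function(x, labels, nFolds = 5, seed = 1,
                             stratifyTerm = NULL, threshold = 50,
                             folds = NULL) {
  m <- labelValues(labels)
  ids <- proteinIds(x)
  stopifnot(all(rownames(m) == ids))
  if (is.null(stratifyTerm)) stratifyTerm <- colnames(m)[1]
  if (is.null(folds))
    folds <- stratifiedFolds(m[, stratifyTerm], nFolds, seed)
  nFolds <- max(folds)
  predM <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  hits <- NULL
  for (f in seq_len(nFolds)) {
    tr <- which(folds != f); te <- which(folds == f)
    db <- x[tr]
    for (i in te) {
      h <- bestHit(sequences(x)[i], db, threshold)
      if (!is.na(h$hit)) predM[i, ] <- m[h$hit, ]
      hits <- rbind(hits, data.frame(query = ids[i], hit = h$hit,
                                     score = h$score, fold = f))
    }
  }
  res <- NULL
  for (tm in colnames(m))
    for (f in seq_len(nFolds)) {
      te <- folds == f
      res <- rbind(res, cbind(term = tm,
                              foldMetrics(m[te, tm], predM[te, tm], f)))
    }
  list(results = res, folds = folds, hits = hits, predictions = predM)
}
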