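#' Run the full predictability pipeline
#'
#' Chains the stages end to end: read inputs (FASTA + secondary-structure
#' TSV + annotations + OBO/slim, e.g. as written by [simulateScenario]),
#' redundancy-filter at the identity cutoff, build and size-filter the
#' label matrix, featurize, cluster features, evaluate every kept term
#' (per-cluster grid and/or full set with FCBF), run the alignment-transfer
#' baseline on the same folds, and propagate predictions. Writes a
#' long-format results CSV and a run manifest (config snapshot, seeds,
#' input digests, package version, stage outputs) from which a rerun
#' reproduces all outputs.
#'
#' @param inputs list with paths `fasta`, `ss` (optional), `annotations`,
#'   `obo`, `slim` — the `paths` element of [simulateScenario] works as is.
#' @param outDir output directory.
#' @param cutoff identity cutoff (default 0.3, the headline setting; the
#'   published sweep is 0.3-0.8).
#' @param minSize minimum positives per kept category (default 30).
#' @param kClusters feature clusters (default 15).
#' @param grid run the per-cluster grid (slower) in addition to the
#'   full-set evaluation.
#' @param settings an [evalSettings] list.
#' @param seed master seed recorded in the manifest and used for folds.
#' @return invisibly, list with `results`, `summary`, `propagated`,
#'   `manifest`.
#' @export
runPipeline <- function(inputs, outDir, cutoff = 0.3, minSize = 30,
                        kClusters = 15, grid = FALSE,
                        settings = evalSettings(), seed = 1) {
  for (p in inputs[c("fasta", "annotations", "obo")])
    if (!file.exists(p)) stopf("missing input file: %s", p)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  settings$seed <- seed
  prot <- readFasta(inputs$fasta)
  if (!is.null(inputs$ss) && file.exists(inputs$ss)) {
    ssTab <- read.table(inputs$ss, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)
    ss <- setNames(ssTab$ss, ssTab$protein)[proteinIds(prot)]
    prot <- ProteinSet(sequences(prot), ss)
  }
  ann <- readAnnotations(inputs$annotations)
  dag <- readObo(inputs$obo, slim = if (!is.null(inputs$slim)) inputs$slim
                                    else character())
  filt <- filterByIdentity(prot, cutoff)
  prot <- filt$representatives
  labels <- buildLabelMatrix(ann, dag, proteins = proteinIds(prot))
  labels <- filterMinSize(labels, minSize)
  if (ncol(labelValues(labels)) == 0)
    stopf("no category reaches %d positives at cutoff %g", minSize, cutoff)
  X <- featurize(prot)
  clustering <- NULL
  if (grid) {
    keep <- apply(X, 2, sd) > 0
    clustering <- wardClusterFeatures(absCorDist(X[, keep, drop = FALSE]),
                                      k = min(kClusters, sum(keep)))
  }
  gr <- runGrid(X, labels, clustering, settings = settings)
  base <- transferEvaluate(prot, labels, nFolds = settings$nFolds,
                           seed = seed)
  predLM <- LabelMatrix((gr$predictions > 0) * 1L)
  propagated <- evaluatePropagated(predLM, labels, dag)
  resultsCsv <- file.path(outDir, "results.csv")
  baseRes <- base$results
  baseRes <- cbind(term = baseRes$term, group = "full",
                   baseRes[setdiff(names(baseRes), "term")])
  all <- rbind(cbind(method = "svm", gr$results),
               cbind(method = "blast_transfer", baseRes))
  write.table(all, resultsCsv, sep = ",", quote = FALSE, row.names = FALSE)
  manifest <- list(
    package = as.character(utils::packageVersion("GOSlimPred")),
    seed = seed, cutoff = cutoff, minSize = minSize,
    kClusters = if (grid) kClusters else NA,
    inputs = lapply(inputs, function(p)
      if (!is.null(p) && file.exists(p))
        unname(tools::md5sum(p)) else NA_character_),
    nProteins = length(prot),
    terms = colnames(labelValues(labels)),
    outputs = list(results = resultsCsv))
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  write.table(propagated, file.path(outDir, "propagated.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  invisible(list(results = all, summary = gr$summary,
                 propagated = propagated, manifest = manifest))
}
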