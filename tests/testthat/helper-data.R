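# Shared synthetic fixtures, generated once per test run under the seeds
# fixed in the scenario files.

.fixtures <- new.env(parent = emptyenv())

fixtureBundle <- function(name) {
  key <- paste0("bundle_", name)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generateSequences(referenceScenarios()[[name]])
  .fixtures[[key]]
}

fixtureFeatures <- function(name) {
  key <- paste0("X_", name)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- featurize(fixtureBundle(name)$proteins)
  .fixtures[[key]]
}

fixtureLabels <- function(name, minSize = 30) {
  b <- fixtureBundle(name)
  filterMinSize(buildLabelMatrix(b$annotations, b$dag,
                                 proteins = proteinIds(b$proteins)),
                minSize)
}
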