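#' Synthetic-data generator configuration
#'
#' Describes a synthetic study: an ontology shape, class-conditional
#' residue-composition signals planted on slim categories, optional
#' sequence families (founder plus mutated copies), a log-normal sequence
#' length distribution, and a Markov chain over \{H, E, C\} for secondary
#' structure. The generator emulates the statistical structure the analysis
#' assumes — multi-label DAG-consistent annotations, compositional signal,
#' family redundancy, class imbalance — not real protein evolution.
#'
#' @param name scenario name.
#' @param seed default RNG seed for the scenario.
#' @param depth,branching,slimFraction ontology shape: a rooted
#'   `branching`-ary tree of `depth` levels per namespace; `slimFraction`
#'   of the non-root terms are marked slim (the root never is).
#' @param namespace GO namespace label for the generated tree.
#' @param classes list of class specs, each a list with `n` (positives),
#'   optional `signal` (list `residues`, `fold`: the named residues'
#'   abundance multiplied by `fold`, then renormalized), optional
#'   `families` (list `copies`, `mutRate`: founders are copied with i.i.d.
#'   substitution at `mutRate`, substitutions drawn from the class
#'   distribution). Classes are assigned to distinct slim terms.
#' @param background number of background proteins (no class, annotated at
#'   the root, negatives everywhere).
#' @param lengthMeanLog,lengthSdLog log-normal sequence length parameters
#'   (defaults give a median length of ~300 residues).
#' @param ssSelf self-transition probability of the secondary-structure
#'   Markov chain (remaining mass split evenly).
#' @return a `GeneratorConfig` list.
#' @export
generatorConfig <- function(name = "custom", seed = 1, depth = 3,
                            branching = 2, slimFraction = 0.5,
                            namespace = "biological_process",
                            classes = list(), background = 0,
                            lengthMeanLog = log(300), lengthSdLog = 0.25,
                            ssSelf = 0.8) {
  for (cl in classes) {
    stopifnot(cl$n >= 1)
    if (!is.null(cl$families)) {
      stopifnot(cl$families$copies >= 1,
                cl$families$mutRate >= 0, cl$families$mutRate < 1)
      if (cl$families$copies > cl$n)
        stopf("family copies (%d) exceed class size (%d)",
              cl$families$copies, cl$n)
    }
  }
  structure(list(name = name, seed = seed, depth = depth,
                 branching = branching, slimFraction = slimFraction,
                 namespace = namespace, classes = classes,
                 background = background, lengthMeanLog = lengthMeanLog,
                 lengthSdLog = lengthSdLog, ssSelf = ssSelf),
            class = "GeneratorConfig")
}

#' Generate a synthetic GO DAG
#'
#' Rooted `branching`-ary tree of `depth` levels (acyclic by construction)
#' with GO-shaped term ids; a fraction of the non-root terms is marked slim.
#'
#' @param config a [generatorConfig] list.
#' @param seed RNG seed override (default: the scenario seed).
#' @return a [GoDag-class]
#' @export
generateDag <- function(config, seed = config$seed) {
  stopifnot(config$depth >= 2)
  b <- config$branching
  n <- sum(b^(0:(config$depth - 1)))
  ids <- sprintf("GO:%07d", 1000000 + seq_len(n))
  parents <- vector("list", n)
  parents[[1]] <- character()
  for (i in 2:n) parents[[i]] <- ids[(i + b - 2) %/% b]  # b-ary heap parent
  nonroot <- ids[-1]
  nSlim <- round(config$slimFraction * length(nonroot))
  slim <- withLocalSeed(seed, sort(sample(nonroot, nSlim)))
  GoDag(ids, parents, namespace = config$namespace,
        name = paste0("term ", seq_len(n)), slim = slim)
}

## Class-conditional residue distribution: background priors with the
## signal residues' mass multiplied by `fold`, renormalized.
classDistribution <- function(signal, tables) {
  p <- tables$abundance
  if (!is.null(signal)) {
    p[signal$residues] <- p[signal$residues] * signal$fold
    p <- p / sum(p)
  }
  p
}

sampleSeq <- function(len, p) paste(sample(AA20, len, TRUE, p), collapse = "")

mutateSeq <- function(seq, rate, p) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- runif(length(chars)) < rate
  if (any(hit)) chars[hit] <- sample(AA20, sum(hit), TRUE, p)
  paste(chars, collapse = "")
}

sampleSs <- function(len, self) {
  P <- matrix((1 - self) / 2, 3, 3, dimnames = list(SS3, SS3))
  diag(P) <- self
  s <- character(len)
  s[1] <- sample(SS3, 1)
  if (len > 1)
    for (i in 2:len) s[i] <- sample(SS3, 1, prob = P[s[i - 1], ])
  paste(s, collapse = "")
}

#' Generate a synthetic protein bundle
#'
#' Draws the ontology, then one protein set: class members are sampled from
#' their class's residue distribution (families: a founder is sampled and
#' copied with substitutions at the configured rate), background proteins
#' from the plain abundance priors. Classes are attached to distinct slim
#' terms (those with the largest contributing sets first) and each member
#' is annotated to a term drawn from the slim term's contributing set, so
#' positives arise both directly and via descendants. Background proteins
#' are annotated at the root. Secondary-structure strings come from the
#' H/E/C Markov chain. Fully reproducible under the seed.
#'
#' @param config a [generatorConfig] list.
#' @param seed RNG seed override (default: the scenario seed).
#' @return a `SyntheticBundle` list: `proteins` ([ProteinSet-class]),
#'   `annotations` (data.frame), `dag` ([GoDag-class]), `classTerm` (class
#'   index -> slim term), `truth` (named class index per protein, 0 =
#'   background), `ledger` (data.frame naming each planted signal; empty
#'   when nothing is planted), `config`.
#' @export
generateSequences <- function(config, seed = config$seed) {
  tables <- residueTables()
  dag <- generateDag(config, seed = childSeed(seed, 1))
  slim <- slimTerms(dag)
  if (length(config$classes) > length(slim))
    stopf("%d classes but only %d slim terms", length(config$classes),
          length(slim))
  contribSize <- vapply(slim, function(s)
    length(contributingTerms(s, dag)), 0L)
  slimOrd <- slim[order(-contribSize, slim)]
  classTerm <- slimOrd[seq_along(config$classes)]
  seqs <- character(); ss <- character(); truth <- integer()
  ann <- NULL; ledger <- NULL
  withLocalSeed(childSeed(seed, 2), {
    pid <- 0
    emit <- function(seq, cls, term) {
      pid <<- pid + 1
      id <- sprintf("SP%05d", pid)
      seqs[id] <<- seq
      ss[id] <<- sampleSs(nchar(seq), config$ssSelf)
      truth[id] <<- cls
      ann <<- rbind(ann, data.frame(protein = id, term = term,
                                    evidence = "EXP"))
    }
    rlen <- function() max(30L, round(stats::rlnorm(1, config$lengthMeanLog,
                                                    config$lengthSdLog)))
    for (k in seq_along(config$classes)) {
      cl <- config$classes[[k]]
      p <- classDistribution(cl$signal, tables)
      contrib <- contributingTerms(classTerm[k], dag)
      drawTerm <- function() sample(contrib, 1)
      if (is.null(cl$families)) {
        for (j in seq_len(cl$n)) emit(sampleSeq(rlen(), p), k, drawTerm())
      } else {
        copies <- cl$families$copies
        nFam <- ceiling(cl$n / copies)
        made <- 0
        for (fam in seq_len(nFam)) {
          founder <- sampleSeq(rlen(), p)
          for (j in seq_len(min(copies, cl$n - made))) {
            emit(mutateSeq(founder, cl$families$mutRate, p), k, drawTerm())
            made <- made + 1
          }
        }
      }
      if (!is.null(cl$signal))
        ledger <- rbind(ledger, data.frame(
          class = k, term = classTerm[k],
          residues = paste(cl$signal$residues, collapse = ","),
          fold = cl$signal$fold))
    }
    root <- dagTerms(dag)[1]
    p0 <- tables$abundance
    for (j in seq_len(config$background)) emit(sampleSeq(rlen(), p0), 0L, root)
  })
  if (is.null(ledger))
    ledger <- data.frame(class = integer(), term = character(),
                         residues = character(), fold = numeric())
  list(proteins = ProteinSet(seqs, ss), annotations = ann, dag = dag,
       classTerm = classTerm, truth = truth, ledger = ledger,
       config = config)
}

#' Bundled reference scenarios
#'
#' Reads the scenario YAML files shipped with the package and returns their
#' [generatorConfig]s:
#' \describe{
#'   \item{planted-easy}{strong K/R compositional signal, balanced (250
#'     positives / 250 background).}
#'   \item{imbalanced-30}{a minority class of exactly 30 positives against
#'     470 background — the size floor of the class filter.}
#'   \item{null}{balanced classes with no planted signal (empty ledger);
#'     the calibration scenario.}
#'   \item{family-bias}{two moderately signalled classes built from
#'     5-copy sequence families, for demonstrating the identity-filter
#'     effect on alignment transfer.}
#' }
#'
#' @return named list of `GeneratorConfig`s.
#' @export
referenceScenarios <- function() {
  dir <- system.file("scenarios", package = "GOSlimPred", mustWork = TRUE)
  files <- list.files(dir, pattern = "\\.yaml$", full.names = TRUE)
  out <- list()
  for (f in files) {
    cfg <- readScenarioYaml(f)
    out[[cfg$name]] <- cfg
  }
  out
}

#' Read / write a scenario YAML file
#' @param path YAML file.
#' @return a [generatorConfig] list.
#' @export
readScenarioYaml <- function(path) {
  y <- yaml::read_yaml(path)
  classes <- lapply(y$classes, function(cl) {
    list(n = cl$n,
         signal = if (!is.null(cl$signal))
           list(residues = as.character(cl$signal$residues),
                fold = cl$signal$fold),
         families = cl$families)
  })
  generatorConfig(name = y$name, seed = y$seed, depth = y$dag$depth,
                  branching = y$dag$branching,
                  slimFraction = y$dag$slimFraction,
                  namespace = y$dag$namespace,
                  classes = classes, background = y$background,
                  lengthMeanLog = y$length$meanLog,
                  lengthSdLog = y$length$sdLog,
                  ssSelf = y$ss$self)
}

#' Write a synthetic bundle to disk in the pipeline's input formats
#'
#' Emits FASTA (sequences), a secondary-structure TSV, the GAF-like
#' annotation TSV, the OBO ontology, the slim-term list, the ground-truth
#' table and the planted-signal ledger, plus a config snapshot.
#'
#' @param scenario a scenario name from [referenceScenarios] or a
#'   [generatorConfig].
#' @param dir output directory (created).
#' @param seed optional seed overriding the scenario default.
#' @return invisibly, a list with the `bundle` and the output `paths`.
#' @export
simulateScenario <- function(scenario, dir, seed = NULL) {
  cfg <- if (is.character(scenario)) {
    sc <- referenceScenarios()
    if (!(scenario %in% names(sc)))
      stopf("unknown scenario '%s'; available: %s", scenario,
            paste(names(sc), collapse = ", "))
    sc[[scenario]]
  } else scenario
  if (!is.null(seed)) cfg$seed <- seed
  bundle <- generateSequences(cfg)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    fasta = file.path(dir, "proteins.fasta"),
    ss = file.path(dir, "secondary_structure.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    obo = file.path(dir, "ontology.obo"),
    slim = file.path(dir, "slim_terms.txt"),
    truth = file.path(dir, "truth.tsv"),
    ledger = file.path(dir, "signal_ledger.tsv"),
    config = file.path(dir, "scenario.yaml"))
  writeFasta(bundle$proteins, paths$fasta)
  write.table(data.frame(protein = proteinIds(bundle$proteins),
                         ss = ssStrings(bundle$proteins)),
              paths$ss, sep = "\t", quote = FALSE, row.names = FALSE)
  writeAnnotations(bundle$annotations, paths$annotations)
  writeObo(bundle$dag, paths$obo)
  writeLines(slimTerms(bundle$dag), paths$slim)
  write.table(data.frame(protein = names(bundle$truth),
                         class = bundle$truth), paths$truth,
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(bundle$ledger, paths$ledger, sep = "\t", quote = FALSE,
              row.names = FALSE)
  yaml::write_yaml(configToYaml(cfg), paths$config)
  invisible(list(bundle = bundle, paths = paths))
}

configToYaml <- function(cfg) {
  list(name = cfg$name, seed = cfg$seed,
       dag = list(depth = cfg$depth, branching = cfg$branching,
                  slimFraction = cfg$slimFraction,
                  namespace = cfg$namespace),
       length = list(meanLog = cfg$lengthMeanLog, sdLog = cfg$lengthSdLog),
       ss = list(self = cfg$ssSelf),
       background = cfg$background,
       classes = cfg$classes)
}
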