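#' Read protein sequences from a FASTA file
#'
#' Headers are truncated at the first whitespace to form the protein id;
#' sequences are uppercased and validated against the 20 canonical residues
#' plus B/Z/X/J/U/O. Illegal characters raise an error naming the offending
#' position.
#'
#' @param path FASTA file.
#' @return a [ProteinSet-class] (without secondary structure).
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  # BStringSet keeps every byte, so illegal residues survive to be
  # reported with their position (readAAStringSet silently drops them)
  aas <- Biostrings::readBStringSet(path)
  if (length(aas) == 0) return(ProteinSet(character()))
  ids <- sub("\\s.*$", "", names(aas))
  if (any(ids == "")) stopf("malformed FASTA header (empty id) in %s", path)
  seqs <- setNames(toupper(as.character(aas)), ids)
  ProteinSet(seqs)
}

#' Write a ProteinSet to FASTA
#' @param x a [ProteinSet-class]
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path) {
  aas <- Biostrings::AAStringSet(sequences(x))
  Biostrings::writeXStringSet(aas, path)
  invisible(path)
}

#' Read a protein-to-GO annotation table
#'
#' Tab-separated file with columns `protein_id`, `go_id`, `evidence` (no
#' header). Rows whose evidence code is excluded are dropped; by default
#' electronically inferred annotations (IEA) are excluded, so only
#' curated/experimental annotations enter the analysis. Unparseable rows and
#' syntactically invalid GO ids are skipped with a counted warning;
#' duplicated (protein, term) pairs are collapsed.
#'
#' @param path TSV file.
#' @param excludedEvidence character vector of evidence codes to drop
#'   (default `"IEA"`); `character()` keeps everything.
#' @return data.frame with columns `protein`, `term`, `evidence`.
#' @export
readAnnotations <- function(path, excludedEvidence = "IEA") {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (length(lines) == 0)
    return(data.frame(protein = character(), term = character(),
                      evidence = character(), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(parts, length, 1L) >= 3
  badTerm <- ok & !grepl("^GO:[0-9]{7}$",
                         vapply(parts, function(p) if (length(p) >= 2) p[2] else "", ""))
  skipped <- sum(!ok) + sum(badTerm)
  if (skipped > 0)
    warnf("skipped %d unparseable annotation row(s)", skipped)
  keep <- ok & !badTerm
  df <- data.frame(
    protein = vapply(parts[keep], `[`, "", 1L),
    term = vapply(parts[keep], `[`, "", 2L),
    evidence = vapply(parts[keep], `[`, "", 3L),
    stringsAsFactors = FALSE)
  df <- df[!(df$evidence %in% excludedEvidence), , drop = FALSE]
  df <- df[!duplicated(df[c("protein", "term")]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write an annotation table to TSV
#' @param ann data.frame with `protein`, `term`, `evidence` columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAnnotations <- function(ann, path) {
  write.table(ann[c("protein", "term", "evidence")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a GO ontology subset from an OBO file
#'
#' Parses `[Term]` stanzas with `id`, `name`, `namespace` and `is_a` tags.
#' Obsolete terms are dropped (and edges pointing at them, from them). Only
#' `is_a` edges are used; `relationship:` tags are ignored. Cycles and
#' dangling `is_a` targets are hard errors.
#'
#' @param path OBO file.
#' @param slim optional character vector of term ids to mark as the slim
#'   subset, or a file with one GO id per line.
#' @return a [GoDag-class]
#' @export
readObo <- function(path, slim = character()) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  starts <- which(lines == "[Term]")
  if (length(starts) == 0) stopf("no [Term] stanzas in %s", path)
  bounds <- c(starts, length(lines) + 1L)
  ids <- character(); nms <- character(); nss <- character()
  parents <- list(); obsolete <- character()
  for (i in seq_along(starts)) {
    blk <- lines[bounds[i]:(bounds[i + 1] - 1L)]
    getTag <- function(tag) {
      v <- blk[startsWith(blk, paste0(tag, ": "))]
      sub(paste0("^", tag, ": "), "", v)
    }
    id <- getTag("id")
    if (length(id) != 1) stopf("stanza %d lacks a unique id", i)
    if (any(grepl("^is_obsolete: true", blk))) {
      obsolete <- c(obsolete, id)
      next
    }
    isa <- getTag("is_a")
    isa <- sub("\\s*!.*$", "", isa)           # strip trailing "! name" comment
    isa <- isa[nzchar(isa)]
    nm <- getTag("name"); ns <- getTag("namespace")
    ids <- c(ids, id)
    nms <- c(nms, if (length(nm)) nm[1] else id)
    nss <- c(nss, if (length(ns)) ns[1] else NA_character_)
    parents[[id]] <- isa
  }
  parents <- lapply(parents, function(p) setdiff(p, obsolete))
  dangling <- setdiff(unlist(parents), ids)
  if (length(dangling))
    stopf("dangling is_a target '%s'", dangling[1])
  if (length(slim) == 1 && file.exists(slim))
    slim <- readLines(slim)
  slim <- intersect(slim, ids)
  dag <- GoDag(ids, parents[ids], namespace = nss, name = nms, slim = slim)
  validObject(dag)  # raises on cycles
  dag
}

#' Write a GoDag to a minimal OBO file
#' @param dag a [GoDag-class]
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeObo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (t in dag@terms) {
    pp <- dag@parents[[t]]
    writeLines(c("", "[Term]", paste0("id: ", t),
                 paste0("name: ", dag@termName[[t]]),
                 paste0("namespace: ", dag@namespace[[t]]),
                 if (length(pp)) paste0("is_a: ", pp)), con)
  }
  invisible(path)
}

#' CSV dialects
#'
#' The feature/label matrices are exchanged as character-separated files in
#' one of two dialects: `"standard"` (separator `,`, decimal `.`) or
#' `"paper"` (separator `;`, decimal `,` — the Western-European Excel CSV
#' convention used by the published supplementary matrices).
#'
#' @param separator column separator character.
#' @param decimal decimal mark character.
#' @return a `CsvDialect` list.
#' @export
csvDialect <- function(separator = ",", decimal = ".") {
  if (separator == decimal)
    stopf("separator and decimal mark must differ")
  structure(list(separator = separator, decimal = decimal),
            class = "CsvDialect")
}

#' @rdname csvDialect
#' @param name `"standard"` or `"paper"`.
#' @export
namedDialect <- function(name = c("standard", "paper")) {
  switch(match.arg(name),
         standard = csvDialect(",", "."),
         paper = csvDialect(";", ","))
}

formatNum <- function(x, dialect, digits = 6) {
  s <- vapply(x, function(v) sprintf("%.*g", digits, v), "")
  if (dialect$decimal != ".") s <- sub(".", dialect$decimal, s, fixed = TRUE)
  s
}

#' Write a feature matrix as CSV
#'
#' Layout: first column holds protein ids, first row feature names, the
#' top-left cell is empty. Numbers are rendered with the dialect's decimal
#' mark at `digits` significant digits. A separator character occurring in a
#' row/column name is an error (quoting is deliberately not emitted so the
#' file round-trips bytewise with [readFeatureCsv]).
#'
#' @param mat numeric matrix with rownames (ids) and colnames (features).
#' @param path output file.
#' @param dialect a [csvDialect] (default standard).
#' @param digits significant digits (default 6).
#' @return `path`, invisibly.
#' @export
writeFeatureCsv <- function(mat, path, dialect = namedDialect("standard"),
                            digits = 6) {
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stopf("feature matrix must have row ids and feature names")
  nmAll <- c(rownames(mat), colnames(mat))
  if (any(grepl(dialect$separator, nmAll, fixed = TRUE)))
    stopf("separator '%s' occurs in a name", dialect$separator)
  header <- paste(c("", colnames(mat)), collapse = dialect$separator)
  body <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], formatNum(mat[i, ], dialect, digits)),
          collapse = dialect$separator)
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a feature matrix written by [writeFeatureCsv]
#' @param path CSV file.
#' @param dialect the dialect it was written with.
#' @return numeric matrix with ids as rownames.
#' @export
readFeatureCsv <- function(path, dialect = namedDialect("standard")) {
  lines <- readLines(path)
  cells <- strsplit(lines, dialect$separator, fixed = TRUE)
  feats <- cells[[1]][-1]
  ids <- vapply(cells[-1], `[`, "", 1L)
  num <- function(s) {
    if (dialect$decimal != ".") s <- sub(dialect$decimal, ".", s, fixed = TRUE)
    as.numeric(s)
  }
  mat <- t(vapply(cells[-1], function(r) num(r[-1]), numeric(length(feats))))
  if (length(feats) == 1) mat <- matrix(mat, ncol = 1)
  dimnames(mat) <- list(ids, feats)
  mat
}

#' Write / read a label matrix as CSV
#'
#' Same layout as the feature CSV ((n_proteins + 1) x (n_terms + 1) cells,
#' empty top-left) but cells are strictly 0/1.
#'
#' @param labels a [LabelMatrix-class]
#' @param path file.
#' @param dialect a [csvDialect].
#' @return `path` / a [LabelMatrix-class].
#' @export
writeLabelCsv <- function(labels, path, dialect = namedDialect("standard")) {
  m <- labelValues(labels)
  header <- paste(c("", colnames(m)), collapse = dialect$separator)
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], m[i, ]), collapse = dialect$separator)
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname writeLabelCsv
#' @export
readLabelCsv <- function(path, dialect = namedDialect("standard")) {
  lines <- readLines(path)
  cells <- strsplit(lines, dialect$separator, fixed = TRUE)
  terms <- cells[[1]][-1]
  ids <- vapply(cells[-1], `[`, "", 1L)
  m <- t(vapply(cells[-1], function(r) as.integer(r[-1]),
                integer(length(terms))))
  if (length(terms) == 1) m <- matrix(m, ncol = 1)
  if (!all(m %in% c(0L, 1L))) stopf("label CSV must contain only 0/1")
  dimnames(m) <- list(ids, terms)
  LabelMatrix(m)
}
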