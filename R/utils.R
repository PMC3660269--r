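#' @importFrom methods new validObject is slot
#' @importFrom stats cor sd cutree hclust runif setNames
#' @importFrom utils head read.table write.table
NULL

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Twenty canonical residues in the fixed column order used throughout.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

## IUPAC ambiguity codes accepted on input, plus U/O mapped to their
## nearest canonical residues (selenocysteine -> C, pyrrolysine -> K).
AA_AMBIG <- list(
  B = c("D", "N"),
  Z = c("E", "Q"),
  J = c("I", "L"),
  X = AA20,
  U = "C",
  O = "K"
)

AA_ALPHABET_FULL <- c(AA20, names(AA_AMBIG))

SS3 <- c("H", "E", "C")

## Run `expr` under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is untouched. seed = NULL runs on the current stream.
withLocalSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Derive a stream-specific child seed from a base seed (kept < 2^31).
childSeed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 48271 + 7919 * k) %% 2147483629
}

validateSequence <- function(seq, id = "?", alphabet = AA_ALPHABET_FULL) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% alphabet))
  if (length(bad) > 0)
    stopf("illegal character '%s' at position %d in sequence '%s'",
          chars[bad[1]], bad[1], id)
  invisible(TRUE)
}

gmean <- function(sens, spec) sqrt(sens * spec)
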