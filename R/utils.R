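# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' @noRd
is_dna <- function(x) {
  nzchar(x) && !grepl("[^ACGT]", x)
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Watson-Crick complement per base; G.T wobble handled by callers.
#' @noRd
comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

# Run thunk under a fixed RNG seed, restoring the caller's RNG state.
# Keeps every simulator a pure function of its config.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Geometric mean of strictly positive values.
#' @noRd
geomean <- function(x) exp(mean(log(x)))
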