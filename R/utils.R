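`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state, so
#' seeded helpers never perturb the global random stream.
#'
#' @param seed Integer seed, or `NULL` to evaluate without touching the RNG.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!is.null(seed) && !is.na(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Byte-order (C locale) sort, so k-mer and label ordering never depends on
# the session collation.
radixSort <- function(x) sort(x, method = "radix")

radixMin <- function(x) sort(x, method = "radix")[1L]

#' Reverse complement of nucleotide strings
#'
#' @param x Character vector of ACGT strings.
#' @return Character vector of reverse complements.
#' @examples
#' reverseComplement(c("ACGT", "GT"))
#' @export
reverseComplement <- function(x) {
  if (length(x) == 0L) return(character(0))
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}

# Full-precision number formatting used wherever artifacts must be
# byte-stable across reruns.
fmtFull <- function(x) sprintf("%.17g", x)

fmtLen <- function(x) sprintf("%.12g", x)
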