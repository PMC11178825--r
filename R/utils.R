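#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbinom rpois runif sd setNames
#' @importFrom utils head write.table read.delim
NULL

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC nucleotide classes, used for PAM patterns such as NGG / NGN.
IUPAC_CLASSES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N", "-" = "-")

#' Reverse complement of a DNA string
#'
#' Thin character-vector wrapper used where a full `DNAStringSet` round trip
#' would be overkill.
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTT")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_base <- function(b) {
  out <- COMPLEMENT[b]
  if (anyNA(out)) stop("non-ACGTN base in complement_base()")
  unname(out)
}

# Evaluate `code` under a local Mersenne-Twister stream seeded with `seed`,
# restoring the caller's RNG state afterwards. Every stochastic operation in
# the package funnels through this, which is what makes (spec, seed) pairs
# reproduce byte-identical outputs.
with_rng <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

# Draw n random bases, optionally excluding (per element) the base in `not`.
random_bases <- function(n, not = NULL) {
  if (is.null(not)) return(sample(DNA_BASES, n, replace = TRUE))
  stopifnot(length(not) == n)
  idx <- sample.int(3L, n, replace = TRUE)
  vapply(seq_len(n), function(i) setdiff(DNA_BASES, not[i])[idx[i]], character(1))
}

# Expand an IUPAC pattern into one concrete random realization ("NGG" -> "TGG").
realize_iupac <- function(pattern) {
  syms <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(syms, names(IUPAC_CLASSES))
  if (length(bad) > 0) stop("non-IUPAC symbol in pattern: ", paste(bad, collapse = ","))
  paste(vapply(syms, function(s) sample(IUPAC_CLASSES[[s]], 1), character(1)),
        collapse = "")
}

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= min && x == as.integer(x)
}
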