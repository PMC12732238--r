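# shared helpers

#' Standard amino-acid alphabet
#'
#' The 20 proteinogenic residues, one-letter code, alphabetical order.
#' @return Character vector of length 20.
#' @export
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Round half away from zero
#'
#' Base [round()] uses banker's rounding; immunopeptidome summary tables are
#' conventionally printed with half-up rounding (2.575 -> 2.58), which this
#' helper implements for non-negative inputs.
#'
#' @param x Numeric vector (non-negative).
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # nudge by an ulp-scale epsilon so values like 2.575 stored as 2.5749999...
  # still round up as printed arithmetic would
  floor(x * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

#' Validate peptide sequences against the amino-acid alphabet
#'
#' @param x Character vector of candidate sequences.
#' @return Logical vector: TRUE where `x` is a non-empty string over the
#'   20-letter alphabet (after upper-casing).
#' @export
is_valid_peptide <- function(x) {
  x <- toupper(as.character(x))
  nzchar(x) & !is.na(x) & grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", x)
}

# split peptides of equal length into a character matrix (n x L)
peptide_matrix <- function(peptides) {
  L <- unique(nchar(peptides))
  stopifnot(length(L) == 1L)
  matrix(unlist(strsplit(peptides, "")), ncol = L, byrow = TRUE)
}

# run code with a local RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
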