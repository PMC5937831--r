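#' Round half-up
#'
#' Plain decimal rounding where halves go away from zero, the convention that
#' reproduces printed summary percentages (base `round()` rounds halves to
#' even).
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 2) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of IUPAC DNA strings
#' @return character vector of reverse complements
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# scoped RNG: run expr with a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# count occurrences of characters in `class` (a regex character class) per string
count_chars <- function(x, class) {
  nchar(x) - nchar(gsub(class, "", x, perl = TRUE))
}

# random DNA of given lengths
random_dna <- function(n, len) {
  vapply(rep_len(len, n), function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
}
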