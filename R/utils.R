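#' @keywords internal
#' @importFrom Rcpp sourceCpp
#' @useDynLib organellr, .registration = TRUE
"_PACKAGE"

#' @importFrom rlang .data
NULL

# Reverse complement of character vectors of DNA (ACGTN).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Uppercase and map anything outside ACGTN to N (masked references are common).
clean_dna <- function(x) {
  x <- toupper(x)
  stringr::str_replace_all(x, "[^ACGTN]", "N")
}

# Uniform random DNA string(s); relies on the session RNG.
random_dna <- function(n) {
  vapply(n, function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

flip_orient <- function(o) ifelse(o == "+", "-", "+")

`%||%` <- function(a, b) if (is.null(a)) b else a
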