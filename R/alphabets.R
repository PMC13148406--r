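#' @useDynLib markerphylo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Residue orderings follow the HMMER3 text format column order.
ALPHABETS <- list(
  amino20 = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
  dna4    = c("A", "C", "G", "T")
)

# Ambiguity/missing codes treated as unknown residues (scored at null
# frequency, counted as missing by alignment statistics).
AMBIGUOUS <- list(
  amino20 = c("X", "B", "Z", "J", "U", "O", "*"),
  dna4    = c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
)

alphabet_residues <- function(alphabet) {
  res <- ALPHABETS[[alphabet]]
  if (is.null(res)) stop("unknown alphabet: ", alphabet, call. = FALSE)
  res
}

# Encode a residue string to 0-based codes for the C++ kernels.
# Unknown/ambiguous residues are not representable there, so callers that
# tolerate them must pre-filter; `strict` governs whether to error.
encode_seq <- function(seq, alphabet, strict = TRUE) {
  chars <- strsplit(toupper(seq), "")[[1]]
  codes <- match(chars, alphabet_residues(alphabet)) - 1L
  if (anyNA(codes)) {
    bad <- unique(chars[is.na(codes)])
    if (strict) {
      stop("residue(s) not in ", alphabet, " alphabet: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    codes <- codes[!is.na(codes)]
  }
  codes
}
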