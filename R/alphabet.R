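#' @useDynLib deimmunize, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim quantile rnorm runif sd dnorm dlnorm setNames
#' @importFrom utils head read.delim write.table
NULL

#' Amino-acid alphabets
#'
#' `aa_alphabet()` returns the 20 standard amino acids in the conventional
#' one-letter ordering used throughout the package; `gapped_alphabet()`
#' prepends the gap symbol `"-"`, the 21-state alphabet used during model
#' inference from gapped alignments.
#'
#' @return Character vector of single-letter residue codes.
#' @export
aa_alphabet <- function() {
  strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
}

#' @rdname aa_alphabet
#' @export
gapped_alphabet <- function() {
  c("-", aa_alphabet())
}

# Encode a character matrix/vector of residues as 1-based integer indices
# into `alphabet`. Unknown symbols are an error unless `unknown_to` names a
# symbol to map them to (used for non-standard codes in real alignments).
encode_seq <- function(x, alphabet, unknown_to = NULL) {
  idx <- match(x, alphabet)
  if (anyNA(idx)) {
    if (is.null(unknown_to)) {
      bad <- unique(x[is.na(idx)])
      stop("symbols outside alphabet: ", paste(bad, collapse = " "))
    }
    idx[is.na(idx)] <- match(unknown_to, alphabet)
  }
  if (is.matrix(x)) dim(idx) <- dim(x)
  idx
}

# Split a sequence string into a character vector of residues.
seq_chars <- function(s) {
  strsplit(s, "")[[1]]
}

chars_to_string <- function(x) paste(x, collapse = "")

# Index of pair (i, j), i < j, in the lexicographic list of all L-choose-2
# position pairs. Used for the i < j coupling storage of Potts models.
pair_index <- function(i, j, L) {
  stopifnot(i < j, j <= L)
  (i - 1L) * L - (i * (i - 1L)) %/% 2L + (j - i)
}

all_pairs <- function(L) {
  if (L < 2) return(matrix(integer(0), ncol = 2))
  ij <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  colnames(ij) <- c("i", "j")
  ij
}
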