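#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

## Integer encoding used throughout: A=1, C=2, G=3, T=4 (factor-free, fast).
base_to_int <- function(x) {
  m <- match(x, DNA_BASES)
  if (anyNA(m)) stop("non-ACGT base encountered")
  m
}

## Encode a single sequence string as an integer vector.
seq_to_int <- function(seq) {
  base_to_int(strsplit(seq, "", fixed = TRUE)[[1]])
}

int_to_seq <- function(x) paste(DNA_BASES[x], collapse = "")

#' Reverse complement of DNA strings
#'
#' Vectorised over its input; uppercase ACGT only.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Random DNA string of length n under the current RNG state.
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

## Substitute each selected position by a uniformly chosen different base.
mutate_bases <- function(int_seq, idx) {
  if (length(idx) == 0) return(int_seq)
  shift <- sample.int(3, length(idx), replace = TRUE)
  int_seq[idx] <- ((int_seq[idx] - 1L + shift) %% 4L) + 1L
  int_seq
}

## Phred+33 encoding of integer qualities.
phred33 <- function(q) {
  intToUtf8(pmin(q, 93L) + 33L, multiple = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
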