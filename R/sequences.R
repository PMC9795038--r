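# Low-level nucleotide-sequence primitives shared by the design and
# quantification stages. Sequences are plain uppercase character strings over
# {A,C,G,T,N}; heavy lifting (complementation, the genetic code) is delegated
# to Biostrings.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Validate and canonicalize a DNA sequence
#'
#' Uppercases the input and checks it is a non-empty string over
#' `{A,C,G,T,N}`.
#'
#' @param seq Character scalar.
#' @param what Label used in error messages.
#' @return The canonical (uppercase) sequence.
#' @keywords internal
as_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    stop(what, " must be a single non-empty character string", call. = FALSE)
  }
  seq <- toupper(seq)
  bad <- setdiff(unique(strsplit(seq, "", fixed = TRUE)[[1]]), DNA_ALPHABET)
  if (length(bad)) {
    stop(what, " contains invalid characters: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  seq
}

#' Reverse complement
#'
#' Reverse-complements one or more DNA sequences. `N` maps to `N`; the
#' operation is an involution (`reverse_complement(reverse_complement(x))`
#' returns `x`).
#'
#' @param seq Character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return Character vector of the same length.
#' @examples
#' reverse_complement("GACGATCATGTACAGGACCGG")
#' @export
reverse_complement <- function(seq) {
  vapply(seq, function(s) {
    s <- as_dna(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1L), USE.NAMES = FALSE)
}

#' Hamming distance between two equal-length sequences
#'
#' @param a,b Character scalars of equal length.
#' @return Integer count of mismatching positions.
#' @examples
#' hamming("GACGATCATGTACAGGACCGG", "CACTATCATATATAGTACTGG") # 6
#' @export
hamming <- function(a, b) {
  a <- as_dna(a, "a")
  b <- as_dna(b, "b")
  if (nchar(a) != nchar(b)) {
    stop("hamming() requires equal-length sequences (", nchar(a), " vs ",
         nchar(b), ")", call. = FALSE)
  }
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

#' Positions at which two equal-length sequences differ
#'
#' @param a,b Character scalars of equal length.
#' @return Integer vector of 1-based mismatch positions.
#' @export
diff_positions <- function(a, b) {
  a <- as_dna(a, "a")
  b <- as_dna(b, "b")
  if (nchar(a) != nchar(b)) stop("equal lengths required", call. = FALSE)
  which(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

#' Translate a sequence in a given frame
#'
#' Translates complete codons only, starting at `frame_offset` bases into the
#' sequence (standard genetic code). Trailing bases that do not fill a codon
#' are ignored. Stop codons render as `"*"`; codons containing an ambiguous
#' base render as `"X"`.
#'
#' @param seq DNA sequence.
#' @param frame_offset Integer in `{0,1,2}`.
#' @return Amino-acid string.
#' @examples
#' translate_frame("ATGAAA")                      # "MK"
#' translate_frame("CCGGTCCTGTACATGATCGTC")       # "PVLYMIV"
#' @export
translate_frame <- function(seq, frame_offset = 0L) {
  seq <- as_dna(seq)
  stopifnot(frame_offset %in% 0:2)
  n <- nchar(seq) - frame_offset
  if (n < 3L) {
    stop("sequence too short to translate in frame ", frame_offset,
         call. = FALSE)
  }
  n_codon <- n %/% 3L
  sub <- substr(seq, frame_offset + 1L, frame_offset + 3L * n_codon)
  # no.init.codon: an interior site must not get initiator-codon treatment
  as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                     no.init.codon = TRUE,
                                     if.fuzzy.codon = "X"))
}

# codon -> amino acid lookup and its inverse, from the standard code
codon_table <- function() Biostrings::GENETIC_CODE

synonymous_codons <- function(codon) {
  gc <- codon_table()
  names(gc)[gc == gc[[codon]]]
}

is_stop_codon <- function(codon) codon_table()[[codon]] == "*"
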