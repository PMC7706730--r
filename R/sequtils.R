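# Low-level sequence helpers. Sequences are plain character strings of
# A/C/G/T; random access uses raw vectors (constant-time in-place edits).

BASES <- c("A", "C", "G", "T")

#' Reverse complement
#'
#' @param x character vector of DNA sequences (A/C/G/T only).
#' @return character vector of reverse complements.
#' @keywords internal
rc <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## substitute bases at positions (1-based) in a single sequence string
str_assign <- function(s, pos, bases) {
  if (length(pos) == 0L) return(s)
  r <- charToRaw(s)
  r[pos] <- charToRaw(paste0(bases, collapse = ""))
  rawToChar(r)
}

## characters at positions (1-based) of a single string, as a vector
str_at <- function(s, pos) {
  if (length(pos) == 0L) return(character(0))
  r <- charToRaw(s)[pos]
  vapply(r, rawToChar, "")
}

## fetch [start, end] (1-based inclusive) in the given orientation
ref_fetch <- function(ref, contig, start, end, strand = "+") {
  seq <- ref$contigs[[contig]]
  stopifnot(start >= 1L, end <= nchar(seq), start <= end)
  s <- substr(seq, start, end)
  if (strand == "-") rc(s) else s
}

## a deterministic "different base"
other_base <- function(b) {
  idx <- match(b, BASES)
  BASES[(idx %% 4L) + 1L]
}

## number of mismatching characters between two equal-length strings
str_mismatches <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  sum(ra != rb)
}

## fraction of matching characters (0 if lengths differ after truncation to min)
str_identity <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0)
  1 - str_mismatches(substr(a, 1L, n), substr(b, 1L, n)) / n
}
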