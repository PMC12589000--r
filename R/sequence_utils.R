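#' @importFrom stats rnorm runif setNames sd quantile coef lm predict
#' @importFrom utils read.delim write.table head
NULL

# Normalize a nucleotide string to DNA alphabet (U -> T), uppercase,
# and verify it only contains A/C/G/T. Used by every sequence-level entry
# point so T/U inputs are interchangeable.
norm_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop(what, " must be a single character string", call. = FALSE)
  s <- chartr("u", "U", toupper(seq))
  s <- chartr("U", "T", s)
  bad <- gsub("[ACGT]", "", s)
  if (nzchar(bad))
    stop("invalid alphabet symbol '", substr(bad, 1, 1), "' in ", what,
         call. = FALSE)
  s
}

check_protein <- function(seq, what = "protein sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop(what, " must be a single character string", call. = FALSE)
  s <- toupper(seq)
  bad <- regmatches(s, regexpr(sprintf("[^%s]", paste(.aa_letters, collapse = "")), s))
  if (length(bad) && nzchar(bad)) {
    pos <- regexpr(sprintf("[^%s]", paste(.aa_letters, collapse = "")), s)
    stop("unknown residue letter '", bad, "' at position ", as.integer(pos),
         call. = FALSE)
  }
  s
}

# Split a string into single characters.
str_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

#' Scan a 5'UTR for upstream start codons and upstream ORFs
#'
#' A scanning 43S pre-initiation complex can be captured by an AUG upstream of
#' the main start codon; if that AUG is followed by an in-frame stop codon
#' still inside the UTR it opens an upstream ORF (uORF), otherwise it is a
#' bare uAUG. Both features depress the mean ribosome load of the UTR.
#'
#' @param sequence 5'UTR nucleotide string (T and U are equivalent). The main
#'   start codon is assumed to lie immediately downstream and is not part of
#'   the input.
#' @return A list with `uaug_count`, `uorf_count`, `uaug_positions` (0-based
#'   start of every ATG) and `uorf_positions` (subset whose reading frame hits
#'   an in-frame TAA/TAG/TGA before the UTR ends).
#' @export
#' @examples
#' scan_uaug_uorf("ATGTAA")  # one uAUG that is also a uORF
#' scan_uaug_uorf("ATGCCC")  # a bare uAUG
scan_uaug_uorf <- function(sequence) {
  s <- norm_dna(sequence, "5'UTR sequence")
  n <- nchar(s)
  starts <- integer(0)
  if (n >= 3L) {
    hits <- gregexpr("(?=ATG)", s, perl = TRUE)[[1L]]
    if (hits[1L] != -1L) starts <- as.integer(hits)  # 1-based
  }
  stops <- c("TAA", "TAG", "TGA")
  has_stop <- vapply(starts, function(p) {
    if (p + 3L > n - 2L) return(FALSE)
    cs <- seq.int(p + 3L, n - 2L, by = 3L)
    any(vapply(cs, function(i) substr(s, i, i + 2L) %in% stops, logical(1)))
  }, logical(1))
  list(uaug_count = length(starts),
       uorf_count = sum(has_stop),
       uaug_positions = starts - 1L,
       uorf_positions = (starts - 1L)[has_stop])
}

#' Kozak context score of a 5'UTR
#'
#' Scores the initiation context a UTR offers to the main start codon that
#' immediately follows it. The canonical strong context is a purine at
#' position -3 and a G at +4 (gccRccAUGG). Only the -3 position lies inside
#' the UTR itself (third-to-last base); the +4 base belongs to the coding
#' sequence and is assumed to match, so the default score is 1 when the -3
#' base is A or G and 0 otherwise.
#'
#' @param sequence 5'UTR nucleotide string.
#' @return 0 or 1.
#' @export
kozak_context_score <- function(sequence) {
  s <- norm_dna(sequence, "5'UTR sequence")
  n <- nchar(s)
  if (n < 3L) return(0L)
  as.integer(substr(s, n - 2L, n - 2L) %in% c("A", "G"))
}

#' GC content of a nucleotide sequence
#'
#' @param seq Nucleotide string (T/U equivalent).
#' @return Percent G+C in `[0, 100]`.
#' @export
#' @examples
#' gc_content("GGCC")  # 100
#' gc_content("AUGC")  # 50
gc_content <- function(seq) {
  s <- norm_dna(seq)
  if (nchar(s) == 0L) stop("empty sequence", call. = FALSE)
  ch <- str_chars(s)
  100 * sum(ch %in% c("G", "C")) / length(ch)
}

# Fraction-scale GC used internally by the generator.
gc_fraction <- function(s) gc_content(s) / 100
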