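#' Load a codon usage table and derive relative adaptiveness
#'
#' Reads a TSV with columns `codon` and `frequency` (occurrences per
#' thousand codons or any proportional measure; only relative values within
#' a synonymous family matter) and attaches the encoded amino acid and the
#' relative adaptiveness `w = frequency / max(frequency within family)`.
#' Stop codons are retained in the table but never contribute to CAI.
#'
#' @param path TSV file path.
#' @return Data frame `codon`, `aa`, `frequency`, `w` covering all 64
#'   codons.
#' @export
codon_usage_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("codon", "frequency") %in% names(tab)))
  tab$codon <- chartr("U", "T", toupper(tab$codon))
  gc <- Biostrings::GENETIC_CODE
  tab$aa <- unname(gc[tab$codon])
  if (anyNA(tab$aa)) stop("unknown codon in usage table", call. = FALSE)
  sense <- tab$aa != "*"
  if (sum(sense) != 61L)
    stop("usage table must cover all 61 sense codons (has ", sum(sense), ")",
         call. = FALSE)
  if (any(tab$frequency < 0)) stop("negative codon frequency", call. = FALSE)
  tab$w <- stats::ave(tab$frequency, tab$aa,
                      FUN = function(x) x / max(x))
  tab
}

#' The packaged human codon usage snapshot
#'
#' A standard human codon-usage table (frequencies per thousand codons, of
#' the kind distributed with codon-usage databases compiled from GenBank
#' coding sequences), shipped so CAI and codon optimization work offline.
#' Replaceable by any table read with [codon_usage_table()].
#'
#' @return Data frame as from [codon_usage_table()].
#' @export
default_human_usage <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- codon_usage_table(system.file("extdata",
                                              "human_codon_usage.tsv",
                                              package = "mevax",
                                              mustWork = TRUE))
    cache
  }
})

split_codons <- function(seq) {
  s <- norm_dna(seq)
  if (nchar(s) %% 3L != 0L)
    stop("sequence length not divisible by 3", call. = FALSE)
  substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
}

#' Codon adaptation index
#'
#' Geometric mean of the relative adaptiveness `w` of each sense codon with
#' respect to a reference usage table. A terminal stop codon is excluded;
#' an internal stop is an error. Single-codon families (Met, Trp) have
#' `w = 1` and thus do not move the index.
#'
#' @param seq In-frame coding nucleotide sequence (T/U equivalent).
#' @param usage Usage table from [codon_usage_table()]; default human.
#' @return CAI in (0, 1].
#' @export
cai <- function(seq, usage = default_human_usage()) {
  codons <- split_codons(seq)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  n <- length(codons)
  if (aa[n] == "*") { codons <- codons[-n]; aa <- aa[-n] }
  if (any(aa == "*"))
    stop("internal stop codon at codon ", which(aa == "*")[1L], call. = FALSE)
  w <- usage$w[match(codons, usage$codon)]
  exp(mean(log(w)))
}

#' Reverse-translate a protein with a codon strategy
#'
#' Two built-in strategies over the usage table's synonymous families:
#' \describe{
#'   \item{max_cai}{pick each family's most-used codon (`w = 1`), so the
#'     output has CAI exactly 1;}
#'   \item{gc_balance}{greedy left-to-right choice of the synonymous codon
#'     whose inclusion keeps the running GC fraction closest to 50%.}
#' }
#' Either way the output translates back to the input protein exactly.
#'
#' @param protein Amino-acid string.
#' @param usage Usage table; default human.
#' @param mode `"max_cai"` or `"gc_balance"`.
#' @return In-frame DNA ORF (no stop codon appended).
#' @export
optimize_codons <- function(protein, usage = default_human_usage(),
                            mode = c("max_cai", "gc_balance")) {
  mode <- match.arg(mode)
  p <- check_protein(protein)
  ch <- str_chars(p)
  fams <- split(usage[usage$aa != "*", ], usage$aa[usage$aa != "*"])
  if (mode == "max_cai") {
    best <- vapply(fams, function(f) f$codon[which.max(f$w)], character(1))
    return(paste(best[ch], collapse = ""))
  }
  out <- character(length(ch))
  gc_so_far <- 0; len_so_far <- 0
  for (i in seq_along(ch)) {
    f <- fams[[ch[i]]]
    gcs <- vapply(f$codon, function(cd)
      sum(str_chars(cd) %in% c("G", "C")), numeric(1))
    dev <- abs((gc_so_far + gcs) / (len_so_far + 3) - 0.5)
    pick <- which.min(dev)  # ties: first codon in table order (documented)
    out[i] <- f$codon[pick]
    gc_so_far <- gc_so_far + gcs[pick]
    len_so_far <- len_so_far + 3
  }
  paste(out, collapse = "")
}

#' Maximum base-pair count of an RNA sequence (structure proxy)
#'
#' Nussinov-style dynamic program maximizing the number of nested base
#' pairs, allowing Watson-Crick pairs (and G-U wobble by default) with a
#' minimum hairpin loop of `min_loop` unpaired bases. The pair count is a
#' fast comparative proxy for secondary-structure stability when ranking
#' candidate ORFs; it is not a thermodynamic folding energy.
#'
#' @param seq Nucleotide sequence (T/U equivalent), length <= `max_n`.
#' @param min_loop Minimum hairpin loop size (default 3).
#' @param wobble Allow G-U pairs (default TRUE).
#' @param max_n Length cap for the cubic dynamic program (default 2000);
#'   longer molecules should go to a dedicated folding tool.
#' @return Maximum number of nested pairs.
#' @export
pairing_score <- function(seq, min_loop = 3L, wobble = TRUE, max_n = 2000L) {
  s <- norm_dna(seq)
  n <- nchar(s)
  if (n > max_n)
    stop("sequence of length ", n, " exceeds the dynamic-program cap (",
         max_n, "); use a dedicated RNA folding tool for molecules this ",
         "long", call. = FALSE)
  if (n == 0L) return(0L)
  nussinov_cpp(s, as.integer(min_loop), isTRUE(wobble))
}

#' Exhaustive base-pair maximization oracle
#'
#' Enumerates every nested pairing compatible with the pairing rules and
#' returns the maximum cardinality. Exponential; intended only to verify
#' [pairing_score()] on short sequences (length <= ~14).
#'
#' @inheritParams pairing_score
#' @return Maximum number of nested pairs.
#' @export
pairing_score_brute <- function(seq, min_loop = 3L, wobble = TRUE) {
  s <- str_chars(norm_dna(seq))
  can_pair <- function(a, b) {
    wc <- (a == "A" && b == "T") || (a == "T" && b == "A") ||
      (a == "G" && b == "C") || (a == "C" && b == "G")
    gu <- wobble && ((a == "G" && b == "T") || (a == "T" && b == "G"))
    wc || gu
  }
  # enumerate over the first position: unpaired, or paired with each legal k
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (k > length(s)) break
      if (can_pair(s[i], s[k]))
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
    }
    best
  }
  if (length(s) == 0L) return(0L)
  rec(1L, length(s))
}
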