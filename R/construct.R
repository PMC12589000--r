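#' Blueprint of a multi-epitope mRNA vaccine construct
#'
#' Describes the fixed architecture of the construct from 5' to 3': m7G cap,
#' 5'UTR, a Kozak sequence carrying the start codon, a secretory signal
#' peptide, the HTL epitope block joined by GPGPG spacers (with one GPGPG
#' after the signal), the LBL block joined by KK linkers (one KK before the
#' first LBL), the CTL block joined by AAY linkers (one AAY before the first
#' CTL and one before the MITD), an MHC class I trafficking domain (MITD), a
#' stop codon, a 3'UTR and a poly(A) tail.
#'
#' The default signal peptide is the human tissue-plasminogen-activator
#' secretory leader and the default MITD is the HLA class I
#' transmembrane/cytoplasmic trafficking domain; both are literature
#' defaults supplied here because construct listings conventionally print
#' them only as "tPA" / "MITD" placeholders, and both are configurable. The
#' initiator methionine of the signal peptide is the AUG inside the Kozak
#' motif, and the Kozak's trailing G is the first base of the second codon,
#' so the second residue must admit a G-starting codon (the default
#' signal's Asp does).
#'
#' An `eaaak_linker` option inserts a rigid EAAAK spacer between the signal
#' peptide and the first GPGPG, an alternative junction sometimes used
#' between a leader and the epitope cargo (off by default).
#'
#' @param utr5,utr3 Untranslated region nucleotide strings.
#' @param kozak Kozak sequence containing ATG (default `GCCACCATGG`).
#' @param signal_peptide Amino-acid string; must start with M.
#' @param mitd Amino-acid string.
#' @param htl_linker,lbl_linker,ctl_linker Linker peptides.
#' @param eaaak_linker Insert EAAAK after the signal peptide.
#' @param stop_codon Stop codon for the mRNA (default `TAA`, i.e. UAA).
#' @param polya_length Poly(A) tail length in nucleotides (default 120).
#' @param htl_length,lbl_length,ctl_lengths Epitope lengths per class,
#'   used by the parser to segment linker-delimited blocks (defaults:
#'   HTL 15-mers, LBL 16-mers, CTL 9- or 10-mers).
#' @param cap Cap label, annotation only.
#' @return An object of class `construct_blueprint`.
#' @export
construct_blueprint <- function(utr5 = "",
                                utr3 = "",
                                kozak = "GCCACCATGG",
                                signal_peptide = "MDAMKRGLCCVLLLCGAVFVSPS",
                                mitd = paste0("IVGIVAGLAVLAVVVIGAVVATVMCRRKS",
                                              "SGGKGGSYSQAASSDSAQGSDVSLTA"),
                                htl_linker = "GPGPG",
                                lbl_linker = "KK",
                                ctl_linker = "AAY",
                                eaaak_linker = FALSE,
                                stop_codon = "TAA",
                                polya_length = 120L,
                                htl_length = 15L,
                                lbl_length = 16L,
                                ctl_lengths = c(9L, 10L),
                                cap = "m7G") {
  kozak <- norm_dna(kozak, "kozak")
  if (!grepl("ATG", kozak, fixed = TRUE))
    stop("kozak sequence must contain the ATG start codon", call. = FALSE)
  stopifnot(polya_length >= 0, nzchar(htl_linker), nzchar(lbl_linker),
            nzchar(ctl_linker))
  signal_peptide <- check_protein(signal_peptide, "signal peptide")
  if (substr(signal_peptide, 1, 1) != "M")
    stop("signal peptide must begin with the initiator methionine",
         call. = FALSE)
  mitd <- check_protein(mitd, "MITD")
  if (nzchar(utr5)) utr5 <- norm_dna(utr5, "5'UTR")
  if (nzchar(utr3)) utr3 <- norm_dna(utr3, "3'UTR")
  structure(list(cap = cap, utr5 = utr5, utr3 = utr3, kozak = kozak,
                 signal_peptide = signal_peptide, mitd = mitd,
                 htl_linker = htl_linker, lbl_linker = lbl_linker,
                 ctl_linker = ctl_linker, eaaak_linker = eaaak_linker,
                 stop_codon = norm_dna(stop_codon, "stop codon"),
                 polya_length = as.integer(polya_length),
                 htl_length = as.integer(htl_length),
                 lbl_length = as.integer(lbl_length),
                 ctl_lengths = as.integer(ctl_lengths)),
            class = "construct_blueprint")
}

check_epitopes <- function(epitopes, linkers, class) {
  for (e in epitopes) {
    check_protein(e, paste(class, "epitope"))
    for (l in linkers)
      if (grepl(l, e, fixed = TRUE))
        stop(class, " epitope '", e, "' contains linker motif '", l,
             "' — construct would be ambiguous to parse", call. = FALSE)
  }
  invisible(TRUE)
}

#' Assemble the vaccine polypeptide from epitope sets
#'
#' Concatenates signal peptide, HTL, LBL and CTL blocks and the MITD under
#' the linker schedule: `signal [EAAAK] GPGPG htl1 GPGPG htl2 ... KK lbl1 KK
#' ... AAY ctl1 AAY ... AAY MITD`. Epitopes containing a linker motif as a
#' substring are rejected outright: permitting them would make the construct
#' string ambiguous to parse back.
#'
#' @param blueprint A [construct_blueprint()].
#' @param htl,lbl,ctl Character vectors of epitope sequences (each
#'   non-empty).
#' @return A list of class `vaccine_construct` with `protein`, `elements`
#'   (data frame: name, start, end; 0-based half-open coordinates tiling the
#'   protein) and `block_counts`.
#' @export
assemble_protein <- function(blueprint, htl, lbl, ctl) {
  stopifnot(inherits(blueprint, "construct_blueprint"),
            length(htl) >= 1, length(lbl) >= 1, length(ctl) >= 1)
  bp <- blueprint
  linkers <- c(bp$htl_linker, bp$lbl_linker, bp$ctl_linker)
  check_epitopes(htl, linkers, "HTL")
  check_epitopes(lbl, linkers, "LBL")
  check_epitopes(ctl, linkers, "CTL")

  parts <- c(signal = bp$signal_peptide)
  if (bp$eaaak_linker) parts <- c(parts, eaaak = "EAAAK")
  for (i in seq_along(htl))
    parts <- c(parts, setNames(c(bp$htl_linker, htl[i]),
                               c(paste0("htl_linker_", i), paste0("HTL_", i))))
  for (i in seq_along(lbl))
    parts <- c(parts, setNames(c(bp$lbl_linker, lbl[i]),
                               c(paste0("lbl_linker_", i), paste0("LBL_", i))))
  for (i in seq_along(ctl))
    parts <- c(parts, setNames(c(bp$ctl_linker, ctl[i]),
                               c(paste0("ctl_linker_", i), paste0("CTL_", i))))
  parts <- c(parts, ctl_linker_mitd = bp$ctl_linker, mitd = bp$mitd)

  lens <- nchar(parts)
  ends <- cumsum(lens)
  elements <- data.frame(name = names(parts),
                         start = ends - lens, end = ends,
                         stringsAsFactors = FALSE)
  structure(list(protein = paste(parts, collapse = ""),
                 elements = elements,
                 block_counts = c(n_htl = length(htl), n_lbl = length(lbl),
                                  n_ctl = length(ctl)),
                 epitopes = list(htl = unname(htl), lbl = unname(lbl),
                                 ctl = unname(ctl)),
                 blueprint = bp),
            class = "vaccine_construct")
}

# Reverse-translation codon choice used by the assembler (most-adapted codon
# per residue; optionally constrained to start with G for the residue whose
# first base is the Kozak's trailing +4 G).
pick_codon <- function(residue, usage, must_start_g = FALSE) {
  fam <- usage[usage$aa == residue, ]
  if (nrow(fam) == 0L)
    stop("codon table missing residue '", residue, "'", call. = FALSE)
  if (must_start_g) {
    fam <- fam[substr(fam$codon, 1, 1) == "G", ]
    if (nrow(fam) == 0L)
      stop("residue '", residue, "' after the initiator Met has no ",
           "G-starting codon compatible with the Kozak context",
           call. = FALSE)
  }
  fam$codon[which.max(fam$frequency)]
}

#' Assemble the mRNA for a vaccine construct
#'
#' Emits `5'UTR + GCCACC + AUG + codons(protein[2..n]) + stop + 3'UTR +
#' poly(A)`, where the AUG encodes the protein's initiator methionine and
#' the codon of the second residue starts with the Kozak's trailing G, so
#' the full Kozak motif appears verbatim and the open reading frame is in
#' frame with it. Codons are chosen as each family's most-used codon in
#' `usage` (see [optimize_codons()] for other strategies). The result
#' carries element coordinates on the mRNA and is verified internally to
#' contain no premature stop codon.
#'
#' @param construct A `vaccine_construct` from [assemble_protein()].
#' @param usage Codon usage table (see [codon_usage_table()]); default human.
#' @param as_rna Return the sequence in the RNA alphabet (U) instead of DNA.
#' @return The construct with `mrna` and `mrna_elements` added.
#' @export
assemble_mrna <- function(construct, usage = default_human_usage(),
                          as_rna = FALSE) {
  bp <- construct$blueprint
  protein <- construct$protein
  if (substr(protein, 1, 1) != "M")
    stop("protein must begin with the initiator methionine", call. = FALSE)
  rest <- str_chars(substr(protein, 2, nchar(protein)))
  codons <- character(length(rest))
  codons[1L] <- pick_codon(rest[1L], usage, must_start_g = TRUE)
  for (i in seq_along(rest)[-1L])
    codons[i] <- pick_codon(rest[i], usage)
  # Kozak = GCCACC + ATG + G; the trailing G is codon 1 of the second residue
  kz <- bp$kozak
  atg_at <- regexpr("ATG", kz, fixed = TRUE)
  pre_kozak <- substr(kz, 1L, atg_at - 1L)
  trailing <- substr(kz, atg_at + 3L, nchar(kz))
  if (nzchar(trailing) && trailing != substr(codons[1L], 1L, nchar(trailing)))
    stop("codon of residue 2 does not reproduce the Kozak trailing context",
         call. = FALSE)
  orf <- paste0("ATG", paste(codons, collapse = ""), bp$stop_codon)
  segs <- c(utr5 = bp$utr5,
            kozak_pre = pre_kozak,
            orf = orf,
            utr3 = bp$utr3,
            polyA = strrep("A", bp$polya_length))
  lens <- nchar(segs)
  ends <- cumsum(lens)
  mrna_elements <- data.frame(name = names(segs), start = ends - lens,
                              end = ends, stringsAsFactors = FALSE)
  mrna <- paste(segs, collapse = "")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(orf)))
  if (substr(aa, nchar(aa), nchar(aa)) != "*" ||
      gsub("\\*$", "", aa) != protein || grepl("\\*.", aa))
    stop("internal error: ORF does not translate back to the protein",
         call. = FALSE)
  construct$mrna <- if (as_rna) chartr("T", "U", mrna) else mrna
  construct$mrna_elements <- mrna_elements
  construct
}

#' Parse a construct protein string back into its blocks
#'
#' Inverts [assemble_protein()] using the linker schedule and the per-class
#' epitope length constraints (HTL 15; LBL 16; CTL 9-10). The signal peptide
#' and MITD are taken from the blueprint (their sequences are not themselves
#' encoded in the linker grammar). CTL parsing disambiguates 9- versus
#' 10-mers by looking ahead for the next AAY linker or the MITD.
#'
#' @param protein Construct polypeptide string.
#' @param blueprint The [construct_blueprint()] used to build it.
#' @return A `vaccine_construct` (without mRNA) with the recovered epitope
#'   lists and `block_counts`.
#' @export
parse_construct <- function(protein, blueprint) {
  bp <- blueprint
  pos <- 1L  # 1-based cursor
  n <- nchar(protein)
  expect <- function(what, s) {
    if (substr(protein, pos, pos + nchar(s) - 1L) != s)
      stop("parse error at position ", pos - 1L, ": expected ", what,
           " '", s, "'", call. = FALSE)
    pos <<- pos + nchar(s)
  }
  peek <- function(s) substr(protein, pos, pos + nchar(s) - 1L) == s
  expect("signal peptide", bp$signal_peptide)
  if (bp$eaaak_linker) expect("EAAAK linker", "EAAAK")

  htl <- character(0); lbl <- character(0); ctl <- character(0)
  # HTL block: (htl_linker htl)+ with fixed HTL length
  while (peek(bp$htl_linker)) {
    expect("HTL linker", bp$htl_linker)
    htl <- c(htl, substr(protein, pos, pos + bp$htl_length - 1L))
    pos <- pos + bp$htl_length
  }
  if (length(htl) == 0L)
    stop("parse error at position ", pos - 1L, ": no HTL block found",
         call. = FALSE)
  # LBL block: (lbl_linker lbl)+
  while (peek(bp$lbl_linker)) {
    expect("LBL linker", bp$lbl_linker)
    lbl <- c(lbl, substr(protein, pos, pos + bp$lbl_length - 1L))
    pos <- pos + bp$lbl_length
  }
  if (length(lbl) == 0L)
    stop("parse error at position ", pos - 1L, ": no LBL block found",
         call. = FALSE)
  # CTL block: (ctl_linker ctl)+ ctl_linker MITD; CTL length ambiguity is
  # resolved by looking ahead for the next linker
  repeat {
    if (!peek(bp$ctl_linker))
      stop("parse error at position ", pos - 1L, ": expected CTL linker",
           call. = FALSE)
    expect("CTL linker", bp$ctl_linker)
    if (peek(bp$mitd)) break
    len <- NA_integer_
    for (cand in sort(bp$ctl_lengths)) {
      after <- pos + cand
      nxt <- substr(protein, after, after + nchar(bp$ctl_linker) - 1L)
      if (nxt == bp$ctl_linker) { len <- cand; break }
    }
    if (is.na(len))
      stop("parse error at position ", pos - 1L,
           ": residue stretch matches no legal CTL length", call. = FALSE)
    ctl <- c(ctl, substr(protein, pos, pos + len - 1L))
    pos <- pos + len
  }
  expect("MITD", bp$mitd)
  if (pos != n + 1L)
    stop("parse error at position ", pos - 1L, ": trailing residues after ",
         "MITD", call. = FALSE)
  if (length(ctl) == 0L)
    stop("parse error: no CTL block found", call. = FALSE)
  assemble_protein(bp, htl, lbl, ctl)
}

#' Validate a vaccine construct
#'
#' Runs the structural checks an assembled (or parsed) construct must
#' satisfy: element coordinates tile the protein without gaps or overlaps;
#' linker counts follow the schedule (n_htl GPGPG, n_lbl KK, n_ctl + 1 AAY);
#' if an mRNA is attached, its ORF contains no internal stop codon,
#' translates to the protein, and the molecule ends with exactly
#' `polya_length` adenosines.
#'
#' @param construct A `vaccine_construct`.
#' @return A data frame report (check, pass, detail); all-pass iff
#'   `all(report$pass)`.
#' @export
validate_construct <- function(construct) {
  bp <- construct$blueprint
  el <- construct$elements
  checks <- list()
  tiling <- all(el$start[-1L] == el$end[-nrow(el)]) &&
    el$start[1L] == 0L && el$end[nrow(el)] == nchar(construct$protein)
  checks[["element_tiling"]] <- list(tiling, "0-based half-open, no gaps")
  cnt <- construct$block_counts
  n_htl_link <- sum(grepl("^htl_linker_", el$name))
  n_lbl_link <- sum(grepl("^lbl_linker_", el$name))
  n_ctl_link <- sum(grepl("^ctl_linker", el$name))
  checks[["linker_schedule"]] <- list(
    n_htl_link == cnt["n_htl"] && n_lbl_link == cnt["n_lbl"] &&
      n_ctl_link == cnt["n_ctl"] + 1L,
    sprintf("%d %s, %d %s, %d %s", n_htl_link, bp$htl_linker,
            n_lbl_link, bp$lbl_linker, n_ctl_link, bp$ctl_linker))
  lens_ok <- all(nchar(construct$epitopes$htl) == bp$htl_length) &&
    all(nchar(construct$epitopes$lbl) == bp$lbl_length) &&
    all(nchar(construct$epitopes$ctl) %in% bp$ctl_lengths)
  checks[["epitope_lengths"]] <-
    list(lens_ok, sprintf("HTL %d, LBL %d, CTL %s", bp$htl_length,
                          bp$lbl_length,
                          paste(bp$ctl_lengths, collapse = "-")))
  if (!is.null(construct$mrna)) {
    mrna <- chartr("U", "T", construct$mrna)
    orf_row <- construct$mrna_elements[construct$mrna_elements$name == "orf", ]
    orf <- substr(mrna, orf_row$start + 1L, orf_row$end)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(orf)))
    checks[["orf_no_internal_stop"]] <-
      list(!grepl("\\*.", aa), "single terminal stop")
    checks[["orf_translation"]] <-
      list(gsub("\\*$", "", aa) == construct$protein,
           "ORF translates to protein")
    tail_match <- regmatches(mrna, regexpr("A*$", mrna))
    checks[["polya_length"]] <-
      list(nchar(tail_match) >= bp$polya_length &&
             attr(regexpr(paste0("A{", bp$polya_length, "}$"), mrna),
                  "match.length") == bp$polya_length,
           sprintf("terminal run of %d A", bp$polya_length))
  }
  data.frame(check = names(checks),
             pass = vapply(checks, `[[`, logical(1), 1L),
             detail = vapply(checks, `[[`, character(1), 2L),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' The printed reference construct's epitope inventory
#'
#' Loads the packaged table of the 36 published epitopes (18 HTL, 6 LBL,
#' 12 CTL) of the colorectal-cancer multi-epitope construct, in construct
#' order.
#'
#' @return Data frame with `epitope_class` and `sequence`.
#' @export
reference_epitopes <- function() {
  path <- system.file("extdata", "reference_epitopes.tsv", package = "mevax",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
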