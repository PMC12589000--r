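tiny_blueprint <- function(...) {
  construct_blueprint(signal_peptide = "MDS", mitd = "WWW",
                      utr5 = "GGGAGA", utr3 = "CCTCGC",
                      htl_length = 3, lbl_length = 4, ctl_lengths = 3, ...)
}

rand_epitopes <- function(n, len, seed) {
  set.seed(seed)
  # linker-free alphabet subset avoids accidental GPGPG/KK/AAY motifs
  replicate(n, paste(sample(c("D", "E", "F", "H", "I", "L", "M", "N", "Q",
                              "R", "S", "T", "V", "W"), len, replace = TRUE),
                     collapse = ""))
}

test_that("the linker schedule is assembled exactly as specified", {
  bp <- tiny_blueprint()
  cons <- assemble_protein(bp, htl = "AAA", lbl = "CCCC", ctl = "DDD")
  expect_identical(cons$protein, "MDSGPGPGAAAKKCCCCAAYDDDAAYWWW")
  expect_identical(unname(cons$block_counts), c(1L, 1L, 1L))
  # coordinates tile the protein, 0-based half-open
  el <- cons$elements
  expect_identical(el$start[1], 0L)
  expect_identical(el$end[nrow(el)], nchar(cons$protein))
  expect_true(all(el$start[-1] == el$end[-nrow(el)]))
  # optional rigid linker after the signal peptide
  eaaak <- assemble_protein(tiny_blueprint(eaaak_linker = TRUE),
                            "AAA", "CCCC", "DDD")
  expect_identical(eaaak$protein, "MDSEAAAKGPGPGAAAKKCCCCAAYDDDAAYWWW")
})

test_that("epitopes containing linker motifs are rejected by name", {
  bp <- tiny_blueprint()
  expect_error(assemble_protein(bp, "AGPGPGA", "CCCC", "DDD"),
               "HTL epitope 'AGPGPGA' contains linker motif 'GPGPG'")
  expect_error(assemble_protein(bp, "AAA", "CCKKCC", "DDD"),
               "contains linker motif 'KK'")
  expect_error(assemble_protein(bp, "AAA", "CCCC", "DAAYD"),
               "contains linker motif 'AAY'")
})

test_that("assemble/parse round-trips on random epitope sets", {
  bp <- construct_blueprint()
  for (seed in 1:25) {
    htl <- rand_epitopes(sample(1:6, 1), 15, seed)
    lbl <- rand_epitopes(sample(1:4, 1), 16, seed + 100)
    ctl_len <- sample(c(9, 10), sample(1:5, 1), replace = TRUE)
    ctl <- vapply(seq_along(ctl_len), function(i)
      rand_epitopes(1, ctl_len[i], seed + 200 + i), character(1))
    cons <- assemble_protein(bp, htl, lbl, ctl)
    parsed <- parse_construct(cons$protein, bp)
    expect_identical(parsed$epitopes,
                     list(htl = unname(htl), lbl = unname(lbl),
                          ctl = unname(ctl)))
    expect_identical(parsed$protein, cons$protein)
  }
})

test_that("corrupted linkers produce positioned parse errors", {
  bp <- tiny_blueprint()
  cons <- assemble_protein(bp, c("AAA", "EEE"), "CCCC", "DDD")
  bad <- sub("GPGPG(EEE)", "GPGQG\\1", cons$protein)
  expect_error(parse_construct(bad, bp), "parse error at position")
  # trailing residues after the MITD are flagged
  expect_error(parse_construct(paste0(cons$protein, "R"), bp),
               "trailing residues")
  # a CTL stretch of illegal length is flagged
  bad2 <- assemble_protein(bp, "AAA", "CCCC", c("DDD", "EEE"))$protein
  bad2 <- sub("AAYEEE", "AAYEEEEEEEEEEEEE", bad2)
  expect_error(parse_construct(bad2, bp), "no legal CTL length|parse error")
})

test_that("mRNA assembly is frame-correct with the Kozak context", {
  bp <- tiny_blueprint()
  cons <- assemble_mrna(assemble_protein(bp, "AAA", "CCCC", "DDD"))
  mrna <- cons$mrna
  # Kozak appears verbatim right after the 5'UTR
  expect_identical(substr(mrna, 7, 16), "GCCACCATGG")
  # ORF begins at position 6 of the kozak (0-based): utr5(6) + 6
  orf_row <- cons$mrna_elements[cons$mrna_elements$name == "orf", ]
  expect_identical(orf_row$start, 6L + 6L)
  orf <- substr(mrna, orf_row$start + 1, orf_row$end)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(orf)))
  expect_identical(aa, paste0(cons$protein, "*"))
  # terminal adenosine run of exactly polya_length
  expect_identical(substr(mrna, nchar(mrna) - 119, nchar(mrna)),
                   strrep("A", 120))
  expect_false(substr(mrna, nchar(mrna) - 120, nchar(mrna) - 120) == "A")
  # documented length identity (initiator Met encoded inside the Kozak)
  expect_identical(nchar(mrna),
                   6L + 3L * nchar(cons$protein) + 9L + 6L + 120L)
})

test_that("construct validation reports failures without erroring", {
  bp <- tiny_blueprint()
  cons <- assemble_mrna(assemble_protein(bp, "AAA", "CCCC", "DDD"))
  rep_ok <- validate_construct(cons)
  expect_true(all(rep_ok$pass))
  broken <- cons
  broken$mrna <- substr(broken$mrna, 1, nchar(broken$mrna) - 5)
  rep_bad <- validate_construct(broken)
  expect_false(rep_bad$pass[rep_bad$check == "polya_length"])
})

test_that("the published epitope inventory reproduces the printed construct layout", {
  ep <- reference_epitopes()
  bp <- construct_blueprint()
  htl <- ep$sequence[ep$epitope_class == "HTL"]
  lbl <- ep$sequence[ep$epitope_class == "LBL"]
  ctl <- ep$sequence[ep$epitope_class == "CTL"]
  expect_identical(c(length(htl), length(lbl), length(ctl)), c(18L, 6L, 12L))
  cons <- assemble_protein(bp, htl, lbl, ctl)
  parsed <- parse_construct(cons$protein, bp)
  expect_identical(unname(parsed$block_counts), c(18L, 6L, 12L))
  # linker tallies implied by the schedule: 18 GPGPG, 6 KK, 13 AAY
  core <- substr(cons$protein, nchar(bp$signal_peptide) + 1,
                 nchar(cons$protein) - nchar(bp$mitd))
  count_motif <- function(s, m) length(gregexpr(m, s, fixed = TRUE)[[1]])
  expect_identical(count_motif(core, "GPGPG"), 18L)
  expect_identical(count_motif(core, "AAY"), 13L)
  expect_identical(count_motif(core, "KK"), 6L)
  v <- validate_construct(cons)
  expect_true(all(v$pass))
})
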