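test_that("GC content covers the trivial identities", {
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("AUGC"), 50)
  expect_error(gc_content(""), "empty")
})

test_that("the packaged usage table satisfies the adaptiveness contract", {
  u <- default_human_usage()
  expect_identical(nrow(u), 64L)
  expect_true(all(u$w > 0 & u$w <= 1))
  fams <- split(u$w[u$aa != "*"], u$aa[u$aa != "*"])
  expect_true(all(vapply(fams, max, numeric(1)) == 1))
  # single-codon families are maximally adapted by construction
  expect_equal(u$w[u$codon == "ATG"], 1)
  expect_equal(u$w[u$codon == "TGG"], 1)
})

test_that("CAI is the geometric mean of family-relative adaptiveness", {
  u <- default_human_usage()
  maxima <- vapply(split(u[u$aa != "*", ], u$aa[u$aa != "*"]),
                   function(f) f$codon[which.max(f$w)], character(1))
  expect_equal(cai(paste(maxima[c("A", "G", "L", "K")], collapse = ""), u), 1)
  # single codon: CAI equals its own w
  w_gca <- u$w[u$codon == "GCA"]
  expect_equal(cai("GCA", u), w_gca)
  # three codons: hand geometric mean
  cods <- c("GCC", "GCA", "GCG")  # one family, known w values
  expect_equal(cai(paste(cods, collapse = ""), u),
               prod(u$w[match(cods, u$codon)])^(1 / 3), tolerance = 1e-12)
  # terminal stop is excluded, internal stop rejected
  expect_equal(cai("GCCTAA", u), u$w[u$codon == "GCC"])
  expect_error(cai("TAAGCC", u), "internal stop")
  expect_error(cai("GCCGC", u), "divisible by 3")
})

test_that("codon optimization round-trips and hits its objectives", {
  set.seed(7)
  u <- default_human_usage()
  dev_max <- dev_gc <- numeric(20)
  for (i in 1:20) {
    prot <- paste(sample(mevax:::.aa_letters, 25, replace = TRUE),
                  collapse = "")
    orf_max <- optimize_codons(prot, u, "max_cai")
    expect_equal(cai(orf_max, u), 1)
    tr <- as.character(Biostrings::translate(Biostrings::DNAString(orf_max),
                                             no.init.codon = TRUE))
    expect_identical(tr, prot)
    orf_gc <- optimize_codons(prot, u, "gc_balance")
    expect_identical(
      as.character(Biostrings::translate(Biostrings::DNAString(orf_gc),
                                         no.init.codon = TRUE)),
      prot)
    dev_max[i] <- abs(gc_content(orf_max) - 50)
    dev_gc[i] <- abs(gc_content(orf_gc) - 50)
  }
  # the greedy balancer is myopic, so per-protein dominance is not
  # guaranteed, but it must win on average and never lose by much
  expect_lt(mean(dev_gc), mean(dev_max))
  expect_true(all(dev_gc <= dev_max + 2))
})

test_that("gc_balance picks the balanced glycine codons over GGG", {
  u <- default_human_usage()
  orf <- optimize_codons(strrep("G", 10), u, "gc_balance")
  cods <- substring(orf, seq(1, 28, 3), seq(3, 30, 3))
  # every glycine codon starts GG; the third base steers GC, so the greedy
  # choice alternates A/T third bases rather than compounding GGG/GGC
  naive <- abs(gc_content(strrep("GGG", 10)) - 50)
  expect_lt(abs(gc_content(orf) - 50), naive)
  expect_true(all(substr(cods, 1, 2) == "GG"))
})

test_that("Nussinov DP reproduces hand-derived pairings", {
  expect_identical(pairing_score("AAAA"), 0L)
  expect_identical(pairing_score("GGGAAACCC"), 3L)
  expect_identical(pairing_score("GCGCAAAGCGC", min_loop = 3), 4L)
  # min_loop forbids tight hairpins
  expect_identical(pairing_score("GAAAC", min_loop = 3), 1L)
  expect_identical(pairing_score("GAAC", min_loop = 3), 0L)
  # wobble adds the G-U pair unavailable to strict Watson-Crick
  expect_identical(pairing_score("GAAAT", min_loop = 3, wobble = FALSE), 0L)
  expect_identical(pairing_score("GAAAT", min_loop = 3, wobble = TRUE), 1L)
  expect_identical(pairing_score("TAAAG", wobble = TRUE), 1L)
  expect_identical(pairing_score("TAAAG", wobble = FALSE), 0L)
  expect_identical(pairing_score("GTTTT", wobble = TRUE), 1L)
  expect_identical(pairing_score("GTTTT", wobble = FALSE), 0L)
  expect_error(pairing_score(strrep("A", 2001)), "exceeds the dynamic")
})

test_that("DP equals exhaustive enumeration on short sequences", {
  set.seed(31)
  alph <- c("A", "C", "G", "U")
  # all sequences of length 5-6 over a reduced alphabet, plus random 7-12-mers
  for (len in 5:6) {
    combos <- expand.grid(rep(list(c("A", "C", "G")), len))
    seqs <- apply(combos, 1, paste, collapse = "")
    for (s in seqs)
      expect_identical(pairing_score(s), pairing_score_brute(s))
  }
  for (i in 1:60) {
    s <- paste(sample(alph, sample(7:12, 1), replace = TRUE), collapse = "")
    expect_identical(pairing_score(s), pairing_score_brute(s))
    expect_identical(pairing_score(s, wobble = FALSE),
                     pairing_score_brute(s, wobble = FALSE))
  }
})

test_that("Watson-Crick-only score is reverse-complement symmetric", {
  set.seed(5)
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  for (i in 1:40) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(6:14, 1),
                      replace = TRUE), collapse = "")
    expect_identical(pairing_score(s, wobble = FALSE),
                     pairing_score(rc(s), wobble = FALSE))
  }
})
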