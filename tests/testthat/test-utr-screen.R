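test_that("uAUG/uORF scanner agrees with direct reasoning", {
  expect_identical(scan_uaug_uorf("ATGTAA")[c("uaug_count", "uorf_count")],
                   list(uaug_count = 1L, uorf_count = 1L))
  expect_identical(scan_uaug_uorf("ATGCCC")[c("uaug_count", "uorf_count")],
                   list(uaug_count = 1L, uorf_count = 0L))
  # out-of-frame stop does not close a uORF
  expect_identical(scan_uaug_uorf("ATGCTAAC")$uorf_count, 0L)
  # in-frame stop two codons downstream does
  sc <- scan_uaug_uorf("CCATGAAATGACC")
  expect_identical(sc$uaug_count, 2L)   # positions 2 and 7 (0-based)
  expect_identical(sc$uaug_positions, c(2L, 7L))
  expect_identical(sc$uorf_count, 1L)   # first AUG hits TGA in frame
  # U and T are interchangeable
  expect_identical(scan_uaug_uorf("AUGUAA")$uorf_count, 1L)
  # the screening winner of the reference workflow carries no uAUG at all
  top <- "GGGATCTTATTCCACCTTCTGAAGCTTCTGTCGAACCAGTTGTAAGGAGA"
  expect_identical(scan_uaug_uorf(top)$uaug_count, 0L)
  expect_identical(nchar(top), 50L)
})

test_that("onehot embedding has unit rows on real positions, zeros on padding", {
  sp <- embedding_spec(max_length = 6)
  m <- embed_utr("ACGT", sp)
  expect_identical(dim(m), c(6L, 4L))
  expect_equal(m[1:4, ], diag(4), ignore_attr = TRUE)
  expect_equal(rowSums(m), c(1, 1, 1, 1, 0, 0))
  expect_error(embed_utr("ACGTACGT", sp), "longer")
  expect_error(embedding_spec(provider = "file"), "requires an embedding store")
})

test_that("file-backed embedding stores enforce ids and dimensions", {
  mats <- list(u1 = matrix(rnorm(20), 5, 4), u2 = matrix(rnorm(12), 3, 4))
  st <- embedding_store(mats)
  dir <- withr::local_tempdir()
  write_embedding_store(st, dir)
  st2 <- embedding_store(dir = dir)
  expect_identical(st2$dimension, 4L)
  sp <- embedding_spec("file", dimension = 4, max_length = 5, store = st2)
  m <- embed_utr(spec = sp, id = "u2")
  expect_equal(m[1:3, ], mats$u2, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(m[4:5, ], matrix(0, 2, 4), ignore_attr = TRUE)
  expect_error(embed_utr(spec = sp, id = "missing"), "missing from embedding")
  sp640 <- embedding_spec("file", dimension = 640, max_length = 5,
                          store = st2)
  expect_error(embed_utr(spec = sp640, id = "u1"),
               "store has 4 channels, spec declares 640")
})

test_that("the train/validation split is seeded, disjoint and exhaustive", {
  lib <- gen_mrl_library(mrl_generator_spec(10, seed = 1))
  s1 <- split_mrl_dataset(lib, seed = 5)
  expect_identical(sum(s1$split == "train"), 8L)
  expect_identical(sum(s1$split == "validation"), 2L)
  expect_identical(s1, split_mrl_dataset(lib, seed = 5))
  expect_false(identical(s1$split, split_mrl_dataset(lib, seed = 6)$split))
  expect_error(split_mrl_dataset(lib[1, ]), "at least 2")
  big <- split_mrl_dataset(gen_mrl_library(mrl_generator_spec(501, seed = 2)),
                           ratio = c(0.7, 0.3), seed = 1)
  expect_lte(abs(sum(big$split == "train") - 501 * 0.7), 1)
})

test_that("regression metrics satisfy their identities", {
  y <- c(1, 2, 3, 4.5)
  m <- regression_metrics(y, y)
  expect_equal(c(m$r2, m$mse, m$mae, m$rmse), c(1, 0, 0, 0))
  m2 <- regression_metrics(y, rep(mean(y), 4))
  expect_equal(m2$r2, 0)
  set.seed(1)
  for (i in 1:20) {
    a <- rnorm(30); b <- rnorm(30)
    mm <- regression_metrics(a, b)
    expect_lt(abs(mm$rmse^2 - mm$mse), 1e-9)
  }
  # the published error metrics are internally consistent: sqrt(0.307) = 0.554
  expect_equal(round(sqrt(0.307), 2), 0.55)
  flat <- regression_metrics(c(1, 1, 1), c(1, 2, 3))
  expect_true(is.na(flat$r2))
  expect_true(attr(flat, "degenerate"))
})

test_that("candidate pool assembles 212+8+1+1 = 222 records and rejects duplicate ids", {
  src <- reference_pool_sources(seed = 4)
  pool <- build_candidate_pool(src)
  expect_identical(nrow(pool), 222L)
  expect_identical(anyDuplicated(pool$id), 0L)
  expect_identical(as.integer(table(pool$source)[c("literature",
                                                   "kozak_variants")]),
                   c(212L, 8L))
  single <- build_candidate_pool(src["kozak_variants"])
  expect_identical(nrow(single), 8L)
  dup <- src
  dup$literature$id[1] <- "alpha_globin"
  expect_error(build_candidate_pool(dup), "duplicate ids.*alpha_globin")
})

test_that("pool building reads CSV and FASTA sources equivalently", {
  dir <- withr::local_tempdir()
  df <- data.frame(id = c("a", "b"), sequence = c("ACGT", "GGGCCC"))
  csv <- file.path(dir, "x.csv")
  write.csv(df, csv, row.names = FALSE)
  fa <- file.path(dir, "y.fasta")
  writeLines(c(">c", "TTTT"), fa)
  pool <- build_candidate_pool(list(csv = csv, fasta = fa))
  expect_identical(pool$id, c("a", "b", "c"))
  expect_identical(pool$length, c(4L, 6L, 4L))
})

test_that("ranking matches the sort oracle with stable id tie-break", {
  set.seed(9)
  rec <- data.frame(id = sprintf("u%03d", 1:50),
                    sequence = replicate(50, paste(sample(c("A", "C", "G",
                                                            "T"), 20,
                                                          replace = TRUE),
                                                   collapse = "")),
                    predicted_mrl = round(runif(50), 2))
  top <- rank_candidates(rec, 10)
  expect_identical(nrow(top), 10L)
  expect_true(min(top$predicted_mrl) >=
                max(rec$predicted_mrl[!rec$id %in% top$id]))
  oracle <- rec[order(-rec$predicted_mrl, rec$id), ][1:10, "id"]
  expect_identical(top$id, oracle)
  expect_error(rank_candidates(rec, 0), "positive")
  full <- rank_candidates(rec, 50)
  expect_identical(nrow(full), 50L)
  expect_false(is.unsorted(rev(full$predicted_mrl)))
})
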