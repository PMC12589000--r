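make_cands <- function(class, n, score = NULL, seqs = NULL, antig = 0.9,
                       rank = 0.5, cons = 0.95, allerg = FALSE,
                       toxic = FALSE, protein = "THBS2") {
  len <- switch(class, LBL = 16L, HTL = 15L, CTL = 9L)
  if (is.null(seqs))
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I"),
                   len, replace = TRUE), collapse = ""), character(1))
  data.frame(sequence = seqs, source_protein = protein,
             epitope_class = class,
             server_score = if (is.null(score)) runif(n) else score,
             percentile_rank = rank, antigenicity = antig,
             allergenic = allerg, toxic = toxic, conservation = cons,
             stringsAsFactors = FALSE)
}

test_that("top-k retention keeps the k best scores with lexicographic ties", {
  set.seed(1)
  g <- make_cands("LBL", 7, score = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.5, 0.4))
  g$sequence[5:6] <- c("ZZZZZZZZZZZZZZZZ", "AAAAAAAAAAAAAAAA")
  top <- select_top_k(g, 5)
  expect_identical(nrow(top), 5L)
  # brute-force oracle: stable sort by (-score, sequence)
  oracle <- g[order(-g$server_score, g$sequence), ][1:5, ]
  expect_identical(top$sequence, oracle$sequence)
  # the tied pair at the cutoff resolves to the lexicographically smaller
  expect_true("AAAAAAAAAAAAAAAA" %in% top$sequence)
  expect_false("ZZZZZZZZZZZZZZZZ" %in% top$sequence)
})

test_that("top-k handles degenerate group sizes", {
  set.seed(2)
  g <- make_cands("CTL", 1)
  expect_identical(select_top_k(g, 1)$sequence, g$sequence)
  short <- select_top_k(g, 5)
  expect_identical(nrow(short), 1L)
  expect_true(attr(short, "short"))
  mixed <- rbind(make_cands("CTL", 2), make_cands("HTL", 2))
  expect_error(select_top_k(mixed, 2), "one \\(class, source_protein\\) group")
})

test_that("class-specific thresholds apply with their printed orientations", {
  # LBL at antigenicity 0.49 fails the >= 0.5 bound; at exactly 0.5 passes
  lbl <- make_cands("LBL", 2, antig = c(0.49, 0.5))
  fl <- filter_epitopes(lbl)
  expect_identical(fl$audit$antigenicity_ok, c(FALSE, TRUE))
  expect_identical(fl$retained$sequence, lbl$sequence[2])
  # CTL: rank < 1.0, antigenicity > 0.7, conservation > 0.8 (all strict)
  ctl <- make_cands("CTL", 4, antig = c(0.71, 0.7, 0.71, 0.71),
                    rank = c(0.5, 0.5, 1.0, 0.5),
                    cons = c(0.81, 0.81, 0.81, 0.8))
  fl <- filter_epitopes(ctl)
  expect_identical(fl$audit$pass, c(TRUE, FALSE, FALSE, FALSE))
  # HTL conservation bound is 0.85
  htl <- make_cands("HTL", 2, cons = c(0.85, 0.86))
  expect_identical(filter_epitopes(htl)$audit$pass, c(FALSE, TRUE))
})

test_that("safety flags veto otherwise perfect candidates", {
  x <- make_cands("LBL", 3, allerg = c(FALSE, TRUE, FALSE),
                  toxic = c(FALSE, FALSE, TRUE))
  expect_identical(filter_epitopes(x)$audit$pass, c(TRUE, FALSE, FALSE))
})

test_that("empty input and unknown classes are handled explicitly", {
  fl <- filter_epitopes(empty_candidates <- gen_epitope_candidates(
    candidate_generator_spec(0)))
  expect_identical(nrow(fl$retained), 0L)
  bad <- make_cands("CTL", 1)
  bad$epitope_class <- "XXX"
  expect_error(filter_epitopes(bad), "unknown epitope_class 'XXX'")
})

test_that("filtering is idempotent and monotone in thresholds", {
  cands <- gen_epitope_candidates(candidate_generator_spec(80, 0.5, seed = 13))
  fl1 <- filter_epitopes(cands)
  fl2 <- filter_epitopes(fl1$retained)
  expect_identical(fl2$retained, fl1$retained)
  # relaxing every threshold can only grow the retained set
  relaxed <- filter_policy(antigenicity_min_lbl_htl = 0.3,
                           antigenicity_min_ctl = 0.5,
                           ctl_rank_max = 2,
                           ctl_conservation_min = 0.6,
                           htl_conservation_min = 0.6)
  fl3 <- filter_epitopes(cands, relaxed)
  expect_true(all(fl1$retained$sequence %in% fl3$retained$sequence))
  # retained order preserves input order
  expect_identical(fl1$retained$sequence,
                   cands$sequence[cands$sequence %in% fl1$retained$sequence])
})

test_that("selection summary reproduces the reference class tallies", {
  ep <- reference_epitopes()
  ep$source_protein <- "THBS2"
  s <- summarize_selection(ep)
  expect_identical(unname(s$per_class), c(6L, 12L, 18L))
  expect_identical(s$t_lymphocyte_total, 30L)
  expect_identical(s$total, 36L)
  empty <- summarize_selection(ep[0, ])
  expect_identical(unname(empty$per_class), c(0L, 0L, 0L))
  # tally oracle on generated labels
  cands <- gen_epitope_candidates(candidate_generator_spec(40, seed = 3))
  s2 <- summarize_selection(cands)
  expect_identical(unname(s2$per_class),
                   unname(vapply(c("LBL", "CTL", "HTL"), function(k)
                     sum(cands$epitope_class == k), integer(1))))
})
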