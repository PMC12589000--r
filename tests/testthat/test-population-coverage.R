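# Hand-checkable worlds for the Hardy-Weinberg hit distribution.
two_allele_world <- function() {
  structure(list(
    freq = data.frame(region = "r", locus = "A",
                      allele = c("A*01", "A*02"),
                      frequency = c(0.5, 0.5), stringsAsFactors = FALSE),
    binding = data.frame(epitope = "e1", allele = "A*01", locus = "A",
                         stringsAsFactors = FALSE)),
    class = "allele_world")
}

test_that("single forced allele gives a point mass at one hit", {
  w <- structure(list(
    freq = data.frame(region = "r", locus = "A", allele = "A*01",
                      frequency = 1.0),
    binding = data.frame(epitope = "e1", allele = "A*01", locus = "A")),
    class = "allele_world")
  pmf <- locus_hit_pmf(w, "r", "A", "e1")
  expect_equal(pmf, c(0, 1))
  expect_equal(coverage_metrics(pmf)$coverage, 1.0)
})

test_that("two equal alleles with one bound reproduce the genotype enumeration", {
  # genotypes: AA (0.25) -> 1 hit, AB (0.5) -> 1, BB (0.25) -> 0
  pmf <- locus_hit_pmf(two_allele_world(), "r", "A", "e1")
  expect_equal(pmf, c(0.25, 0.75))
  cv <- coverage_metrics(pmf)
  expect_equal(cv$coverage, 0.75)
  expect_equal(cv$average_hit, 0.75)
})

test_that("frequency mass over 1 is rejected; residual becomes a null allele", {
  w <- two_allele_world()
  w$freq$frequency <- c(0.7, 0.4)
  expect_error(locus_hit_pmf(w, "r", "A", "e1"), "sum to .* > 1")
  w$freq$frequency <- c(0.5, 0.45)  # residual 0.05 null allele
  pmf <- locus_hit_pmf(w, "r", "A", "e1")
  expect_equal(sum(pmf), 1, tolerance = 1e-12)
  # one hit: A*01 homozygote (0.25, counted once) + A*01/A*02 het (0.45)
  # + A*01/null het (0.05)
  expect_equal(pmf[2], 0.25 + 2 * 0.5 * 0.45 + 2 * 0.5 * 0.05,
               tolerance = 1e-12)
})

test_that("locus convolution matches hand results and is identity at zero", {
  expect_equal(combine_loci(list(c(1), c(0.3, 0.7))), c(0.3, 0.7))
  expect_equal(combine_loci(list(c(0.5, 0.5), c(0.5, 0.5))),
               c(0.25, 0.5, 0.25))
  expect_equal(combine_loci(list()), 1)
  # mean adds across loci
  p1 <- c(0.2, 0.5, 0.3); p2 <- c(0.6, 0.4)
  m <- function(p) sum((seq_along(p) - 1) * p)
  expect_equal(m(combine_loci(list(p1, p2))), m(p1) + m(p2),
               tolerance = 1e-12)
})

test_that("coverage metrics implement the documented pc90 rule", {
  expect_error(coverage_metrics(c(0.5, 0.4)), "not normalized")
  z <- coverage_metrics(c(1))
  expect_equal(c(z$coverage, z$average_hit, z$pc90), c(0, 0, 0))
  o <- coverage_metrics(c(0, 1))
  expect_equal(c(o$coverage, o$average_hit, o$pc90), c(1, 1, 1))
  x <- coverage_metrics(c(0.2, 0.5, 0.3))
  expect_equal(x$pc90, 0.5)        # 0.1 / (1 - 0.8)
  expect_equal(x$average_hit, 1.1)
  # the printed-style regime: coverage 89.13% -> pc90 0.92
  y <- coverage_metrics(c(1 - 0.8913, 0.8913))
  expect_equal(round(y$pc90, 2), 0.92)
})

test_that("convolution path equals the exhaustive genotype oracle", {
  for (seed in 1:12) {
    set.seed(seed)
    w <- gen_allele_world(sample(1:4, 1), sample(1:6, 1),
                          sample(1:8, 1), seed = seed)
    a <- compute_coverage(w, "region01")
    b <- coverage_oracle(w, "region01")
    expect_lt(abs(a$coverage - b$coverage), 1e-9)
    expect_lt(abs(a$average_hit - b$average_hit), 1e-9)
    expect_lt(abs(a$pc90 - b$pc90), 1e-9)
  }
})

test_that("adding an epitope never lowers coverage or average hits", {
  w <- gen_allele_world(3, 5, 10, seed = 42)
  epis <- unique(w$binding$epitope)
  prev <- compute_coverage(w, "region01", epitopes = epis[1])
  for (k in 2:length(epis)) {
    cur <- compute_coverage(w, "region01", epitopes = epis[1:k])
    expect_gte(cur$coverage + 1e-12, prev$coverage)
    expect_gte(cur$average_hit + 1e-12, prev$average_hit)
    prev <- cur
  }
})

test_that("average hit equals the analytic allele-sum corrected for homozygotes", {
  w <- gen_allele_world(2, 4, 6, seed = 11)
  epis <- unique(w$binding$epitope)
  cv <- compute_coverage(w, "region01", epitopes = epis)
  analytic <- 0
  for (lc in unique(w$freq$locus)) {
    fr <- w$freq[w$freq$locus == lc, ]
    e <- vapply(fr$allele, function(a)
      sum(w$binding$allele == a & w$binding$epitope %in% epis), numeric(1))
    # E[hits] = sum_a 2 f_a e_a - sum_a f_a^2 e_a (homozygotes count once)
    analytic <- analytic + sum(2 * fr$frequency * e) -
      sum(fr$frequency^2 * e)
  }
  expect_equal(cv$average_hit, analytic, tolerance = 1e-12)
})

test_that("regional summary reproduces the packaged report's summary rows", {
  tab <- read_regional_coverage(system.file("extdata",
                                            "regional_coverage.tsv",
                                            package = "mevax"))
  expect_identical(nrow(tab), 16L)
  s <- summarize_regions(tab)
  expect_equal(round(s$mean_coverage, 2), 62.69)
  expect_equal(round(s$sd_coverage, 2), 16.29)       # population divisor n
  expect_equal(round(s$mean_average_hit, 2), 1.44)
  expect_equal(round(s$mean_pc90, 2), 0.33)
  expect_identical(s$max_region, "Europe")
  expect_equal(s$max_coverage, 89.13)
  # the sample-variance divisor would NOT reproduce the printed row
  expect_false(round(sd(tab$coverage), 2) == 16.29)
})

test_that("regional summary rejects degenerate input", {
  expect_error(summarize_regions(data.frame()), "empty")
  one <- data.frame(region = "r", coverage = 50, average_hit = 1, pc90 = 0.2)
  s <- summarize_regions(one)
  expect_equal(s$sd_coverage, 0)
  expect_equal(s$mean_coverage, 50)
  bad <- one; bad$coverage <- 150
  expect_error(summarize_regions(bad), "\\[0, 100\\]")
})
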