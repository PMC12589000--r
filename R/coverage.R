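#' Generate a synthetic allele world
#'
#' Builds the substrate for population-coverage computation: per-region,
#' per-locus HLA allele frequencies plus an epitope-to-allele binding map.
#' Frequencies within a (region, locus) are drawn and scaled to sum to at
#' most 1; the unaccounted residual mass represents alleles absent from the
#' frequency table and is absorbed by an implicit null allele that binds no
#' epitope. Class I loci (A, B, C) are targeted by CTL epitopes, class II
#' (DRB1) by HTL epitopes; each synthetic epitope binds a random subset of
#' alleles of exactly one locus.
#'
#' @param n_loci Number of loci (1-4, drawn from A, B, C, DRB1).
#' @param n_alleles_per_locus Alleles per locus (>= 1).
#' @param n_epitopes Number of epitopes (>= 1).
#' @param n_regions Number of regions (default 1).
#' @param seed Integer seed.
#' @param total_mass Frequency mass accounted by named alleles (default
#'   drawn in `[0.85, 1]` per locus).
#' @param max_bound_alleles Cap on how many alleles of its locus one
#'   epitope can bind (default: no cap). Dense maps saturate coverage at
#'   100%; a cap of 1-2 keeps the hit distribution informative.
#' @return A list of class `allele_world` with `freq` (data frame: region,
#'   locus, allele, frequency) and `binding` (data frame: epitope, allele,
#'   locus).
#' @export
gen_allele_world <- function(n_loci, n_alleles_per_locus, n_epitopes,
                             n_regions = 1L, seed = 1L, total_mass = NULL,
                             max_bound_alleles = NULL) {
  stopifnot(n_loci >= 1, n_loci <= 4, n_alleles_per_locus >= 1,
            n_epitopes >= 1, n_regions >= 1)
  set.seed(seed)
  loci <- c("A", "B", "C", "DRB1")[seq_len(n_loci)]
  regions <- sprintf("region%02d", seq_len(n_regions))
  freq <- do.call(rbind, lapply(regions, function(rg) {
    do.call(rbind, lapply(loci, function(lc) {
      raw <- runif(n_alleles_per_locus)
      mass <- if (is.null(total_mass)) runif(1, 0.85, 1) else total_mass
      data.frame(region = rg, locus = lc,
                 allele = sprintf("%s*%02d", lc, seq_len(n_alleles_per_locus)),
                 frequency = raw / sum(raw) * mass,
                 stringsAsFactors = FALSE)
    }))
  }))
  alleles_by_locus <- split(unique(freq$allele), sub("\\*.*", "", unique(freq$allele)))
  binding <- do.call(rbind, lapply(seq_len(n_epitopes), function(i) {
    lc <- sample(loci, 1)
    al <- alleles_by_locus[[lc]]
    kmax <- if (is.null(max_bound_alleles)) length(al)
            else min(max_bound_alleles, length(al))
    k <- sample.int(kmax, 1)
    data.frame(epitope = sprintf("epi%03d", i),
               allele = sample(al, k),
               locus = lc, stringsAsFactors = FALSE)
  }))
  rownames(freq) <- rownames(binding) <- NULL
  structure(list(freq = freq, binding = binding), class = "allele_world")
}

# Per-allele epitope hit counts for one (region, locus), with the residual
# null allele appended. Returns list(f = frequencies, e = hit counts).
locus_allele_hits <- function(world, region, locus, epitopes) {
  fr <- world$freq[world$freq$region == region & world$freq$locus == locus, ]
  if (nrow(fr) == 0L)
    stop("no frequency data for region '", region, "', locus '", locus, "'",
         call. = FALSE)
  tot <- sum(fr$frequency)
  if (tot > 1 + 1e-9)
    stop("allele frequencies for locus '", locus, "' sum to ", signif(tot, 6),
         " > 1", call. = FALSE)
  bind <- world$binding[world$binding$epitope %in% epitopes &
                          world$binding$allele %in% fr$allele, ]
  e <- vapply(fr$allele, function(a) sum(bind$allele == a), integer(1))
  f <- fr$frequency
  if (tot < 1) {  # explicit null allele absorbs the residual mass
    f <- c(f, 1 - tot)
    e <- c(e, 0L)
  }
  list(f = as.numeric(f), e = as.integer(e))
}

#' Hit-count distribution at one HLA locus
#'
#' Under Hardy-Weinberg equilibrium an individual's genotype at a locus is an
#' unordered pair of alleles with probability \eqn{2 f_a f_b} (heterozygote)
#' or \eqn{f_a^2} (homozygote). The number of epitope/HLA combinations the
#' individual presents is the number of (epitope, allele) pairs over the two
#' alleles, counted once for homozygotes (distinct combinations). Frequency
#' mass missing from the table becomes an explicit null allele binding
#' nothing.
#'
#' @param world An `allele_world` (see [gen_allele_world()] /
#'   [read_allele_world()]).
#' @param region,locus Region and locus names.
#' @param epitopes Character vector of epitope ids to include.
#' @return Numeric vector `pmf` where `pmf[k+1] = P(hits = k)`.
#' @export
locus_hit_pmf <- function(world, region, locus, epitopes) {
  fe <- locus_allele_hits(world, region, locus, epitopes)
  f <- fe$f; e <- fe$e
  maxh <- 2L * max(e)
  pmf <- numeric(maxh + 1L)
  for (i in seq_along(f)) {
    for (j in i:length(f)) {
      p <- if (i == j) f[i]^2 else 2 * f[i] * f[j]
      h <- if (i == j) e[i] else e[i] + e[j]
      pmf[h + 1L] <- pmf[h + 1L] + p
    }
  }
  # drop hit counts that no genotype attains (homozygotes count distinct
  # combinations once, so 2*max(e) is only an upper bound)
  last <- max(which(pmf > 0))
  pmf[seq_len(last)]
}

#' Combine independent per-locus hit distributions
#'
#' Loci are treated as independent, so the distribution of total hits is the
#' discrete convolution of the per-locus distributions. An empty list yields
#' the point mass at zero hits.
#'
#' @param pmfs List of pmf vectors (each summing to 1).
#' @return Convolved pmf vector.
#' @export
combine_loci <- function(pmfs) {
  out <- 1
  for (p in pmfs) {
    stopifnot(abs(sum(p) - 1) < 1e-9)
    n <- length(out) + length(p) - 1L
    acc <- numeric(n)
    for (k in seq_along(p))
      acc[k:(k + length(out) - 1L)] <- acc[k:(k + length(out) - 1L)] + p[k] * out
    out <- acc
  }
  out
}

#' Coverage metrics from a hit-count distribution
#'
#' Computes the three IEDB-style population-coverage summaries:
#' \itemize{
#'   \item `coverage`: fraction of the population with at least one
#'     epitope/HLA combination, `1 - pmf[1]`.
#'   \item `average_hit`: expected combinations per individual.
#'   \item `pc90`: minimum number of combinations recognized by 90% of the
#'     population. When fewer than 90% recognize any epitope (coverage
#'     < 0.9) the value is fractional: interpolating the survival function
#'     P(hits >= h) linearly between h = 0 and h = 1 gives
#'     `pc90 = 0.1 / (1 - coverage)` (0 when coverage is 0). When coverage
#'     >= 0.9, pc90 is the largest integer h with P(hits >= h) >= 0.9.
#' }
#'
#' @param pmf Hit-count pmf (`pmf[k+1] = P(hits = k)`), summing to 1 within
#'   1e-9.
#' @return List of class `coverage_result`: `coverage`, `average_hit`,
#'   `pc90`, `hit_pmf`.
#' @export
coverage_metrics <- function(pmf) {
  if (abs(sum(pmf) - 1) > 1e-9)
    stop("pmf is not normalized (sums to ", sum(pmf), ")", call. = FALSE)
  k <- seq_along(pmf) - 1L
  coverage <- 1 - pmf[1L]
  average_hit <- sum(k * pmf)
  surv <- rev(cumsum(rev(pmf)))   # surv[h+1] = P(hits >= h)
  if (coverage >= 0.9) {
    pc90 <- max(k[surv >= 0.9 - 1e-12])
  } else if (coverage > 0) {
    pc90 <- 0.1 / (1 - coverage)
  } else {
    pc90 <- 0
  }
  structure(list(coverage = coverage, average_hit = average_hit,
                 pc90 = pc90, hit_pmf = pmf),
            class = "coverage_result")
}

#' Population coverage for a region (convolution path)
#'
#' @param world An `allele_world`.
#' @param region Region name.
#' @param epitopes Epitope ids; defaults to all mapped epitopes.
#' @param loci Loci to include; defaults to all loci present in the region.
#' @return A `coverage_result` (see [coverage_metrics()]).
#' @export
compute_coverage <- function(world, region, epitopes = NULL, loci = NULL) {
  if (is.null(epitopes)) epitopes <- unique(world$binding$epitope)
  if (is.null(loci))
    loci <- unique(world$freq$locus[world$freq$region == region])
  pmfs <- lapply(loci, function(lc) locus_hit_pmf(world, region, lc, epitopes))
  coverage_metrics(combine_loci(pmfs))
}

#' Brute-force population-coverage oracle
#'
#' Exhaustively enumerates every multi-locus genotype with its
#' Hardy-Weinberg probability and tallies epitope/HLA hits directly, with no
#' convolution. Intended as an independent cross-check of
#' [compute_coverage()] on small worlds (at most 4 loci and 6 named alleles
#' per locus).
#'
#' @inheritParams compute_coverage
#' @return A `coverage_result`.
#' @export
coverage_oracle <- function(world, region, epitopes = NULL, loci = NULL) {
  if (is.null(epitopes)) epitopes <- unique(world$binding$epitope)
  if (is.null(loci))
    loci <- unique(world$freq$locus[world$freq$region == region])
  if (length(loci) > 4L)
    stop("oracle instance too large: > 4 loci", call. = FALSE)
  per_locus <- lapply(loci, function(lc) {
    fe <- locus_allele_hits(world, region, lc, epitopes)
    if (length(fe$f) > 7L)
      stop("oracle instance too large: > 6 named alleles at locus ", lc,
           call. = FALSE)
    gp <- list(); gh <- list()
    m <- length(fe$f)
    for (i in seq_len(m)) for (j in i:m) {
      gp[[length(gp) + 1L]] <- if (i == j) fe$f[i]^2 else 2 * fe$f[i] * fe$f[j]
      gh[[length(gh) + 1L]] <- if (i == j) fe$e[i] else fe$e[i] + fe$e[j]
    }
    list(p = unlist(gp), h = unlist(gh))
  })
  idx <- expand.grid(lapply(per_locus, function(x) seq_along(x$p)))
  prob <- rep(1, nrow(idx)); hits <- rep(0L, nrow(idx))
  for (l in seq_along(per_locus)) {
    prob <- prob * per_locus[[l]]$p[idx[[l]]]
    hits <- hits + per_locus[[l]]$h[idx[[l]]]
  }
  maxh <- max(hits)
  pmf <- vapply(0:maxh, function(h) sum(prob[hits == h]), numeric(1))
  # independent metric arithmetic (no call into coverage_metrics)
  coverage <- sum(prob[hits > 0])
  average_hit <- sum(prob * hits)
  surv <- vapply(0:maxh, function(h) sum(prob[hits >= h]), numeric(1))
  if (coverage >= 0.9) {
    pc90 <- max((0:maxh)[surv >= 0.9 - 1e-12])
  } else if (coverage > 0) pc90 <- 0.1 / (1 - coverage) else pc90 <- 0
  structure(list(coverage = coverage, average_hit = average_hit,
                 pc90 = pc90, hit_pmf = pmf),
            class = "coverage_result")
}

#' Summarize a regional coverage table
#'
#' Reproduces the summary rows of an IEDB-style regional coverage report:
#' arithmetic means of coverage, average hits and pc90, the population
#' standard deviation of coverage (divisor n, which is the convention such
#' reports print), and the region of maximum coverage.
#'
#' @param table Data frame with columns `region`, `coverage` (percent),
#'   `average_hit`, `pc90`.
#' @return List: `mean_coverage`, `sd_coverage`, `mean_average_hit`,
#'   `mean_pc90`, `max_region`, `max_coverage`, `n`.
#' @export
summarize_regions <- function(table) {
  if (is.null(table) || nrow(table) == 0L)
    stop("empty regional coverage table", call. = FALSE)
  stopifnot(all(c("region", "coverage", "average_hit", "pc90") %in%
                  names(table)))
  if (any(table$coverage < 0 | table$coverage > 100))
    stop("coverage must be in [0, 100] percent", call. = FALSE)
  n <- nrow(table)
  sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
  list(mean_coverage = mean(table$coverage),
       sd_coverage = sd_pop(table$coverage),
       mean_average_hit = mean(table$average_hit),
       sd_average_hit = sd_pop(table$average_hit),
       mean_pc90 = mean(table$pc90),
       sd_pc90 = sd_pop(table$pc90),
       max_region = table$region[which.max(table$coverage)],
       max_coverage = max(table$coverage),
       n = n)
}

#' Read / write allele-world tables (TSV)
#'
#' `freq_path` columns: region, locus, allele, frequency. `binding_path`
#' columns: epitope, allele, locus.
#' @param freq_path,binding_path TSV file paths.
#' @return An `allele_world`.
#' @export
read_allele_world <- function(freq_path, binding_path) {
  freq <- utils::read.delim(freq_path, stringsAsFactors = FALSE)
  binding <- utils::read.delim(binding_path, stringsAsFactors = FALSE)
  stopifnot(all(c("region", "locus", "allele", "frequency") %in% names(freq)),
            all(c("epitope", "allele") %in% names(binding)))
  structure(list(freq = freq, binding = binding), class = "allele_world")
}

#' @rdname read_allele_world
#' @param world An `allele_world` to write.
#' @export
write_allele_world <- function(world, freq_path, binding_path) {
  utils::write.table(world$freq, freq_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(world$binding, binding_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(list(freq_path, binding_path))
}

#' Read a regional coverage report (TSV: region, coverage, average_hit, pc90)
#'
#' Accepts coverage given either as percent numbers or strings with a
#' trailing percent sign.
#' @param path TSV path.
#' @return Data frame with numeric coverage in percent.
#' @export
read_regional_coverage <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$coverage <- as.numeric(sub("%$", "", tab$coverage))
  tab
}
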