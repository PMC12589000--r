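# Published reference 5'UTRs used as singleton pool sources. The alpha-globin
# 5'UTR and the BNT162b2-type vaccine 5'UTR (an alpha-globin-derived leader
# ending in a Kozak context) are classic high-translation leaders.
.utr_alpha_globin <- "ACTCTTCTGGTCCCCACAGACTCAGAGAGAACCCACC"
.utr_bnt162b2 <- "GAGAATAAACTAGTATTCTTCTGGTCCCCACAGACTCAGAGAGAACCCGCCACC"

#' Build the four-source candidate 5'UTR screening pool
#'
#' Assembles the screening pool used by the design workflow: 212
#' variable-length literature-style candidates and 8 Kozak-context variants
#' (both generated synthetically here, with uniform random composition and
#' lengths 25-75 nt — stand-ins for literature-curated collections), plus
#' the alpha-globin 5'UTR and a BNT162b2-type vaccine 5'UTR as published
#' singletons, for a pool of 222 records.
#'
#' @param n_literature Size of the variable-length synthetic source
#'   (default 212).
#' @param n_kozak Size of the Kozak-variant synthetic source (default 8).
#' @param seed Integer seed for the synthetic sources.
#' @return Named list of four data frames suitable for
#'   [build_candidate_pool()].
#' @export
reference_pool_sources <- function(n_literature = 212L, n_kozak = 8L,
                                   seed = 1L) {
  set.seed(seed)
  rand_utr <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = "")
  lit_len <- sample(25:75, n_literature, replace = TRUE)
  lit <- data.frame(id = sprintf("lit%03d", seq_len(n_literature)),
                    sequence = vapply(lit_len, rand_utr, character(1)),
                    stringsAsFactors = FALSE)
  koz <- data.frame(id = sprintf("kozak%02d", seq_len(n_kozak)),
                    sequence = vapply(rep(40L, n_kozak), function(l)
                      paste0(rand_utr(l - 6L), "GCCACC"), character(1)),
                    stringsAsFactors = FALSE)
  list(literature = lit,
       kozak_variants = koz,
       alpha_globin = data.frame(id = "alpha_globin",
                                 sequence = .utr_alpha_globin,
                                 stringsAsFactors = FALSE),
       bnt162b2 = data.frame(id = "bnt162b2",
                             sequence = .utr_bnt162b2,
                             stringsAsFactors = FALSE))
}
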