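#' Specification for synthetic epitope candidate tables
#'
#' Emulates the output of epitope-prediction servers for the three epitope
#' classes used in multi-epitope vaccine design: linear B-cell epitopes
#' (LBL, 16-mers), cytotoxic T-lymphocyte epitopes (CTL, 9-10-mers, HLA class
#' I) and helper T-lymphocyte epitopes (HTL, 15-mers, HLA class II). Each
#' candidate is assigned a ground-truth `should_pass` label; scores and flags
#' are then drawn so that the label is consistent with the default
#' [filter_policy()]: passing candidates satisfy every applicable rule,
#' failing candidates violate at least one (chosen at random), with score
#' values drawn from shifted Gaussians truncated at the thresholds so the
#' decision boundaries are exercised.
#'
#' @param n_per_class Candidates per class (0 allowed; yields no rows for
#'   that class).
#' @param pass_fraction Target fraction designed to survive the filter, in
#'   `[0, 1]`.
#' @param source_proteins Labels to assign (recycled at random) as the
#'   antigen of origin.
#' @param seed Integer seed.
#' @return An object of class `candidate_generator_spec`.
#' @export
candidate_generator_spec <- function(n_per_class, pass_fraction = 0.5,
                                     source_proteins = c("THBS2", "FSTL3",
                                                         "TNNT1", "BGN",
                                                         "CTHRC1", "NOX4"),
                                     seed = 1L) {
  stopifnot(n_per_class >= 0, pass_fraction >= 0, pass_fraction <= 1)
  structure(list(n_per_class = as.integer(n_per_class),
                 pass_fraction = pass_fraction,
                 source_proteins = source_proteins,
                 seed = as.integer(seed)),
            class = "candidate_generator_spec")
}

.epitope_lengths <- list(LBL = 16L, CTL = c(9L, 10L), HTL = 15L)

rand_peptides <- function(n, lengths) {
  if (n == 0L) return(character(0))
  len <- sample(rep(lengths, length.out = max(n, length(lengths))), n,
                replace = TRUE)
  vapply(len, function(l)
    paste(sample(.aa_letters, l, replace = TRUE), collapse = ""),
    character(1))
}

# Draw from a Gaussian truncated to one side of `bound`.
rtrunc_side <- function(n, mean, sd, bound, above, strict = TRUE) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- rnorm(1, mean, sd)
      ok <- if (above) (if (strict) x > bound else x >= bound)
            else (if (strict) x < bound else x <= bound)
      if (ok) { out[i] <- x; break }
    }
  }
  out
}

#' Generate synthetic epitope candidates with known filter outcomes
#'
#' @param spec A [candidate_generator_spec()].
#' @param policy The [filter_policy()] the labels should be consistent with
#'   (default policy if omitted).
#' @return Data frame of candidates with columns `sequence`,
#'   `source_protein`, `epitope_class`, `server_score`, `percentile_rank`,
#'   `antigenicity`, `allergenic`, `toxic`, `conservation` and the
#'   ground-truth `should_pass`.
#' @export
gen_epitope_candidates <- function(spec, policy = filter_policy()) {
  stopifnot(inherits(spec, "candidate_generator_spec"))
  set.seed(spec$seed)
  n <- spec$n_per_class
  if (n == 0L)
    return(empty_candidates())
  out <- lapply(c("LBL", "CTL", "HTL"), function(cls) {
    seqs <- rand_peptides(n, .epitope_lengths[[cls]])
    pass <- runif(n) < spec$pass_fraction
    ag_min <- if (cls == "CTL") policy$antigenicity_min_ctl
              else policy$antigenicity_min_lbl_htl
    ag_strict <- if (cls == "CTL") policy$antigenicity_ctl_strict
                 else policy$antigenicity_lbl_htl_strict
    cons_min <- switch(cls, CTL = policy$ctl_conservation_min,
                       HTL = policy$htl_conservation_min, NA_real_)
    df <- data.frame(
      sequence = seqs,
      source_protein = sample(spec$source_proteins, n, replace = TRUE),
      epitope_class = cls,
      server_score = round(runif(n, 0.3, 1), 4),
      percentile_rank = NA_real_,
      antigenicity = NA_real_,
      allergenic = FALSE,
      toxic = FALSE,
      conservation = NA_real_,
      should_pass = pass,
      stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
      if (pass[i]) {
        df$antigenicity[i] <- rtrunc_side(1, ag_min + 0.2, 0.15, ag_min,
                                          above = TRUE, strict = ag_strict)
        df$percentile_rank[i] <- if (cls == "CTL")
          rtrunc_side(1, 0.5, 0.3, policy$ctl_rank_max, above = FALSE) else
          round(runif(1, 0, 10), 2)
        df$conservation[i] <- if (!is.na(cons_min))
          rtrunc_side(1, cons_min + 0.05, 0.05, cons_min, above = TRUE) else
          runif(1)
      } else {
        # violate at least one applicable rule, drawn at random
        rules <- c("antigenicity", "allergen", "toxin")
        if (cls == "CTL") rules <- c(rules, "rank", "conservation")
        if (cls == "HTL") rules <- c(rules, "conservation")
        viol <- sample(rules, sample.int(length(rules), 1))
        df$antigenicity[i] <- if ("antigenicity" %in% viol)
          rtrunc_side(1, ag_min - 0.2, 0.15, ag_min,
                      above = FALSE, strict = !ag_strict) else
          rtrunc_side(1, ag_min + 0.2, 0.15, ag_min,
                      above = TRUE, strict = ag_strict)
        df$allergenic[i] <- "allergen" %in% viol
        df$toxic[i] <- "toxin" %in% viol
        df$percentile_rank[i] <- if (cls == "CTL") {
          if ("rank" %in% viol)
            rtrunc_side(1, policy$ctl_rank_max + 0.5, 0.4,
                        policy$ctl_rank_max, above = TRUE, strict = FALSE)
          else rtrunc_side(1, 0.5, 0.3, policy$ctl_rank_max, above = FALSE)
        } else round(runif(1, 0, 10), 2)
        df$conservation[i] <- if (!is.na(cons_min)) {
          if ("conservation" %in% viol)
            rtrunc_side(1, cons_min - 0.1, 0.08, cons_min,
                        above = FALSE, strict = FALSE)
          else rtrunc_side(1, cons_min + 0.05, 0.05, cons_min, above = TRUE)
        } else runif(1)
      }
    }
    df$percentile_rank <- pmax(df$percentile_rank, 0)
    df$conservation <- pmin(df$conservation, 1)
    df
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_candidates <- function() {
  data.frame(sequence = character(0), source_protein = character(0),
             epitope_class = character(0), server_score = numeric(0),
             percentile_rank = numeric(0), antigenicity = numeric(0),
             allergenic = logical(0), toxic = logical(0),
             conservation = numeric(0), should_pass = logical(0),
             stringsAsFactors = FALSE)
}
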