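#' Epitope filtering policy
#'
#' Encodes the triage rules applied to predicted epitopes before vaccine
#' inclusion. The three classes are treated differently:
#' \itemize{
#'   \item LBL (linear B-cell): top-k retention by prediction score happens
#'     upstream (see [select_top_k()]); the filter then requires antigenicity
#'     >= 0.5 plus non-allergenicity and non-toxicity.
#'   \item CTL (HLA class I): percentile binding rank < 1.0, antigenicity
#'     > 0.7, conservation > 0.8, plus the safety flags.
#'   \item HTL (HLA class II): antigenicity >= 0.5, conservation > 0.85,
#'     plus the safety flags.
#' }
#' The open/closed orientation of each bound is stored explicitly
#' (`*_strict = TRUE` means a strict inequality) because the source
#' conventions differ between the class-I and class-II/B-cell thresholds.
#'
#' @param lbl_top_k Per-protein retention count for B-cell epitopes.
#' @param antigenicity_min_lbl_htl,antigenicity_min_ctl Antigenicity
#'   thresholds (VaxiJen-style score).
#' @param ctl_rank_max Maximum MHC-I percentile rank (lower is better).
#' @param ctl_conservation_min,htl_conservation_min Conservation-index
#'   thresholds on a 0-1 scale.
#' @param require_nonallergen,require_nontoxic Safety-flag requirements.
#' @param antigenicity_lbl_htl_strict,antigenicity_ctl_strict,
#'   rank_strict,conservation_strict Bound orientations.
#' @return An object of class `filter_policy`.
#' @export
filter_policy <- function(lbl_top_k = 5L,
                          antigenicity_min_lbl_htl = 0.5,
                          antigenicity_min_ctl = 0.7,
                          ctl_rank_max = 1.0,
                          ctl_conservation_min = 0.8,
                          htl_conservation_min = 0.85,
                          require_nonallergen = TRUE,
                          require_nontoxic = TRUE,
                          antigenicity_lbl_htl_strict = FALSE,
                          antigenicity_ctl_strict = TRUE,
                          rank_strict = TRUE,
                          conservation_strict = TRUE) {
  stopifnot(lbl_top_k >= 1,
            is.finite(antigenicity_min_lbl_htl), is.finite(antigenicity_min_ctl),
            is.finite(ctl_rank_max), is.finite(ctl_conservation_min),
            is.finite(htl_conservation_min))
  structure(as.list(environment()), class = "filter_policy")
}

cmp_ge <- function(x, bound, strict) if (strict) x > bound else x >= bound
cmp_le <- function(x, bound, strict) if (strict) x < bound else x <= bound

#' Retain the top-k candidates of one (class, protein) group by score
#'
#' Ties at the cutoff are broken by lexicographic sequence order, giving a
#' stable, reproducible selection. Asking for more candidates than exist
#' returns the whole group with an attribute `short = TRUE` for the audit
#' trail rather than an error.
#'
#' @param candidates Candidate data frame (one class/protein group).
#' @param k Retention count (>= 1).
#' @return The k highest-scoring rows, input columns preserved.
#' @export
select_top_k <- function(candidates, k) {
  stopifnot(k >= 1)
  if (nrow(candidates) == 0L) return(candidates)
  if (length(unique(candidates$epitope_class)) > 1L ||
      length(unique(candidates$source_protein)) > 1L)
    stop("candidates must share one (class, source_protein) group",
         call. = FALSE)
  ord <- order(-candidates$server_score, candidates$sequence)
  short <- k > nrow(candidates)
  out <- candidates[ord[seq_len(min(k, nrow(candidates)))], , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "short") <- short
  out
}

#' Filter epitope candidates under a policy
#'
#' Applies every rule applicable to each candidate's class and retains the
#' candidates that pass all of them, preserving input order. A full
#' per-candidate audit of rule outcomes is returned so rejected candidates
#' can be traced to the rule that removed them.
#'
#' @param candidates Candidate data frame (see [gen_epitope_candidates()] for
#'   the column contract).
#' @param policy A [filter_policy()].
#' @return A list with `retained` (subset of `candidates`) and `audit` (one
#'   row per input candidate: the boolean outcome of every rule, `NA` where a
#'   rule does not apply to the class, and the overall `pass`).
#' @export
filter_epitopes <- function(candidates, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  n <- nrow(candidates)
  if (n == 0L)
    return(list(retained = candidates,
                audit = data.frame(sequence = character(0),
                                   epitope_class = character(0))))
  cls <- candidates$epitope_class
  unknown <- !cls %in% c("LBL", "CTL", "HTL")
  if (any(unknown))
    stop("unknown epitope_class '", cls[unknown][1L], "' for candidate '",
         candidates$sequence[unknown][1L], "'", call. = FALSE)

  ag_min <- ifelse(cls == "CTL", policy$antigenicity_min_ctl,
                   policy$antigenicity_min_lbl_htl)
  ag_strict <- ifelse(cls == "CTL", policy$antigenicity_ctl_strict,
                      policy$antigenicity_lbl_htl_strict)
  ok_ag <- ifelse(ag_strict, candidates$antigenicity > ag_min,
                  candidates$antigenicity >= ag_min)
  ok_allergen <- if (policy$require_nonallergen) !candidates$allergenic
                 else rep(TRUE, n)
  ok_toxin <- if (policy$require_nontoxic) !candidates$toxic
              else rep(TRUE, n)
  ok_rank <- rep(NA, n)
  ok_rank[cls == "CTL"] <- cmp_le(candidates$percentile_rank[cls == "CTL"],
                                  policy$ctl_rank_max, policy$rank_strict)
  ok_cons <- rep(NA, n)
  ok_cons[cls == "CTL"] <- cmp_ge(candidates$conservation[cls == "CTL"],
                                  policy$ctl_conservation_min,
                                  policy$conservation_strict)
  ok_cons[cls == "HTL"] <- cmp_ge(candidates$conservation[cls == "HTL"],
                                  policy$htl_conservation_min,
                                  policy$conservation_strict)
  pass <- ok_ag & ok_allergen & ok_toxin &
    (is.na(ok_rank) | ok_rank) & (is.na(ok_cons) | ok_cons)
  audit <- data.frame(sequence = candidates$sequence,
                      epitope_class = cls,
                      antigenicity_ok = ok_ag,
                      nonallergen_ok = ok_allergen,
                      nontoxic_ok = ok_toxin,
                      rank_ok = ok_rank,
                      conservation_ok = ok_cons,
                      pass = pass,
                      stringsAsFactors = FALSE)
  retained <- candidates[pass, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, audit = audit)
}

#' Summarize a retained epitope selection
#'
#' @param retained Data frame of retained candidates.
#' @return List with `per_class` (named counts LBL/CTL/HTL), `per_protein`
#'   (named counts), `total` and `t_lymphocyte_total` (CTL + HTL).
#' @export
summarize_selection <- function(retained) {
  per_class <- vapply(c("LBL", "CTL", "HTL"),
                      function(k) sum(retained$epitope_class == k),
                      integer(1))
  per_protein <- if (nrow(retained)) table(retained$source_protein)
                 else table(character(0))
  list(per_class = per_class,
       per_protein = per_protein,
       total = nrow(retained),
       t_lymphocyte_total = unname(per_class["CTL"] + per_class["HTL"]))
}
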