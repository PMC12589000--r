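#' Residue and elemental composition of a polypeptide
#'
#' @param seq Amino-acid string (20-letter alphabet).
#' @return List: `residue_counts` (named, all 20 letters),
#'   `formula` (element counts C, H, N, O, S for the whole peptide, i.e. the
#'   residue formulas plus one water), `atom_total`, `negative_count`
#'   (Asp + Glu), `positive_count` (Arg + Lys), `length`.
#' @export
#' @examples
#' composition("G")$formula   # free glycine, C2 H5 N O2
composition <- function(seq) {
  s <- check_protein(seq)
  ch <- str_chars(s)
  counts <- vapply(.aa_letters, function(a) sum(ch == a), integer(1))
  formula <- drop(counts %*% .aa_formula) + c(C = 0, H = 2, N = 0, O = 1, S = 0)
  list(residue_counts = counts,
       formula = formula,
       atom_total = sum(formula),
       negative_count = unname(counts["D"] + counts["E"]),
       positive_count = unname(counts["R"] + counts["K"]),
       length = length(ch))
}

#' Molecular weight of a polypeptide (average masses, Da)
#'
#' Sum of average residue masses plus one water, the convention of
#' ProtParam-style calculators.
#' @param seq Amino-acid string.
#' @return Mass in daltons.
#' @export
#' @examples
#' molecular_weight("G")   # 75.07
molecular_weight <- function(seq) {
  s <- check_protein(seq)
  ch <- str_chars(s)
  sum(.aa_residue_mass[ch]) + .water_mass
}

# Net charge of a peptide at a given pH, Henderson-Hasselbalch over the
# termini and the D/E/C/Y/H/K/R side chains. Vectorized over pH.
peptide_charge <- function(counts, pH, pka = .pka_sets$bjellqvist) {
  pos_groups <- c(Nterm = 1, counts[c("K", "R", "H")])
  names(pos_groups) <- c("Nterm", "K", "R", "H")
  neg_groups <- c(Cterm = 1, counts[c("D", "E", "C", "Y")])
  names(neg_groups) <- c("Cterm", "D", "E", "C", "Y")
  pos <- Reduce(`+`, lapply(names(pos_groups), function(g)
    pos_groups[[g]] / (1 + 10^(pH - pka$positive[[g]]))))
  neg <- Reduce(`+`, lapply(names(neg_groups), function(g)
    neg_groups[[g]] / (1 + 10^(pka$negative[[g]] - pH))))
  pos - neg
}

#' Net charge of a peptide at a given pH
#'
#' Evaluates the same Henderson-Hasselbalch charge model used by
#' [isoelectric_point()], including the residue-specific terminal pKa
#' adjustments of the Bjellqvist set.
#'
#' @param seq Amino-acid string.
#' @param pH pH value(s); vectorized.
#' @param pka_set `"bjellqvist"` (default) or `"emboss"`.
#' @return Net charge in elementary-charge units.
#' @export
net_charge <- function(seq, pH, pka_set = c("bjellqvist", "emboss")) {
  s <- check_protein(seq)
  pka <- .pka_sets[[match.arg(pka_set)]]
  ch <- str_chars(s)
  first <- ch[1L]; last <- ch[length(ch)]
  if (first %in% names(pka$nterm_by_residue))
    pka$positive["Nterm"] <- pka$nterm_by_residue[[first]]
  if (last %in% names(pka$cterm_by_residue))
    pka$negative["Cterm"] <- pka$cterm_by_residue[[last]]
  counts <- vapply(.aa_letters, function(a) sum(ch == a), numeric(1))
  peptide_charge(counts, pH, pka)
}

#' Theoretical isoelectric point
#'
#' Finds the pH at which the peptide's net charge vanishes by bisection on
#' `[0, 14]`. The charge model sums Henderson-Hasselbalch occupancies over
#' the two termini and the ionizable side chains (D, E, C, Y, H, K, R) with
#' the Bjellqvist-style pKa set used by ProtParam-compatible tools (an
#' EMBOSS-style set is available via `pka_set = "emboss"`). The net charge
#' at the returned pH is within 0.01 charge units of zero.
#'
#' @param seq Amino-acid string.
#' @param pka_set `"bjellqvist"` (default) or `"emboss"`.
#' @param tol Charge tolerance at the root (default 0.01).
#' @return pH in (0, 14).
#' @export
isoelectric_point <- function(seq, pka_set = c("bjellqvist", "emboss"),
                              tol = 0.01) {
  s <- check_protein(seq)
  pka <- .pka_sets[[match.arg(pka_set)]]
  ch <- str_chars(s)
  first <- ch[1L]; last <- ch[length(ch)]
  if (first %in% names(pka$nterm_by_residue))
    pka$positive["Nterm"] <- pka$nterm_by_residue[[first]]
  if (last %in% names(pka$cterm_by_residue))
    pka$negative["Cterm"] <- pka$cterm_by_residue[[last]]
  counts <- vapply(.aa_letters, function(a) sum(ch == a), numeric(1))
  lo <- 0; hi <- 14
  # bisect on the interval (not on |charge|): the charge curve is flat near
  # the root for strongly buffered peptides, and stopping on a small charge
  # would return a pH well away from the actual crossing
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (peptide_charge(counts, mid, pka) > 0) lo <- mid else hi <- mid
  }
  mid <- (lo + hi) / 2
  if (abs(peptide_charge(counts, mid, pka)) > tol)
    warning("net charge at returned pI exceeds tolerance", call. = FALSE)
  mid
}

#' Instability index (Guruprasad dipeptide method)
#'
#' \deqn{II = \frac{10}{L} \sum_{i=1}^{L-1} DIWV(x_i, x_{i+1})}
#' over the shipped 400-entry dipeptide instability weight table. Values
#' above 40 classify a protein as unstable by the usual convention.
#'
#' @param seq Amino-acid string, length >= 2.
#' @return The instability index.
#' @export
instability_index <- function(seq) {
  s <- check_protein(seq)
  ch <- str_chars(s)
  L <- length(ch)
  if (L < 2L) stop("instability index needs length >= 2", call. = FALSE)
  idx <- cbind(match(ch[-L], rownames(.diwv)),
               match(ch[-1L], colnames(.diwv)))
  (10 / L) * sum(.diwv[idx])
}

#' Aliphatic index
#'
#' Relative volume occupied by aliphatic side chains:
#' `AI = X(Ala) + 2.9 X(Val) + 3.9 (X(Ile) + X(Leu))` with X in mole
#' percent. Higher values correlate with thermostability.
#'
#' @param seq Amino-acid string.
#' @return The aliphatic index.
#' @export
#' @examples
#' aliphatic_index("AAAA")  # 100
aliphatic_index <- function(seq) {
  s <- check_protein(seq)
  ch <- str_chars(s)
  molpct <- 100 * vapply(names(.aliphatic_weights),
                         function(a) mean(ch == a), numeric(1))
  sum(.aliphatic_weights * molpct)
}

#' Grand average of hydropathicity (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over all residues; positive values are
#' hydrophobic, negative hydrophilic.
#'
#' @param seq Amino-acid string.
#' @return GRAVY score.
#' @export
#' @examples
#' gravy("I")  # 4.5, the scale maximum
gravy <- function(seq) {
  s <- check_protein(seq)
  mean(.kyte_doolittle[str_chars(s)])
}

#' N-end-rule half-life class
#'
#' Estimated half-life in mammalian reticulocytes (in vitro), determined by
#' the identity of the N-terminal residue alone.
#'
#' @param seq Amino-acid string.
#' @return Character label such as `"30 hours"`.
#' @export
half_life_class <- function(seq) {
  s <- check_protein(seq)
  unname(.n_end_half_life[substr(s, 1, 1)])
}

#' Full physicochemical profile of a polypeptide
#'
#' Computes the standard ProtParam-style panel in one call: length,
#' molecular weight, elemental formula and atom total, charged-residue
#' counts, theoretical pI, instability index (with the >40 = unstable
#' convention), aliphatic index, GRAVY and N-end-rule half-life.
#'
#' @param seq Amino-acid string (length >= 2 for the instability index).
#' @return A list of class `protein_profile`.
#' @export
protein_profile <- function(seq) {
  comp <- composition(seq)
  ii <- instability_index(seq)
  structure(list(
    length = comp$length,
    molecular_weight = molecular_weight(seq),
    formula = comp$formula,
    atom_total = comp$atom_total,
    negative_count = comp$negative_count,
    positive_count = comp$positive_count,
    pI = isoelectric_point(seq),
    instability_index = ii,
    instability_class = if (ii > 40) "unstable" else "stable",
    aliphatic_index = aliphatic_index(seq),
    gravy = gravy(seq),
    half_life_class = half_life_class(seq),
    residue_counts = comp$residue_counts),
    class = "protein_profile")
}

#' @export
print.protein_profile <- function(x, ...) {
  cat("Protein profile\n")
  cat(sprintf("  residues          %d\n", x$length))
  cat(sprintf("  molecular weight  %.1f Da\n", x$molecular_weight))
  cat(sprintf("  formula           C%d H%d N%d O%d S%d (%d atoms)\n",
              x$formula["C"], x$formula["H"], x$formula["N"],
              x$formula["O"], x$formula["S"], x$atom_total))
  cat(sprintf("  Asp+Glu / Arg+Lys %d / %d\n", x$negative_count,
              x$positive_count))
  cat(sprintf("  theoretical pI    %.2f\n", x$pI))
  cat(sprintf("  instability index %.2f (%s)\n", x$instability_index,
              x$instability_class))
  cat(sprintf("  aliphatic index   %.2f\n", x$aliphatic_index))
  cat(sprintf("  GRAVY             %.3f\n", x$gravy))
  cat(sprintf("  est. half-life    %s (mammalian reticulocytes, in vitro)\n",
              x$half_life_class))
  invisible(x)
}
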