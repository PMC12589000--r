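# Physicochemical constant tables for the 20 standard amino acids.
# Masses are average (not monoisotopic) residue masses in Da, i.e. the free
# amino acid minus one water; adding .water_mass to a residue sum gives the
# peptide mass, matching ProtParam-style calculators.

.aa_letters <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.water_mass <- 18.0153

.aa_residue_mass <- c(
  A = 71.0779, C = 103.1429, D = 115.0874, E = 129.1140, F = 147.1738,
  G = 57.0513, H = 137.1393, I = 113.1576, K = 128.1723, L = 113.1576,
  M = 131.1960, N = 114.1026, P = 97.1152, Q = 128.1292, R = 156.1857,
  S = 87.0773, T = 101.1039, V = 99.1310, W = 186.2099, Y = 163.1732)

# Residue elemental composition (C, H, N, O, S), free amino acid minus water.
.aa_formula <- matrix(c(
  # C   H   N  O  S
    3,  5,  1, 1, 0,  # A
    3,  5,  1, 1, 1,  # C
    4,  5,  1, 3, 0,  # D
    5,  7,  1, 3, 0,  # E
    9,  9,  1, 1, 0,  # F
    2,  3,  1, 1, 0,  # G
    6,  7,  3, 1, 0,  # H
    6, 11,  1, 1, 0,  # I
    6, 12,  2, 1, 0,  # K
    6, 11,  1, 1, 0,  # L
    5,  9,  1, 1, 1,  # M
    4,  6,  2, 2, 0,  # N
    5,  7,  1, 1, 0,  # P
    5,  8,  2, 2, 0,  # Q
    6, 12,  4, 1, 0,  # R
    3,  5,  1, 2, 0,  # S
    4,  7,  1, 2, 0,  # T
    5,  9,  1, 1, 0,  # V
   11, 10,  2, 1, 0,  # W
    9,  9,  1, 2, 0   # Y
), nrow = 20, byrow = TRUE,
  dimnames = list(.aa_letters, c("C", "H", "N", "O", "S")))

# Kyte-Doolittle hydropathy scale.
.kyte_doolittle <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3)

# Aliphatic-index side-chain weights (Ikai): AI = X(A) + a X(V) + b (X(I)+X(L))
.aliphatic_weights <- c(A = 1.0, V = 2.9, I = 3.9, L = 3.9)

# Ionizable-group pKa sets. "bjellqvist" is the ProtParam-style set,
# including its residue-specific terminal pKa adjustments (the N-terminal
# amine pKa depends on the first residue; the C-terminal carboxyl shifts
# when the last residue is D or E); "emboss" is the alternative used by the
# EMBOSS iep tool, without terminal adjustments.
.pka_sets <- list(
  bjellqvist = list(
    positive = c(Nterm = 7.5, K = 10.0, R = 12.0, H = 5.98),
    negative = c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0),
    nterm_by_residue = c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82,
                         V = 7.44, E = 7.7),
    cterm_by_residue = c(D = 4.55, E = 4.75)),
  emboss = list(
    positive = c(Nterm = 8.6, K = 10.8, R = 12.5, H = 6.5),
    negative = c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1),
    nterm_by_residue = numeric(0),
    cterm_by_residue = numeric(0)))

# N-end rule half-lives, mammalian reticulocytes in vitro (ProtParam table).
.n_end_half_life <- c(
  A = "4.4 hours", R = "1 hour",     N = "1.4 hours",  D = "1.1 hours",
  C = "1.2 hours", E = "1 hour",     Q = "0.8 hour",   G = "30 hours",
  H = "3.5 hours", I = "20 hours",   L = "5.5 hours",  K = "1.3 hours",
  M = "30 hours",  F = "1.1 hours",  P = ">20 hours",  S = "1.9 hours",
  T = "7.2 hours", W = "2.8 hours",  Y = "2.8 hours",  V = "100 hours")
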