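---
title: "mevax: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mevax: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mevax` implements the computational core of an in silico multi-epitope
mRNA vaccine design workflow for tumor-specific antigens: epitope triage,
HLA population-coverage mathematics, a convolutional regressor for 5'UTR
mean ribosome load, construct assembly and parsing, protein
physicochemical profiling, and codon-level sequence metrics. This
vignette documents the models, the parameters that matter, the synthetic
data the pipeline is tested on, and the design decisions taken where the
problem was genuinely open.

## Synthetic inputs and what they stand for

The real workflow consumes outputs of web predictors (epitope scores,
antigenicity, allergenicity, toxicity), curated HLA allele-frequency
snapshots and a massively parallel polysome-profiling library. None of
these are reproducible offline, so `mevax` ships generators that emulate
their statistical structure with known ground truth:

* `gen_epitope_candidates()` draws per-class candidates (linear B-cell
  16-mers, MHC-I cytotoxic 9-10-mers, MHC-II helper 15-mers) with a
  Bernoulli `should_pass` label; scores are then drawn from Gaussians
  truncated on the correct side of each filter threshold, so the decision
  boundaries of the filter are exercised and the observed pass fraction
  concentrates binomially around the target.
* `gen_allele_world()` draws per-region, per-locus allele frequencies
  scaled to a total mass at most 1 — the residual is an explicit null
  allele binding nothing — and a random epitope-to-allele binding map in
  which each epitope targets exactly one locus.
* `gen_mrl_library()` draws uniform-composition UTR sequences (default 50
  nt, the fixed-length regime of published reporter libraries) and
  assigns each a mean ribosome load (MRL)

  $$\mathrm{MRL} = b_0 - b_1\,\#\mathrm{uAUG} - b_2\,\#\mathrm{uORF}
    + b_3\,\mathrm{Kozak} - b_4\,\lvert \mathrm{GC}-0.5\rvert
    + \varepsilon, \qquad \varepsilon \sim N(0, \sigma^2).$$

  Defaults $b = (0.8, 0.25, 0.35, 0.1, 0.6)$ with $\sigma = 0.1$ make
  upstream start codons and upstream ORFs the dominant negative
  regulators, which is the mechanism this screen is designed around: a
  scanning 43S pre-initiation complex captured by an upstream AUG — worse
  still, one that opens a reading frame with an in-frame stop inside the
  UTR — fails to initiate at the main start. The Kozak term scores the
  context the UTR offers its downstream start codon: +1 when the −3
  position (the UTR's third-to-last base) is a purine; the +4 position
  belongs to the coding sequence and is assumed canonical. Every record
  keeps its generative components (`uaug_count`, `uorf_count`,
  `kozak_score`, `gc`, `mrl_true`), so recovery can be tested: ordinary
  least squares on the generated table returns the coefficients within
  estimation error, and a sequence-only model can be scored against the
  noise-free signal.

What the generators do *not* emulate: the empirical score distributions
of any particular predictor, linkage between HLA loci, length/GC biases
of real UTR libraries, or polysome-measurement noise structure. Passing
tests on this synthetic world therefore demonstrate that the
*computational machinery* is correct and recoverable, not that any
biological prediction is accurate.

## Epitope triage

`filter_policy()` encodes the class-specific rules: B-cell and helper
epitopes need antigenicity ≥ 0.5; cytotoxic epitopes face a stricter
antigenicity bound (> 0.7), an MHC-I percentile-rank bound (< 1.0, lower
is better) and a conservation bound (> 0.8); helper epitopes a
conservation bound (> 0.85); all classes must be non-allergenic and
non-toxic. The open/closed orientation of each bound is stored explicitly
because the source conventions are mixed (the B-cell antigenicity bound
is closed, the class-I bounds are strict); `filter_epitopes()` returns a
per-candidate audit of every rule so rejections are traceable. Top-k
retention by prediction score (`select_top_k()`, default k = 5) applies
to B-cell candidates only, per antigen, with lexicographic tie-breaking
for reproducibility. The filter is monotone (relaxing a threshold never
shrinks the retained set) and idempotent; both are property-tested.
Conservation is consumed as an input column on a 0-1 scale — computing it
(e.g. from phylogenetic profiles) is out of scope.

## Population coverage

For one locus, an individual's genotype under Hardy-Weinberg equilibrium
is an unordered allele pair with probability $2f_af_b$ ($a \ne b$) or
$f_a^2$. The number of epitope/HLA combinations the individual presents
is the number of distinct (epitope, allele) pairs across the two alleles
— a homozygote's combinations are counted once, following the
"combinations" reading; the alternative (count both copies) is isolated
behind `locus_hit_pmf()` should anyone want it. Unaccounted frequency
mass becomes an explicit null allele binding nothing. Loci are treated as
independent and their hit distributions convolved (`combine_loci()`).

`coverage_metrics()` reports coverage $=1-p(0)$, the expected hits per
individual, and pc90, the minimum number of combinations recognized by
90% of the population. For pc90 we interpolate the survival function
$S(h) = P(\mathrm{hits} \ge h)$ linearly between integer hit counts; in
the regime where coverage < 90% this reduces to $0.1/(1-\mathrm{coverage})$,
which reproduces the published regional reports' fractional pc90 column
exactly (e.g. coverage 89.13% → pc90 0.92), and pc90 is 0 when coverage
is 0. When coverage ≥ 0.9 the largest integer $h$ with $S(h) \ge 0.9$ is
returned. Regional summaries use the arithmetic mean and the *population*
standard deviation (divisor $n$): that is the convention that reproduces
the published summary row (divisor $n-1$ does not), and it is asserted in
the tests.

`coverage_oracle()` is a brute-force cross-check that enumerates every
multi-locus genotype with its probability and tallies hits directly, with
its own metric arithmetic; the convolution path must agree to $10^{-9}$
on randomized small worlds. Absolute regional coverage values of any
published report depend on the frequency snapshot behind it and are not a
target here; the summary statistics of the packaged report are.

## The 5'UTR ribosome-load regressor

Architecture: three 1D convolutions with ReLU activations — the first two
with `filters` channels, the third reducing to a single channel — then
two fully-connected layers (hidden width `fc_hidden`, one output node)
on the flattened per-position map. Inputs are position-by-channel
embeddings: one-hot (4 channels) by default, or precomputed
language-model embeddings (e.g. 640-dimensional per-position vectors)
consumed from an id-indexed store; the embedding model itself is never
run here, and a declared-dimension mismatch is an error.

Choices the architecture leaves open, and our defaults: kernel 8 with
same-padding and no pooling; mean-squared-error loss; adaptive-moment
(Adam) optimizer at learning rate $10^{-3}$, batch 128; 50 epochs with an
8:2 train/validation split; best-epoch selection by validation R².
Variable-length sequences are right-padded with zero rows to
`max_length`; no padding mask is used. Targets are centered on the
training mean (restored at prediction).

Several numerical safeguards deserve note because the single-channel
third convolution makes the network fragile: a lone ReLU channel can die
— early optimizer steps push its (initially uninformative) variance to
the ReLU floor, after which no gradient reaches the convolutional stack.
We therefore (i) initialize that channel's bias well inside the active
regime (+2), (ii) zero-initialize the output layer, so gradients reach
the convolutions only along directions already correlated with the
target, (iii) rescale each convolution's weights at initialization to
unit pre-activation variance on a calibration batch (one-hot inputs are
sparse, so fan-in-based scaling alone leaves the activation scale
strongly kernel- and width-dependent), (iv) clip the global gradient
norm at 1, and (v) warm the learning rate up over the first four epochs
(factors 0.1/0.25/0.5/0.75 of the configured rate). All five are
standard remedies; without them training collapses to the constant
predictor for a substantial fraction of seeds, and at learning rate
2×10⁻³ and above the collapse is systematic.

The training loop is written as one GEMM per layer over an
offset-concatenated weight layout plus shifted block additions (the
im2col matrix is never materialized), with the inner kernels compiled
(`src/conv1d.cpp`). Gradients are verified against finite differences in
the tests.

On the noiseless synthetic library the sequence-only ceiling is R² = 1 by
construction. The local terms (uAUG count, Kozak, GC) are learned
quickly; the uORF term is intrinsically long-range — whether an upstream
AUG is closed by an in-frame stop can depend on bases tens of
nucleotides downstream — and is where residual error concentrates. The
synthetic-recovery experiment in the acceptance suite runs n = 5000
sequences with one-hot embeddings; its companion null experiment
(labels shuffled before training) must stay near zero, showing the model
cannot manufacture signal. Metrics (`regression_metrics()`) satisfy
rmse² = mse to $10^{-9}$ by construction and are asserted to.

Candidate screening builds a 222-sequence pool from four sources (212
variable-length literature-style candidates and 8 Kozak-context variants,
both synthetic stand-ins; the alpha-globin 5'UTR; a BNT162b2-type
vaccine leader), predicts MRL for each, and ranks descending with id
tie-breaks; the ranking is verified against a sort oracle.

## Construct assembly

The construct grammar, 5'→3': m7G cap, 5'UTR, Kozak `GCCACCAUGG`,
signal peptide, `GPGPG`-joined helper block (one GPGPG after the signal),
`KK`-joined B-cell block (one KK before the first), `AAY`-joined
cytotoxic block (one AAY before the first and one before the MITD), the
MHC class I trafficking domain, UAA stop, 3'UTR, 120-nt poly(A). For the
published inventory (18 + 6 + 12 epitopes) this yields 18 GPGPG, 6 KK
and 13 AAY linkers, which `validate_construct()` checks. An optional
rigid `EAAAK` spacer can be inserted between the signal peptide and the
first GPGPG; the realized published construct does not use one there, so
it is off by default.

Decisions where the sources are silent or inconsistent:

* The tPA signal peptide (`MDAMKRGLCCVLLLCGAVFVSPS`) and the MITD (the
  HLA class I transmembrane/cytoplasmic trafficking domain) are
  literature defaults — construct listings print them only as "tPA" and
  "MITD" — and are configurable blueprint fields.
* The initiator methionine is the signal peptide's own first residue,
  encoded by the AUG inside the Kozak motif. Frame correctness then
  forces the Kozak's trailing G to be the first base of the second
  residue's codon, so that residue must admit a G-starting codon (the
  default signal's Asp does; violations are an error). The resulting
  length identity, asserted in the tests, is
  $|\mathrm{mRNA}| = |\mathrm{UTR5}| + 3|\mathrm{protein}| + 9 +
  |\mathrm{UTR3}| + \mathrm{polyA}$ — the 9 covering `GCCACC` and the
  stop codon. A naive "Kozak plus whole codons" layout is one base out
  of frame; we prioritized a translating ORF over that simpler
  arithmetic.
* Epitopes containing a linker motif as a substring are rejected at
  assembly: allowing them would make the construct string ambiguous to
  parse, and parse unambiguity (the assemble→parse round trip is
  property-tested) was preferred over permissiveness.
* The parser segments linker-delimited blocks using per-class epitope
  lengths carried in the blueprint (defaults 15/16/9-10); 9- versus
  10-mer cytotoxic epitopes are disambiguated by looking ahead for the
  next linker.

Published full-construct size and mass values are not reproduction
targets: the printed epitopes plus linkers are not consistent with any
single segment set we can derive, so which segments the published
physicochemical run included is indeterminate. The profile is instead
reported for both the full construct and the epitope core.

## Protein physicochemistry

ProtParam-compatible conventions throughout: average (not monoisotopic)
residue masses plus one water; elemental formulas as residue sums plus
H₂O; pI by bisection of the Henderson-Hasselbalch net charge over the
termini and D/E/C/Y/H/K/R side chains with the Bjellqvist-style pKa set,
including its residue-specific terminal adjustments (the N-terminal
amine pKa depends on the first residue, the C-terminal carboxyl on a
terminal D/E; an EMBOSS-style set is a flag away). The bisection narrows
the pH interval to $10^{-4}$ — stopping on a small |charge| instead is
wrong for strongly buffered peptides, where the charge curve is nearly
flat around the root — and the returned root leaves |net charge| ≤ 0.01,
asserted exhaustively over all 8000 tripeptides. The instability index
uses the 400-entry Guruprasad dipeptide weight table shipped in the
package source; values above 40 are labelled unstable, the standard
convention (note that published reports sometimes label such values
"stable"; we report the number and the standard label). Aliphatic index
and GRAVY are the usual closed forms; half-life is the N-end-rule lookup
(mammalian reticulocytes, in vitro) on residue 1. All calculators are
checked against a committed 10-peptide reference panel computed once
with an independent implementation (MW to 0.01 Da, pI to 0.01, II/AI/
GRAVY to $10^{-3}$).

## Codon metrics

CAI is the geometric mean of relative synonymous-codon adaptiveness
$w = f/f_{\max}$ against a packaged human codon-usage snapshot
(frequencies per thousand codons; any table with the same two columns can
be substituted — only within-family ratios matter). Terminal stops are
excluded; internal stops and length-indivisible sequences are errors;
single-codon families contribute $w = 1$.

`optimize_codons()` offers two strategies: `max_cai` (each family's top
codon; CAI of the output is exactly 1 by construction) and `gc_balance`
(greedy per-residue choice minimizing the running deviation from 50%
GC). The greedy balancer is myopic, so per-protein dominance over
`max_cai` is not guaranteed — on random proteins it wins on average and
never loses by much, which is what the tests assert. The conventional
mRNA-design GC window of 45-55% is reported and flagged, not enforced:
practical designs routinely land above it.

The structure proxy is Nussinov base-pair maximization (Watson-Crick
plus G·U wobble, minimum hairpin loop 3) implemented as a compiled
$O(n^3)$ dynamic program capped at 2000 nt — beyond that a real
thermodynamic folding tool is the right instrument, and the error says
so. The DP is verified against exhaustive enumeration of all nested
pairings on short sequences, and Watson-Crick-only scores are
reverse-complement symmetric by construction (also asserted). Pair
counts order candidate ORFs by structure content; they are not free
energies, and no thermodynamic claim is attached.

## Problem sizes and determinism

Every stochastic stage is a pure function of its seed: generators of
their spec, the train/validation split of its seed, training of the
model seed (initialization and batch order). The analysis scripts and
the acceptance script re-derive everything from scratch at fixed seeds;
the test suite runs the CNN at reduced width (32-64 filters rather than
the 120-filter default) and n = 5000 training sequences, sizes chosen so
the full suite completes comfortably on a single CPU while leaving the
synthetic-recovery margins wide. The oracle cross-checks (coverage
enumeration, Nussinov enumeration, sort oracles, finite-difference
gradients) are exact and independent of those sizes.

## Known limitations

* The synthetic world is deliberately simple; no claim about real
  predictor outputs, real HLA linkage or real ribosome-load data follows
  from green tests here.
* The CNN's single-channel bottleneck limits what the convolutional
  stack can express about long-range uORF structure; with one-hot inputs
  at n = 5000 the validation R² on noiseless data plateaus well below
  the theoretical ceiling of 1, driven almost entirely by the uORF term.
* CAI depends on the usage snapshot; swap the table for another organism
  or source before comparing absolute values.
* The base-pair proxy ignores stacking, loop entropies and
  pseudoknots; it ranks, it does not fold.
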