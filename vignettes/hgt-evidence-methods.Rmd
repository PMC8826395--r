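---
title: "Methods: divergence, composition and clock evidence for horizontal gene transfer"
author: "hgtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: divergence, composition and clock evidence for horizontal gene transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgtrace)
```

# The problem

When a gene tree conflicts with the species tree — say, an animal enzyme
family whose closest relatives are cyanobacterial — three explanations
compete: many independent gene losses under vertical descent, endosymbiotic
gene transfer (EGT) through the proto-mitochondrion, and a later horizontal
gene transfer (HGT). `hgtrace` implements four quantitative lines of
evidence that discriminate among them, each runnable end to end on seeded
synthetic data with known truth:

1. an **accumulated genetic divergence (AGD)** statistic over homolog
   triples, with control panels and z outlier tests;
2. a **k-mer signature scan** that flags compositionally anomalous genomic
   segments (candidate transferred or misattributed regions);
3. **synapomorphy typing** of peptidylarginine deiminase (PADI)-like
   sequences from diagnostic residue states;
4. a **calibrated strict-clock root-age estimator**.

The motivating case is the PADI (peptidylarginine deiminase) family:
calcium-dependent enzymes that citrullinate peptidyl-arginine, present in
animals, some cyanobacteria, some actinobacteria and fungi, and almost
nowhere else.

# Bit-score density and AGD

For query $q$ and target $t$, the bit-score density is

$$ D(q, t) = \frac{\mathrm{bits}(q, t)}{\mathrm{bits}(q, q)} \in [0, 1], $$

a length-normalized similarity with $D(q,q) = 1$. Bit scores come from a
Smith–Waterman local alignment under BLOSUM62 (gap open 11, extend 1; a gap
of length $L$ costs $\mathrm{open} + L\cdot\mathrm{extend}$; `X` scores 0
against everything) passed through the Karlin–Altschul transform
$\mathrm{bits} = (\lambda\,S - \ln K)/\ln 2$ with the standard gapped
BLOSUM62 parameters $\lambda = 0.267$, $K = 0.041$. The original analysis
used profile-search bit scores from an external tool; the built-in pairwise
scorer is a deterministic, self-contained substitute, and `agd_from_scores()`
accepts externally computed bit scores for users who prefer the profile
route. Only the optimal score is ever used, never a traceback, so DP ties
need no resolution.

Given a protein with homologs in a **reference** taxon (human in the
motivating study), a **bridge** taxon (*Branchiostoma*, spanning the deepest
animal divergence available) and a **distal** taxon (a cyanobacterium), with
the reference as the query in both comparisons,

$$ \mathrm{AGD} = D(\mathrm{ref}, \mathrm{bridge}) - D(\mathrm{ref}, \mathrm{distal}). $$

Under vertical descent the distal homolog has accumulated divergence over
the full host–bacterium timescale, so AGD is large; a family transferred
from the distal lineage into the reference/bridge clade shows similar
densities on both comparisons and AGD near zero. The source text's
subtraction sentence reads in the opposite order, which would make conserved
proteins negative; since the values it prints (ribosomal mean 0.70, PADI
0.07) are positive divergences, this package orients AGD as
bridge-density minus distal-density. Swapping bridge and distal negates the
statistic.

A control **panel** (e.g. the 26 vertically inherited ribosomal proteins
shipped in `panel_members()`) is summarized by mean, sample (n−1) standard
deviation, and a Shapiro–Wilk normality test (via `stats::shapiro.test`,
Royston approximation; normality retained at $p > 0.05$). A candidate's AGD
is then tested with a one-tailed lower z test, $z = (x - \bar x)/s$,
$p = \Phi(z)$. One-tailed is the default because the alternative of interest
is directional (too little divergence); the corresponding two-tailed p would
be twice as large.

# K-mer signature scan

The genome signature is the L1-normalized frequency vector of all $4^k$
k-mers (`k = 4` by default, i.e. tetranucleotides). "Unit vector" is read as
frequencies summing to one — the count total is the stated normalizer — with
L2 normalization available as an option. K-mers are counted on the given
strand only (no reverse-complement canonicalization), matching the original
analysis's silence on strand handling; windows containing `N` skip the
affected words.

`sliding_scan()` scores each 1 kb window (500 bp step) by the summed
absolute difference between the window spectrum and the genome-average
spectrum; the score lies in $[0, 2]$. Windows are emitted only where a full
window fits; windows more than half `N` are reported unscored. Coordinates
are 0-based half-open throughout (BED convention). The genome average
includes the window under test — excluding it is asymptotically identical
and complicates the rolling computation.

The original analysis inspected these deviation profiles visually;
`flag_anomalies()` is an explicit extension that turns them into calls:
windows whose robust z-score $(s - \mathrm{median})/\mathrm{MAD}$ exceeds 5
are flagged and merged into intervals. If the MAD is zero (featureless
scores) it falls back to a strict 99th-percentile rule with a warning, which
flags nothing when all scores are equal.

# Synapomorphy typing

Diagnostic residues are addressed in 1-based ungapped human-PADI2
coordinates, mapped onto alignment columns by `build_column_map()`. The
shipped rule table (`residue_rules()`) encodes, as severity-critical
diagnostics: the calcium switch D389 (glycine, metal-incompetent, in the
two-domain actinobacterial/fungal "Bi" type), the calcium-site-6
conservative substitutions D125→N and E131→D, and the triple-histidine motif
at 300–302 that marks the Bi connector beta-sheet (the "Ai" side of that
rule is "anything but H", encoded with the `!` token). Catalytic/substrate
residues (D351, H471, D473, C647) are `conserved` rules: reported, expected
everywhere, and never used to separate the types. Region rules (155–180,
292–302, 369–389) are advisory only; the exact residue composition of
calcium sites 2 and 4 is shown only graphically in the source material, so
those sites are left to user curation rather than guessed.

A sequence is `Ai_like` when every critical diagnostic matches its Ai state
and none matches a Bi state, `Bi_like` in the mirror case, `ambiguous`
otherwise — including when any rule position is gapped (a gap makes that
member unevaluable rather than a mismatch). Per-group consensus
(`conservation_report()`) follows the one-or-two-amino-acid convention: one
shared state prints the letter, exactly two print `X/Y`, three or more print
`nc`.

The shipped demonstration alignment (`make_padi_demo_alignment()`) is
synthetic: seeded random background divergence around the documented
diagnostic states. It exercises the machinery; it is not PADI sequence data.

# Strict-clock dating

`fit_strict_clock()` is a penalized weighted least-squares stand-in for a
Bayesian relaxed-clock analysis. On a fixed rooted topology with branch
lengths $b_i$ in substitutions/site, it minimizes

$$ \sum_i \frac{(b_i - r\,\tau_i)^2}{\max(b_i, \varepsilon)} +
   \sum_c \frac{(t_c - \mu_c)^2}{\sigma_c^2} $$

over one rate $r$ and internal node ages $t$ (tips fixed at 0, parent ≥
child), where $\tau_i$ is the branch duration and the calibrations
$(\mu_c, \sigma_c)$ are normal node-age priors. Branch variance is
approximated as proportional to branch length (Poisson-like), floored at
$\varepsilon = 10^{-6}$. Optimization alternates a closed-form rate update
with coordinate-wise clamped age updates from a deterministic
initialization (depths scaled so calibrated nodes match their means),
stopping when a sweep changes the objective by less than
$10^{-10}(1 + \mathrm{obj})$. This tests the logic — can a clock plus
fossil calibrations date a root? — not any particular MCMC implementation;
tree inference, relaxed clocks and tree priors are out of scope. The six
fossil calibrations used in the motivating analysis (deepest mean 797.0 Ma,
sigma 72.5; shallowest 89.5, sigma 3.0) ship verbatim in
`default_calibrations()`, keyed by full species names because two of the
original two-letter abbreviations collide.

`root_age_interval()` is a residual bootstrap. Three numerical choices
matter and were made after measuring their effect on interval coverage in
simulation (8 taxa, root 900 Ma, rate $10^{-3}$, 10% multiplicative branch
noise, truth-centered calibrations on the three deepest non-root nodes with
sigma 5% of age):

* residuals are standardized by the branch standard deviation
  $\sqrt{\max(b,\varepsilon)}$ before resampling and rescaled to the target
  branch — raw-residual resampling creates zero-length pseudo-branches whose
  $1/\varepsilon$ weights destabilize the refit;
* refits keep the weights of the *observed* branches (fixed-design WLS
  bootstrap) for the same reason;
* standardized residuals are inflated by $\sqrt{n/(n-p)}$ with $p$ = number
  of internal nodes + 1, since the clock fit shrinks its own residuals.
  Without the correction, measured coverage of the 95% interval was 69–79%;
  with it, 87%.

By default the bootstrap resamples branch residuals only, so a perfectly
clock-like input yields a degenerate interval. With
`resample_calibrations = TRUE` each replicate also redraws calibration means
from $N(\hat t_c, \sigma_c)$, propagating calibration uncertainty; measured
coverage under the conditions above is then 97%, and this mode is the right
one whenever the question is "does the interval cover the truth".

# Synthetic data

`simulate_family()` evolves a uniformly drawn root sequence along an
ultrametric species tree under the 20-state Poisson model: substitution
events arrive at the per-My rate and each event moves to one of the 19 other
states uniformly. This model is deliberately simple — its pairwise expected
difference has the closed form
$\tfrac{19}{20}\bigl(1 - e^{-\frac{20}{19} r t}\bigr)$, and its stationary
distribution is uniform, both of which the tests verify against simulation.
There is no indel model (the AGD statistic operates on fixed-length
families) and no empirical exchangeability matrix; an empirical-matrix
option is a natural extension point. HGT replaces the recipient lineage's
sequence with the donor lineage's sequence at the transfer time; EGT is the
same mechanism placed at the recipient clade's stem, mirroring the treatment
of EGT candidates as anciently transferred genes.

The default AGD study conditions (`agd_species_tree()`) are a
reference–bridge split at 700 Ma (chordate scale), distal divergence at
2700 Ma (host–cyanobacterium scale under vertical descent), rate
$2.2\times10^{-4}$ subs/site/My and 300-residue families. The rate is chosen
so the distal comparison remains alignable (about 33% identity — roughly
where highly conserved proteins sit over this timescale, and the regime the
AGD statistic was designed for: only very conserved proteins yield a
measurable distal bit score at all). Vertical panels use 26 families,
matching the size of the ribosomal control panel; HGT scenarios transfer at
750 Ma, just before the reference/bridge radiation.

`simulate_genome_with_island()` draws i.i.d. host bases and inserts an
island of distinct composition with 0-based half-open truth coordinates.
Default island conditions for recovery tests: 100 kb uniform-composition
host, 5 kb island at 80% G+C. I.i.d. backgrounds are cleaner than real
genomes — no repeats, no skew gradients, no genes — so a passing recovery
test shows the scan and flagging logic work, not that real islands of
arbitrary composition contrast are detectable; conversely the deviation
statistic makes no assumption the i.i.d. model would hide.

What passing tests show, and what they do not: the simulators contain
exactly the signal the statistics target (a transferred sequence, a
composition contrast, a clock), so the tests are parameter-recovery and
calibration checks. Real data add alignment error, rate heterogeneity
across sites and lineages, base-composition structure, and profile-vs-
pairwise scoring differences; none of those are emulated here.

# Survey tabulation

`filter_hits()` keeps hits strictly below E-value $10^{-3}$;
`drop_fragments()` removes sequences shorter than 450 aa (450 is retained).
`survey_table()` counts each species once per group (exact string identity;
no taxonomy service) and rounds percentages half-up — the convention that
reproduces every published row, e.g. 56/506 → 11.07 — at 2 decimals by
default, per-row configurable because the published virus row prints 3
(0.001).

# Problem sizes used by the shipped checks

The test suite and acceptance script run: 200 random pairs (length ≤ 30)
against the brute-force alignment oracle; 1000 pairs for density bounds;
50 genomes for k-mer recount equality; 26 vertical + 50 HGT families of
300 aa for AGD discrimination; 25 genomes of 105 kb for island recovery;
100 coverage replicates × 100 bootstrap refits on 8-taxon trees; one
10,000-site two-taxon family for the closed-form calibration. These sizes
give stable pass/fail behavior at conventional seeds while keeping a full
run in the low minutes on one core.

# Limitations

* The pairwise local-alignment bit score is not a profile bit score; AGD
  values from the built-in scorer are comparable with each other but not
  numerically with profile-search outputs (use `agd_from_scores()` there).
* The strict clock assumes one global rate; rate variation across lineages
  biases the root estimate in ways only a relaxed clock would absorb.
* `flag_anomalies()` thresholds are heuristics over an intentionally
  threshold-free scan; flagged intervals are candidates for phylogenetic
  follow-up, not taxonomic assignments.
* The 20-state Poisson model understates the realism of empirical
  substitution processes; it trades realism for exact, testable
  expectations.
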