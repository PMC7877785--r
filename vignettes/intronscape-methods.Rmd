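---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(intronscape)
```

This vignette documents the scientific models behind `intronscape`, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical and design decisions a maintainer would want to
know about.

## The system and the genotype space

The package analyses variation at eight intron positions, N2..N5 and
N18..N21, flanking the 5' splice site of a group I intron embedded in a
kanamycin-resistance reporter. These positions pair with each other to form
the 4-bp P1 extension helix (P1ex: N2-N21, N3-N20, N4-N19, N5-N18). After
cleavage at the 5' splice site the right half dissociates from P1ex, and
intron positions 15-20 pair with the first bases of the 3' exon to form the
6-bp P10 helix that aligns the 3' splice site. N18..N20 therefore act in
both helices; selection on them is pleiotropic.

Genotypes are stored as DNA (`A,C,G,T`) because sequencing reads and the
construct sequence are DNA; RNA display (`U` for `T`) is purely a formatting
option (`gt_format(..., rna = TRUE)`). The canonical text form is
`"LLLL-RRRR"`; the parser accepts the form with or without the hyphen. The
master genotype is `AGGT-ACAT`, the high-activity Tet-119(C20A) variant; its
P1ex profile is 1 strong, 2 weak, 1 unpaired rung (G3.A20 is the mismatch),
and exactly two single mutations (G3T, A20C) complete the helix.

Wobble policy: whether a G.T (G.U) rung counts as "weak", separate, or
non-pairing in `pair_profile()` is genuinely ambiguous in this assay's
conventions, so it is exposed as `wobble_policy` on `p1ex_scheme()`, with
`separate_class` as the default.

## Forced-helix energetics

Helix stabilities are computed from primary sequence by forcing the helix
closed: each helix is evaluated as an artificial hairpin — 5' strand, six
undefined loop nucleotides, 3' strand — with every rung paired whether or
not the bases are compatible:

* P1ex: `N2 N3 N4 N5` + `NNNNNN` + `N18 N19 N20 N21`, bracket
  `((((......))))`.
* P10: exon strand `GGUCGU` + `NNNNNN` + intron strand `ACG N18 N19 N20`,
  bracket `((((((......))))))`.

The P10 geometry deserves a note. The construct was designed so that intron
positions 15-20 (`ACG` + N18 N19 N20 in the master numbering) base-pair
with the start of the 3' exon; the exon partner strand `GGUCGU` is the
Watson-Crick complement of the designed intron strand. N21 sits outside
P10, directly at the splice-site pair. This geometry — three fixed rungs,
three variable — is also the only one consistent with the observed
degeneracy of the energy spectrum: across the 4^4 right-half genotypes only
4^3 distinct helices exist, collapsing to 21 unique energies. Both strands
and the orientation are stored in the `helix_spec` (`p10_helix()`), not
hard-coded in the evaluator, so alternative transcriptions can be swapped
in.

The energy function is a nearest-neighbor model over the forced rungs, in
exact integer units of 0.01 kcal/mol:

* published Turner 2004 stacking free energies (37 °C) for each adjacent
  pair of canonical rungs (Watson-Crick and G.U wobble), shipped as an
  inspectable TSV (`inst/extdata/turner2004_stacks.tsv`); the lookup
  convention is `stack(i -> i+1) = table[type_i, reverse(type_{i+1})]`;
* hairpin initiation for the 6-nt undefined loop (5.40 kcal/mol), with a
  −0.50 kcal/mol closing term when the closing rung is G.C — the mismatch
  term loop evaluators apply against undefined loop bases;
* a terminal A-U penalty (0.50 kcal/mol) at *every end of every contiguous
  canonical segment*: a forced mismatch interrupts the helix, and each
  resulting sub-helix carries its own terminal penalties (A.U/U.A only);
* a flat penalty of 7.10 kcal/mol per forced non-canonical rung, with zero
  stacking across such rungs.

Established folding engines do not document how they score forced
non-canonical pairs, and their lumped treatments give far fewer distinct
values than the reference counts for this space (the installed ViennaRNA
evaluator, used during development to fix the stacking, hairpin and
terminal-penalty conventions, yields 131 unique P1ex values). The policy
terms above — segment-terminal penalties, the closing-G.C term, and the
non-canonical penalty — were therefore calibrated so that the model
reproduces the reference unique-value counts exactly: **211** unique P1ex
energies over 4^8 genotypes and **21** unique P10 energies over 4^4. The
penalty has a second, physical role: fully mismatched "helices" end up at
+28 to +34 kcal/mol, so they always occupy the least-stable rank bins, as
forced pairing of incompatible bases should.

Integer arithmetic makes unique-value counting exact and platform
independent; energies are only converted to numeric kcal/mol at the API
boundary. Because forced energies of mismatch-containing helices are not
physically meaningful as quantities, downstream analyses use them as
*ordered ranks*: `stability_rank_bins()` ranks unique values by increasing
stability and partitions them into near-equal bins of unique values (ties
can never straddle a bin); `landscape_surface()` reports median fitness per
(P1ex bin × P10 bin) cell and flags empty cells as `NA` rather than zero.

## The two-state generative fitness model

The simulator's ground truth encodes the three constraints that structure
the real landscape, as a product:

$$w(g) = w_0\; \mathrm{band}(s_1)\;\sigma\!\left(\frac{s_{10}-\theta_{10}}{\tau_{10}}\right)\,
\delta^{[\mathrm{C2}\wedge \mathrm{C21}]}\; e^{\sigma_g Z_g},$$

where \(s_1 = -\Delta G_{\mathrm{P1ex}}\), \(s_{10} = -\Delta G_{\mathrm{P10}}\)
(kcal/mol), \(\sigma\) is the logistic function and
\(\mathrm{band}(x) = \sigma((x-\theta_{lo})/\tau)\,(1-\sigma((x-\theta_{hi})/\tau))\).

* the **P1ex band** (must form, must not be too stable): `theta_lo = -20`,
  `theta_hi = 0`, `tau = 1` kcal/mol. These were set once from the energy
  spectrum so that the master (`s1 = -11.8`) sits well inside the band,
  fully mismatched helices (about `-34`) fall below it, and perfect
  Watson-Crick helices (up to `+5.1`) fall above it — over-stable P1ex
  cannot dissociate to let P10 form;
* the **P10 benefit**: `theta10 = -8`, `tau10 = 1`, mid-range of the
  21-value P10 spectrum (`-22.6` to `+6.6`), so single P10 mismatches are
  tolerated but two or more are strongly deleterious;
* the **splice-site geometry defect**: `delta = 0.1` multiplies fitness
  when cytosines occupy both N2 and N21 (the pair adjacent to the splice
  site), emulating the minor-groove deformation seen for that genotype;
* **genotype noise**: lognormal with `sigma = 0.2`, representing
  unmodelled genotype-specific biology;
* **temperature**: at 37 °C `theta_hi` is raised by +2 kcal/mol — kinetic
  traps are easier to escape at the higher temperature, so the
  excess-stability penalty is milder. This makes fitness defects milder on
  average at 37 °C while preserving ranks (the simulated between-temperature
  rank correlation is ~0.93).

All of these are `two_state_params()` arguments; the defaults above are the
package's fixed study conditions. The master's fitness is rescaled to
exactly 1.

Emergent properties of this model, verified by the tests: the master sits
in the top 2% of the landscape; median fitness decreases monotonically with
Hamming distance; the DFE is bimodal (dead class: no P10 pairing or no
P1ex); the two-axis stability landscape shows the ridge — fitness rising
with P10 stability and collapsing in the most-stable P1ex bins; pairwise
epistasis around the master is enriched for positive values (a fitness
ceiling plus thresholded constraints give diminishing returns), more so
within N18..N21 than within N2..N5; and the mirror correlation is low
(asymmetric constraint). Two published real-data directions do **not**
emerge from this generator and are documented rather than asserted: the
overall GC-count/fitness correlation is ~0 (G/C at N19/N20 is exactly what
enables P10 pairing; the negative, selection-against-stability direction
holds within fully paired P1ex helices), and the N18..N21 gain share
exceeds the permutation-null mean but not its 97.5th percentile (see
Attribution below).

## The selection-experiment simulator

`sim_config()` fixes the study conditions: 6 replicates, 2×10^6 reads per
sample, library-skew rate `lambda = 0.1`, pure multinomial sampling
(`phi = 0`) by default.

* **Library**: sampling weights `lambda^d(g)` emulate the overlap-extension
  mutagenesis protocol, in which oligos closer to the template amplify
  better; the expected read share at distance d is
  `C(8,d) (3 lambda)^d / (1+3 lambda)^8` (29.4% at d = 1 for the default).
  The experiment's actual skew is not quantified, so `lambda` is an
  illustrative default and the estimator tests exercise the pipeline at
  the coverage this skew induces.
* **Selection**: one fitness-weighted multinomial resampling per replicate,
  weights `n_pre(g) w(g)`, re-sequenced at constant depth. Gamma-multinomial
  overdispersion (`phi > 0`) is available to model extra-Poisson replicate
  scatter.
* **Reads**: `write_amplicon_fastq()` emits the 204-bp amplicon layout —
  38-nt 5' constant region, N2..N5, the constant 12-nt loop, N18..N21, then
  the 3' constant region. The primer-adjacent constant regions are the real
  ones; the internal 68 nt of the 3' constant region are a synthetic filler
  (`AMPLICON_FILLER_SYNTH`), since genotype calling never touches them.
  Per-base substitution errors and the quality string are configurable.

Everything derives deterministically from `seed`; FASTQ output is
byte-identical across runs. What the simulator does *not* emulate: PCR
jackpotting and chimeras, batch or lane effects, unequal sample depths,
indels, cryptic splice-site artefacts, and multi-generation competition
(selection is a single resampling step). Passing the recovery tests
therefore shows the estimator is correct under clean multinomial noise, not
that it is robust to every artefact of real libraries.

## Counting

`parse_amplicons()` anchors each forward read by an exact-or-1-mismatch
match of the 5' constant region at the read start and reads the eight
targeted bases at fixed offsets (no indel tolerance — the library is
substitution-only by construction). A read is discarded only if a targeted
base is `N` or below Phred 30; backbone bases are deliberately not
filtered, since stringent backbone filtering discards many reads for no
gain in genotype accuracy. Genotypes are called from the forward read
alone (all eight sites lie within 58 bases of the anchor); the reverse
read of the 204-bp amplicon does not reach the variable region at 100-bp
read length. Per-sample QC (reads seen / anchored / passed) travels with
each count vector.

## Fitness estimation

The estimator is a transparent stand-in for heavier count-based frameworks
(differential-abundance shrinkage estimators or DMS-specific error
models), chosen because the two published approaches agree closely on this
kind of data and because a simple estimator can be validated directly
against simulated ground truth:

* per replicate r:
  `s_r(g) = ln[(n_post(g)+c)/(n_post(wt)+c)] − ln[(n_pre(g)+c)/(n_pre(wt)+c)]`,
  with Poisson error propagation `var_r = Σ 1/(n+c)` over the four counts;
* combination: inverse-variance weights; the nominal
  `se = 1/sqrt(Σ w_r)` is inflated by `max(1, chi²/(R−1))` when replicate
  scatter exceeds the Poisson expectation;
* `f = exp(s)` rescaled so `f(master) = 1` exactly; two-sided z-test on
  `s/se` with Benjamini-Hochberg adjustment;
* alongside: a pooled log2 fold-change on median-of-ratios-normalised
  counts (the differential-abundance view of the same data), used as the
  default response for the attribution model.

Pseudocount `c = 0.5` everywhere (keeps zero counts finite; standard DMS
practice; exposed as an argument). Genotypes with zero pre-selection
counts in all replicates are reported as missing (`NA`), never as fitness
0 — absence of evidence is not lethality. Size factors follow the literal
median-of-ratios definition (median over all-nonzero genotypes of
count/geometric-mean), which matches the standard implementation up to its
convention of not rescaling; a unit test cross-checks against
`DESeq2::estimateSizeFactorsForMatrix`.

Calibration, verified in the acceptance tests at the fixed study
conditions (6 replicates, depth 2×10^6, noise-free landscape): Spearman
rho ≥ 0.9 between estimated and true fitness over genotypes with a mean
pre-selection count of at least 50 reads per replicate, and a BH-adjusted
type-I error ≤ 5% under a null (w ≡ 1) experiment (empirically far below,
as Poisson propagation is conservative for multinomial sampling). The
coverage filter is per-replicate-mean by design: genotypes at 25 reads per
replicate with near-zero true fitness yield all-zero post counts, which no
estimator can rank.

## Diversity and DFE statistics

Shannon diversity (natural log) and Bray-Curtis dissimilarity are computed
with `vegan` (`diversity`, `vegdist`), the standard ecology
implementations; skewness and kurtosis are the plain moment formulas
(kurtosis non-excess, i.e. a normal distribution scores 3). Bimodality of
the DFE is summarised by a two-component Gaussian mixture on log fitness
(`mclust`, unequal variances with an equal-variance fallback) and reported
as component means/sds/weights plus Ashman's D
(`|mu1−mu2| / sqrt((s1²+s2²)/2)`), with `bimodal = D > 2` — a simple,
sufficient summary for a qualitative claim, deliberately not a formal dip
test.

## Epistasis

Pairwise epistasis uses relative fitness (master = 1):
`epsilon = log10(f_wt f_m12 / (f_m1 f_m2))`. Records with missing or
non-positive fitness are excluded, never clipped — clipping would
manufacture epistasis. The complete double-mutant map of the master has
252 records: 54 within N2..N5, 54 within N18..N21, 144 cross-helix;
`partitioned_epistasis()` compares the class distributions by rank-sum
tests.

`gamma_correlation()` operationalises the correlation of fitness effects
as: for each single mutation m and each background g at Hamming distance d
from the reference that carries the reference base at m's site, correlate
(Pearson) the effect of m in the reference with its effect in g, on log
fitness (the additivity scale consistent with epsilon's log form), pooling
all (m, g) pairs at that distance. gamma(0) = 1 by construction and
log-additive landscapes give gamma ≡ 1 — both are tested analytically.

The mirror test correlates `f(g)` with `f(mirror(g))` where the mirror
reflects bases across the helix axis. A geometric fact constrains the
equal-distance design: the reference and its mirror differ at all eight
sites, so a genotype at distance d from the reference has its mirror at
distance ≥ 8−d; the set {d(g) = d(mirror(g)) = d} is empty below d = 4.
The default is therefore d = 4 (27 unordered pairs in the complete space,
self-mirrors excluded). The published mirror analysis reports rho = 0.21
(N = 19) at a nominal d = 2; that selection cannot be reconstructed from
the stated definition and is retained as a documentation reference only.

## Attribution

`train_gbm()` fits gradient-boosted regression trees (`xgboost`, RMSE
objective, `colsample_bytree = gamma = 1`) on the 32 one-hot
site/nucleotide features, with a 2/3-1/3 train/test split and 5-fold
cross-validated grid search on the training split. The default grid is a
reduced, fast subset (nrounds 100/200, eta 0.1/0.3, depth 4/6); the
complete grid (nrounds up to 1000, eta down to 0.01, depth up to 10,
subsample 0.5-1, min-child-weight 5-20) sits behind
`attr_config(full_grid = TRUE)` — desk-feasible but slow. All seeds come
from the config; xgboost runs single-threaded for reproducibility.
Higher-level features (GC count, helix energies) are deliberately not in
the default model: binary identity features keep all 32 features directly
comparable, and the tree model recovers the emergent structure from them.

SHAP values are the tree-path-dependent exact contributions
(`predict(..., predcontrib = TRUE)`); local accuracy (base value + sum of
contributions = prediction) is asserted in the tests at 10^-6 of the
response scale. `delta_shap()` aggregates to mean-present minus
mean-absent per feature. `gain_share_test()` compares the observed share
of total gain carried by a site region against the null obtained by
permuting the 32 per-feature gains (features never split on count as
gain 0), reporting the null mean, 2.5/97.5 percentiles and a permutation
tail probability.

A power caveat discovered on the synthetic landscape and worth knowing
when interpreting this test: when gains concentrate on a few features (here
the top feature carries ~20% of total gain), the permutation null becomes
very wide, and an observed share can exceed the null mean by a large margin
yet stay inside the 95% band. On the simulated experiment the N18..N21
share is ~0.58 against a null mean of ~0.49 with a null 97.5th percentile
of ~0.75 — the pleiotropy direction is reproduced, its permutation
significance is not. `leave_one_replicate_out()` retrains on fold-changes
from R−1 replicates and scores against the held-out replicate's own
fold-change; single-replicate responses are noisier, so this accuracy is
expected to sit below the pooled held-out accuracy (0.64 vs 0.75 on the
simulated experiment).

## Numerical choices and degenerate inputs

* Energies: integer 0.01 kcal/mol throughout; unique-value counting and
  tie handling are exact; `n_bins` larger than the number of unique values
  degrades gracefully to identity binning.
* Enumeration is guarded at 12 sites (16.7M genotypes) to prevent
  accidental memory blowups.
* `pairwise_epsilon`/`gamma`/`mirror_test` return `NA` (with counts) when
  inputs are undefined or too few, never a clipped or imputed value;
  constant features in correlations are flagged rather than propagated as
  `NaN`.
* Spearman correlations use midranks for ties (base R `cor`).
* Simulation randomness: each stage seeds its own stream from the config
  seed (library, selection, noise, FASTQ shuffling are offset by fixed
  increments), so stages are individually reproducible.

## Problem sizes used by the tests

The test suite and the acceptance script run the complete 65,536-genotype
space for the energy, landscape and epistasis analyses; simulated
experiments use 6 replicates at 2×10^6 reads per sample (5×10^5 for the
null-calibration run); attribution tests train on samples of 1,500-4,000
genotypes with a fixed single hyperparameter point, while the acceptance
attribution model trains on the full space. These sizes are the package's
chosen study scale: large enough that every qualitative claim is measured
on the same space as the analysis, small enough to run comfortably on a
laptop.

## Known limitations

* The forced-helix energy model is calibrated to reproduce the reference
  spectrum *counts*; absolute energies for mismatch-containing helices are
  rank-meaningful only.
* The generator is a three-factor caricature: it encodes no kinetics, no
  cryptic splice sites, no G5-specific effect outside P1ex, and its
  GC-count correlate and gain-share significance differ from the real
  data's, as noted above.
* Real-data quantities (published fitness tables and accuracy bands)
  require the deposited reads (SRA PRJNA636762) and are out of scope.
* The fitness estimator deliberately omits dispersion-trend fitting and
  shrinkage; with very few replicates its dispersion inflation is a crude
  guard, not a calibrated hierarchical model.
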