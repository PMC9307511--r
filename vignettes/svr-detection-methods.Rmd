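---
title: "Detecting structurally variable regions in structure-probing data: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting structurally variable regions in structure-probing data: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svrscan)
```

This vignette is the package's own account of the statistics it implements:
the normalization model, the scan statistic and its Monte-Carlo calibration,
the conformation-mixture simulator, and the places where the design was
genuinely open and a choice had to be made.

## The data and the problem

A structure-probing (SP) experiment yields, per transcript and replicate, a
vector of per-nucleotide reactivities; high reactivity indicates an
unpaired, flexible nucleotide.  Given $n_A$ replicates in condition A and
$n_B$ in condition B on a shared coordinate system, the task is to report
*structurally variable regions* (SVRs): intervals where the underlying
structure, hence the reactivity distribution, differs between conditions —
with family-wise control of false region calls.

Two obstacles shape the design.  First, conditions differ systematically in
sequencing depth and signal-to-noise ratio, so raw reactivities are not
comparable between conditions.  Second, SVR lengths vary over two orders of
magnitude, so any fixed window length either dilutes short signals or
truncates long ones; scanning all window lengths creates strongly dependent
multiple tests.

## Normalization

Three steps, applied per transcript:

1. **Winsorize and rescale, per replicate.**  Values below the 5th
   percentile are set to it and above the 95th to it (90% winsorization),
   then the vector is min-subtracted and divided by its new maximum, so
   every replicate lives on $[0,1]$.  Percentiles are empirical quantiles
   with linear interpolation (R type 7) — continuous in the data.  A
   profile that is constant after clipping is mapped to all zeros rather
   than raising an error: it carries no structural information.

2. **Quantile normalization within conditions.**  Replicates of one
   condition are forced to share a value distribution.  With equal
   non-missing counts this is the classic construction (each k-th order
   statistic replaced by the mean k-th order statistic).  Missing data make
   the counts unequal, so we interpolate: each replicate's empirical
   quantile function is evaluated on a common probability grid, averaged,
   and the mean quantile function is read back at each replicate's own
   plotting positions $(k - 0.5)/m$.  This reduces exactly to the classic
   construction when counts are equal, preserves ranks within a replicate,
   and leaves missing positions missing.

3. **Between-condition anchoring.**  A *pivot set* $S$ of structurally
   invariant positions anchors a log-linear transform
   $\log \bar r^A_j \sim \log\alpha + \beta \log \bar r^B_j$, $j \in S$,
   fitted robustly and extrapolated to all positions:
   $\tilde r^B = \exp(\widehat{\log\alpha} + \hat\beta \log r^B)$, with
   condition A unchanged.  $\log\alpha$ absorbs depth differences, $\beta$
   signal-to-noise differences.

### Why the robust fit is symmetric

The fit relates two *noisy* quantities: both $\log \bar r^A_j$ and
$\log \bar r^B_j$ are sample means over a handful of replicates.  A plain
regression of one on the other is therefore attenuated toward zero by
errors-in-variables (regression dilution): in null simulations with three
replicates per side the one-directional Huber slope centers near 0.84 where
the truth is exactly 1.  An attenuated slope is not a cosmetic problem — it
compresses condition B's dynamic range, so every block of high- or
low-reactivity positions (and pairing status is blocky) acquires a
systematic A-vs-B difference, which the scan then calls.  In our null
experiments this single bias drove the family-wise error rate from the
nominal 0.05 to 0.4.

The package therefore fits a *reweighted robust standardized major axis*:
Huber IRLS (tuning constant 1.345 robust-scale units, MAD residual scale,
convergence when coefficients move less than $10^{-8}$, at most 50
iterations) in the forward direction; a reverse-direction slope computed
under the forward fit's final Huber weights, so gross outliers identified
as residual outliers cannot re-enter as leverage points; the symmetric
slope $\hat\beta = \mathrm{sign} \cdot \sqrt{b_{yx}/b_{xy}}$; and a Huber
M-location intercept of $y - \hat\beta x$.  Under equal error variances
this estimator is consistent where the one-directional fit is not; with a
noiseless predictor it agrees with the one-directional fit; and it retains
Huber robustness (in simulations with 10% gross one-sided outliers it
recovers $(\log\alpha, \beta)$ with mean absolute error below 0.05 while
ordinary least squares does not).

### The pivot screen

The pivot set can be supplied from prior knowledge (`pivot =` argument,
used verbatim).  Otherwise it is found by an iterative screen: positional
Wilcoxon p-values (window radius 2) are computed on the current data,
positions with $p < 0.25$ are excluded, the transform is refitted on the
remainder and condition B re-transformed, and the screen repeats until the
set stabilizes or 5 iterations.  The loose 0.25 threshold deliberately
over-excludes: the cost of dropping invariant positions from the fit is
small (the fit has two parameters), while including truly variable
positions biases the anchor.  If the screen empties the pivot the pipeline
stops and asks for an explicit pivot rather than guessing.

Log-domain details: pivot positions enter the fit only when both condition
means exceed $10^{-3}$ (after step 1 the minimum of every replicate is
exactly 0, so zeros always exist).  When the transform is extrapolated,
values at or below $10^{-3}$ pass through *unchanged* instead of being
floored into the formula: flooring would lift exact zeros to
$\approx \alpha 10^{-3\beta}$, manufacturing a difference between
conditions precisely at the least informative positions, and would break
the identity-transform property on identical inputs.

## The scan

**Positional tests.**  For each position $j$, reactivities of all
replicates over the window $C_j = [j-r, j+r] \cap [1, n]$ (default radius
$r = 2$, truncated at transcript ends) are pooled per condition and
compared with a two-sided Wilcoxon rank-sum test.  The test is exact (via
the null Mann-Whitney distribution) when both pooled samples have at most
10 tie-free values, otherwise a normal approximation with tie and
continuity corrections — the same conventions as `stats::wilcox.test`,
against which the implementation is tested.  Identical pooled samples give
$p = 1$ (no mid-p), keeping $p \in (0, 1]$ as the scan statistic requires.
A position needs at least 3 pooled values per condition to be testable
(below that the rank test is vacuous); untestable positions are missing and
no candidate region may span them.

**Scan statistic.**  $Q(R) = (-\sum_{j\in R}\log p_j)/\sqrt{|R|}$ (natural
log) over every region with $L_{\min} \le |R| \le L_{\max}$ (defaults 1 and
100 nt; stride 1).  The $\sqrt{|R|}$ penalty is what lets regions of
different lengths compete on one scale: under the uniform null the
numerator has standard deviation proportional to $\sqrt{|R|}$, so the
penalty equalizes the null fluctuation scale across lengths, and extending
a region past its true boundary costs more than the diluted evidence adds.

**Monte-Carlo calibration.**  The global null is taken literally as
$p_j \sim \text{i.i.d. } U(0,1)$: for each of $B$ draws (default 1000;
minimum 100) an $n$-vector of uniforms is drawn and the maximum of $Q$ over
all candidate regions recorded.  A region's p-value is the add-one
estimator $(1 + \#\{T_b \ge Q\})/(B+1)$ — never exactly zero, bounded below
by $1/(B+1)$ — and regions with $p \le \alpha$ are significant.  Because
the reference distribution is the *maximum* over all candidate regions,
this controls the family-wise error rate across the overlapping windows of
a transcript.  Reported SVRs are a greedy non-overlapping subset of the
significant regions, in order of decreasing $Q$ (ties: longer region, then
smaller start).

Two honest caveats.  First, neighbouring positional p-values are positively
correlated (windows share $2r$ of their $2r+1$ positions), which the
i.i.d. null ignores.  In practice the positional p-values from real pooled
rank tests are discrete and conservative, and in our calibration
experiments the pipeline's realized FWER stays below nominal (see the
acceptance suite); a `null_type = "permutation"` mode — permute replicate
condition labels, recompute the positional tests, take the max — is
provided as a sensitivity analysis that preserves the dependence.  Second,
FWER is controlled per transcript by default; `global = TRUE` additionally
Bonferroni-corrects $\alpha$ across transcripts.

**Null reuse.**  The null depends on $n$ only through the candidate-region
count, so transcript lengths are binned on a 5% geometric grid, rounded
*up* (a longer null transcript has more regions, hence larger maxima —
conservative), and one null per bin is cached and reused across transcripts
and runs.

**Nucleotide ranking.**  For top-k evaluation curves every position gets a
total order: positions inside called SVRs first, by covering-region $Q$
(descending) then positional p; remaining positions by positional p,
untestable last.  The underlying ranking rule for such curves is not
uniquely determined by the method; this one is consistent with the calls by
construction (top-k for k = total called length returns exactly the called
positions).

## The simulator

The generator emulates the conformational-ensemble view of structural
variation: a transcript occupies a mixture of $K = 10$ conformations, and a
condition change shifts the mixture weights rather than flipping a single
structure.

- **Conformations.**  Pairing-status vectors come from a two-state Markov
  chain (self-transition $1 - 1/\texttt{mean\_run}$, default mean run 6 nt
  — helix-like blocks).  Conformation 1 is the reference; each other
  conformation copies it and resamples shuffled geometric-length blocks
  until 40% of positions are covered, giving $\approx 20\%$ expected
  disagreement between conformations 1 and 2 (block selection is by
  cumulative covered length, not per-block coin flips, so the disagreement
  rate concentrates instead of occasionally collapsing toward 0).  Maximal
  runs of conformation-1-vs-2 disagreement are the ground-truth SVRs.
- **Weights.**  90% of the weight sits on conformations 1 and 2, split
  $(0.4, 0.5)$ vs $(0.5, 0.4)$ ("low" signal), $(0.3, 0.6)$ vs
  $(0.6, 0.3)$ ("medium"), $(0, 0.9)$ vs $(0.9, 0)$ ("high"), or equal in
  both conditions ("null"); the remaining 10% is split uniformly at random
  over conformations 3..10, shared between conditions.  Each replicate
  perturbs the two leading weights with $N(0, 0.1^2)$ noise; negative
  components are clipped to 0 and the vector renormalized (the clipping
  rule is ours; some handling of invalid weights is unavoidable and this
  one keeps the simplex geometry).
- **Reactivities.**  Conditional on pairing status, draws come from
  pluggable status-conditional models: a Gamma pair for SHAPE-like data
  (paired mean 0.08, unpaired mean 0.72), a zero-inflated Beta pair for
  icSHAPE-like data on $[0,1]$, and a degenerate "point" model for
  closed-form tests.  These parameterizations are synthetic stand-ins
  chosen for qualitative shape (nonnegativity, unpaired stochastically
  dominating paired, realistic overlap); they are not fits to any published
  training set.  The observed reactivity is
  $\sum_c w_c x_{c,j}$ with a *fresh* draw per conformation, replicate and
  position; sharing draws across replicates would create artificial
  replicate correlation that the mixture description does not require.

What passing tests on this generator do **not** show: the simulator has no
sequence-dependent reactivity bias, no coverage gradient along transcripts,
no correlated missingness, and replicate noise enters only through mixture
weights and independent draws — real SP data violate all four.  Results on
the simulator demonstrate the statistical machinery (calibration, power
ordering, recovery), not platform-specific performance.

## Numerical and default choices

| Parameter | Default | Why |
|---|---|---|
| winsorization | 5th/95th pct | tames outliers while keeping 90% of data untouched |
| window radius $r$ | 2 nt | 5-nt window: enough pooled values for a rank test, little blurring |
| `min_obs` | 3 per condition | below that the rank test cannot reach interesting levels |
| $L_{\min}, L_{\max}$ | 1, 100 nt | single-nucleotide variants are real; 100 covers the simulated SVR range |
| $\alpha$ | 0.05 | conventional family-wise level |
| $B$ | 1000 (500 in studies) | add-one p resolution $1/(B+1)$; studies trade resolution for runtime |
| screen p | 0.25 | loose on purpose; see pivot screen |
| pivot floor | $10^{-3}$ | keeps the log-domain fit away from $-\infty$ |
| Huber constant | 1.345 | standard 95%-efficiency tuning |
| null length bins | 5%, rounded up | bounded cache, conservative at bin edges |

Degenerate inputs: all-missing replicates are rejected; constant profiles
rescale to zero; transcripts with a single replicate per condition skip
quantile normalization (identity); `l_max` beyond the transcript length is
clamped; `Jaccard(∅, ∅)` is defined as 0; an empty prediction reports the
average distance as not applicable rather than 0.

The test and calibration studies in this package use transcripts of
100–300 nt, 2–4 replicates per condition, $B = 500$, 200 null runs and
20-seed power grids — sizes at which every statistical property under test
(FWER below nominal, power ordering low < medium < high, parameter
recovery) is already stable.

## Known limitations

- The positional test is nonparametric by design; when a platform's
  reactivity distribution is known, a parametric positional test would buy
  power.
- Replicate structure is ignored by the pooled rank test (values from the
  same replicate are treated as exchangeable with values from another).
- The i.i.d. uniform null ignores window-induced dependence; the realized
  error rate is below nominal in our experiments, but the calibration is
  indirect.  The permutation mode exists precisely to check this on a given
  dataset.
- The data-driven pivot screen fails in the extreme case where nearly all
  positions vary structurally; supply a pivot from prior knowledge there.
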