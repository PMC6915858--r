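---
title: "Inferring ploidy sequences from gene-triplet profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring ploidy sequences from gene-triplet profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgdtriplets)
```

## The model

A genome's paralog-similarity distribution is modelled as the outcome of
two stacked processes.

**Branching with fractionation.**  Each of $G$ independent root genes
passes through $m$ polyploidy events.  At event $i$ a gene is replaced by
$r_i \in \{2, 3\}$ progeny (WGD or WGT), of which $j \ge 1$ survive to
the next event with probability $p_j^{(i)}$; total loss is conditioned
away, because a lineage with no survivors leaves no trace in the data.
In the traditional two-event notation $u = p_2^{(1)}$, $u' = p_3^{(1)}$,
$v = p_2^{(2)}$, $v' = p_3^{(2)}$.  The probability of an aggregated
trajectory is a product of multinomial coefficients and survival-power
terms (`trajectory_probability()`), and the full set of survivor-count
configurations of one root can be enumerated exhaustively
(`enumerate_genealogies()`).  Because children subtrees are
exchangeable, the package enumerates *unordered* configurations and
folds the orbit size into the weight; the weights sum to 1 exactly.

**Gaussian divergence.**  Every extant pair of paralogs within a root
carries a divergence event: the first event at which the two lineages
separated.  Its percent similarity is modelled as normal,
$x \sim N(\mu_e, \sigma_e^2)$, with older events at lower means.

A *triplet* is a set of three genes pairwise present in the similarity
graph; its *type* is the multiset of the three pairwise divergence
events, e.g. $\{t_1, t_1, t_2\}$.  Under the ultrametric branching
process the two youngest divergences of a triple always share their
oldest divergence, so a type is realizable only when its smallest event
index occurs at least twice; all other types are structural zeros.  For
$m$ events there are $m(m+1)(m+2)/6$ types (4, 10, 20 for $m$ = 2, 3, 4)
and $2^m$ candidate ploidy sequences.

Expected per-root triplet counts $W_M(\Delta)$ are available by three
independent routes that agree to $10^{-10}$ and are cross-checked in the
test suite:

* `method = "closed"` — the tabulated polynomials for 2- and 3-event
  models, transcribed model by model;
* `method = "enumeration"` — classify every leaf triple in every
  enumerated genealogy and weight by its probability;
* `method = "product"` — per-event factors multiplied out for any $m$:
  with leaf factor $e_i = E[\text{survivors}]$, pair factor
  $q_i = E[\text{surviving pairs}]$ and triple factor $s_i =
  E[\text{surviving triples}]$ per gene,
  $W(\{a,a,a\}) = \prod_{i<a} e_i \, s_a \prod_{i>a} e_i^3$ and
  $W(\{a,a,b\}) = \prod_{i<a} e_i \cdot 2 q_a \cdot \prod_{i>a} e_i
  \cdot \prod_{a<i<b} e_i \, q_b \prod_{i>b} e_i^2$.

The enumeration is capped at four events and guarded by a configuration
count: four-event schedules containing two or more triplings exceed any
reasonable cap, and the product route (which the cap message points to)
is exact for them.

## From underlying to predicted profiles

The underlying profile is not observable: the similarity components
overlap, so a data triple classified as one type may have been generated
by another.  The chain to a comparable prediction is:

1. **Mixture fit** (`fit_mixture()`): EM for a $k$-component univariate
   Gaussian mixture.  Initialization is deterministic — quantile-spaced
   means, pooled sd, equal proportions — so fits are reproducible with
   no seed.  Selected means can be pinned (`fixed_means`), the device
   used when two old events are too conflated to separate freely.
   Component sds are floored at $10^{-3}$; identical-valued input is
   rejected.  The log-likelihood trace is stored and is non-decreasing.
2. **Transition points** (`ml_transition_point()`): the cutoff $H$
   between two adjacent components maximizes the product of the lower
   component's full normal density over $x \le H$ and the upper one's
   over $x > H$.  As printed, the objective contains the densities only
   — no mixture proportions — and the package keeps that form.  The
   objective is piecewise constant with jumps exactly at data values, so
   the default search walks the data breakpoints and returns the
   midpoint of the maximal plateau (a `grid_step` grid search is
   available as an option; the breakpoint search equals an infinitely
   fine grid).  A similarity exactly at $H$ is assigned to the older
   event, a convention the printed inequalities leave open.
3. **Observed profile** (`extract_triples()`, `observed_profile()`):
   triangles of the filtered pair graph, each similarity classified by
   the cutoffs, ordered outcomes collapsed into type multisets.
4. **Covariance** (`estimate_triplet_covariance()`): per event, the
   variance of that event's similarities across triples and the
   within-triplet covariance of same-event pairs; cross-event covariance
   is fixed at 0 on Markov grounds.  The source description of this
   estimator is garbled ("triplets containing at least of them"); the
   package reads it as the within-triplet covariance between two
   same-event similarities, estimated from triples containing at least
   two of them, with a triple of three same-event similarities
   contributing all three unordered pairs (a first-pair-only variant is
   behind a flag).  Occurrences are counted with multiplicity by
   default; `unique_values = TRUE` switches to distinct values.
5. **Prediction** (`predicted_profile()`): for each underlying type, a
   trivariate normal with component means and the assembled covariance
   is integrated over every classification cell; cell masses collapse
   into categories, are weighted by $W_M(\Delta)$, summed, and rescaled
   so the total matches the observed triple count.
6. **Ranking** (`compare_profiles()`): the source says only "closest
   fit"; the package ranks by $\sum (O-E)^2 / \max(E, 0.5)$ (scale-aware
   and finite at structural zeros) and reports the L1 distance
   alongside, always as a full table.

### Numerical choices

* **Rectangle probabilities.**  Cross-event covariance is zero, so the
  3×3 covariance is block diagonal by event with blocks of dimension at
  most 3.  Each block is integrated by conditioning on the leading
  coordinates with Gauss–Legendre quadrature (96 nodes); the integrands
  are smooth and effectively compactly supported, so convergence is
  spectral and self-converged to machine precision (the test suite
  cross-checks against an independent integrator).  A fixed-seed
  Monte-Carlo fallback (10⁶ draws) exists for pathological inputs and
  warns when used.  No MVN package from the declared environment is
  needed at run time; `mvtnorm` serves only as the test oracle.
* **PSD repair.**  An empirically assembled covariance can fail positive
  semi-definiteness; off-diagonals are shrunk by 0.9 iteratively until
  the smallest eigenvalue clears $-10^{-10}$ (diagonal fallback after
  200 rounds), and the repair is logged.
* **Percent scale.**  All similarities and cutoffs live on the 0–100
  scale end to end; the printed objective's $h \in (0,1)$ is the same
  quantity rescaled.

## Parameter estimation

The survival probabilities are described in the source only as "maximum
likelihood values" with no procedure.  The package matches the observed
per-event pair counts and a gene count to $G$ times the per-root
expectations by bounded least squares on relative error (moment matching
standing in for ML), with multi-start L-BFGS-B and a derivative-free
polish; exact expectations are inverted to $10^{-6}$.  A
likelihood-based refinement is behind `method = "ml"`: independent
Poisson likelihoods on the same observables.  (A pure multinomial over
pair-event categories, as one might first write down, is underdetermined
for two events — one free proportion against two parameters — which is
why the Poisson form was chosen.)

Two gene-count conventions are exposed because a pair list cannot show
genes with no surviving paralog: `genes = "paired"` (default in the
pipeline) matches the observed paralog-bearing gene count against
$G\,(\prod_i e_i - \prod_i p_1^{(i)})$; `genes = "all"` is the full
inventory $G \prod_i e_i$ for callers who know it.

The squared constraint $u' = u^2$ at triplings (a necessity when pair
data constrain only one parameter per event) is on by default and caps
$u$ at $(\sqrt5 - 1)/2$ so that $p_1 \ge 0$; it can be switched off
wherever three-survivor probabilities are separately identifiable.

## What the generator emulates — and what it does not

`simulation_config()` states the package's default world: schedule
(3,2), $u = 0.3$, $v = 0.4$ with the squared constraint, $G = 20000$,
components $N(71, 4^2)$ and $N(90, 3^2)$ — values taken from the worked
example this package is tested against; they produce realistically
overlapping components (transition point near 82 %).  The generator
draws genealogies per the survival probabilities, labels every
within-root pair by its divergence event, draws each pair's similarity
independently from its event's component truncated to (0, 100] (redraw
up to 100 times, then clamp), and can add uniform low-similarity
background pairs and >98 % contaminants to exercise the exclusion
filters.

It does *not* emulate: correlated similarities along a triangle's edges
(each pair is drawn independently, so the within-triplet covariance of
real data, which the prediction step estimates, is essentially zero in
simulated data); synteny-block geometry or block-limited triangle
formation; tandem arrays; non-Gaussian divergence; rate variation across
the genome.  A green end-to-end test therefore establishes that the
chain of estimators is consistent under the stated model, not that the
model captures every feature of a real genome.

## Degenerate inputs and edge behaviour

* Pair lists: self-pairs are dropped with a count; duplicate unordered
  pairs keep the maximum similarity with a warning; similarities outside
  (0, 100] are errors.
* `filter_pairs(p, low, high)` keeps the half-open window
  $(\text{low}, \text{high}]$.
* An event with fewer than two classified similarities falls back to the
  mixture sd with zero covariance, logged.
* All-zero pair counts are unidentifiable (error); a single zero count
  drives that event's survival to the boundary 0 with a warning.
* Ties in the transition-point objective resolve to the plateau
  midpoint, never silently to an endpoint.

## Known limitations

Closed forms stop at three events; the enumeration cap excludes
tripling-heavy four-event schedules (the product route covers them).
Model selection across *different* event counts (AIC/BIC) is out of
scope, as is everything upstream of the pair list (synteny detection,
$K_s$ computation) and cross-genome ortholog analysis.
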