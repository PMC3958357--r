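---
title: "Data-driven subgrouping from directed functional connectivity: models and methods"
author: "gimmeclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-driven subgrouping from directed functional connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Clinical neuroimaging samples are heterogeneous: individuals sharing a
diagnostic label can carry quite different patterns of directed functional
connectivity, and averaging over them blurs every pattern. `gimmeclust`
organizes a sample of individuals into data-driven subgroups using only
their resting-state connectivity maps: it first estimates a directed
connectivity map per individual, then clusters individuals by the
similarity of their shared connection weights, with every analytic choice
(in particular the similarity threshold) made from the data rather than by
the analyst.

## The individual-level model: a unified SEM

Each individual's ROI time series $y_t \in \mathbb{R}^p$ is modeled as a
lag-1 structural vector autoregression ("unified SEM"),

$$ y_t = A\,y_t + \Phi\,y_{t-1} + \zeta_t,\qquad
   \zeta_t \sim \mathcal{N}(0, \Psi),\ \Psi \text{ diagonal}, $$

where $A$ (zero diagonal) holds contemporaneous directed paths,
$\Phi$ holds lagged paths with the autoregressive (AR) effects on its
diagonal, and $(I-A)$ must be invertible. Including the lagged paths is
what renders the contemporaneous estimates unbiased and their directions
identifiable; the contemporaneous weights are in turn the features used
for subgrouping, since they carry most of the neuronally interpretable
signal in BOLD-like data.

Estimation is maximum likelihood on the lag-embedded sample covariance of
$[y_{t-1}, y_t]$ pairs, with the lagged block treated as saturated
(exogenous). Pairs spanning a missing frame — e.g. a motion-scrubbed scan
kept as an `NA` placeholder row — are dropped, so scrubbing never breaks
temporal ordering. With $\Psi$ diagonal, the residual variances profile
out analytically and the fit reduces to minimizing

$$ G(A,\Phi) \;=\; \sum_{i=1}^p \log V_{ii}(A,\Phi)\; -\; 2\log\lvert\det(I-A)\rvert, $$

where $V_{ii}$ is the sample variance of the $i$-th structural residual
$u = (I-A)y - \Phi y_{-1}$. The optimizer is BFGS with analytic gradients,
started from per-equation least squares; for recursive (acyclic) patterns
the ML solution coincides with equation-wise least squares, which the test
suite exploits as an oracle. The model $\chi^2$ is $(n-1)(G - \log|S_{y|x}|)$
with $n$ the number of usable pairs. Score tests (modification indices,
MI) for every fixed path come from the analytic gradient and Hessian of
$G$; each MI estimates the $\chi^2$ drop from freeing that one element,
an approximation that is accurate for local misfits and conservative to
interpret for gross ones.

Series are **not** standardized by default. In generated data we found
that per-individual standardization couples every path weight to the
individual's stationary ROI variances; since those variances depend on the
individual's own connectivity (including paths that are irrelevant to
subgroup membership), standardization injects a shared scale factor and
carrier-specific shifts into the similarity features and visibly degrades
subgroup separation. Raw structural weights are free of this confound.
`standardize = TRUE` remains available for data whose ROI scales are not
comparable across individuals.

## The two-stage GIMME search

Fitting each individual alone invites noise paths; fitting one pooled
model denies heterogeneity. The group-iterative search threads between
them:

1. **Group stage.** Everyone starts AR-only (AR paths are freed a priori
   and never pruned — every plausible generating process for smooth
   biological signals has them). Iteratively, each individual's model is
   fitted and MIs are computed for all fixed candidate paths; a path is
   freed when the number of individuals whose MI exceeds the
   Bonferroni-corrected $\chi^2_1$ critical value reaches a proportion
   $\gamma$ of the sample (default 0.75 — a strict majority criterion).
   Among tied candidates the larger summed MI wins. For a contemporaneous
   candidate, the two orientations of the same pair are never freed in
   one step: the count qualifies the *pair*, and the orientation with the
   larger summed MI is the one freed. Both orientations tap the same
   missing covariance, so per-individual exceedance counts are nearly
   uninformative about direction, while the MI mass concentrates sharply
   on the generating orientation; deciding by count alone occasionally
   freed reversed paths which then attracted compensatory cross-lags.
   After the search stops, any group path whose estimate is
   non-significant for more than $(1-\gamma)N$ individuals is pruned,
   worst first, refitting in between.
2. **Individual stage.** Starting from the group map, each individual
   repeatedly frees their largest-MI candidate exceeding the
   Bonferroni-corrected critical value until the model reaches excellent
   fit or no candidate qualifies, then prunes non-significant
   individual-level (never group-level) paths. "Excellent fit" is the
   conventional two-of-four rule: RMSEA $\le .05$, SRMR $\le .05$,
   CFI $\ge .95$, NNFI $\ge .95$, computed against an AR-only null model.

## Similarity network and data-driven threshold

For subgrouping, each individual contributes the vector of their
**group-level contemporaneous** path weights: these exist for everyone,
are approximately normally distributed across individuals, and exclude the
sparse individual-level paths whose heterogeneity would otherwise shred
the sample into singletons. Pearson-correlating these vectors across
individuals gives an $N \times N$ similarity matrix $X$, binarized at a
threshold $r$: $A_{ij} = \mathbf{1}\{X_{ij} \ge r\}$ (closed inequality at
the boundary; negative similarities never connect on the $[0,1]$ grid).

The threshold is chosen by scanning $r = 0, .01, \dots, 1$ and running
the randomized modularity maximization 100 times per threshold:

* **Stability.** The standard deviation of the modularity $Q$ across the
  100 runs quantifies how sensitive the solution is to the maximizer's
  random starting conditions. Where competing partitions of similar
  quality exist, runs disagree and sd$(Q) > 0$; where one structure
  dominates, every run lands on it and sd$(Q) = 0$ exactly.
* **Reachability.** The mean over individuals of the number of others
  reachable through any path. As $r$ grows the network thins; beyond some
  point it fragments and community quality is moot. The elbow is located
  geometrically: a chord is drawn from the first to the last point of the
  mean-reachability curve (x = grid index) and the grid point at maximum
  perpendicular distance from the chord marks the drop; ties break to the
  smallest index, and a perfectly linear curve has no drop (the last
  index is returned with a warning).

The selected $r^\*$ minimizes sd$(Q)$ among thresholds strictly before
the drop whose network has at least one edge; ties break to the highest
$r$, then the highest mean $Q$. The final assignment at $r^\*$ is the
modal partition across 100 fresh runs (ties to the highest $Q$).

## The modularity maximizer

Newman's modularity
$Q = \frac{1}{2m}\sum_{ij}\left[A_{ij} - \frac{k_ik_j}{2m}\right]\delta(c_i,c_j)$
is maximized by a multi-level local-moving scheme with a randomized node
visit order (the source of the run-to-run variability that the stability
criterion requires), iterated with Kernighan–Lin-style single-node
refinement and aggregated merge moves until a fixpoint, and each call
returns the best of 3 independent restarts. The restarts matter for the
threshold scan: they push the probability of missing the dominant optimum
at a cleanly structured threshold low enough that sd$(Q)$ is exactly zero
there, while thresholds with genuinely competing optima retain their
variability — precisely the contrast the selection rule keys on. On every
small test graph with clear structure the returned $Q$ equals the
exhaustive-search optimum over all partitions; randomness is drawn from
R's RNG, so `set.seed()` reproduces entire analyses. An edgeless network
yields singleton communities with $Q = 0$ and a warning.

Partitions are compared to ground truth (and across perturbations) by
maximum-weight one-to-one matching of communities on the contingency
table (a small exact assignment dynamic program); members of unmatched
communities count as misassigned.

## Robustness of the community solution

A community structure worth reporting should not hinge on a few edges.
Following the degree-preserving perturbation strategy: at each level
$\alpha \in \{0, .025, \dots, 1\}$, approximately $\alpha m$ of the $m$
edges are relocated by double-edge swaps — $(a\!-\!b, c\!-\!d) \to
(a\!-\!d, c\!-\!b)$ — which preserve every vertex degree exactly and
reject self-loops and multi-edges. Because swaps draw edges with
replacement, the swap count is calibrated as $s = -\tfrac{m}{2}\ln(1-\alpha)$
so that the *expected number of distinct relocated edges* is $\alpha m$;
level 1 uses $5m$ swaps, giving an approximately uniform draw from the
graphs with the original degree sequence. Each perturbed network is
re-partitioned by a single randomized maximization run (the network is
already binary, so there is no threshold to re-select), and compared to
the original partition by Meilă's variation of information,
$\mathrm{VI} = H(P) + H(P') - 2I(P;P')$, in bits (configurable to nats,
optional normalization by $\log_2 N$), and by the matched fraction of
reassigned vertices. A size-matched Erdős–Rényi graph provides the
baseline: its "communities" are noise, and the slightest perturbation
reassigns a large fraction of its vertices, while a real structure stays
flat until substantial perturbation.

One property of this package's simulated data deserves emphasis: because
the generator's subgroups are well separated and raw path weights are
estimated precisely at $T = 200$, the similarity network binarized at
$r^\*$ has near-complete blocks with almost no between-block edges.
Half-rewiring such a network leaves its blocks clearly detectable, so the
fraction of reassigned vertices at level 0.5 is near zero — the detected
structure is *more* robust than that of a noisier network whose blocks
are fuzzier, where mid-level perturbation typically reassigns a fifth of
the vertices. The shape of the curve (flat through mid levels, rising
toward full randomization, with the random baseline degrading instantly)
is the diagnostic; the level at which it lifts off depends on block
crispness.

## Comparing subgroups

For each group-level contemporaneous path, a one-way ANOVA tests the
omnibus subgroup effect, and one contrast per subgroup compares its mean
weight against the pooled remaining individuals (two-sample
pooled-variance *t*; the "each subgroup versus the average of the others"
comparison). False discovery rate control is applied jointly across all
path × subgroup contrasts — the most conservative family — using Storey
q-values with the smoother estimate of $\pi_0$ (Benjamini–Hochberg
selectable; with too few p-values to smooth, $\pi_0$ falls back to 1).
Verdicts at $q \le \alpha$ are `higher`/`lower` by the sign of the mean
difference, otherwise `similar`; contrasts of singleton subgroups are
flagged untestable. A conventional two-group diagnostic comparison
(per-path *t* tests with FDR across paths) is provided for reference.

## The synthetic-data generator

`simulation_design()` encodes the Monte Carlo conditions under which the
pipeline is validated. Defaults: 100 individuals in four equal subgroups,
10 ROIs, 200 scans; every ROI has AR weight 0.60; nine shared
contemporaneous paths (a chain $1\to2\to\cdots\to10$) of weight 0.50;
each subgroup shifts three of the nine by $\pm0.20$ (consecutive triples
with alternating sign patterns, so subgroups are pairwise distinct); each
subgroup owns one unique contemporaneous path of weight 0.50 carried by
any member with probability 0.5 (Bernoulli), adding individual-level
heterogeneity; process noise is unit-variance Gaussian; 200 burn-in
samples from a zero state are discarded. Series arise from the reduced
form $y_t = (I-A)^{-1}(\Phi y_{t-1} + \zeta_t)$; designs whose reduced-form
lag matrix has spectral radius $\ge 1$, or whose $(I-A)$ is singular, are
rejected at construction with the offending subgroup named.

Two generator choices were genuinely open and are worth recording:

* **Unique-path placement.** The default unique paths (6→10, 5→9, 2→6,
  4→8) target ROIs whose incident shared paths are *not* among the owning
  subgroup's deviant paths. An extra path into ROI $t$ perturbs the
  stationary variance of $t$ and hence (under standardization, or through
  any scale-dependent feature) the apparent weights of paths through $t$;
  pointing it into the subgroup's own defining region would make
  unique-path carriage mimic a subgroup split. Individual-level
  heterogeneity and subgroup identity are kept orthogonal by
  construction.
* **Subgroup count and sizes.** Four equal subgroups of 25, fully
  configurable; equal sizes make the expected accuracy granularity
  compatible with the validation targets.

What the generator does *not* emulate: hemodynamic convolution, scanner
noise and drifts, spatial structure, inter-regional delays beyond one
lag, or non-Gaussian innovations. Passing the simulation-based tests
therefore demonstrates correctness of the estimation and subgrouping
machinery under the stated generative model, not performance on real
BOLD data.

## Numerical choices and degenerate inputs

* Optimizer: BFGS, relative tolerance $10^{-10}$, at most 500 iterations,
  restarted once on non-convergence; a singular $(I-A)$ or non-positive
  residual variance during the search is handled by an objective plateau
  and, if terminal, reported as an estimation failure. Individuals who
  persistently fail are excluded with a warning and the sample size
  criterion adjusts.
* Fewer than $10p$ usable lag pairs is an error (too little data for a
  $p$-ROI model).
* Degrees of freedom: $p^2 + p(p+1)/2$ testable saturated parameters
  minus free paths and residual variances; df $= 0$ flags RMSEA/CFI/NNFI
  undefined; SRMR is computed from the standardized residuals of the
  implied current-frame and cross-frame covariance blocks.
* The elbow geometry uses grid *indices* as the x-coordinate (the grid is
  uniform, and the fixture values are defined on indices).
* Zero-variance beta vectors get undefined similarities and the
  individual is flagged; the grid ends ($r=0$ complete-ish, $r=1$ mostly
  empty) participate in the scan but an edgeless network is never
  selected.
* Test-suite problem sizes: the acceptance checks run 10 replicates of
  the full reference design; unit tests use compact designs (6 ROIs, 12
  individuals) and longer single series ($T$ = 2000–10000) where a
  convergence property is the target. These sizes were chosen to give
  each statistical assertion comfortable Monte Carlo margins.

## Known limitations

* Lag order is fixed at 1; slower hemodynamic couplings fold into the
  contemporaneous matrix.
* The score-test MI overestimates the achievable $\chi^2$ drop for
  grossly misspecified paths (it is a local approximation); the search
  only ranks candidates with it, so this affects efficiency, not
  correctness, but MI values should not be read as exact $\chi^2$ drops.
* Contemporaneous cycles are permitted whenever $(I-A)$ stays invertible,
  but heavily cyclic generating structures were not part of the
  validation design.
* Similarity uses group-level contemporaneous paths only; individuals
  whose distinguishing physiology lives in lagged or individual-level
  paths are not separable by construction.
* The robustness liftoff level depends on the crispness of the similarity
  blocks (see above); compare curves against the matched random baseline
  rather than against absolute levels.
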