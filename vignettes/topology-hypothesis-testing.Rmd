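---
title: "Testing topology hypotheses on rooted phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing topology hypotheses on rooted phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladetest)
```

## The problem

Competing scenarios for the origin of a group of organisms or viruses often
reduce to statements about tree topology: *does clade A group with clade B
to the exclusion of everything else?* For the large double-stranded DNA
viruses of eukaryotes (kingdom *Bamfordvirae* — NCLDVs, adenoviruses,
virophages, *Mavericks*/polintons and polinton-like viruses), the
"nuclear-escape" scenario predicts a sister grouping of adenoviruses and
NCLDVs, while alternative scenarios predict anything but that grouping.
Deciding between such scenarios is a model-selection problem, and this
package implements the four complementary lines of evidence used for it:

1. **Size-corrected AIC** on constrained maximum-likelihood fits: fit the
   best tree consistent with each hypothesis, then compare fits with
   AICc and Akaike weights.
2. **Posterior model odds**: filter the trees visited by a Bayesian MCMC by
   a topological predicate and take the ratio of consistent to inconsistent
   samples as an estimate of the posterior odds of the two models.
3. **Bayes factors** from stepping-stone marginal-likelihood runs performed
   under a positive and a negative topological constraint.
4. **Root-placement frequencies**: tally where the root falls across a
   posterior sample of rooted trees, giving a direct posterior distribution
   over root hypotheses.

The package consumes the outputs of the standard inference programs
(posterior `.trees` samples, ML fit summaries, per-run log marginal
likelihoods) and also ships a small likelihood engine and synthetic-data
generators so the entire workflow can be exercised end-to-end on a desktop,
with known ground truth, without any external software.

## Information-criterion comparison

For a fit with maximised log-likelihood $\log L_i$ and $K$ free parameters
on $n$ characters,

$$\mathrm{AIC}_i = -2\log L_i + 2K, \qquad
  \mathrm{AICc}_i = \mathrm{AIC}_i + \frac{2K(K+1)}{n-K-1},$$

and the Akaike weight of model $i$ within a candidate set is

$$w_i = \frac{e^{-\Delta_i/2}}{\sum_j e^{-\Delta_j/2}}, \qquad
  \Delta_i = \mathrm{AICc}_i - \min_j \mathrm{AICc}_j.$$

The small-sample correction matters whenever $n/K < 40$
(`small_sample_flag()`), which is the norm for partitioned protein
phylogenies where $K$ includes every branch length. Weights are computed
through a log-sum-exp so that deltas in the hundreds (routine for
likelihood-based comparisons) underflow gracefully rather than producing
`0/0`. `K` and `n` are always caller-supplied: the package never guesses
them from model names.

```{r}
akaike_weights(c(11.41, 0))
```

## Posterior model odds

`posterior_model_odds()` counts, over a post-burn-in tree sample, how many
trees satisfy a `clade_hypothesis()` (monophyly, sister grouping, or
negative monophyly). Two ratios are defensible and published tables mix
them, so both are always reported:

* `odds` $= n_\mathrm{consistent} / n_\mathrm{inconsistent}$ — the ratio of
  the posterior masses of the two models, used as the headline value;
* `odds_total` $= n_\mathrm{consistent} / n_\mathrm{total}$ — the sampled
  frequency of the hypothesis.

With 15 consistent trees out of 28,001 the two differ only in the fourth
significant figure (5.361e-4 vs 5.357e-4), but they are not the same
quantity. Burn-in discards the first `floor(fraction * N)` trees; sample
counts are treated as properties of the input file rather than recomputed
from chain settings. `posterior_odds_from_counts()` builds the same record
from published counts when the raw sample is unavailable.

## Bayes factors from run-level marginal likelihoods

Stepping-stone analyses are usually replicated; each run $r$ returns an
estimate $v_r$ of $\ln P(X \mid M)$. Because the runs estimate the same
marginal *likelihood* (not log-likelihood), they are combined on the
likelihood scale:

$$\widehat{\ln P(X \mid M)} = \ln\!\Big(\tfrac1R \sum_r e^{v_r}\Big),$$

a log-mean-exp computed stably relative to the largest run. This is a
deliberate and consequential choice: the arithmetic mean of the logs can
differ by tens of units when runs disagree (for the two-run set
{−36,376.42, −36,352.75} the log-mean-exp is −36,353.44 while the
arithmetic mean is −36,364.59), and only the log-mean-exp bounds the
combined value inside $[\max v_r - \ln R,\ \max v_r]$. The Bayes factor is
$e$ to the difference of combined values; it is carried in log space and
reported as a base-10 mantissa/exponent pair so magnitudes like $10^{-94}$
survive serialisation. `interpret_evidence()` bands $2\ln\mathrm{BF}$ as
0–2 negligible, 2–6 positive, 6–10 strong, >10 very strong, mirrored for
evidence against the first model, with band edges belonging to the stronger
category.

## Root-placement analysis

`root_bipartition()` reduces a rooted tree to the split between the two
subtrees under its root — placements are equivalence classes of splits, and
branch lengths are ignored. `root_frequency_table()` tallies these splits
over a sample, sorted by descending frequency with lexicographic
tie-breaking. `mcc_tree()` selects the sampled tree maximising the sum of
log clade frequencies (the log product of clade credibilities), with clades
of size 1 and $n$ excluded and ties resolving to the earliest sampled tree;
node-height summarisation is out of scope. `outgroup_root()` roots an
unrooted tree on the edge separating a designated outgroup, splitting that
edge's length evenly between the two root children.

## The likelihood engine

`tree_log_likelihood()` implements Felsenstein pruning for amino-acid data
under the LG model with optional discrete-gamma rate heterogeneity,
invariant sites and observed frequencies (+F):

* **Exchangeabilities and frequencies** are read from a bundled plain-text
  file in the standard published-matrix layout (`read_paml_matrix()`); the
  rate matrix is scaled so branch lengths are expected substitutions per
  site, and transition probabilities come from the symmetrised
  eigendecomposition valid for reversible models.
* **Gamma categories** use equal-probability slices with *mean* category
  rates (the dominant convention in ML phylogenetics tools), so the rates
  average exactly 1.
* **+I with +Γ:** the mixture weights are $(1-p_\mathrm{inv})/n_\mathrm{cat}$
  and $p_\mathrm{inv}$, and variable-site rates are *not* renormalised by
  $1/(1-p_\mathrm{inv})$ by default; `renormalize_inv = TRUE` switches to
  the renormalising convention used by some ML programs (the two
  conventions differ by a reparametrisation of branch lengths, so fits are
  comparable only within one convention).
* **Numerics:** per-site likelihoods are accumulated with per-node scaling
  vectors, site patterns are compressed, and gaps/ambiguity codes (`-`,
  `X`, `B`, `Z`, ...) contribute all-ones partials. Site ranges in
  partition schemes are 0-based half-open internally; the text format read
  from disk uses 1-based inclusive ranges.
* **Partitions** share one topology and one set of branch lengths (linked
  lengths, as for a single concatenated tree); per-partition rate
  multipliers are out of scope.

Branch lengths are optimised by round-robin one-dimensional search: each
sweep computes inside ("down") and outside ("up") partial vectors once,
after which each branch's likelihood profile costs a single matrix product
per evaluation, and the branch is optimised by golden-section search in a
bracket around its current value (expanded when the optimum lands on a
boundary). A sweep that fails to improve the log-likelihood — possible
because within-sweep updates reuse partials from the sweep start — is
retried with partials refreshed before every branch, which is strictly
non-decreasing, so the reported trajectory is monotone. Sweeps stop when
the improvement falls below `tol` (default 1e-6).

`constrained_best_tree()` enumerates all unrooted topologies (up to 8 taxa;
10,395 topologies), keeps those satisfying — or, for negative constraints,
violating — the hypothesis, and optimises each. A two-stage schedule keeps
this affordable: all candidates are screened with a cheap optimisation
(2 sweeps at coarse tolerance), and only the leading candidates are
refined, since screening only has to rank topologies. Enumeration order
breaks exact ties, making the search deterministic. For the resulting AICc
comparison, `count_free_params()` counts $K$ as the number of branch
lengths plus, per partition, one parameter for the gamma shape, one for the
invariant proportion, and 19 for +F frequencies; the empirical
exchangeabilities and the topology itself are not counted.

## What the synthetic generators emulate

The generators provide every input the workflow needs with known truth:

* `simulate_yule_tree()` — a constant-rate pure-birth tree, stopped after
  the waiting time at $n$ lineages, so the expected root height is
  $\sum_{k=2}^{n} 1/(\lambda k)$; used as a neutral source of ultrametric
  topologies.
* `simulate_alignment()` — sites are assigned to the invariant class or a
  gamma category, then evolved edge-by-edge from a stationary root draw.
* `simulate_tree_sample()` — posterior-like samples in which a focal
  hypothesis holds independently per tree with probability $p$: consistent
  trees are built constructively (focal subtrees assembled first, then
  embedded as units in a random backbone), inconsistent trees are
  rejection-sampled from unconstrained topologies, with a 10,000-attempt
  safety cap (absence is overwhelmingly likely at realistic taxon counts).
  Branch lengths are gamma(2) with mean 0.2 substitutions/site — moderate,
  protein-like divergence that is neither saturated nor uninformative.
* `simulate_root_sample()` — a fixed unrooted tree rooted on edges drawn
  from a specified placement distribution.
* `simulate_marginal_runs()` — run-level log marginals as truth plus
  Gaussian noise.

Each generator draws from its own seeded stream (`seed` combined with an
operation tag), so adding one generator call never shifts another's output
under the same seed. What these simulations do **not** emulate: alignment
error, compositional heterogeneity across lineages, autocorrelation of
MCMC samples (synthetic "posterior" trees are independent draws), and
model misspecification. Passing estimator-recovery tests on this synthetic
surface therefore validates the *counting and optimisation machinery*, not
the robustness of the underlying inference programs to real-data
pathologies.

## Taxon subsampling

`diversity_subsample()` reduces a tree to a target leaf count by repeatedly
locating the closest leaf pair (patristic distance) and removing the
member with the smaller total distance to the remaining leaves. The
classic tool drops a *random* member of the pair; the deterministic rule is
the default here so results are reproducible without a seed, and the
randomised variant is available behind `mode = "random"`. Ties remove the
lexicographically larger label. On random 10-leaf trees the greedy retained
set's total pairwise distance averages about 95% of the exhaustive best
subset's, though individual instances can fall 10–17% short — the greedy
heuristic is not an optimality guarantee. Groups are subsampled
independently on their own trees (`subsample_groups()`), matching workflows
that build per-group phylogenies, and groups at or below the target are
kept whole.

## Problem sizes and test design

The test-suite simulations are sized to exercise every code path at desk
scale: brute-force likelihood cross-checks enumerate all ancestral states
on trees of 2–4 leaves; re-rooting invariance runs on 5–7 leaf trees;
estimator-recovery checks use 5,000 synthetic posterior trees per clade
frequency and 10,000 for root placements; and the end-to-end comparison
simulates 6-taxon alignments of 2,000 sites (105 topologies per exhaustive
search), where high-signal data make the constraint-consistent model win
with Akaike weight near 1. These sizes were chosen as the smallest at
which each statistical claim is sharply testable.

## Known limitations

* Exhaustive search stops at 8 taxa; there is no heuristic (NNI/SPR)
  search, no bootstrap, and no clock models — full-scale inference stays
  with the dedicated external programs whose outputs this package consumes.
* Only the LG exchangeability family is bundled; other empirical matrices
  can be supplied via `read_paml_matrix()` + `subst_model()`.
* The MCC tree is selected among *sampled* trees only, and its node heights
  are not summarised.
* NEXUS support covers the TREES block dialects of the common Bayesian
  samplers (translate tables, `[&...]` annotations); NeXML/PhyloXML and
  annotation preservation are out of scope.
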