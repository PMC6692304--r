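---
title: "Screening class orders with ordinal classifier cascades"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening class orders with ordinal classifier cascades}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`ocscreen` asks whether a total order of `m` class labels is reflected in a
real-valued feature representation. The instrument is the ordinal classifier
cascade: for an assumed order $y_{(1)} \prec \dots \prec y_{(m)}$, binary
base classifiers $c_{(k)}$ of adjacent classes are evaluated sequentially,
the first one predicting its *first* class stops the cascade, and a sample
passed on by all $m-1$ classifiers receives the last label. Each base
classifier is trained *pairwise inductively* — on the samples of its two
classes only, with no knowledge of the order. That training scheme is
deliberate: it makes the cascade maximally susceptible to wrong order
assumptions, because each classifier's decision region was shaped without
regard to the classes that will flow through it later.

The quality of an order is the cascade's minimal class-wise sensitivity
$$p^* = \min_{1 \le i \le m} p_h\!\left(y_{(i)} \mid \mathcal{X}_{(i)}\right),$$
where $p_h(y_j \mid \mathcal{X}_i)$ is a conditional prediction rate: the
held-out fraction of class-$i$ samples that the cascade labels $y_j$. An
order is *reflected* in feature space when every class keeps a usable
decision region, i.e. $p^* \ge t$ for a sensitivity threshold $t$. We follow
the convention $t = 0.5$: every class must be recognised at better than
coin-flip sensitivity.

## Rates, bounds, and why they are exact here

All rates derive from one shared repeated stratified cross-validation. For
every ordered pair $(i, j)$ a classifier is fitted per (repeat, fold) cell
on the training portion of classes $y_i, y_j$ and applied to the test
portion of **all** classes, yielding

* $FC_{i,j}$ — the first-class sensitivity of $c_{i,j}$ on held-out
  $\mathcal{X}_i$, and
* $SC_{i,j}(r)$ — the rate at which held-out class-$r$ samples are passed on
  (predicted $y_j$), defined for every $r$, including the external classes
  the pair was never trained on.

Two structural facts bound any cascade built from these pieces. The cascade
cannot recognise $y_{(i)}$ more often than its own base classifier does
($p_h \le FC$ of the $i$-th pair), and a class-$i$ sample claimed by an
earlier classifier never reaches position $i$
($p_h \le \min_{k<i} SC_{\text{pair }k}(y_{(i)})$). The per-class bound is
the minimum of the two, and its minimum over positions bounds $p^*$.

Design choices that matter for exactness:

* **One fold assignment for everything.** The same (repeat, fold) partition
  underlies the rate table and every cascade evaluation, and cascade
  evaluation reuses the identical fitted fold models through a per-sample
  prediction cache. The bound inequalities then hold *per fold cell* and
  survive averaging, so dominance of the bound over the evaluated
  sensitivity is exact to floating-point, not approximate. This also makes
  screening over millions of orders tractable: no model is ever refitted
  per order.
* **External rates on test portions.** $SC_{i,j}(r)$ for $r \notin \{i, j\}$
  is measured on the test portion of class $r$ in each fold, never on the
  full class, so every rate lives on the same held-out sample sets.
* **Aggregation** is the unweighted mean of per-fold class-conditional
  rates over all repeat × fold cells; stratification makes the per-class
  cell sizes equal, so micro- and macro-pooling coincide up to rounding.
* **Stratification** (each fold's test set contains every class) is required
  for the external rates to be well defined in every cell; samples sharing a
  group id (paired designs) are assigned to folds wholesale.

## The screen

`cascades_screen()` fills orders depth-first. The first position is free (no
classifier exists yet); appending $y_j$ to a partial order ending in $y_i$
requires $FC_{i,j} \ge t$ and $SC_{i,j}(r) \ge t$ for every remaining class
$r$. A failed check prunes $(\text{remaining}-1)!$ complete orders at once,
which is also how the rejected count is obtained without enumeration.

The pass-on check ranges over the remaining classes *including* $y_j$
itself. Under this inclusive reading the union of checks along a complete
order is exactly the set of terms of its bound, so the candidates are
precisely the orders with certified bound $\ge t$ — verified in the test
suite against a pruning-free brute-force oracle. An `inclusive = FALSE`
switch provides the laxer reading that only constrains classes placed
later. Ties pass ($\ge t$), thresholds are compared at full precision, and
percent formatting to one decimal happens only in rendered reports.

Because the certified bound can only shrink as an order grows (each
extension adds constraints), the maximum bound over all orders can be found
exactly by branch and bound: extend partial orders tracking the running
minimum of their checked terms and discard a prefix as soon as that minimum
falls to the best completed order. `max_cascade_bound()` implements this
with best-first child ordering; it is the deterministic equivalent of
probing the pruned screen with ever higher thresholds, without the risk of
a probe below the maximum enumerating an uncontrolled candidate set.

Surviving candidates are never reported on the bound alone: `cross_check()`
evaluates each one as a full cascade on the shared folds and keeps bound and
realised $p^*$ side by side, since the bound is an upper limit, not a
guarantee.

## Base learner

The default learner is a linear soft-margin SVM with cost 1 (LIBSVM through
`e1071`), no feature scaling, no class weighting; a decision value of
exactly 0 predicts the second class (the sample is passed on), a tie-break
that continuous data never meets. Both ordered directions of a pair share
one fitted boundary with the first/second roles swapped — the optimisation
problem is symmetric in the label order, so this halves the fit count
without changing any rate. Any learner can be substituted through
`base_learner()`; the bounds and the screen are agnostic to it.

## Synthetic benchmark families

Three two-dimensional Gaussian designs, all with isotropic common standard
deviation `sd` and (by default) 10 classes × 100 samples:

* **linear** — class $i$ centred at $(i, i)$: an ordered chain on a line.
* **curved** — centroids follow a random monotone walk from the origin with
  per-step increments uniform in $(0.5, 2)$ per coordinate; ordered but
  bent. The walk is drawn from the seed before any noise, so centroids and
  samples are independently reproducible.
* **non-ordinal** — centroids on a fixed grid spanning $[1, 4]^2$ in a
  scrambled class assignment chosen so that no permutation of the classes
  is monotone in both coordinates (the layout ships with the package and is
  overridable). The negative control: no order should survive.

The defaults (`sd = 0.2` for headline runs, the sweep `0.1–1.0` for noise
scaling, 10 × 10 CV) are the package's standard study conditions. What these
generators emulate is the *geometry* of ordered class clouds; they do not
mimic the marginal distributions, feature counts or correlation structure of
expression data. A passing screen on them shows the machinery is correct —
recovery of planted orders, rejection of non-ordinal layouts — not that any
particular real dataset is ordinal.

Two behaviours of the method on these designs deserve naming, because they
are properties, not bugs:

* On the linear design, the strongest wrong orders are *tail swaps*
  (`…, y8, y10, y9`): their decisive rate is the pass-on rate of the
  $(y_8, y_{10})$ classifier on class $y_9$, whose centroid lies exactly on
  that decision boundary. The rate therefore hovers at 50% and the swapped
  order enters or leaves the candidate set with the draw of the data. The
  screen's verdict on such orders is genuinely borderline — mirroring the
  fact that the last positions of a cascade are the least constrained.
* On the curved design, when the walk steps of two end classes invert
  (class 2's increment exceeding class 3's, say), an order that descends to
  $y_3$ and then ascends $y_1 \prec y_2$ carves feature space perfectly and
  is reported as a third candidate with a bound near 100%. This is a real
  ordinal embedding of the data, found by the screen as designed; whether a
  given draw admits one is decided by the walk increments.

## Problem sizes and numerical choices

The packaged test suite runs the full 10-class × 100-sample protocol under
10 × 10 CV for the headline screens and scales the noise sweep to
`sd ∈ {0.2, 0.6, 1.0}`; property-style invariants (oracle equivalence,
bound dominance, prefix monotonicity, count conservation, threshold
nesting) run on 5–6-class problems where brute force over all permutations
is feasible. The acceptance script regenerates all nine generator × noise
settings from a single seed. Degenerate inputs are rejected at the surface:
fewer than two classes, classes smaller than the fold count, single-fold
layouts, thresholds outside $[0, 1]$, orders with repeated or unknown
labels. Rates are stored at full double precision; serialised rate tables
round-trip bit-exactly (17 significant digits).

## Known limitations

* The worst-case lookup formula $f(m) = \sum_{k=2}^{m} k \binom{m}{k+1}$ is
  reported for reference (`worst_case_lookups()`); realised lookup counts
  of heavily pruned runs fall far below the unpruned enumeration, which is
  the operative claim the tests assert.
* Screening certifies orders of the labels it is given (or an explicit
  subset); it does not search for maximal ordinal sub-structures on its
  own.
* Candidate counts near the threshold are sensitive to ties by design
  (`≥ t` passes); report thresholds jointly with candidate sets.
* The cross-check requires the per-sample prediction cache; a rate table
  deserialised from JSON supports bounds and screening only.
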