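---
title: "Network-structured pathway features for predicting hepatocarcinogenicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-structured pathway features for predicting hepatocarcinogenicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(carcinopath)
```

## The problem

The two-year rodent cancer bioassay is the reference standard for chemical
carcinogenicity, but it is slow and expensive. A recurring idea in
toxicogenomics is to predict its outcome from much shorter exposures:
measure hepatic gene expression after a 90-day study at the maximum
tolerated dose, summarize the transcriptional response at the level of
biochemical pathways, and learn a mapping from pathway responses to the
bioassay's quantitative tumor statistic. Because pathways — unlike
individual probes — have orthologous counterparts across species, a model
trained on mouse data can be applied to rat and human data sets that share
the pathway panel.

`carcinopath` implements that pipeline end to end: pathway networks and
topological weights, a network-structured enrichment statistic with a
permutation null, the survival-adjusted poly-3 carcinogenicity target, a
super-learner prediction model with honest nested cross-validation, ROC and
dose-response evaluation, and a synthetic-data generator with known ground
truth so every stage is testable without any external downloads.

## Pathways as networks

A pathway is a directed graph whose nodes are gene identifiers; an
undirected interaction is stored as two ordered pairs. Two topological
quantities feed the enrichment statistic:

* **Terminus weights.** Signalling pathways funnel toward a terminating
  end that drives transcription, so genes near that end are more
  informative about pathway engagement. With $T$ the set of out-degree-0
  nodes, $d_T(v)$ the shortest directed distance from $v$ to $T$, and $D$
  the largest finite $d_T$, each node gets weight
  $w(v) = 1 + \lambda\,(1 - d_T(v)/D)$, linear from $1$ at the most
  upstream node to $1+\lambda$ at a terminus ($\lambda = 1$ by default).
  Degenerate cases are explicit: unreachable nodes weigh 1, a pathway with
  no terminus (fully undirected) is weighted uniformly, and an edge-free
  gene set gets uniform weights — so GMT input degrades gracefully to a
  set-based analysis.
* **Proximity.** Perturbations clustered on the network are stronger
  evidence than the same perturbations scattered across it. Pairwise
  distances are unweighted shortest paths on the *undirected* skeleton:
  interaction maps mix directed and undirected edges and proximity is a
  symmetric notion, so direction is ignored here by design (it matters
  only for the terminus weights). Disconnected pairs carry an explicit
  infinite distance, never a numeric sentinel.

## The enrichment statistic

For one treated-vs-control study, each gene's perturbation is scored by the
absolute pooled-variance two-sample $t$ statistic on $\log_2$ values (a
deliberate minimal choice; degenerate zero-variance genes score 0 when the
means agree and the table's maximum when they do not). For a pathway whose
measured nodes are $V$ with scores $s$, weights $w$ and distances $d$, the
score is

$$
S \;=\; \frac{\sum_{v \in V} w_v s_v}{\sum_{v \in V} w_v}
\;\times\;
\left(1 + \frac{\sum_{u<v} s_u s_v\,\kappa(d_{uv})}{\sum_{u<v} s_u s_v}\right),
\qquad \kappa(d) = \frac{1}{1+d},\ \kappa(\infty) = 0 .
$$

The first factor is the terminus-weighted mean perturbation; the second
rewards score mass concentrated on nearby nodes. The bracket is defined as
1 when fewer than two nodes are measured or all pairwise products vanish.
The gene-set variant replaces $s$ with a membership indicator — it is
literally the same code path, which is also why one permutation scheme
serves both.

Significance comes from a gene-label permutation null: the observed score
multiset is reassigned at random over the measured universe and the pathway
rescored, $K$ times (default $5 \times 10^4$ to match the headline
analysis convention; the simulations in this package use $10^3$–$2 \times
10^3$, which is ample for features and keeps a full 26-chemical run around
a minute per chemical-set on one CPU). The add-one estimator
$p = (1 + \#\{S^{null} \ge S\})/(K+1)$ keeps $p$ in $[1/(K{+}1), 1]$, and
the feature is $Z = \Phi^{-1}(1-p)$, clamped at $p \le 1 - 1/(K{+}1)$ so a
pathway scoring below its entire null still yields a finite feature. The
orientation (small $p$ $\to$ large $Z$) makes strongly perturbed pathways
the elevated features. One set of $K$ global permutations is shared across
all pathways of a collection; each pathway reads its own node positions
from each permutation, which is exactly the single-pathway null but $O(K)$
rather than $O(K \times N_p)$ in permutation draws.

Skipped pathways (no measured node) are imputed $Z = 0$ in the feature
vector — the median feature under a uniform $p$ — so feature columns stay
aligned across species; dropping columns would break cross-species
prediction.

## The carcinogenicity target

The regression target is the poly-3 survival-adjusted tumor statistic: a
pooled two-proportion $z$ on the survival-adjusted counts,

$$
z = \frac{p^{treat} - p^{cont}}
  {\sqrt{\hat p (1-\hat p)\left(\tfrac{1}{n^{treat}} + \tfrac{1}{n^{cont}}\right)}},
\qquad
\hat p = \frac{n^{treat} p^{treat} + n^{cont} p^{cont}}{n^{treat} + n^{cont}},
$$

where an animal dying tumor-free at study fraction $t$ contributes weight
$t^3$ to its arm's effective $n$ (tumor-bearing animals and terminal
survivors contribute 1). The pooled-variance form and the one-sided
upper-tail orientation are recorded design choices: the bioassay question
is a tumor *increase*, and the outlier cap is correspondingly one-sided —
$z$ is truncated at $\Phi^{-1}(1 - 2\times10^{-5}) \approx 4.107$, with no
lower cap. Binary calls use one-sided $p \le 0.01$ (inclusive); equivocal
bioassay outcomes with $p$ near 0.075–0.084 therefore count as negative,
which matters for the confusion arithmetic below.

## Prediction model

The model $z_i = f(Z_{i1}, \dots, Z_{iN_p})$ is selected by a super
learner over a small library — random forest (500 trees,
$\sqrt{N_p}$ features per split), radial support-vector regression, and
ridge regression. The library is intentionally minimal: the forest is the
member the final-model path relies on (it alone provides pathway
importances), and the others exist so selection is a genuine comparison.
Two selection paths are implemented: the *discrete* super learner picks
the learner with minimum cross-validated MSE (ties break in library
order), and the *continuous* super learner solves a non-negative least
squares over the out-of-fold predictions and normalizes the weights to a
simplex, with a uniform-weight fallback (and warning) when the problem is
degenerate.

With only 26 chemicals, selection itself can overfit, so held-out
predictions are *honest*: an outer 5-fold split (fixed per run) is
evaluated by running the entire inner 5-fold selection on each outer
training complement, refitting the selection on that complement, and
predicting the held-out fold. A chemical's own row — features or target —
never enters any fit that predicts it, and the test suite asserts this
bitwise. Folds are built by sorting chemicals on the target and dealing
serpentine-style (1..5, 5..4..1, ...), which pairs each stratum's high
values with the next stratum's low values; this satisfies the balance
requirement (every fold's mean within 1.5 of the global mean on a 1..10
toy target) deterministically, with the seed randomizing only tie order.
An alternative with an extra within-stratum shuffle was rejected because
it can violate exactly that balance bound.

Pathway importances come from the final all-data forest as unscaled
permutation importance (mean increase in out-of-bag squared error when a
column is permuted), reported in descending order.

## Evaluation

AUC is the tie-aware Mann–Whitney probability
$P(S^+ > S^-) + \tfrac12 P(S^+ = S^-)$, computed from midranks and checked
in the tests against both an $O(n^2)$ pair-counting oracle and `pROC`.
Operating points reconstruct "errors at a comparable type-I error rate":
among ROC vertices with specificity in a window (default 0.56–0.75), the
one maximizing sensitivity (ties toward higher specificity) is reported
with its false-positive and false-negative id lists. Applied to the
published mouse calls and confusion lists this reproduces the printed
sensitivity/specificity of 0.6/0.56, and 0.93/0.58 on the human risk-factor
panel — the latter requires reading the polymorphism list as 25 sets (24
negative), which is the only reading consistent with the printed numbers.
Dose-response evaluation is an OLS slope of predicted $z$ on administered
dose with a one-sided upper-tail $t$ test ($n-2$ df); an exactly collinear
series degenerates to $p \in \{0, \tfrac12, 1\}$ by the slope's sign.

## What the generator emulates — and what it does not

The synthetic generator defines the study conditions under which the
pipeline is validated: 26 chemicals, half carcinogenic; 4 animals per
expression arm; a 4000-gene universe; 200 pathways of 10–80 genes built as
preferential-attachment trees with 1–3 terminus roots plus shortcut edges;
5 shared causal pathways whose genes shift by $\delta = 1$ $\log_2$ unit
(terminal halves by $1.5\,\delta$, so the terminus weighting has real
signal to find) against $\sigma = 1$ noise on a Normal(7, 1) baseline;
per-chemical potency multipliers uniform on 0.5–1.5 so the continuous
target varies; and bioassay arms of 50 animals with control tumor rate
0.2, treated rate $\mathrm{logit}^{-1}(\mathrm{logit}(0.2) + 1.5\,m)$
for mean causal shift $m$, and 20% of tumor-free animals dying uniformly
in the final 60% of the study. Tumor outcomes flow through per-animal
poly-3 weights, so the full target-construction path is exercised, not
just its endpoint. Non-reference species share pathway topology with 10%
of genes re-drawn as species-private (orthology broken), which is the
mechanism that degrades — but does not destroy — cross-species transfer.

These choices emulate the *statistical structure* the analysis assumes,
not microarray reality: there are no probe effects, batch structure,
correlated gene noise, litter effects, or historical-control drift, and
carcinogens act through a common causal-pathway set rather than diverse
modes of action. Passing the simulation-based checks therefore shows the
machinery is correct and the signal-recovery logic sound at realistic
sizes; it does not certify performance on real array data, and the
package makes no claim to reproduce the real-data AUCs, which require the
original data sets.

## Numerical choices and degenerate inputs

* Permutation $p$ uses add-one counting; $Z$ is computed from the clamped
  $p$, so features are always finite.
* Infinite distances propagate explicitly and $\kappa(\infty)=0$, so a
  disconnected pair simply contributes no proximity reward.
* `cap_z` is idempotent and order-preserving below the cap.
* Learner failures inside cross-validation mark the learner failed and
  excluded rather than aborting the run; all-failed is an error.
* All randomness is governed by explicit integer seeds; package functions
  restore the caller's RNG state. Inner-fold seeds derive deterministically
  from the master seed (offset by a multiple of the outer fold index).
* Simulation scale in the tests — $K$ of 1000–2000, 10 pipeline seeds, 50
  noise seeds — was chosen as the smallest scale at which the checked
  quantities (null uniformity, median AUC, sign-test centering) are stable,
  and is stated alongside each result.

## Known limitations

* The enrichment statistic is a faithful-by-description network statistic
  (terminus-monotone weights, proximity kernel, gene-label permutation
  null); the companion method it follows is specified in a separate
  reference whose exact formulas are not reproduced here, so exact
  numerical agreement with that implementation is not claimed.
* The variance form of the poly-3 statistic (pooled) and the exponent-3
  survival weight follow the statistic's standard construction; the
  source tables print neither formula.
* The learner library is a minimal stand-in for the larger historical
  super-learner library (bagging, conditional forests, loess, neural
  nets, sparse PLS are not included).
* ROC confidence intervals, partial AUC, moderated gene-level statistics,
  and multiple-testing correction of pathway p-values are out of scope —
  the pipeline consumes all pathway z's as features and never selects on
  significance.
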