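---
title: "Abstraction augmented Markov models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Abstraction augmented Markov models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Protein subcellular localization prediction is a sequence classification
problem: given an amino-acid sequence, predict the cellular compartment
(cytoplasm, periplasm, outer membrane, ...) in which the protein resides.
Reliable labels require experiments and curation, so labeled sets are small
while unlabeled sequence data are abundant. `aammseq` implements a
semi-supervised generative approach built on k-th order Markov models whose
conditioning contexts are *abstracted* — grouped into clusters of k-grams
that behave alike — with the clustering learned from labeled and unlabeled
sequences together.

# Models

## The k-th order Markov model

For a sequence $x = x_0 \dots x_{n-1}$ over an alphabet $\mathcal{X}$ and a
class $c$, the model factorizes as

$$p(x \mid c) = p(s_0 \mid c) \prod_{i=k}^{n-1} p(x_i \mid s_{i-1}, c),$$

where $s_{i-1} = x_{i-k} \dots x_{i-1}$ is the length-$k$ context (a
*k-gram*) preceding position $i$. Parameters are estimated per class by
maximum likelihood with Laplace smoothing (pseudocount $\alpha$, default 1):

* transitions: $\hat\theta_{\sigma|s,c} = \frac{\#[s\sigma] + \alpha}{\#[s] + \alpha|\mathcal{X}|}$,
* initial k-gram: $\hat\theta_{s,c} = \frac{\#[s] + \alpha}{T_c + \alpha(N+1)}$
  over the $N$ observed k-grams plus one pooled *unseen* slot ($T_c$ is the
  class's total parent count), so a test sequence starting with a
  never-observed k-gram keeps nonzero likelihood,
* class priors: $\hat\theta_c = \frac{n_c + \alpha}{|D_L| + \alpha|C|}$.

$\#[s]$ counts $s$ at *parent* positions only (positions with at least one
following residue), so $\sum_\sigma \#[s\sigma] = \#[s]$ exactly and the
transition and initial estimates share one conservation law. Classification
applies Bayes' rule and takes the class with the highest posterior, ties
going to the earlier class in sorted order. All likelihood arithmetic is in
log space.

The vocabulary is the *observed* k-gram set, not the full
$|\mathcal{X}|^k$ enumeration: for protein 3-grams the observed set is
typically just under $20^3 = 8000$, and unobserved k-grams carry no counts
anyway. At prediction time a context that is absent from the vocabulary (or
touches the sentinel character, see below) contributes the uninformative
uniform factor $1/|\mathcal{X}|$.

## Abstraction hierarchies

The *context* of a k-gram is the conditional distribution of the next
symbol given that k-gram, estimated by pooling successor counts over **all**
sequences, labels ignored. This is the only place unlabeled data enter the
model — and it is exactly where small labeled sets are weakest, because a
labeled set with few sequences observes most k-grams a handful of times.

K-grams with similar contexts are merged bottom-up: starting from one
singleton abstraction per k-gram, the pair of active abstractions with the
smallest *weighted Jensen–Shannon divergence* is merged, $N - 1$ times,
recording merges on a LIFO stack. For contexts $p_a, p_b$ with occurrence
weights $n_a, n_b$:

$$d(a, b) = (n_a + n_b)\,\mathrm{JS}_{\pi_a,\pi_b}(p_a, p_b), \qquad
\pi_a = \frac{n_a}{n_a + n_b},$$

where $\mathrm{JS}_{\pi_a,\pi_b}(p,q) = H(\pi_a p + \pi_b q) - \pi_a H(p) -
\pi_b H(q)$ with base-2 entropies. The $(n_a + n_b)$ factor makes
low-frequency contexts merge first; a configuration switch (`scaling =
"unscaled"`) drops it. A merged node's context is the count-weighted mean of
its children's contexts (weight = sum of weights), which equals the direct
aggregation of all constituent leaves — contexts are therefore maintained
incrementally and exactly. Ties between equal-distance pairs are broken by
the lexicographically smallest (min node id, max node id) pair, making the
hierarchy deterministic across runs and platforms.

An *m-cut* undoes the last $m - 1$ merges; the remaining active nodes are
$m$ abstractions whose leaf sets partition the vocabulary. `m = 1` is the
root (one pooled context), `m = N` the singleton cut.

## The AAMM

An abstraction augmented Markov model replaces the conditioning k-gram with
its abstraction under a chosen m-cut: the next symbol depends on
$a(s_{i-1})$ rather than $s_{i-1}$, reducing per-class parameters from
$N|\mathcal{X}|$ to $m|\mathcal{X}|$. Parameters are estimated from labeled
data only, by pooling the **raw** successor counts of each abstraction's
constituent k-grams and smoothing once:

$$\hat\theta_{\sigma|a,c} =
\frac{\sum_{s \in a}\#[s\sigma] + \alpha}{\sum_{s \in a}\#[s] + \alpha|\mathcal{X}|}.$$

Pooling raw counts rather than averaging already-smoothed leaf estimates is
deliberate: it makes the singleton cut reduce *exactly* to the plain Markov
model (the package's central correctness oracle, asserted at $10^{-13}$
log-likelihood tolerance), and avoids compounding pseudocounts. The initial
term is the abstraction-level initial distribution over $m + 1$ slots
(including an unseen slot), consistent with the $m$-abstraction
parameterization.

Semi-supervised training (`fit_semisupervised()`) is therefore: vocabulary,
contexts and hierarchy from all sequences with labels ignored; an m-cut
(default `m = 1500`, a mild compression for 8000-k-gram protein
vocabularies); parameters from the labeled subset only.

# Baselines

**EM over Markov models.** Initialize from the labeled subset; iterate an
E-step (posterior class memberships of each unlabeled sequence) and an
M-step (refit of all tables on hard-labeled plus fractionally weighted
unlabeled counts, the latter scaled by an `unlabeled_weight` in $[0,1]$).
Convergence is declared when no parameter moves more than `tolerance`
(default $10^{-6}$) or after `max_iterations` (default 100). The
observed-data log-likelihood is traced per iteration. One honest caveat:
because the initial-k-gram distribution is estimated from all parent
positions (the same convention as the supervised fit) rather than from
first positions only, the M-step is a very close approximation to the
surrogate maximizer, not the exact one — the trace is monotone up to
$\sim 10^{-11}$ wiggle near convergence rather than provably monotone. The
smoothing-penalized objective is recorded alongside.

**Co-training.** Two Markov models on two views — the first 60 residues and
the last 15 residues, motivated by N-terminal sorting signals — label a
working pool of 75 unlabeled examples for each other. Each round, each
classifier promotes its most confident predictions (confidence = maximum
posterior), apportioned across classes by the current labeled class
distribution via largest remainder with at least one per class; the pool is
replenished by the number of examples consumed, and both models are refit.
At test time the two view log-posteriors are *averaged* (a normalized
geometric mean of the view posteriors). The averaging rule was chosen over
summing log-posteriors minus one log-prior because only the average
reproduces the single-view classifier exactly when the two views and models
coincide, and preserves any prediction both views agree on.

# Evaluation machinery

* Stratified k-fold CV (default 5 folds): per class, shuffle and deal
  round-robin, so fold class counts are within one of proportionality.
  Within each training fold, $D_L$ and $D_U$ are drawn from that fold only —
  the test fold never enters hierarchy construction, the stricter
  no-transductive-leakage reading.
* Labeled-fraction subsampling: per class, records are permuted once per
  seed; $D_L$ is the permutation prefix of size $\lceil f \cdot n_c \rceil$
  and $D_U$ the suffix. Prefix allocation makes labeled subsets *nested*
  across growing fractions, and suffix allocation keeps $D_U$ fixed while
  $D_L$ grows — both properties the experimental protocol relies on.
  (Ceiling allocation is used instead of largest remainder because largest
  remainder is not monotone in the fraction and cannot guarantee nesting.)
* Relative error reduction: $|e_a - e_b| / \max(e_a, e_b)$, reported to the
  nearest whole percent in tables, raw fractions in machine output.
* Cross-validated paired t test: $t = \bar d \sqrt{n} / s_d$ with the
  sample (n−1) standard deviation, $df = n - 1$, two-sided critical value
  2.776 at 5 folds and level 0.05. Zero variance with nonzero mean is
  reported as an infinite t with an explicit flag.

# The synthetic generator

`make_ground_truth()` builds a known generative AAMM: all
$|\mathcal{X}|^k$ k-grams are split into `m_true` balanced random blocks
and each (class, block) pair receives a next-symbol distribution drawn from
a symmetric Dirichlet (concentration 0.3 by default, giving well-separated
blocks). Sequences are sampled class-first, then symbol by symbol from the
(class, block) emission of the sliding context. Defaults — alphabet 4,
k = 2, 6 blocks, 2 classes, lengths uniform on [50, 200] — keep the
vocabulary at 16 k-grams so the full stack runs in seconds; they echo
protein-scale sequence lengths without protein-scale alphabet cost.

What the generator does *not* emulate: real amino-acid composition,
signal-peptide or motif structure, class imbalance, and — importantly —
hard class overlap. Because each class draws its emissions independently,
every abstraction block separates the classes strongly, and with 50–200
residues per sequence the per-sequence Bayes margin is enormous. A
consequence observed in this package's own benchmarks: at 1% labeled / 50%
unlabeled of 2000 training sequences, both the semi-supervised AAMM and its
labeled-only counterpart classify held-out data at ≈100% accuracy, so the
*accuracy* margin between them is ≈0 even though the hierarchy learned with
unlabeled data is measurably closer to the true partition (pairwise
co-assignment agreement ≈0.90 vs ≈0.88, asserted in the test suite). The
accuracy-based semi-supervised benefit at this desk scale is therefore a
saturated comparison; the structural benefit is what the tests can and do
demonstrate. Passing tests on this generator show correctness of the
machinery, not real-data performance.

# Numerical choices and edge cases

* Non-canonical residues (B, J, O, U, X, Z, `*`, anything outside the
  alphabet) become a single sentinel character; any window containing the
  sentinel is excluded from counting and falls back to the uniform factor
  in likelihoods. The alternative `extend-alphabet` policy is available.
  How the original curated datasets handled such residues is not
  documented anywhere we know of; this is a policy choice, not an
  inference.
* Sequences shorter than $k$ contribute only the unseen-initial mass.
* Zero-weight contexts (possible with a zero pseudocount) are treated as
  uniform; two zero-weight abstractions are at distance 0.
* Under a zero pseudocount, transition rows for contexts unseen in a class
  fall back to uniform rather than 0/0.
* Model JSON is written with 17-significant-digit shortest-round-trip
  precision so serialization is bit-exact.
* The agglomeration stores the full distance matrix with per-row
  nearest-neighbour caching ($O(N^2)$ space); an 8000-leaf, 20-symbol
  hierarchy builds in ~20 s on one CPU.

# Problem sizes used in the test suite

The suite exercises the stack at the 16-k-gram scale (alphabet 4, k = 2)
for all model-correctness checks, 2000 sequences of length 100 for
parameter recovery (total-variation ≤ 0.05), 20 replicates of the
2000-sequence semi-supervised benchmark, and one 8000-leaf hierarchy for
the performance contract. These sizes were chosen so the whole suite
completes in a few minutes while each check retains statistical teeth.

# Known limitations

* No MDL-guided search for an optimal cut size; `m` is user-chosen.
* No interpolated or back-off smoothing; no variable-order models
  (probabilistic suffix trees).
* The co-training replenishment count and test-time combination rule are
  design choices exposed in configuration; published descriptions of this
  family of methods are not specific enough to pin them down.
* Real-data benchmarks (plant / non-plant / Gram-negative collections)
  require user-supplied FASTA and label files; the package ships no
  downloaders.
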