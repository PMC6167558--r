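---
title: "The fundamental Boolean model: dynamics, the orchard cube, and rule mining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The fundamental Boolean model: dynamics, the orchard cube, and rule mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbmnet)
```

## The model

A conventional synchronous Boolean network assigns each gene one update rule
mixing activating triggers with negated context. The fundamental Boolean
model (FBM) instead gives every gene two lists of *fundamental Boolean
functions* — indivisible conjunctions of gene literals that either activate
or inhibit the target — plus a protein-decay channel. Writing
$\sigma_i^t$ for the state of gene $i$ at step $t$, the synchronous update is

$$
\sigma_i^{t+1} \;=\; \Bigl(f_{decay}(\sigma_i^t,\vartheta)\;\vee\;
\bigvee_j P\!\left[C_{a_j}\right]\, f_{a_j}(t)\Bigr)\;\wedge\;
\neg \bigvee_k P\!\left[C_{d_k}\right]\, f_{d_k}(t)
$$

where $f_{a_j}$ / $f_{d_k}$ fire when all their input literals are satisfied,
$P[c]$ is a stochastic gate that passes with probability equal to the rule's
confidence $c$ (a uniform draw $\mu < c$; deterministic when $c = 1$), and
inhibition always dominates activation. The decay gate keeps an unregulated
gene on for a tolerance window: a counter $\tau_i$ is reset to 0 whenever any
function affects gene $i$, incremented otherwise, and the gate evaluates
$\sigma_i^t \wedge (\tau_i < \vartheta)$ after the increment. With the
default window $\vartheta = 1$ a gene that no rule refreshes switches off at
the next step; with $\vartheta = 2$ it persists one extra step, matching the
standard two-step protein-decay assumption for long time series. (A printed
form of the decay equation negates $\tau \le \vartheta$, which would keep a
freshly affected gene off during the window and on after it — the opposite of
its stated contract; we implement the contract, which also reproduces the
worked two-gene equilibrium traces and the decay-driven switch-offs in the
cell-cycle trajectory.)

Initial counters are 0: the initial observation is treated as a fresh
regulatory effect. Counters reset on *any* firing function, activating or
inhibiting; the alternative (reset only on activation) is observationally
indistinguishable at $\vartheta = 1$ and we found no principled reason to
treat an inhibitory effect as "no effect" for the decay clock.

### Parameters

| parameter | meaning | default | units |
|---|---|---|---|
| `decay` ($\vartheta$) | steps an untouched gene stays on | 1 | time steps |
| `confidence` | probability a satisfied rule fires | 1 | probability |
| `timestep` | per-rule update delay | 1 | time steps |

Per-rule time steps other than 1 are stored and serialized but rejected by
the synchronous engine: honouring them would make the schema asynchronous,
whose trajectories are nondeterministic and cannot be verified against
reconstructions.

## Decomposing compressed rules

`decompose_boolean_function()` splits a conventional rule into the two
channels. Inhibition functions are the terms of a minimal disjunctive normal
form of the rule's negation (Quine–McCluskey prime implicants, essential
primes first, greedy cover with a deterministic size-then-lexicographic
tie-break): every way the rule can be vetoed becomes an explicit inhibitor.
Activation functions are the minimal-DNF terms of the rule itself with each
term reduced to its positive literals. The negative literals a term carries
are absence-of-inhibitor context, and that context is exactly what the
inhibition channel now owns: enlarging an activation term can only add
states on which some inhibitor fires, and inhibition dominates, so the
reconstructed update `(OR activators) AND NOT (OR inhibitors)` is logically
equivalent to the original rule (a property the test suite checks by
exhaustive truth table on random networks). A term with no positive literal
is kept whole. For the cell-cycle CycA rule this yields the expected six
functions — activators `{E2F}`, `{CycA}` and inhibitors `{Rb}`, `{Cdc20}`,
`{!E2F & !CycA}`, `{Cdh1 & UbcH10}`:

```{r}
decompose_boolean_function(
  "E2F & !Rb & !Cdc20 & !(Cdh1 & UbcH10) | CycA & !Rb & !Cdc20 & !(Cdh1 & UbcH10)",
  target = "CycA")
```

## The orchard cube

Inference precomputes, for every target gene, a prefix tree of candidate
regulator conditions over the training transitions (one tree per gene, built
independently — the trees can be constructed in parallel and merged with
byte-identical results). A node fixes one conditional gene beyond its
prefix and stores four dimension records — TT, TF, FT, FF: target outcome
(on/off at $t+1$) crossed with the polarity of the conditional gene at $t$,
with all upstream prefix literals fixed. Each record carries exact counts
from which the measures derive lazily:

* **confidence** $p(\sigma^{t+1} = o \mid \text{condition at } t)$;
* **error**, the confidence of the paired opposite-outcome dimension, so
  $P(TT) = 1 - P(FT)$ and $P(TF) = 1 - P(FF)$ hold exactly on the counts;
* **support**, co-occurrences over the total transition count
  $\aleph = \sum_i (t_i - 1)$;
* **counter-confidence** $p(\text{condition at } t{+}1 \mid \sigma^t)$, the
  reverse-direction probability;
* **conditional causality**, confidence over counter-confidence — at least 1
  supports the condition-to-target direction ($+\infty$ when the reverse
  direction has probability 0, 0 when both are 0);
* **mutual information** (bits) between the condition indicator at $t$ and
  the target state at $t+1$ over all transitions.

Candidate genes expand in ascending gene order only, so each literal *set*
is computed once rather than once per permutation, and each node scans only
the transition subset matched by its parent (bottom-up counting). Branches
with no matched transitions at $t$ or $t+1$ are not expanded — their
measures are all zero and can never yield a rule. Depth is capped at `maxK`
(default 4, the size of the largest cell-cycle rule; raise it if larger
regulator complexes are plausible).

Before any tree grows, a Pearson chi-square screen (no continuity
correction, `alpha = 0.05`) on the 2×2 table of each gene's state at $t$
against the target's state at $t+1$ removes genes with no detectable
marginal association. The screen is applied to *all* genes including the
target itself — self-input rules such as `CycD = CycD` are legitimate and
must remain discoverable. Two caveats are worth stating plainly. First, the
screen is a computational device, not an inferential one: it bounds the
combinatorial cost of tree construction. Second, its power depends on the
transition count; at desk scale (a 4-gene network contributes ~112
transitions) it routinely discards true regulators whose marginal
association is weak, so the package's small-network recovery tests disable
it (`alpha = 1`), while the cell-cycle experiment (43,008 transitions, where
power is ample) keeps the 0.05 default.

## Mining criteria

`mine_network()` turns cube dimensions into candidate rules (outcome 1 →
activation, outcome 0 → inhibition) and filters:

1. causality ratio ≥ 1;
2. a mutual-information test value of (at least) `mi_threshold`, default 1;
3. essentiality — if flipping the deepest literal leaves the conditional
   outcome distribution unchanged (compared exactly on the counts,
   cross-multiplied), the literal is not essential and both polarity
   candidates are discarded in favour of the shorter prefix;
4. confidence strictly above `confidence_threshold` (default 0.7);
5. subsumption — a longer rule whose literal set contains a surviving
   shorter rule with identical confidence adds nothing and is dropped;
6. stable ranking by mutual information (descending), error (ascending),
   support (descending) and input size (ascending), with a lexicographic
   tie-break, truncated to `max_functions` (default 5) per target and kind.

The sort directions are a design choice (the criteria list names the keys
but not their directions): prefer informative, low-error, well-supported,
short rules, in that order, with a deterministic tie-break so mining is a
pure function of cube and configuration.

**The mutual-information test.** The test value we use is the determinism
score $1 - H_2(c)$, where $H_2$ is the binary entropy of the rule's
conditional outcome distribution (confidence $c$). It is exactly 1 when the
condition determines the outcome without residual uncertainty — as every
true rule is on noiseless data — and degrades continuously with noise, which
is when the threshold should be relaxed below 1. We deliberately do not use
the node's raw mutual information normalized by the target's next-state
entropy for this criterion: for any target regulated by more than one rule
(CycA has four activators), no single rule's condition determines the
target's next state, that ratio sits strictly below 1, and a threshold of 1
would reject every correct rule — the criterion would contradict the
method's own validation. The raw mutual information is still computed,
stored on every dimension record, and used as the primary ranking key.

**Constant targets.** A gene whose next state is 1 over every training
transition defeats the essentiality filter (every polarity pair is equally
predictive), so no cube candidate survives; such a gene receives the pair of
self-literal activation rules (`g` and `!g`), one of which always fires,
keeping it on. A constant-off gene needs no rule at all — no activator plus
decay is the FBM's native "off". Both cases are reported via `message()`.

## Synthetic data and what the tests show

The generator simulates noiseless synchronous trajectories from a known
network, one sample per initial state. The cell-cycle experiment uses the
printed ten-gene network, all $2^{10} = 1024$ exhaustive initial states and
43 steps (43,008 transitions); the test suite runs the same pipeline on a
seeded 128-state subsample plus twenty random 4-gene networks (1–2 DNF
terms of 1–3 literals per gene, all 16 initial states, 8 steps), sizes
chosen so the whole suite and the acceptance run stay comfortably at desk
scale. Under these conditions the simulate → cube → mine → reconstruct loop
recovers training series exactly (AR = PMR = 100%), and on the full
cell-cycle data mining returns the 46 printed functions plus two logically
redundant inhibitors (`Cdh1 = CycA & !p27 & !Cdc20`,
`UbcH10 = !CycA & !Cdc20 & Cdh1 & !CycB`) — complement prime implicants with
confidence 1 that can never misfire on data the network generated.

What passing these tests does *not* show: real expression data are noisy,
irregularly sampled, binarized with error, and never visit the full state
space. Exhaustive noiseless trajectories make "confidence 1" equivalent to
logical implication, which is precisely why recovery is perfect; on real
data the confidence and MI thresholds become genuine tuning parameters and
reconstruction accuracy is an optimistic upper bound. The package provides
the threshold plumbing but reproduces no noise study.

## Numerical and representation choices

* All cube counting is exact integer arithmetic; probabilities are derived
  lazily. Essentiality and pairwise-identity comparisons cross-multiply
  counts rather than comparing floating ratios.
* Attractors are enumerated over the extended state (values plus decay
  counters, counters saturated at $\vartheta$), because the value vector
  alone is non-Markovian when $\vartheta > 1$; at $\vartheta = 1$ this
  coincides with plain state-space cycles. Cycles are deduplicated up to
  rotation with a canonical lexicographically-smallest starting state.
* Stochastic simulation consumes one uniform draw per (function,
  transition) in a fixed order — targets in network gene order, activators
  before inhibitors, list order — so seeded runs are bit-reproducible.
* Degenerate inputs: empty input sets, out-of-range confidences and unknown
  genes are rejected at validation; samples of length 1 contribute no
  transitions; a zero-matched condition has confidence 0 and is flagged.
* k-means binarization uses deterministic extreme-value centers
  (`stats::kmeans` with the per-gene min and max as starting centers), so
  repeated runs agree; constant genes binarize to all 0 with a warning.

## Limitations

* Synchronous updating only; per-rule delays are parsed and stored but not
  simulated.
* The chi-square screen can discard weakly associated true regulators on
  small data (see above); disable it when gene counts are small.
* Mining recovers only rules expressible as conjunctions of at most `maxK`
  literals; deeper logic is truncated to its best shallow approximation.
* The `max_functions` cap trades completeness for parsimony; a target
  needing more rules than the cap to cover its activation region will
  reconstruct imperfectly.
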