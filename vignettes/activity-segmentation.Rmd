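---
title: "Segmenting long-term activities from wrist accelerometer data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting long-term activities from wrist accelerometer data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actseg)
```

## The problem

A wrist-worn triaxial accelerometer sampled at 20 Hz produces, over a day,
on the order of a million samples. The task actseg addresses is
*segmentation*: given such a recording, recover which long-term activities
of daily living (working, commuting, having a meal, showering, ...) the
wearer performed and in which order. Long-term activities span minutes to
hours and are themselves concatenations of short motion regimes — working
is mostly typing with interludes of sitting still; commuting may be riding
a bus or walking. Fixed-window classification, the standard approach for
*simple* activities (walk/run/sit), fails here: a 3-s window of walking
inside a working episode says nothing about the episode. Models over
sequences are needed.

## The pipeline

1. **Smoothing.** Each axis is filtered with a causal average filter:
   the output at position $t$ is the mean of the $n = 10$ samples strictly
   before $t$. The filter is undefined for the first $n$ positions, where
   we average all available preceding samples and pass the first sample
   through — a deterministic edge rule that preserves length.
2. **Windowing and features.** The signal is cut into windows of $l = 60$
   samples (3 s at 20 Hz) with 33% overlap, i.e. a hop of
   $l - \mathrm{round}(0.33\,l) = 40$ samples. Each window yields 12
   features: per-axis mean and variance, the three pairwise axis
   correlations, and the mean, variance and mean absolute first difference
   of the magnitude $m_t = \sqrt{x_t^2+y_t^2+z_t^2}$. Variances are
   population variances; a zero-variance axis pair has correlation defined
   as 0; the magnitude derivative is the mean *absolute* difference, since
   the signed mean telescopes to an almost information-free endpoint
   difference. Each window carries the ground-truth label covering the
   majority of its samples (ties to the earlier labeled interval; windows
   outside all labeled intervals are `not_tagged`, which is treated as an
   ordinary class throughout).
3. **Vector quantization.** k-means (k-means++ initialisation, Lloyd
   iterations, best of `n_restarts` by within-cluster sum of squares,
   fully seeded; empty clusters re-seeded from the farthest point) learns
   $M$ centroids on the *training* windows only. Every window is then
   replaced by the ID of its nearest centroid — its *motion primitive* —
   so a day becomes a string over an alphabet of size $M$. Features enter
   k-means unscaled by default (a `standardize` flag exists for
   sensitivity analysis).
4. **Sequence model.** From labeled training strings we estimate, with
   additive smoothing $\alpha$ (default 1): the emission matrix
   $B[q,k] = P(o_t = k \mid q_t = q)$, the transition matrix
   $A[i,j] = P(q_{t+1}=j \mid q_t=i)$ from adjacent label pairs (or a
   uniform matrix, for the ablation), a uniform initial distribution
   $\pi$, per-state k-mer tables (below), and the minimum-run-length array
   $\kappa$: half the shortest training episode of each activity, floored
   and clamped at 1.
5. **Decoding.** Three decoders share one implementation:
   * `hmm` — standard Viterbi on the HMM joint score
     $\log\pi(q_1) + \sum_t \log B[q_t,o_t] + \sum_{t\ge2}\log A[q_{t-1},q_t]$;
   * `hmm_c` — the same score maximised only over paths whose every
     maximal run of state $i$ (the first and last runs included) lasts at
     least $\kappa(i)$ positions, by exact dynamic programming over
     (state, run length capped at $\kappa$) pairs;
   * `crf` — the constrained decoder on a linear-chain CRF score
     $\sum_t \omega_1 f_1 + \omega_2 f_2 + \omega_3 f_3$ with
     $f_1 = \log P(o_t\mid q_t)$, $f_2 = \log P(q_t \mid q_{t-1})$
     ($\log \pi$ at $t=1$) and $f_3 = \log P(o_t..o_{t+k-1} \mid q_t)$,
     the k-mer sequence-pattern feature. Weights default to
     $(1,1,1)$; with $(1,1,0)$ the CRF score equals the HMM score exactly,
     which the tests exploit as a reduction identity. The CRF normalizer
     is never computed: only the argmax matters. $f_3$ contributes 0 at
     the last $k-1$ positions, where the k-mer would overrun the sequence.

Ties in either decoder go to the lowest state index, applied identically
in the brute-force enumeration oracles so equivalence tests are exact.

## k-mer tables and smoothing

For each state, the primitive substrings of all its training episodes are
concatenated and every length-$k$ substring is counted *with overlaps*
(`countKmers("ACACTACTGCATACTACTACCT", "CTAC")` is 3). The conditional
probability of a k-mer given the state is its count over
$|PrimSeq| - k + 1$, smoothed. Two numerical choices matter here and were
made after observing concrete failure modes on synthetic data:

* **Smoothing mass.** A flat pseudocount of $\alpha$ on each of the $M^k$
  cells adds total mass $\alpha M^k$, which for $k = 2$ dwarfs the actual
  pair counts and flattens the table. The k-mer pseudocount therefore
  defaults to $\alpha / M^{k-1}$ per cell — total added mass $\alpha M$,
  the same smoothing strength as the emission matrix. Any explicit value
  can be passed instead.
* **Sparse tables.** With a flat default for unseen k-mers, $f_3$
  degenerates into a seen/unseen indicator that systematically favours the
  state with the most training data (we observed whole episodes of a rare
  activity absorbed into the dominant `not_tagged` class this way, with
  $f_1$ favouring the truth and $f_3$ overruling it); and even then, a
  sparsely trained state's own pair estimates are noise-deflated relative
  to a data-rich competitor's smoothed floor. The distribution the $f_3$
  feature actually scores is therefore the Witten–Bell interpolation of
  the smoothed pair table with the independence product of emissions,
  $P(w \mid q) = \lambda_q\, \hat p_\alpha(w \mid q) + (1-\lambda_q)
  \prod_j B[q, w_j]$ with $\lambda_q = n_q / (n_q + d_q)$ ($n_q$ k-mer
  positions observed for the state, $d_q$ distinct k-mers among them).
  A data-rich state trusts its pair counts; a sparse one degrades
  gracefully to emission-product scores. Both components sum to 1 over the
  $M^k$ k-mers, so each per-state table still sums to exactly 1, and at
  $k=1$ (alpha held equal) the mixture reduces *exactly* to $B$,
  preserving the k-mer/emission cross-check identity.

The tables are stored sparsely (observed k-mers plus the per-state
interpolation weight): at the reference configuration $M = 300$, $k = 2$
there are 90,000 possible patterns per state, almost all unobserved.

## Subclassing fragmented classes

One label often covers kinematically different behaviours (commuting by
bus vs on foot). Each training *activity instance* (a maximal run of one
label) is represented by its primitive histogram — relative frequencies,
so duration does not confound content. The search then, per class:
computes a baseline leave-one-instance-out accuracy with a multinomial
naive Bayes classifier (Laplace smoothing; hand-rolled, as no multinomial
NB is available among the package's dependencies) on the original classes;
clusters the class's instance histograms with seeded k-means for
$k = 2..\min(maxK, n_i - 1)$; scores each $k$ with a cluster validity
index (silhouette, PBM, or generalized Dunn GDI33, all Euclidean); takes
the index-optimal $k$ as a candidate split; and keeps the split only if
the cross-validated accuracy — predictions mapped back to original
classes — *strictly* improves the baseline. `maxK` defaults to 5. A
"fixed" mode applies user-supplied per-class counts directly (the
programmatic stand-in for choosing counts by visual inspection of a
dendrogram) and bypasses the gate. The `not_tagged` class is eligible like
any other. After splitting, models are trained on subclasses as
independent classes — $\kappa$ is re-estimated per subclass — and
predictions are mapped back before scoring.

GDI33 is implemented in the Bezdek–Pal (3,3) reading: between-cluster
distance = mean pairwise cross-cluster distance, diameter = twice the mean
distance to the cluster centroid. Degenerate clusterings (all clusters
collapsed to points) return `Inf` as a "perfectly compact" sentinel; a
point in a singleton cluster has silhouette 0.

## The synthetic scenario

The packaged generator emulates the statistical structure the method
assumes, so the whole pipeline is testable without any recorded dataset.
An activity class is a set of motion *regimes* — Gaussian noise around
per-axis mean accelerations, optionally plus a sinusoid — alternating in
short exponential-length bouts within an episode; this is the simplest
family that makes the 12 window features discriminative. A *fragmented*
class draws one regime group per episode instead. The default scenario
(shipped as `inst/extdata/default_scenario.json`) is a desk worker's day:
dominant `working` (typing + stillness), `dinner`, short `hygiene`,
`exercise` (walking, running, stretching, brief pauses), a deliberately
fragmented `commuting` class (bus mode vs walking-with-street-crossing
pauses), and untagged `idle` filling roughly 45% of each day. Three
deliberate overlaps make the problem realistically hard and give each
model component something to do: a `still` regime shared by working,
dinner and idle (duration constraints and transitions must resolve it);
the commuting walk regime *identical* to the exercise walking regime
(this is what fragments the class: without subclassing, the blended
commuting profile loses its walk-mode episodes to exercise — and it is
why the subclassing accuracy gate has something to gain); and
pause-rhythm differences — commute walking is interrupted every few
seconds (street crossings), exercise walking rarely and for longer, with
the pause *share* matched — so the two differ in pair texture while their
symbol marginals barely do, which only the pair-level k-mer feature can
resolve.

Days are desk-scaled to roughly 60–75 minutes (about 1,800–2,300 windows)
so that a full leave-one-day-out grid over three decoders runs in minutes;
episode durations are scaled accordingly (e.g. working episodes 6–12 min,
commuting 4–7 min). The alphabet default used in the packaged evaluations
is $M = 24$: with tens of days rather than weeks of data, a small alphabet
keeps the $M^2$ pair tables dense enough for the k-mer feature to carry
signal rather than smoothing noise; the reference configuration $M = 300$
presumes an order of magnitude more data. What passing tests on this
generator do *not* show: robustness to real sensor artefacts (drift,
re-orientation, non-stationary regimes, label noise at episode edges), or
that the specific accuracy numbers transfer to any recorded dataset.

## Evaluation

`leaveOneDayOut` trains the complete pipeline (codebook, tables, $\kappa$,
optional subclassing) on all days but one, decodes the held-out day, maps
subclasses back, and pools a row-stochastic confusion matrix; accuracy is
the fraction of window positions predicted correctly with `not_tagged`
counted as a class. Per-day accuracies are exported for external
statistical testing. Two clock-only baselines quantify how far time of day
alone goes: a per-15-min-bin majority vote and an HMM whose observations
are the time bins, both under the same leave-one-day-out protocol.

## Worked example

```{r example, eval = FALSE}
days <- defaultScenario(6, seed = 1)
cfg <- pipelineConfig(M = 24, n_restarts = 5, seed = 11)
res <- leaveOneDayOut(days, cfg, methods = c("hmm", "hmm_c", "crf"))
sapply(res, `[[`, "accuracy")
round(res$hmm_c$sensitivity, 2)
```

## Known limitations

* The constrained decoder enforces $\kappa$ on the final run as well; a
  recording that *ends* mid-activity can therefore force an earlier
  boundary than the truth. We chose symmetry (every episode is a real
  episode) over exempting the truncated tail.
* $f_3$ with weights $(1,1,1)$ triples the weight of observation-level
  evidence relative to transitions; on data whose pair statistics carry no
  information beyond the marginals this makes `crf` a noisier `hmm_c`.
  The weights are configurable but, following the estimation-only training
  design, never gradient-trained.
* The subclass search clusters histograms only; order information within
  an episode is invisible to it.
* Episodes shorter than $2\kappa$ of another plausible class can be
  absorbed at decode time; $\kappa$ halving is a heuristic, not a learned
  duration model.
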