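---
title: "Comparing gaze-transition behaviour between interpretation groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing gaze-transition behaviour between interpretation groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the model

When clinicians read a 12-lead ECG, their gaze shifts between the leads,
cross-referencing regions whose joint appearance identifies the condition.
`ecgaze` asks whether that *transition behaviour* — not just how long or
how often each lead is fixated — differs between the people who interpret
a given ECG correctly and the people who do not.

The stimulus is partitioned into rectangular areas of interest (AOIs), one
per lead, rhythm strip, or textual annotation. A participant's fixations,
reduced to the sequence of lead AOIs they land in, form a *scan path*. For
each interpretation group on each stimulus, all members' scan paths are
pooled into a transition count matrix $C$, where $C_{ij}$ counts observed
gaze shifts from lead $i$ to lead $j$ (consecutive fixations within one
path only; self-transitions included). The pooled counts are converted to
a first-order Markov chain with additive smoothing:

$$P_{ij} = \frac{C_{ij} + \alpha}{\sum_j C_{ij} + k\,\alpha},$$

with $k$ the number of lead states and $\alpha > 0$ a per-cell
pseudo-count (default $\alpha = 1$, the Laplace prior). Smoothing exists
to keep every probability strictly positive: rows that were never visited
become uniform rather than undefined, and the divergence below is always
finite.

The discrepancy between the correct group's chain $P$ and the incorrect
group's chain $Q$ is the Jensen–Shannon distance

$$\mathrm{JSD}(p, q) = \sqrt{\tfrac{1}{2} KL(p \| m) +
  \tfrac{1}{2} KL(q \| m)}, \qquad m = \tfrac{p + q}{2},$$

with Kullback–Leibler divergences in base 2, so the distance is a true
metric bounded in $[0, 1]$.

A first-order model is justified empirically by the package's n-gram
profiler: when repeated subsequences of scan paths are counted at each
length, the most frequent repeated unit is typically the bigram — a single
transition — so a model conditioning on the current lead alone captures
the dominant sequential structure.

### Reducing two chains to one number

A Markov chain is a family of $k$ conditional distributions (one row per
current state), so "the JSD between two chains" needs a reduction rule.
Three are implemented in `chain_js_distance()`:

* **`flatten_uniform`** (default): flatten each row-stochastic matrix to a
  $k^2$-vector and divide by $k$. Algebraically this equals the uniform
  row-weighted mixture $\sqrt{\frac{1}{k}\sum_i \mathrm{JSD}^2(P_{i\cdot},
  Q_{i\cdot})}$ — every current-state conditional counts equally,
  regardless of occupancy. It is the most literal reading of a distance
  between the chains as mathematical objects.
* **`joint_bigram`**: normalise the smoothed counts by their grand total
  and compare the resulting bigram distributions — rows are weighted by
  how often each lead was actually occupied.
* **`stationary_weighted`**: weight each chain's rows by the average of
  the two chains' stationary distributions, comparing the implied
  long-run transition distributions.

All three are metrics in $[0, 1]$, zero exactly when the compared
distributions coincide, and all are checked against a brute-force
evaluation of the definitions in the test suite. The default was chosen
because it treats the chain as the object of interest and requires no
occupancy assumption; the alternatives are retained because the reduction
is a genuine modelling choice on which reasonable analysts differ, and on
real data the choice can matter when occupancy is very uneven.

### The permutation test

If interpretation accuracy is unrelated to transition behaviour, the
correct/incorrect split is exchangeable with any other split of the same
sizes. The test therefore draws random splits preserving the group sizes,
recomputes the pooled chains and their distance each time, and locates the
observed distance in that null sample. Two p-value conventions are
offered:

* `smoothed` (default): $p = (\#\{d_{null} \ge d_{obs}\} + 1)/(B + 1)$ —
  the add-one estimator, never zero, ties counted conservatively toward
  rejection;
* `paper`: the plain fraction of null distances strictly greater than the
  observed one.

When the number of distinct splits $\binom{n}{n_1}$ does not exceed the
requested number of permutations, all splits are enumerated and the
p-value is exact (a 2-vs-29 split has only 465 splits, far fewer than the
default 10,000 draws). The three-way outcome at level $\alpha = 0.05$ is:
`distance_larger` when $p \le \alpha$ (the groups transition more
differently than chance), `distance_smaller` when $p \ge 1 - \alpha$ (the
groups are more alike than random splits — some factor other than
accuracy aligns them), otherwise `no_difference`. No multiplicity
correction is applied across stimuli; the per-stimulus tests are reported
as-is, and users comparing across the full design should adjust
externally if their question demands it.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `quality_threshold` | 0.70 | fraction | participants below this recording quality are excluded (the tracker manufacturer's recommended floor); exclusion is per participant |
| `min_fixation_ms` | 60 | ms | minimum fixation duration; 60 ms fixations occur in reading, and ECGs mix graph and text |
| `alpha` (prior) | 1 | pseudo-counts | additive smoothing per cell; results should be reported with the value used |
| `mode` | `flatten_uniform` | — | chain-to-number reduction (above) |
| `n_perm` | 10,000 | draws | permutation sample size |
| `alpha` (level) | 0.05 | — | significance level of the three-way classification |

Filtering conventions worth knowing: AOI membership uses the fixation
centre in half-open rectangles $[x_{min}, x_{max}) \times [y_{min},
y_{max})$, so shared edges belong to exactly one AOI; fixations outside
every AOI, below the duration floor, or on annotation AOIs are *bridged
over* (their surviving neighbours become adjacent), matching a pipeline
that excludes those events before any analysis; and consecutive fixations
in the same AOI stay separate steps by default, producing self-transitions
— the transition matrices of interest include within-lead revisits. A
`collapse_repeats` flag merges such runs (summing dwell) for sensitivity
analyses.

## The synthetic cohort generator

No public gaze data set accompanies this design, so the package ships a
generator (`generate_cohort()`) producing cohorts with exactly the
statistical structure the analysis assumes, in the same file dialects the
ingestion functions read. Per stimulus, two group-level transition kernels
are drawn: the correct group's kernel row-wise from a Dirichlet biased
toward a configurable key-lead block (emulating cross-referencing of the
condition's salient leads), and the incorrect group's as the row-wise
mixture

$$K_{inc} = \frac{1}{1+\delta} K_{cor} + \frac{\delta}{1+\delta} D$$

with $D$ an independent kernel, so $\delta = 0$ is an exact null and
$\delta \to \infty$ an unrelated kernel. Each participant's personal
kernel is drawn row-wise from $\mathrm{Dirichlet}(\kappa \cdot
K_{group})$; paths are simulated from the personal kernel with a uniform
initial lead.

Defaults, chosen once to represent a realistic sitting of the reference
design and not revisited:

* cohort of 31 participants, eleven stimuli with the published
  correct/incorrect splits (16/15 down to 2/29);
* path length negative-binomial with mean 80 and dispersion 10 —
  unhurried inspection leaves a few fixations per lead across 13–15 AOIs;
* per-fixation dwell log-normal with $\mathrm{meanlog} = \log 280,
  \mathrm{sdlog} = 0.4$ (correct) and $\log 380, 0.4$ (incorrect), i.e.
  mean single fixations of roughly 300 ms vs 410 ms, floored at the 60 ms
  minimum — the incorrect group dwells longer, the direction seen in
  practice;
* $\kappa = 50$: mild idiosyncratic deviation of participants from their
  group kernel;
* $\delta = 0.5$ for the default demonstration study — a moderate, clearly
  detectable separation.

Saccade filler events are written between fixations purely to exercise
the event-type filter; they carry no analytic weight. Fixation
coordinates are uniform within the target AOI because AOI-level analysis
never uses within-AOI position.

What the generator does *not* emulate — and therefore what passing tests
do not certify about real data: realistic saccade kinematics, drift and
calibration error in fixation coordinates, time-inhomogeneous viewing
strategies (e.g. an initial systematic sweep followed by targeted
checking), stimulus-specific layout quirks, or dependence of path length
on accuracy. Calibration and power results under the generator
demonstrate the statistical machinery is sound, not that any particular
real effect size will be detected.

## Numerical choices and degenerate inputs

* Logarithms are base 2 throughout, bounding the distance by 1.
* `js_distance` validates normalisation to `1e-9`; smoothed chains' rows
  sum to 1 to machine precision by construction.
* Zero-length or single-step scan paths are valid and simply contribute
  no transitions; a participant whose fixations were all filtered out
  still participates in permutations with an all-zero count matrix.
* A stimulus where one group is empty is reported `untestable`; the study
  run continues.
* Null-vs-observed ties count toward rejection in the smoothed
  convention; an all-ties degenerate cohort (everyone shares one path)
  yields exactly $p = 1$.
* Stationary distributions (needed only in `stationary_weighted` mode)
  exist and are unique because smoothing makes the chain strictly
  positive; they are computed by the leading left eigenvector and checked
  in tests against power iteration.
* Permutation draws are i.i.d. uniform over splits (not guaranteed
  distinct); exhaustive enumeration replaces sampling automatically when
  it is cheaper. Participants are processed in sorted-id order so the
  seeded null sample is invariant to input ordering and relabelling.

## Problem sizes used in the packaged checks

The test suite and the reproduction script run entirely on generated
cohorts: the full default study (31 participants × 11 stimuli, 10,000
permutations per stimulus), a 200-replicate null calibration and
100-replicate power curves at $\delta \in \{0, 0.25, 0.5, 1\}$ with 1,000
permutations per replicate on a single 16/15 stimulus, and metric/oracle
checks over thousands of random distributions with up to $15^2$ cells.
These sizes give Monte-Carlo error comfortably inside the asserted bounds
while keeping a complete run in the low minutes on one CPU.

## Known limitations

* The smoothing magnitude is a genuine free parameter; $\alpha = 1$ is a
  convention, and heavily sparse matrices (short paths, many states) are
  sensitive to it. Reports echo the value used.
* Pooling transitions within a group weights participants by path length;
  a long-looking participant influences the group chain more. This
  matches the "aggregated frequency" design but is worth remembering when
  group sizes are very uneven.
* Only first-order structure is modelled; longer repeated sequences exist
  in real scan paths and would need higher-order chains.
* The per-stimulus tests share one cohort, and no correction for testing
  eleven stimuli is applied.
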