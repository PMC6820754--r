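---
title: "Directed resting-state connectivity with phase transfer entropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed resting-state connectivity with phase transfer entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

ptenet implements a complete analysis chain for directed functional
connectivity in source-space electrophysiological recordings: phase transfer
entropy (pTE) between all node pairs, permutation statistics on the resulting
non-symmetric connectomes, false-discovery-rate thresholding into significant
directed networks, and weighted graph characterization of those networks with
group comparison and behavioral correlation. A synthetic cohort generator
with planted directed couplings provides ground truth, so every stage of the
chain is testable without access to recorded data.

## The estimator

Given two signals, each is reduced to its instantaneous phase — the argument
of the analytic signal obtained by the Hilbert transform (computed here by
the FFT half-spectrum method), wrapped to $(-\pi, \pi]$. Phases are binned
into $B$ equal-width bins spanning $(-\pi, \pi]$, and pTE from $x$ to $y$ at
prediction delay $\delta$ is the difference of joint histogram entropies

$$\mathrm{PTE}_{x \to y} = H(y_t, x_t) + H(y_{t+\delta}, y_t)
  - H(y_t) - H(y_{t+\delta}, y_t, x_t),$$

with natural-log entropies and the convention $0 \log 0 = 0$. This is the
conditional mutual information between the source's present phase and the
target's future phase given the target's present phase, with target-embedding
length $k = 1$: the reduction in uncertainty about where the target's phase
is heading that the source's phase provides beyond the target's own history.
Values are non-negative up to estimator bias; small negative estimates are
kept as-is (no flooring), so downstream z-scoring stays well defined.

Directionality lives in the asymmetry: for a genuine delayed drive
$x \to y$, $\mathrm{PTE}_{x\to y} > \mathrm{PTE}_{y\to x}$. Time-reversing an
epoch maps a delayed drive onto one in which the reversed target leads, so
the estimated direction must flip — a sanity check the validation study
enforces. Note that reversing only *one* series of a coupled pair does not
produce a clean flip: it destroys the stationary lag relation altogether
(the delayed drive then relates the two series at time indices running in
opposite directions), leaving no consistent direction to flip. The package
therefore implements the time-reversal check on the whole epoch.

### The delay

The prediction delay is derived from the data as the average interval
between sign changes of the instantaneous phase, pooled over channels:
$\delta = \mathrm{round}(n_{\mathrm{samples}} \cdot n_{\mathrm{channels}} /
n_{\mathrm{flips}})$, floored at one sample. For a 10 Hz sinusoid at 600 Hz
this gives 30 samples (two zero crossings per 60-sample cycle); for
independent uniform phases it approaches 2. One shared delay is used for all
pairs of an epoch; a fixed per-call delay is available through
`pte_params()`.

### Bin count and histogram occupancy

`choose_bin_count()` ships three rules. `paper_fixed` returns 49 bins per
axis, the value whose three-dimensional joint histogram has
$49^3 = 117{,}649$ cells; `scott_style` is the sample-size-driven rule
$\mathrm{round}(\exp(0.626 + 0.4\ln(n-1)))$ (56 at $n = 4800$). Both put far
more joint cells than there are samples in an 8 s epoch at 600 Hz, which
saturates the three-way entropy near $\log n$ and measurably weakens
direction estimates on planted coupled pairs relative to coarser binning.
The third rule, `occupancy`, sizes the histogram to the data,
$B = \lfloor n^{1/3} \rfloor$ (so $B^3 \le n$; 16 at $n = 4800$), and is
what the package's validation studies use. The fixed 49 remains the default
of `pte_params()` for fidelity to the published arithmetic; analyses of
typical epoch lengths should prefer `occupancy`. The tension between a
49-bin histogram and 4800-sample epochs is inherited from the published
setting and is left visible rather than resolved.

## From epochs to subject connectomes

Per subject, the recording is conditioned the way resting-state pipelines
condition source signals: a causal fourth-order Butterworth high-pass at
0.5 Hz, a forward second-order notch at 50 Hz (quality factor 30), and a
zero-phase fourth-order Butterworth low-pass at 35 Hz. All three filters are
applied to the continuous recording before epoching — a simplification of
the published order (high-pass and notch before segmentation, low-pass
after) with the same net passband. Eight non-overlapping 8 s epochs are then
drawn pseudo-randomly, excluding the first minute; the draw is
rejection-sampled under a seed, with a deterministic jittered partition as
fallback when the recording is packed tight.

Each epoch yields a non-symmetric pTE adjacency matrix; epoch matrices are
averaged element-wise into one matrix per subject, and the off-diagonal
entries are transformed to standardized scores (mean 0, SD 1). Z-scoring is
computed over off-diagonal entries only — whether the published procedure
included the (structurally zero) diagonal is not stated, and including it
would shift the mean toward zero by a known artifact. The diagonal stays
zero throughout.

## Edge-wise permutation statistics

Within-group networks: each directed edge's z-scores across subjects are
tested against zero with a one-sample t statistic, and the two-sided p-value
comes from a sign-flipping null — each subject's value randomly negated —
which is exact under symmetry of the null distribution about zero. The
default flips one sign per subject per permutation (the standard
exchangeability argument); independent per-cell flipping is available behind
a flag, since the published description admits both readings. Between
groups, a pooled-variance independent-samples t statistic per edge is
referenced to a group-label permutation null, optionally combined with sign
flipping.

P-value resolution is the one substantive departure from a literal per-edge
permutation test. A per-edge null of $P$ permutations cannot produce
p-values below $1/(P+1)$, so Benjamini–Hochberg at $q = 0.001$ over
thousands of edges could never reject anything — yet the published analyses
report hundreds of FDR-significant edges from 5000 permutations over
$863 \times 862$ edges. That outcome requires the null distribution to be
pooled across edges, as large-scale edge-wise testing tools do: after
z-scoring, edges share a common null distribution, the pooled empirical null
has resolution $1/(P \cdot m + 1)$, and step-up FDR at small $q$ becomes
meaningful. Pooling is the default (`null_pool = "pooled"`); the classical
per-edge null remains available. An exact enumeration of all $2^n$ sign
patterns is provided for small cohorts. In all modes the observed statistic
is counted into the null (add-one rule), so p-values never reach zero.

Degenerate edges (zero variance) get $t = 0$, $p = 1$, with a message.
`fdr_threshold()` applies Benjamini–Hochberg over all off-diagonal ordered
pairs and returns a rejection mask; `extract_significant_network()` turns a
mask into a directed edge list with t-values, optionally keeping only one
direction of contrast (e.g. patients > controls for hyper-connectivity).

## Graph characterization

Significant networks and masked subject connectomes are characterized as
weighted directed graphs with edge length $1/\mathrm{weight}$:

* **Node strength** — sum of absolute edge weights (t-values) incident to a
  node, in-edges and out-edges alike.
* **Density** — edges divided by unordered node pairs,
  $m / \binom{N}{2}$, reported to 4 decimals. The denominator counts the
  full node set and unordered pairs even though edges are directed; that
  convention is forced by the published worked values
  ($892/\binom{863}{2} = 0.0024$, $441/\binom{863}{2} = 0.0012$).
* **Global efficiency** — mean inverse shortest-path distance over ordered
  pairs, $1/\infty = 0$ for unreachable pairs.
* **Characteristic path length** — mean of finite shortest-path distances;
  the count of unreachable pairs is reported alongside.
* **Small-world propensity** —
  $\mathrm{SWP} = 1 - \sqrt{(\Delta_C^2 + \Delta_L^2)/2}$, with
  $\Delta_C = (C_{\mathrm{latt}} - C_{\mathrm{obs}})/(C_{\mathrm{latt}} -
  C_{\mathrm{rand}})$ and $\Delta_L = (L_{\mathrm{obs}} -
  L_{\mathrm{rand}})/(L_{\mathrm{latt}} - L_{\mathrm{rand}})$, each clipped
  to $[0, 1]$.

SWP uses the Onnela weighted clustering coefficient on the symmetrized
graph (elementwise maximum of the two directions; the underlying construct
is undirected), and null graphs preserving the node count and the observed
weight multiset: a ring lattice with the strongest weights packed nearest
the diagonal, and 50 seeded uniform rewirings averaged for the random
reference. Sparse networks — including every network the pipeline's FDR step
typically produces — have no triangles in either null, so
$C_{\mathrm{latt}} = C_{\mathrm{rand}} = 0$; a degenerate delta denominator
resolves by the sign of its numerator (0 when the observed value sits on or
beyond the favorable side, 1 otherwise), and an error is raised only when
observed, lattice and random graphs are indistinguishable in both clustering
and path length. A hard error on any $C_{\mathrm{latt}} = C_{\mathrm{rand}}$
would make per-subject SWP uncomputable in precisely the intended use.

Per-subject metrics are computed on the subject's z-weights restricted to
the union of the two group-level significant networks — reconciling
"metrics on the basis of the significant networks" with the existence of
per-subject variance; the full unthresholded matrix can be supplied as a
mask instead. Negative z-weights inside the mask are clipped to a small
positive epsilon ($10^{-6}$) so lengths exist; the count of clipped cells is
returned. Group comparison uses the Mann–Whitney U test (exact for groups of
at most 8 without ties, normal approximation with tie correction otherwise),
reporting both raw $U$ and the standardized $|z|$ — published U values in
the low single digits are on the standardized scale. Metric–score
association uses Pearson correlation with a two-sided t-test whose degrees
of freedom come from the supplied vectors; published behavioral p-values
imply a smaller effective n than the cohort size, which the package does not
attempt to reproduce.

## The synthetic cohort generator

Each node carries intrinsic band-limited Gaussian noise (0.5–35 Hz by
default), generated by spectral masking at a 2-3-5-smooth FFT length. A
planted directed edge adds `strength` times the *intrinsic* signal of its
source node, delayed by the edge's delay in samples, into its target; rows
are then renormalized to unit variance, so strength reads as relative drive.
Coupling from the intrinsic rather than the mixed signal keeps the model
closed-form for arbitrary edge sets, including cycles; its visible cost is
that a source node with strong incoming edges transmits only part of its
observed signal, attenuating the detectability of its outgoing planted
edges. Cohorts derive per-subject seeds deterministically from one master
seed, and behavioral scores are generated on their instrument scales, with
`simulate_behavioral_scores()` producing scores at a chosen population
correlation with any per-subject metric: the standardized metric enters as
$r \cdot z + \sqrt{1 - r^2}\,\varepsilon$, mapped to the middle of the score
range with SD = width/6 so clipping is rare.

What the generator does *not* emulate: volume conduction and source
leakage, 1/f spectra and oscillatory peaks, non-stationarity, artifacts,
or subject-level heterogeneity beyond independent noise realizations.
Passing the validation studies therefore demonstrates that the chain
recovers planted delayed linear couplings from band-limited noise — not
that it is robust to the full physics of recorded source estimates.

## Validation studies and the scales used

The standing studies (also run by the test suite and the acceptance script):

* `direction_recovery_study()` — 200 independent pairs, coupling 0.7, delay
  20 samples, 8 s at 600 Hz, occupancy-sized bins: fraction of pairs with
  the planted direction recovered, and the time-reversal flip rate over
  confidently-directed pairs (asymmetry above the 95% band of a
  phase-randomized surrogate null).
* `null_calibration_study()` — 20 subjects per group, 32 nodes (992 directed
  edges), 1000 permutations on signal-free N(0,1) connectomes: rejection
  rate at $\alpha = 0.05$ against its binomial band, and FDR false-edge
  counts at $q = 0.001$.
* `planted_difference_study()` — 20 + 20 subjects, 32 nodes, a common
  10-edge backbone plus 10 patient-only edges at strength 0.6, 140 s
  recordings, 5000 permutations, $q = 0.001$: precision and recall of the
  recovered hyper-connectivity (patients > controls) network against the
  planted edges. The planted edges form a node-disjoint matching on nodes
  the backbone does not touch: when planted edges share nodes with other
  couplings, the co-driven nodes become genuinely correlated in patients
  only, and the resulting true differences off the planted list would be
  scored as false positives of the detector. The confound is a property of
  the generative model and worth knowing about when interpreting edge-level
  results on real data.
* `surrogate_control_study()` — the full pipeline on a cohort whose epochs
  are replaced by phase-randomized surrogates (per-node Fourier amplitudes
  preserved, phases redrawn independently): the group-difference network
  must be empty even at the permissive $q = 0.1$.

Recording durations of 140 s (60 s exclusion + room for eight 8 s epochs)
and 20–32-node source spaces are the package's chosen problem sizes for
these studies; node count, duration and permutation count are all free
parameters of the study functions.

## Numerical choices, in one place

* Phase wrapping maps any $-\pi$ representation onto $+\pi$; bin edges span
  $(-\pi, \pi]$ exactly, values at the lower edge go to the first bin.
* Entropies use natural logarithms; empty cells contribute zero.
* Permutation p-values use the add-one rule; ties between observed and
  permuted statistics count toward the null at a $10^{-12}$ tolerance.
* The jittered-partition fallback in epoching triggers only when rejection
  sampling fails 1000 times (essentially only when the epochs exactly fill
  the usable recording).
* The FFT-based analytic signal assumes the epoch is treated as circular;
  phase estimates at epoch edges are correspondingly less reliable, which
  the delay rule (pooled over the whole epoch) averages out.
* All randomness flows through explicit integer seeds; derived seeds are
  kept below $2^{31}$.

## Limitations

The pTE estimator shares the known biases of histogram transfer entropy:
finite-sample bias grows with bin count, and with $k = 1$ information from
the target's own past can be partially attributed to the source. The
pooled-null default assumes edges are exchangeable under the null, which
z-scoring encourages but does not guarantee in the presence of strong
spatial structure. SWP on very sparse networks is driven almost entirely by
the path-length delta, and its clipping can suppress between-subject
variance. Density is a group-level quantity with no subject variance, as in
the published analysis.
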