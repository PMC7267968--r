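---
title: "Parsing fMRI trials into cognitive states: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parsing fMRI trials into cognitive states: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Event-related fMRI experiments often span tens of seconds per trial, during
which a participant passes through a sequence of cognitive stages — encoding
a problem, solving it, responding, detecting a repetition — whose durations
vary from trial to trial.  `hsmmvpa` segments such trials into a sequence of
latent states directly from multivariate brain activity: each state has a
characteristic spatial activity pattern (its *brain signature*) and a
distribution of dwell times (its *sojourn* distribution).  The output is,
per trial, a posterior probability that each 2-s scan belongs to each state,
from which per-trial state durations follow.

# The model

A trial is an $M \times D$ matrix of z-scored component scores $f_{jk}$
(scan $j$, component $k$; $D = 20$ by default, produced by the spatial PCA
of deconvolved voxel data).  An $N$-state model is *strictly sequential*:
state $i+1$ always follows state $i$; states may be skipped but never
reordered or branched.  Order is therefore identifiable without any label
switching machinery.

**Sojourns.** State $i$ carries a continuous gamma law with shape $v_i$ and
scale $a_i$ (seconds).  Scan durations are whole 2-s scans, so the gamma is
discretized: the probability of occupying $m$ scans is the gamma mass on
$(2m-1,\, 2m+1)$ seconds, and the $m = 0$ bin — mass below 1 s — is the
probability that the state is skipped outright.  The bins partition the
positive axis, so the discretized masses sum to 1.  For a general scan
length $\Delta$ the bins are $(\Delta m - \Delta/2,\, \Delta m + \Delta/2)$.

**Emissions.** Within state $i$, scan vectors are modelled as independent
normals with state means $\mu_{ik}$ and unit standard deviation — the
z-scoring of the reduced data fixes the scale, so the signature is just the
mean vector:
$$P(F_j \mid i) = \prod_{k=1}^{D} \mathcal{N}(f_{jk};\, \mu_{ik},\, 1).$$

**Trial likelihood.** Every way of partitioning the $M$ scans as
$m_1 + \dots + m_N = M$ ($m_i \ge 0$) is considered; the trial likelihood
is the sum over all partitionings of
$\prod_i G_i(m_i) \prod_{j \in \text{segment } i} P(F_j \mid i)$.
The package computes this with an explicit-duration forward–backward
dynamic program in log space, $O(N M^2)$ per trial, implemented in C++.
Its correctness is pinned to a brute-force enumeration oracle over all
compositions for small $M$ and $N$ in the test suite.  Durations far
beyond a state's gamma support (upper tail mass below $10^{-12}$) are
pruned from the recursions; any trial that pruning would make infeasible
is transparently recomputed without pruning.

**Occupancies and sojourn estimates.** The posterior probability that scan
$j$ belongs to state $i$ (the *state occupancy*) sums the probability of
all partitionings assigning $i$ to $j$; rows sum to 1.  Summing occupancies
over scans and multiplying by 2 s gives the expected sojourn of each state
on each trial; these posterior means are used everywhere a per-trial
duration estimate is needed (rather than the single best partitioning).

# Estimation

`em_fit()` runs expectation maximization:

* **Initialization** (`neutral_initialize()`) is deterministic: all
  emission means 0 (the uninformative signature for z-scored data) and all
  sojourns gamma with shape 2 and mean equal to the mean trial duration
  divided by $N$.  States start exchangeable; the sequential topology
  breaks the symmetry because each state can only occupy its own temporal
  window.  Deterministic initialization keeps every fit reproducible.
* **E step**: forward–backward per trial, yielding trial log likelihoods,
  occupancies, and the posterior distribution over each state's duration.
* **M step**: emission means are occupancy-weighted data means; sojourn
  parameters maximize the expected complete-data log likelihood
  $\sum_d \eta_i(d) \log G(d \mid v, a)$ of the discretized gamma by
  Nelder–Mead on $(\log v, \log a)$, warm-started from the current
  parameters with a moment-matched fallback.  Shapes are constrained to
  $[0.1, 50]$.  Sufficient statistics are pooled within tying groups
  (below).  A state whose total occupancy collapses below $10^{-8}$ keeps
  its previous parameters and is flagged.
* **Convergence**: the summed log likelihood is non-decreasing (the M step
  never moves to a worse point because the optimizer's simplex includes
  the current parameters); iteration stops when the gain drops below `tol`
  (default $10^{-3}$) or after `max_iter` (default 200) iterations.

**Condition tying.** With several experimental conditions, three
specifications are supported: `all_shared` (one parameter set per state),
`state1_separate` (only the first state differs by condition), and
`all_separate` (every state differs).  The tying map assigns a parameter
group to each (state, condition) pair and EM pools statistics within
groups, so any intermediate scheme can also be built by hand.

# Choosing the number of states

More states always fit the training subjects better, so the package scores
specifications by leave-one-subject-out cross-validation (`loocv()`): fit
on all but one subject from neutral initialization, evaluate the held-out
subject's summed log likelihood, rotate.  A specification with more
parameters is preferred only if it predicts *significantly more subjects*
better, assessed with a one-sided sign test at chance $1/2$
(`sign_test_compare()`; exact ties are dropped, the standard sign-test
treatment).  `select_n_states()` returns the largest $N$ that beats every
smaller $N$ at `alpha` (default .01, the threshold at which 16 of 20
subjects predicted better is significant).  Each fold refits from neutral
initialization rather than warm-starting, so folds are independent.

Cross-validation can legitimately prefer *more* states than generated the
data: scans that straddle a state boundary carry a blend of two
signatures, and temporally correlated noise rewards short states that
absorb transitions.  The symptoms are *splits* (two fitted states covering
one true state) and *bridges* (a roughly one-scan state correlated with
both neighbours).  `adjacent_state_correlation()` and
`classify_excess_states()` diagnose them; the classification thresholds
(neighbour correlation > 0.5, bridge mean sojourn ≤ 1.5 scans) are
documented tunables, since no canonical cutoff exists.  High-state
solutions with strongly correlated adjacent states deserve caution; a
theoretically motivated smaller model that still beats all smaller counts
is often the better choice.

# Preprocessing chain

`preprocess_runs()` applies, in a fixed order: per-voxel mean-100
normalization; fourth-degree polynomial detrending (orthogonal basis, the
constant removed with the drift — downstream l2-normalization makes the
offset immaterial); Wiener deconvolution of the hemodynamic response;
concatenation of runs; l2-normalization of each scan vector; spatial PCA;
z-scoring of the retained component scores; truncation to $[-5, 5]$.

The HRF kernel is the canonical difference of gammas,
$h(t) = \gamma(t; 6, 1) - \gamma(t; 16, 1)/6$, sampled at the repetition
time over 32 s (tail mass beyond is negligible); it is zero at $t = 0$,
peaks near 5 s, and undershoots around 15 s.  Deconvolution divides in the
frequency domain by $|H|^2 + \phi$ with noise-to-signal $\phi = 0.1$ by
default; a wide range of plausible $\phi$ yields similar series, which the
test suite checks.  Series are zero-padded to the next power of two at
least series + kernel length to avoid circular wrap-around.  PCA loading
signs are fixed by making each loading's largest-magnitude element
positive, for reproducibility.  Trials with more than 2 scans containing
an extreme value (|z| > 5 in any component) can be dropped with
`drop_outlier_trials()`; the per-scan "extreme" rule is a documented
stand-in and tunable.  `backproject_states()` maps fitted states back to
voxel space as occupancy-weighted mean activity, per state and condition.

# The synthetic generator

`ground_truth_design()` and `generate_experiment()` produce fully audited
synthetic experiments for parameter-recovery studies:

* **State structure** (`sample_ground_truth()`): mean sojourns
  $M_i \sim U(2, 8)$ s and gamma shapes $a_i \sim U(2, 5)$, so the
  population scale is $b_i = M_i / a_i$; six such states total 30 s on
  average, a typical trial length.  Population signatures are standard
  normal in each of 20 components.
* **Subjects**: subject $j$ draws scales
  $b_{ij} \sim \Gamma(15,\, b_i / 15)$ — so subject mean sojourns scatter
  with relative SD $1/\sqrt{15} \approx 0.258$ — and signatures
  $B_{kij} = B_{ki} + 0.5\,\mathcal{N}(0,1)$.
* **Trials**: durations $t_{ij} \sim \Gamma(a_i,\, b_{ij})$.  The trial
  occupies $M = \mathrm{round}(\sum_i t_{ij} / 2)$ scans (at least 1; the
  rounding rule is the package's choice).  In `partial` mode the signal at
  a scan is the signature blend weighted by each state's overlap with the
  2-s window; in `whole` mode boundaries are first rounded to scan edges,
  so weights are 0/1 and a state rounded to zero length counts as skipped.
* **Noise**: the `correlated` kind emulates the temporal and tail
  structure of real z-scored component scores — each column is a running
  sum of four consecutive $t_3$ draws,
  $N_t = T_3(t) + T_3(t+1) + T_3(t+2) + T_3(t+3)$, giving lag-$k$
  autocorrelation $(4-k)/4$ and roughly 60-fold excess mass beyond 4 SD
  relative to a normal.  The un-normalized sum is implemented as stated;
  its scale is irrelevant after SNR mixing and z-scoring.  The `iid` kind
  is standard normal.
* **Mixing** (`mix_snr()`): $F = S + a\,N$ with
  $a = \sqrt{\sigma^2_S / (\sigma^2_N\, \mathrm{SNR})}$, variances pooled
  over the entire data set (not per trial), so the realized
  signal-to-noise variance ratio equals the requested SNR by
  construction.  The mixture is then z-scored per component over the data
  set and truncated to $[-5, 5]$, exactly as real reduced data are
  prepared.
* **Condition effects**: a named list of per-state mean sojourns per
  condition; affected states' subject scales are rescaled by the ratio of
  condition mean to population mean, so condition effects act
  multiplicatively on each subject's mean.

Every generated data set carries its ground truth (continuous and
effective in-window durations, occupancy weights, subject parameters, the
z-scoring map), so recovery is auditable and `true_model()` can express
the generating model in the fitted data space.

**What the generator does and does not emulate.**  It reproduces the
statistical skeleton of reduced fMRI data — sequential states with
gamma sojourns, heavy-tailed autocorrelated noise, subject heterogeneity,
SNR-controlled mixing — but not spatial voxel structure, scanner drift,
motion artifacts, non-stationary noise, or hemodynamic blurring (the
generator works directly in the reduced space, downstream of
deconvolution).  Passing recovery tests therefore demonstrates the
estimator's behaviour under the assumed data model, not robustness to
every pathology of real scans.

# Recovery evaluation

`evaluate_recovery()` computes the two standard recovery measures.

**Matching.**  Fitted states are aligned to generating states by the
order-preserving assignment maximizing summed signature correlation
(`match_states()`), with unmatched states reported.  For a well-aligned
fit with equal state counts this is the identity.  The flexible matching
matters at high state counts, where the maximum-likelihood solution often
contains a bridge state followed by a one-position shift: every
generating signature is still well recovered by *some* fitted state, and
mechanical index pairing would misreport that solution as a wholesale
failure.  Of note, such shifted solutions can reach a *higher* training
likelihood than the generating parameters — they are not local minima but
genuine features of the likelihood surface under scan-quantized data.

**Signature correlations** are computed after mapping fitted emission
means back through the data set's z-scoring ($\mu \cdot s_k + c_k$ per
component), i.e. in the generating space.  Correlating across the
z-scoring instead would cap the attainable correlation near 0.89 even for
perfect fits, because z-scoring subtracts an occupancy-weighted mixture
of the signatures from every component.

**Sojourn errors.**  The headline error is at the state level:
$|\bar{t}^{\text{est}}_i - \bar{t}^{\text{true}}_i| / \bar{t}^{\text{true}}_i$
with means over all trials, averaged over states.  Per-trial proportional
errors (also reported, as `trial_sojourn_err`) are several-fold larger
for any estimator, since single-trial estimates are quantized to 2-s
scans; a state of a few seconds cannot be located on one trial to better
than a scan.  True durations are the effective in-window durations, which
sum to the trial length exactly as the estimates do.  Skipped states
(zero true duration) are excluded and flagged.

**Boundary deviation.**  `boundary_rmsd()` measures, for each reference
boundary, the distance to the closest estimated boundary, and returns the
RMSD.  `chance_rmsd_threshold()` calibrates it: random placement of the
same number of boundaries, Monte Carlo quantiles of the resulting RMSD
(default $10^5$ repetitions; the single-boundary case has the analytic
quantile $p \cdot \mathrm{span}/2$ against a centered reference, which
the tests verify), plus the equally-spaced baseline.

**Local minima.**  `detect_local_minimum()` compares the neutral-start
fit with a fit initialized at the generating parameters and flags the
data set when the neutral start ends more than 1 log-likelihood unit
below — an explicit, conservative criterion.  Local minima are rare at
small state counts and increasingly common at high ones; flagged fits
recover the state structure poorly and should be excluded or refit.

# Numerical choices and defaults

| parameter | default | role |
|---|---|---|
| `timepoint_seconds` | 2 | scan duration (TR); discretization bin width |
| `tol` (EM) | 1e-3 | stop when the summed log likelihood gains less |
| `max_iter` (EM) | 200 | iteration cap |
| shape bounds | [0.1, 50] | gamma shape constraint in the M step |
| `alpha` (selection) | .01 | sign-test threshold |
| `noise_to_signal` | 0.1 | Wiener regularizer |
| `n_components` | 20 | retained PCA components |
| truncation bound | 5 | |z| clip after z-scoring |
| `snr` | 0.1 | generator default; the regime that matches typical task fMRI |
| bridge rule | cor > .5, ≤ 1.5 scans | excess-state classification |

All likelihood work is in log space with max-shifted log-sum-exp;
duration masses are floored at $10^{-300}$ inside EM so a single far-out
duration cannot annihilate a trial.  Degenerate trials shorter than the
state count are handled naturally, since any subset of states may take
duration 0.

# Design decisions on open points

* The package's general recovery studies (`run_recovery_study()`) mix the
  state signal with **iid normal noise** and **partial occupancy** by
  default; this is the construction whose recovery behaviour the package
  documents (signature correlation ≈ .98 and state-level sojourn error
  below ≈ 8% at SNR 0.1 with 6 states).  The correlated-t noise remains
  the generator default elsewhere, as the more realistic emulation of
  reduced fMRI data; under it, recovery at the same SNR is slightly worse
  (correlation ≈ .96) because the autocorrelated noise violates the
  emission independence assumption.
* LOOCV refits every fold from neutral initialization; warm-starting
  across folds or state counts would couple the folds.
* The sojourn-duration sweep draws state means uniformly on
  $[0.4, 1.6] \times$ base sojourn.
* Whole-occupancy rounding uses nearest scan edges with monotonicity
  enforced; states rounded to zero length are treated as skipped.
* Test-suite problem sizes: the DP oracle runs exhaustively for
  $M \le 8, N \le 3$; generator laws use $10^5$–$10^6$ draws; the 6-state
  recovery check uses 10 seeded data sets at 20 subjects × 100 trials; the
  2×2 selection study is rendered at one data set per cell — the clean
  cell runs the full 1–7-state selection at 14 subjects × 80 trials, the
  correlated-noise/partial-occupancy cell runs the decisive 6-vs-7 sign
  test at 20 subjects × 100 trials (the comparison needs that much
  per-subject data for sign-test power), and the remaining cells run
  targeted sign tests at 14 × 80; the state-count sweep end point uses
  two 14-state data sets at full size plus smaller replicates for the
  local-minimum rate.  These sizes are the package's choices for a
  single-CPU run; the acceptance script (`scripts/acceptance.R`)
  recomputes the headline recovery quantities at 10 data sets.

# Known limitations

* Scans briefer than ~2 s cannot be resolved: states with mean sojourns
  near half a scan are recovered poorly (the short-sojourn sweep shows
  the sharp degradation below ~2 s), unless other conditions make the
  same state long enough to pin its signature.
* Strictly sequential topology only: no branching, no parallel states,
  no revisits.  Per-state emission variances and non-gamma sojourn
  families are out of scope.
* The emission model assumes temporally independent scans; autocorrelated
  noise is handled only through its effect on the likelihood, which is
  one driver of excess-state solutions.
* At high state counts the likelihood surface genuinely supports shifted
  and bridged solutions with likelihoods above the generating parameters;
  model selection should be read together with the adjacent-correlation
  diagnostics rather than as ground truth.
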