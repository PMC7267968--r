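# hsmmvpa

Parsing event-related fMRI trials into sequences of latent cognitive
states with an explicit-duration hidden semi-Markov model over
multivoxel activity patterns (HSMM-MVPA).

## The problem

Many cognitive tasks — problem solving, multi-step reasoning — unfold
over tens of seconds, passing through stages whose durations vary from
trial to trial.  Standard event-related analyses average over this
variability.  `hsmmvpa` instead treats each trial as a sequence of
latent *states*: each state has a brain *signature* (a mean activity
pattern in a reduced component space) and a gamma-distributed *sojourn*
time, and states follow one another in a fixed order (states may be
skipped, never reordered).  Fitting the model yields, per trial, the
posterior probability that each 2-s scan belongs to each state — the
*state occupancies* — and from them per-trial state durations.

## The model

For a trial of `M` scans with z-scored component scores `f_jk`
(`D = 20` components), an `N`-state model specifies:

- sojourn laws: the probability of spending `m` scans in state `i` is
  the mass of a gamma(`v_i`, `a_i`) on `(2m-1, 2m+1)` seconds; mass
  below 1 s means the state is skipped;
- emissions: `P(F_j | i) = prod_k Normal(f_jk; mu_ik, 1)`;
- the trial likelihood sums `prod_i G_i(m_i) * prod_j P(F_j | i)` over
  **all** partitionings `m_1 + ... + m_N = M`, computed by an
  explicit-duration forward–backward dynamic program (Rcpp, `O(N M^2)`
  per trial).

Parameters are estimated by EM from a deterministic neutral start;
the number of states and the condition-tying scheme are chosen by
leave-one-subject-out cross-validation with sign tests.  A synthetic-data
generator (gamma sojourns, subject-level heterogeneity, heavy-tailed
autocorrelated noise, SNR-controlled mixing) and recovery metrics
(signature correlations, proportional sojourn errors, boundary RMSD with
Monte Carlo chance thresholds) support parameter-recovery studies.
The methods vignette (`vignettes/hsmm-mvpa-methods.Rmd`) documents the
model, the estimation details and every numerical choice.

## Worked example

Simulate a 6-state experiment at the signal-to-noise ratio typical of
task fMRI (0.1), fit it blind, and score recovery:

```r
library(hsmmvpa)

set.seed(1)
design <- sample_ground_truth(n_states = 6)   # means U(2,8) s, shapes U(2,5)
synth  <- generate_experiment(design)         # 20 subjects x 100 trials
fit    <- em_fit(synth$trials, n_states = 6)
fit
#> <hsmm_fit> logLik -856374.492 after 80 EM iterations (converged)
#> <hsmm_model> 6 sequential states, 6 parameter group(s), D = 20, dt = 2 s
#>   condition all: mean sojourns 3.81, 4.92, 5.47, 5.40, 4.44, 7.40 s

design$mean_sojourns
#> [1] 3.593052 4.232743 5.437120 7.449247 3.210092 7.390338

evaluate_recovery(fit, synth)
#> <recovery_report> 6 fitted states; mean signature r 0.953; mean sojourn error 0.177
```

The six fitted signatures correlate r = .95 with the generating ones.
The state-level sojourn error of .18 on this particular data set is
above the ~.06 typical at this SNR: the fit blurs the boundary between
the long state 4 and the short state 5 (their fitted means, 5.40 and
4.44 s, split the difference of the true 7.45 and 3.21 s).  Averaged
over seeded data sets — which is what `run_recovery_study()` and
`scripts/acceptance.R` do, excluding the occasional local-minimum fit —
the mean signature correlation is ≈ .97–.98 and the mean sojourn error
≈ 5–7%.  Per-trial state durations come from the occupancies:

```r
occ <- occupancy(fit, synth$trials[1])        # M x 6 posterior matrix
expected_sojourns(occ)                        # seconds, sums to trial length
#> [1]  1.6509  1.5178  1.8899  0.8028 13.3889  4.7497
```

Model selection on stored data, from the shell:

```sh
Rscript inst/exec/hsmmvpa simulate --config sim.json
Rscript inst/exec/hsmmvpa select   --config select.json
```

writes held-out log likelihoods per subject, all pairwise sign tests,
and the chosen number of states with adjacent-state correlation
warnings.

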