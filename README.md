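# symdyad

Symbolic dynamics and Markov transition networks for dyadic
(patient–therapist) linguistic time series.

## The problem

Computer-assisted content analysis of psychotherapy transcripts (in the
Therapeutic Cycle Model tradition) produces, for every 150-word block of
a session, the relative frequencies of three dictionaries per speaker:
positive emotional tone (POS), negative emotional tone (NEG) and
abstraction (AB). A whole brief therapy then becomes a six-column
multivariate time series — three features for the patient, three for the
therapist — with thousands of word-blocks as rows.

`symdyad` treats that series as a discrete dynamical system:

1. **Discretization.** Each role's blocks are z-scored and clustered by
   k-means (k = 8 by default, multi-restart with D²-weighted seeding,
   states relabelled by descending occupancy). Each cluster is a *state*
   of the system; scarcely populated states (occupancy share < 1%) are
   treated as outliers, and their blocks are deleted.
2. **Markov transition networks.** The state sequence yields a
   first-order Markov transition matrix (MTM): `T[i, j]` is the
   conditional probability of moving from state *i* to state *j* in one
   step. Matrices stay at the full k×k size with undefined rows kept
   blank, so all subjects share one index space. Interleaved
   patient→therapist and therapist→patient matrices capture the dyadic
   dynamic. Networks export to DOT/GraphML with row-maximum transitions
   flagged.
3. **Direct comparison.** Pairwise Pearson correlations between
   linearized MTMs, and the DeltaCorr index
   `DeltaCorr(i, j) = CorrPat(i, j) − CorrTher(i, j)`,
   summarised by outcome class with normal-approximation 95% CIs
   (mean ± 1.96·sd/√n).
4. **Transition laws.** Standardized OLS of the linearized transition
   probabilities on candidate regressors: inter-state centroid distance
   `d_ij` (distance-dependent law), destination frequency `f_j` (fully
   ergodic law), and the composite frequency `f_i·f_j` (random-walk
   law), plus the two-regressor model
   `y = a·d_ij + b·f_i·f_j`.
   Reported per subject: standardized β's, R, R², adjusted R²
   (`1 − (1−R²)(N−1)/(N−k−1)`), the model F-test p, and the β ratio
   `|b|/|a|`.
5. **Non-stationarity.** Odds ratios comparing each state's occupancy
   between the first and last thirds of the treatment
   (`OR = a(n2−b)/(b(n1−a))`, Yates-corrected chi-square by default,
   Benjamini–Hochberg column alongside).

Because clinical transcripts are not publicly available, the package
ships a synthetic dyad generator with known ground truth: a k-state
Markov chain whose kernel mixes a centroid-distance penalty and a
state-frequency attraction,
`T_ij ∝ w_freq·f_i·f_j + w_dist·exp(−d_ij/λ)`,
with Gaussian emission noise around state centroids and a tunable
patient→therapist coupling. Every downstream stage has a
parameter-recovery test against this generator.

## Worked example

The numbered scripts under `analysis/` run the whole study on a
synthetic cohort of 8 dyads (4 good-outcome, 4 poor-outcome; 1000 blocks
each) and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R --seed 1   # cohort block series + ground truth
Rscript analysis/02_states.R   --seed 1   # clustering and pruning
Rscript analysis/03_networks.R            # transition matrices and exports
Rscript analysis/04_compare.R             # correlations and DeltaCorr
Rscript analysis/05_transition_law.R      # transition-law regressions
Rscript analysis/06_drift.R               # odds-ratio drift screen
```

Output from a run with seed 1:

```
patient: variance explained 89.9%, 6/8 states survive 1% pruning (dropped: 7,8)
therapist: variance explained 87.0%, 5/8 states survive 1% pruning (dropped: 6,7,8)
patient matrices: mean pairwise r = 0.930 (sd 0.025)
therapist matrices: mean pairwise r = 0.864 (sd 0.114)
DeltaCorr good-good: mean -0.034 (sd 0.023), 95% CI [-0.053, -0.015] - excludes zero
DeltaCorr poor-poor: mean 0.167 (sd 0.153), 95% CI [0.044, 0.289] - excludes zero
patient: mean beta_dist -0.046, beta_comp +0.629, adj R2 0.384
therapist: mean beta_dist +0.058, beta_comp +0.650, adj R2 0.349
drift screen: 4 of 88 subject-state tests flagged at alpha = 0.05 (0 after BH)
```

Reading this: the generator plants 2 patient and 3 therapist rare
states, and 1% pruning recovers exactly the 6 and 5 active states; the
patients' matrices correlate more tightly with each other than the
(deliberately heterogeneous) poor-outcome therapists' do, so DeltaCorr
is positive in the poor–poor class and slightly negative in good–good;
both roles' transitions are dominated by the composite state frequency
(β_comp ≫ |β_dist|), with the patients' small negative and the
therapists' near-zero distance dependence mirroring their generating
laws; and a stationary cohort shows only a chance-level number of drift
flags, none surviving multiplicity adjustment.

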