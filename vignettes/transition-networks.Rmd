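---
title: "Symbolic dynamics and transition-law regression for dyadic linguistic series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symbolic dynamics and transition-law regression for dyadic linguistic series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symdyad)
```

## The model

`symdyad` analyses a psychotherapy (or any dyadic interaction coded the
same way) as a discrete dynamical system. The observed data are
word-block tables: for every consecutive 150-word block of transcript,
the relative frequency of three dictionaries — positive emotional tone,
negative emotional tone, abstraction — for each of the two speakers.
The pipeline makes three modelling moves, each with its own
assumptions:

1. **States are clusters.** Each role's three features are z-scored and
   partitioned by k-means; a block's state is its nearest centroid.
   This assumes the system occupies a modest number of recurrent
   linguistic configurations ("quasi-attractors") and that Euclidean
   distance in standardized feature space is a meaningful dissimilarity.
2. **Dynamics are first-order Markov.** The state sequence is summarised
   by its one-step transition matrix. Longer-range dependence is
   deliberately ignored; the non-stationarity screen (below) is the
   only concession to time-varying structure.
3. **Transition laws are linear in two candidate drivers.** The
   linearized transition probabilities are regressed (standardized OLS)
   on the inter-state centroid distance and on the composite frequency
   `f_i * f_j`. The competing "laws" — distance-dependent,
   destination-frequency (ergodic), and composite-frequency
   (random-walk) — are compared by adjusted R².

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `block_size` | 150 | words | the coding tradition's unit of analysis; all frequencies share this denominator |
| `k` | 8 | states | the cluster solution balancing information and interpretability for this kind of data |
| `n_restarts` | 50 | restarts | k-means is seeded by D²-weighted (k-means++) draws; 50 restarts make the best-of within-SS stable across seeds |
| `min_share` | 0.01 | occupancy fraction | "scarcely populated" operationalized as under 1% of pooled blocks |
| `cell_policy` | `both_defined` | — | undefined MTM rows are excluded from correlations, not imputed as zeros; `union_zero` is available for sensitivity analysis |
| `include_diagonal` | `TRUE` | — | self-transitions are real transitions of the matrix; a flag drops them for sensitivity analysis |
| `correction` | `yates` | — | default chi-square correction for the 2×2 drift tables; `none` and `fisher` are available |

Generator (`generator_config`): `w_dist`, `w_freq` ≥ 0 mix the two
kernel components; `length_scale` (λ, standardized distance units) sets
how fast the distance kernel decays; `emission_sd` (σ, standardized
feature units) is the Gaussian noise around centroids; `coupling`
(κ ∈ [0, 1]) is the probability the therapist copies a mapped version
of the patient's state instead of following their own chain.

## Conventions and decisions where the design was open

**Dictionary scoring.** Frequencies are computed against the full block
size, not the speaker's word count, so a silent speaker scores
(0, 0, 0) — this is what makes an "all minus signs after
standardization" silence state possible. Dictionaries must be pairwise
disjoint (the published word lists are proprietary, so users supply
their own); with disjoint dictionaries the three frequencies of one
speaker can never sum above 1. Trailing partial blocks are dropped to
keep every block on the same denominator. Tokenization is the caller's
job: the package only lowercases and matches exactly.

**Pooled clustering.** States are fit on data pooled across all
subjects of a role. Cross-subject comparison of transition matrices
(correlations, DeltaCorr) only makes sense in one shared state space.
The variance explained is reported per role; it is a description of the
discretization, not a fit target.

**k-means seeding.** Plain random-restart seeding reliably misses
clusters that hold a fraction of a percent of the data far from the
bulk — precisely the "outlier" states the pruning step is about — so
`fit_states` seeds each restart with D²-weighted (k-means++) draws and
keeps the best of 50 restarts by within-cluster sum of squares. States
are relabelled 1..k by descending occupancy, making the labelling
deterministic given the seed. If the data contain exactly k distinct
rows the perfect partition is constructed directly.

**Pruning.** Only the occupancy criterion is operationalized (share
below `min_share` on the pooled fit); a distance-based outlier
criterion would need a threshold no published account quantifies. The
blocks of pruned states are deleted and the sequence re-concatenated,
so a transition can span a deletion; `count_transitions(breaks = ...)`
supports breaking the chain at deletions instead. Pruning decisions are
made once, on the pooled occupancy, and applied to every subject, so
all subjects keep one index space with undefined rows where a state was
never visited.

**Dyad direction semantics.** The interleaved dyadic dynamic
Pat(1), Ther(1), Pat(2), Ther(2), ... is summarised as
patient-to-therapist pairs (pat_t → ther_t) and therapist-to-patient
pairs (ther_t → pat_{t+1}), aligned on blocks surviving pruning in both
roles. A dyad matrix's rows are indexed by the source role's state
space and its columns by the target role's own state space — the two
spaces need not have the same number of active states.
`dyad_mtm(interleaved_chain = TRUE)` implements the alternative reading
(the full interleaved sequence as a single chain over one shared state
space).

**DeltaCorr class CIs.** The 95% interval is the normal approximation
mean ± 1.96·sd/√n. A t-based interval was considered and rejected: on
the published class moments (mean 0.105, sd 0.100, n 6) only the
z-based interval reproduces the published bounds (0.025, 0.185), so the
normal approximation is what the method, as practiced, computes.

**Regression cells and N.** One design row per ordered pair (i, j) of
active states with the source row defined, diagonal included; with six
active states that is N = 36 cells. Published per-subject adjusted R²
values are not recoverable under any natural N (back-solving points to
a smaller, unreported cell count), so the package uses N = number of
design rows and treats printed adjusted R² values as context, not
targets. "Normalized" coefficients are standardized (z-scored) OLS
betas; for a single regressor the beta equals the plain Pearson
correlation, which the tests exploit as an oracle.

**Drift testing.** Thirds are the leading and trailing floor(n/3)
labels, so the two segments always have equal length. Published
per-test p-values for this procedure are not reproducible from their
own printed counts with any standard 2×2 test (Yates, uncorrected, or
Fisher), so the package standardizes — Yates-corrected chi-square by
default, the alternatives selectable — rather than reverse-engineering
an unknown variant. Zero cells leave the odds ratio undefined unless
the Haldane–Anscombe +0.5 correction is explicitly requested. Raw
p-values are flagged at α = 0.05 to mirror the per-state screen, and a
Benjamini–Hochberg column is always emitted alongside.

## The synthetic generator: what it emulates, what it does not

The generator exists so that every stage has a parameter-recovery test
without access to clinical transcripts. One speaker's states follow a
Markov chain with kernel

```
T_ij ∝ w_freq · f_i · f_j + w_dist · exp(−d_ij / λ)
```

row-normalized, where `d_ij` is the Euclidean distance between state
centroids and `f` is a target frequency profile. The kernel is an
additive mixture, not log-linear, deliberately matching the additive
regression the pipeline fits: recovery of the generating weights by the
regression is then interpretable. The exponential distance kernel is
the simplest monotone choice consistent with "transitions fall off with
distance". Emissions are the state centroid plus isotropic Gaussian
noise, mapped to the [0, 1] frequency scale by per-feature mean/sd and
clipped (clipping is counted; above 5% a warning is raised). Dyadic
coupling: at each block the therapist copies a deterministic map of the
patient's state with probability κ, else advances by their own chain.

The default cohort (`cohort_configs`) encodes the study-shaped
conditions: 8 dyads (4 good, 4 poor outcome), 8 states per role at the
sign-pattern corners of (POS, NEG, AB) space, occupancy profiles
decaying geometrically with 2 (patient) and 3 (therapist) rare states,
series of 1000 blocks per dyad. Specific choices worth recording:

- **Rare states are far as well as scarce** (placed at 5× the major
  cube radius): scarce states in the motivating data also lay far from
  the bulk, and the separation is what lets an 8-center k-means
  solution isolate clusters holding ~0.3% of the data instead of
  splitting a dominant cluster.
- **Patient rare target share 0.0008**: the distance kernel's unit
  diagonal makes rare states sticky (self-transition ≈ 0.8 at these
  weights), inflating realized occupancy roughly six-fold over the
  target; 0.0008 keeps the realized share safely under the 1% pruning
  threshold. Target and realized (stationary) frequencies are reported
  side by side by `analysis/01_simulate.R` — they differ by design and
  are never silently equated.
- **Patients mix laws (w_dist = 0.005, λ = 2), therapists are purely
  frequency-driven (w_dist = 0)**: this reproduces the qualitative
  asymmetry the pipeline should detect — a small negative patient
  distance beta, a near-zero therapist one, composite frequency
  dominant for both. Note the additive kernel's components live on very
  different scales (`f_i·f_j` ~ 10⁻²–10⁻¹, `exp(−d/λ)` up to 1), so
  small `w_dist` values already carry substantial distance influence.
- **Poor-outcome therapists get per-subject log-normal (sd 0.7)
  perturbations of their frequency profile**, making their dynamics
  mutually heterogeneous; that is the mechanism behind a positive
  poor–poor DeltaCorr with a tighter, slightly negative good–good
  class.
- **Emission σ = 0.35** in standardized units with back-transform
  mean 0.15 / sd 0.025 per feature: no clipping in practice, cluster
  recovery is reliable, and the pooled solutions explain slightly under
  90% of the variance — cleaner than real transcript codings, which is
  the point of a recovery study but also its limitation.

What the generator does **not** emulate: natural-language content,
non-Markov (long-memory) dependence, session boundaries, within-subject
drift of the centroids themselves, or measurement error in the
dictionary coding. Passing recovery tests therefore shows the
estimators are correct under the stated model, not that real therapy
data satisfy that model.

## Numerical choices

- Defined MTM rows must sum to 1 within 1e-9; the generator's rows are
  exactly stochastic to 1e-12. Undefined rows are `NA`, never zeros.
- Nearest-centroid assignment breaks exact ties toward the lower state
  label; row-maximum flags in network exports mark all tied maxima.
- Chain sampling inverts the cumulative kernel rows with `findInterval`
  and guards the last bin against 1e-9-scale rounding.
- Every stochastic operation takes an explicit seed; dyad and cohort
  simulations derive stage sub-seeds with a linear-congruential rule
  (`derive_seed`), all below 2³¹.
- Degenerate inputs fail loudly: zero-variance feature columns,
  all-zero kernel rows, collinear regressors, zero-variance responses,
  empty classes and empty segments are all errors naming the offending
  object.

## Problem sizes

The shipped analyses and tests use a cohort of 8 dyads × 1000 blocks
(clustered on 8000 pooled blocks per role), 100-seed recovery batches
of 5000-step chains for the transition-law checks, 500 simulated
subjects for drift type-I calibration and 100 for power. These sizes
give Monte-Carlo error comfortably below the decision margins they feed
(e.g. a ≥ 95% sign-recovery criterion with binomial se ≈ 2% at the
observed rates).

## Known limitations

- Regression cells of one matrix are treated as independent
  observations, as the method prescribes; rows of a stochastic matrix
  are in fact constrained (each sums to 1), so the model p-values are
  optimistic. The package reproduces the method as defined and leaves
  row-constraint-aware inference out of scope.
- The drift screen inherits the occupancy dependence of adjacent
  blocks: on sticky chains the type-I rate exceeds the nominal α. The
  calibration test uses an i.i.d.-row chain where the nominal level is
  exact; on autocorrelated chains the screen is a flagging heuristic,
  which is how its results are reported.
- The beta ratio `|β_comp|/|β_dist|` is unstable when `β_dist` is near
  zero (it is reported as undefined at exactly zero); cohort summaries
  therefore also report the signed means themselves.
- Probabilities are modelled by OLS, not a bounded-response likelihood;
  predicted values outside [0, 1] are possible and harmless for the
  comparative use the statistics are put to.
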