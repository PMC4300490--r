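---
title: "Methods: co-stimulation phosphoproteomics and logic-ODE modelling with costim"
author: "costim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-stimulation phosphoproteomics and logic-ODE modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(costim)
```

## The experimental system

Budding yeast responds to hyper-osmotic shock (NaCl) and to mating
pheromone (alpha-factor) through two MAPK cascades — the HOG pathway
(Sln1/Sho1 → Pbs2 → Hog1) and the pheromone pathway (Ste20 → Ste11 →
Ste7 → Fus3) — which share upstream components (Cdc42, Ste20, Ste11,
Ste50) and therefore crosstalk. `costim` analyses *double time-course*
phosphoproteomics of this system: cultures are stimulated with NaCl for
one period and with pheromone for another, over all combinations of six
periods (0, 1, 5, 10, 20 and 45 min; 0 = never applied), giving a 6 × 6
co-stimulation matrix of 36 conditions with three biological replicates
each. Each measured phosphopeptide (P-pep) then carries a 6 × 6
intensity surface whose structure along one stimulus axis, and whose
modulation by the other stimulus, are the objects of analysis.

The package implements the full path from replicate-level intensities to
model-based inference:

1. **Preprocessing** — total-ion-current (TIC) normalisation, feature
   merging, detection filtering, replicate averaging, cubic-spline
   imputation (`tic_normalize()`, `merge_features()`,
   `detection_filter()`, `average_replicates()`, `impute_spline()`).
2. **Dynamic-effect classification** — per peptide and per modulating
   stimulus: Shape Effect, Intensity Effect or No Effect
   (`classify_effects()`); global profile clustering (`hier_cluster()`).
3. **Specificity statistics** — ratio matrices/vectors quantifying how
   one stimulus modulates the response to the other
   (`specificity_matrix()`, `specificity_vector()`), plus an automated
   similar/opposite pattern screen (`pattern_match()`).
4. **Model building** — CV and missingness filters, affinity-propagation
   merging of redundant trajectories, substitution of peptides into a
   protein-level prior network with combinatorial edge expansion,
   mechanistic variants and a 23-model ensemble (`cv_filter()`,
   `missingness_filter()`, `ap_merge()`, `build_pepnet()`,
   `apply_variant()`, `enumerate_ensemble()`).
5. **Logic-ODE fitting** — Hill normalisation of the data, the logic-ODE
   transform, seeded multistart fitting and MSE/AIC model comparison
   (`hill_normalize()`, `fit_logic_ode()`, `compare_models()`).

Because the original mass-spectrometry measurements are not shipped, a
synthetic-data generator with *planted ground truth* stands in for them
(`panel_effects()`, `panel_modeling()`, `sim_costim()`); every
downstream stage is tested against what was planted.

## The synthetic-data generator

Each synthetic peptide follows a **base shape** along the time axis of
its *driving* stimulus:

* `SPIKE` — $s(t) = (t/p)\,e^{1 - t/p}$ with peak time $p$ (default
  5 min): the fast, transient Hog1-like response;
* `GRADUAL` — a logistic rise with half-time 10 min (slope 3 min) and a
  slow linear decay after 20 min: the Fus3-like response peaking around
  20 min;
* `SUSTAINED` — $1 - e^{-t/5}$; `FLAT` — constant.

Non-flat shapes carry a 10% basal offset so intensities are strictly
positive (a surface value of zero is not a valid MS intensity). A
**crosstalk modifier** driven by the *other* stimulus' duration then
distorts the surface: `DIP_AT(t2)` multiplies one duration column by a
dip factor (default 0.3, mimicking the transient loss of doubly
phosphorylated Hog1 one minute after pheromone); `SCALE_BY_T2` scales
columns linearly up to 2.5-fold (pure level modulation);
`PHASE_SHIFT_BY_T2` shifts the characteristic time in three duration
groups (6 min per group), producing three clearly different curve
shapes. Planted effect labels follow the construction: the modifier
determines the label for the modulating stimulus (`SCALE`/`DIP` ⇒
Intensity, `PHASE_SHIFT` ⇒ Shape), and any non-flat responder is an
Intensity effect along its own driving axis, because its response level
varies strongly with its own stimulation period. Effect sizes (2.5-fold
scaling, 0.3 dip, 6-min shifts) are of the order seen for the strongly
responding MAPK peptides in this system, where activation changes span
several fold.

**Noise model.** Observed intensity = truth × run scale ×
$e^{\varepsilon}$, with $\varepsilon \sim N(0, \sigma)$,
$\sigma = \sqrt{\log(1 + \mathrm{CV}^2)}$, one log-normal scale factor
per run (one run = one condition × replicate; spread 0.15 on the log
scale by default), and missing-completely-at-random dropout (an optional
logistic-in-log-intensity dropout is available for robustness studies).
Defaults (CV 0.2, 5% missingness) describe a routine label-free shotgun
experiment. The recorded run TIC is the sum of the panel's observed
intensities **plus a stable background total** (20 × the panel-average
run total, scaled by the run factor) representing the rest of the
detected phosphoproteome: a real TIC is dominated by the thousands of
peptides outside any one pathway panel, and without the background term
the panel's own spikes would imprint artificial condition structure on
every peptide through the normalisation. `background_factor = 0`
restores the literal panel-only sum.

**What the generator does not emulate:** retention-time and charge-state
structure, peptide-specific ionisation efficiency, intensity-dependent
missingness (off by default), correlated replicate effects, and
biological co-regulation beyond the planted archetypes. Passing the
planted-label benchmarks therefore demonstrates that the statistical
machinery recovers known structure under realistic noise — not that the
biological classifications of any real dataset are correct.

## Preprocessing choices

* **TIC normalisation** divides by the run TIC and rescales by the mean
  TIC, preserving within-run ratios exactly.
* **Detection filter**: a peptide is kept when at least four of the six
  NaCl periods *and* four of the six pheromone periods have a detection
  in any replicate (the coordinate-wise reading of the filter, matching
  the matrix structure of the design).
* **Averaging**: per-cell mean, s.d. and replicate count; a single
  detected replicate records s.d. 0 (flagged via `n = 1`) so the
  downstream CV stays computable; empty cells are MISSING — a
  first-class state, never 0.
* **Imputation**: natural cubic splines along the NaCl axis within the
  fixed pheromone duration (the row-wise sub-experiment structure),
  falling back to the pheromone axis when fewer than three points are
  observed; below three points on both axes the cell stays MISSING with
  a warning. Negative spline output is clipped to 0; observed cells are
  never altered. Imputation happens after averaging (the order is a
  package choice; the alternative order is a one-line change in the
  pipeline).
* **Mock comparison** (`mock_compare()`): a peptide differs negligibly
  from its mock time course only if every cell-wise larger/smaller ratio
  is *strictly* below 1.5; zero denominators receive a pseudocount of 1%
  of the global median intensity.

## Shape and Intensity effects

For a given modulating stimulus, the peptide's six curves along the
*other* stimulus' axis (one per modulating duration) are pooled with all
other peptides' curves and clustered by Euclidean K-means — K = 6 for
NaCl-axis curves, K = 8 for pheromone-axis curves, 50 seeded restarts,
best by within-cluster sum of squares. A peptide whose curves occupy
**three or more clusters** has a Shape Effect. Otherwise the six
per-curve mean intensities $v_j$ (one per modulating duration) are
scored as $(\max v - \min v)/\bar v$; a score **≥ 0.7** is an Intensity
Effect, anything else No Effect.

Two details are deliberate package choices where the procedure admits
more than one reading:

* **Curve rescaling.** Curves are divided by their own mean before
  clustering (`scale = "mean"`), so the cluster step sees shape, not
  level, and the subsequent score step sees level, not shape; `raw`
  clustering is available. This also makes the whole classification
  invariant to a global intensity rescaling (the score is a ratio).
* **Score orientation.** The score uses per-curve means indexed by the
  modulating duration (an Intensity Effect is level modulation *by* the
  second stimulus). The alternative pointwise-mean-then-range reading is
  implemented as `score_mode = "axis_range"`.

Numerically identical curves are collapsed before counting distinct
clusters, so a constant peptide can never reach three clusters by
tie-breaking. Full profiles are additionally grouped by hierarchical
clustering on the 36-condition vectors (Minkowski distance, order 2 by
default; complete linkage; seven groups by default).

## Specificity ratios

For Stimulus 1 period $i$ and modulating Stimulus 2 duration $j$,

$$S(i, j) = \frac{I(i, 0) + \varepsilon}{I(i, j) + \varepsilon},$$

so column $j = 0$ is identically 1, $S < 1$ means Stimulus 2 amplifies
the Stimulus 1 response and $S > 1$ that it inhibits it. The pseudocount
defaults to 1% of the global median intensity and scales with the data,
keeping the statistic exactly scale-free. Basal normalisation of the
"response" cancels in the ratio and is therefore omitted. Column means
collapse the matrix to a specificity vector; the automated screen
correlates *log* specificity vectors within an early window (first four
durations: 0, 1, 5, 10 min) so that amplification and inhibition are
symmetric, ranking candidates by $|r|$ with SIMILAR/OPPOSITE cutoffs at
$\pm r_{\min}$.

## Modelling filters and network construction

Peptides enter modelling when their replicate CV (median over
conditions with at least two detected replicates of s.d./mean,
restricted to the 16 training conditions) is **below 0.25**, and when
**less than 25%** of their training-condition cells are missing.
Same-protein peptides with redundant trajectories are merged by
affinity propagation (damping 0.9) on mean-centred log-trajectories
with similarity = negative squared Euclidean distance; each cluster is
represented by its member with previously known function (lexicographic
tie-break), else by the exemplar. The affinity-propagation
**preference is an absolute redundancy scale (−1)** rather than the
classic median-pairwise-similarity rule: with a median preference the
exemplar-cost argument shows that any below-median-distance pair merges,
so a protein with several genuinely distinct sites could never keep
them all — the absolute scale merges only trajectories within about one
natural-log unit of aggregate divergence, one to two orders of
magnitude above duplicated dynamics and well below distinct site
dynamics. `preference = NULL` restores the median rule.

The protein-level prior network shipped with the package
(`costim_prior_network()`) is a **synthetic reconstruction** of the
HOG/pheromone wiring assembled from the pathway biology (two osmosensor
branches converging on Pbs2 and Hog1; the pheromone cascade through the
G-protein, Ste20, Ste5-bound Ste11/Ste7/Fus3; phosphatase and feedback
inhibition via Ptp2, Ptc1/Nbp2, Hog1 ⊣ Ste50; the TORC2 branch
Bit61 → Ypk1/2 → Gpd1), not a transcription of any published figure.
Substituting the 33 modelling peptides (`costim_modeling_ppeps()`)
expands every protein edge combinatorially — an edge between a protein
with $m$ peptides and one with $n$ peptides becomes $m \times n$ peptide
edges — yielding a base model of 45 nodes (33 measured peptides + 12
undetected proteins; stimulus nodes are not counted) and 93
interactions. The two mechanistic variants are: restricting Ste20's
crosstalk mediation to Ste20_T511 (removing the six other Ste20 peptide
nodes and their incident edges), and the Gpd1–Hog1 double-negative loop,
implemented as mutual inhibition between the Gpd1 peptide and *each*
measured Hog1 phospho-form. With both mechanisms the model has 39 nodes
and 73 interactions. The default ensemble combines the four mechanism
combinations, four combinations of the "No Effect upon NaCl" edge
removals, and fifteen single-edge removals — 23 models after
deduplication. Both edge lists ship as editable fixtures; the identity
of the single-removal edges is a documented package choice.

## Logic ODEs

Data are normalised to [0, 1] per peptide with a Hill transform of
coefficient 4 whose half-effect constant is the midpoint of the
peptide's cumulative value distribution (its median). Each non-stimulus
node then follows

$$\frac{dx}{dt} = \tau_x\,\bigl(\Phi_x(\text{inputs}) - x\bigr),$$

with incoming edges and AND gates combined as OR
($1 - \prod(1-\cdot)$), AND gates as products, and the normalised Hill
transfer $f(u) = u^n(1 + k^n)/(u^n + k^n)$ for activation ($1 - f$ for
inhibition). The normalised form satisfies $f(0)=0$ and $f(1)=1$, so a
stimulus clamped at 1 can fully activate its targets — required by the
[0, 1] data normalisation. Stimuli are step clamps from $t = 0$, which
is exact for the 16 training conditions (first row, first column and
diagonal of the matrix: these share a single time origin, which is why
they train the model), and the basal corner provides initial states
(measured basal value where available, else 0).

Integration uses `lsoda` (stiff-capable; relative/absolute tolerances
10⁻⁶/10⁻⁸) with the right-hand side compiled in C; reported
trajectories are clipped to [0, 1]. In the Boolean limit (n = 10,
k = 0.5, fast τ) steady states of acyclic networks reproduce exhaustive
Boolean gate evaluation, and a single activating edge with its input
clamped at $c$ settles at $f(c)$ exactly (0.53125 for $n=4$, $k=0.5$,
$c=0.5$) — both are standing tests.

**Fitting** (`fit_logic_ode()`) estimates τ per node and the Hill $k$
per edge by default ($n$ fixed at 4; any subset of {τ, n, k} can be
freed) within bounds τ ∈ [0.05, 10] min⁻¹, n ∈ [1, 10], k ∈
[0.01, 0.99], by seeded multistart: the first start is the mid-range
default, the rest are uniform draws in the bounds, each refined by
bounded quasi-Newton minimisation of the MSE under a total
objective-evaluation budget; the best-of-restarts fit is returned with
per-restart bests for convergence diagnostics. The fit is deterministic
given the seed. **AIC** is $n \ln(\mathrm{MSE}) + 2k$ (data points $n$,
free parameters $k$); the formula is configurable and recorded in every
fit, and an MSE of exactly 0 reports −∞ with a warning.
`compare_models()` recomputes the MSE on the measured nodes common to
all compared models before ranking, so models with different node sets
are compared fairly.

## Problem sizes and determinism

The shipped benchmarks run at desk scale: the classifier benchmark uses
a 60-peptide panel at CV 5% over 10 seeds; the filter benchmark a
48-peptide panel (33 planted survivors, 15 planted failures); parameter
recovery a 6-node network with 10 restarts and a 20 000-evaluation
budget, which refits noise-free data to MSE below 10⁻³ and recovers τ
well within 20%. Every stochastic stage takes an explicit seed, and
`run_pipeline()` derives one seed per stage from the global seed, so
reruns are bit-identical; the run directory carries an MD5 manifest.

## Known limitations

* The effect classifier's cluster-count rule depends on the curve
  population: a peptide's verdict can change when the surrounding panel
  changes, which mirrors the original procedure but means verdicts are
  panel-relative.
* Logic ODEs describe normalised activities, not concentrations;
  τ values are phenomenological time scales.
* The multistart optimiser is a budgeted local-restart scheme; for
  much larger models a dedicated global optimiser would be preferable.
* The shipped prior network and peptide list are synthetic stand-ins
  with the documented structural properties; conclusions about real
  yeast biology require the real measurements and a curated prior.
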