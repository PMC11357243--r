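---
title: "Mechanistic potassium forecasting under spironolactone: model, workflow and design choices"
author: "spirok"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic potassium forecasting under spironolactone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`spirok` operationalizes a quantitative-systems-pharmacology (QSP) model of
whole-body potassium homeostasis for bedside-style forecasting: given an
inpatient's spironolactone administrations, oral potassium supplements and
sparse potassium laboratory values, the package produces next-day potassium
trajectory predictions by sequential maximum-a-posteriori (MAP) estimation,
and provides the analysis workflow that justifies which parameters are
estimated per patient — local sensitivity analysis, collinearity-based
identifiability analysis, eFAST global sensitivity analysis, and
inter-individual-variability (IIV) estimation. Because real inpatient
records cannot be redistributed, the package ships a synthetic
electronic-health-record (EHR) cohort generator that emulates the structure
of a small pilot sample, and the end-to-end evaluation runs entirely on
generated data.

## The model

The system part follows the established mechanistic picture of renal
potassium handling with aldosterone feedback, built on $N$ identical
nephrons. State variables are potassium amounts in the extracellular fluid
(ECF) and intracellular pool, in the principal cells of the connecting
tubule / cortical collecting duct (CNT/CCD), in four luminal segments
(proximal tubule / loop of Henle, distal convoluted tubule, CNT/CCD,
medullary collecting duct), the cumulative urinary excretion, plasma
aldosterone, an oral-potassium gut depot, and a three-compartment
description of canrenone (absorption depot, central, peripheral) after
spironolactone dosing. Time is measured in minutes throughout, because
intake rates are natively mEq/min and dosing events are timestamped at
minute resolution.

The source publication for the model specifies its structure, compartments
and parameter names but not the algebraic rate laws, so this package fixes
concrete functional forms and calibrates them (see *Calibration*). The
forms, with plasma potassium $[K] = 1000 \, K_{ecf}/V_{ecf}$ (mEq/L) and
$\Delta K = [K] - K_{norm}$:

* **Intake.** Dietary potassium enters the ECF at the constant rate
  $K_{in}$ (mEq/min); oral supplements enter a gut depot absorbed
  first-order at 0.03/min (the source gives no absorption model; this is a
  conventional first-order oral absorption with a ~20-minute half-time).
* **ECF–ICF exchange.** First-order in both directions,
  $k_{ecf \to icf} K_{ecf} - k_{icf \to ecf} K_{icf}$, with the return rate
  derived at calibration so the intracellular pool (3400 mEq) is in balance
  at the normal state. This makes the intracellular pool a slow buffer, as
  it is physiologically.
* **Filtration.** $(GFR/N) \cdot [K] \cdot N$ — deliberately written via the
  single-nephron GFR, the mechanistically active composite. Consequently a
  GFR covariate must scale the nephron number proportionally
  (`apply_covariates()`), and changing GFR alone barely moves predictions
  while changing GFR and $N$ together does.
* **Proximal and distal reabsorption.** Fractional: 95% of the luminal
  outflow of PT/LoH and 60% of DCT return to the ECF; luminal segments are
  first-order transit compartments (turnover 0.2–0.3/min). Fractional
  reabsorption makes delivered distal load scale with filtration, which is
  what renders GFR-alone perturbations weak: the distal secretory machinery,
  not the filtered load, dominates urinary potassium.
* **Distal secretion.** Uptake into the principal-cell pool is
  $U = s_N \, U_0 \, ([K]/K_{norm}) \, g$ and apical secretion into the
  CNT/CCD lumen is first-order in the cell pool. The gain
  $g = (1-\phi) + \phi \cdot MR_{avail} (A/A_{norm})^{\alpha}$ carries the
  aldosterone–receptor signal: $\phi = 0.5$ of transport is
  mineralocorticoid-dependent, $\alpha$ (= `Aldo_KSec_scale`, nominal 2) is
  the aldosterone gain on luminal potassium transport, and
  $MR_{avail} = MR (1 - E_{max} C/(EC_{50}+C))$ is the receptor abundance
  reduced by canrenone occupancy. The split into a receptor-dependent and a
  receptor-independent fraction keeps the gain positive under full blockade
  and makes receptor abundance progressively more influential when
  aldosterone is elevated — the behavior that motivates estimating `MR`
  mainly in (at least mildly) hyperaldosteronemic patients.
* **Medullary collecting duct reabsorption.** A small flux at
  `K_reabsorption_MCD_rate0` per nephron, modulated linearly by plasma
  potassium (slope `m_plasmaK_MCD`, negative: high potassium suppresses
  reabsorption) and proportional to the luminal amount relative to its
  calibrated reference so it cannot drain an empty lumen.
* **Aldosterone.** Production increases exponentially in plasma potassium
  (slope `m_K_ALDO` per mEq/L, referenced to a setpoint slightly below the
  potassium normal value so that the slope itself retains a small, nonzero
  leverage at baseline), decreases in sodium intake and in the measured
  sodium normal value as power laws (the pragmatic direct sodium effect of
  the reference model), and is shifted multiplicatively by
  $(1 + \text{hyperaldo})$; elimination is first-order (turnover 0.01/min).
  Aldosterone units are arbitrary and normalized to 1.
* **Canrenone.** First-order absorption (0.012/min) into a two-compartment
  disposition (CL 0.08 L/min, $V_c$ 35 L, Q 0.03 L/min, $V_p$ 40 L) chosen
  to give a terminal half-life near 23 h, consistent with once-daily
  spironolactone pharmacology; $E_{max} = 0.8$, $EC_{50} = 0.25$ mg/L put
  typical 25–100 mg doses on the informative part of the occupancy curve.
  These PK constants are configuration defaults, not mechanistic claims.

### Calibration

`build_nominal_parameters()` solves the drug-free flux balance in closed
form so that the nominal steady state has plasma potassium exactly at
`norm_plasma_K` (4.2 mEq/L, the population-typical value) with urinary
excretion equal to intake. The derived constants (distal uptake scale,
secretion rate constant, intracellular return rate, luminal references) are
then frozen: `set_parameter()` perturbs a parameter *without* re-deriving
them, which is what sensitivity analysis, global sampling and individual
estimation require — otherwise every perturbation would be silently
re-calibrated away. Overriding a value in `build_nominal_parameters()`
instead re-calibrates, which is what configuration changes require. The
drug-free steady state for arbitrary parameter values is found by a 1-D
root solve on plasma potassium (all other balances cascade algebraically),
followed by the 3000-minute equilibration integration that also defines a
patient's day-zero state; `find_steady_state()` verifies the terminal
residual below $10^{-6}$ of the intake flux.

Quantitative agreement with the original published model is *not* claimed:
the reconstruction reproduces its structure, parameter roles and reported
qualitative behaviors (intake monotonicity, GFR/nephron composite,
sodium–potassium opposition on aldosterone, receptor relevance under
hyperaldosteronism, intake/receptor collinearity patterns), anchored by the
calibration above.

## Parameter ranges

Two range sets coexist deliberately (`param_ranges()`):

* `"efast"` — the narrow physiologically plausible intervals used for
  global sensitivity and uncertainty analysis: potassium intake
  0.073–0.084 mEq/min, sodium intake 0.01–0.17 mEq/min, ECF volume
  10,000–25,000 mL, receptor abundance factor 0.8–1.2, hyperaldosteronism
  effect −0.5–0.5.
* `"clinical"` — wider bounds used as hard constraints for individual (MAP
  and NLME) estimation and for truncating cohort-simulation draws: intake
  0.03–0.30 mEq/min (supplementation can multiply intake), volume
  8,000–30,000 mL, receptor factor 0.3–3, hyperaldosteronism −0.7–1.0.
  Estimation bounds must admit the large historical IIV (80% CV after
  capping) that the narrow analysis ranges cannot contain; conversely the
  global analysis should explore only the physiologically typical box. Using
  one set for both purposes would either break the estimator or inflate the
  sensitivity analysis.

## Sensitivity, identifiability and selection

Local sensitivity is the fully relative form
$S(t) = (\Delta[K](t)/[K](t)) / (\Delta p / p)$ with a forward 10% step
applied at $t=0$ to the scenario's steady state, evaluated over 24 h on an
hourly grid; the ranking summary is the time-averaged $|S(t)|$ (an L2
summary is available). Two operating points are screened — standard and
mild hyperaldosteronism (+0.3, the middle of the upper half of the
physiological range) — because local sensitivities depend on the operating
point; receptor abundance in particular gains leverage under
hyperaldosteronism. The targeted aldosterone sensitivity applies the same
formula to the maximum aldosterone concentration over the open interval
(0, 24 h]; the initial point is excluded because the perturbed and
unperturbed runs share it, which would blind the metric to any decrease.

Identifiability follows the collinearity-index construction: columns of
plasma-potassium sensitivities on the hourly 24-h grid, computed at
parameter points perturbed with 5% CV normal noise (10 replicates by
default), column-normalized; $\gamma = 1/\sqrt{\lambda_{\min}(\tilde S^T
\tilde S)}$ with an eigenvalue floor of $10^{-12}$, and $\gamma > 15$
flagging a poorly identifiable subset. Within a scan all subsets share the
replicate's column matrix, so eigenvalue interlacing (a superset is never
better-conditioned than its subsets) holds exactly.

`select_parameters()` wires the published decision sequence: screen ten
candidate parameters at the 0.01 margin; fix the potassium normal value to
the population-typical constant (model reduction); retain the
hyperaldosteronism effect even though its neutral nominal value of zero
excludes it from a relative screen (it proxies suppressive comedication
effects on aldosterone); flag — but keep — the collinear sodium-intake /
hyperaldosteronism pair, leaving their separation to the priors; confirm
with eFAST over the physiological ranges. The result is five parameters
forwarded to Bayesian estimation: `Kin`, `Nain`, `V_ecf`, `MR`,
`hyperaldo_effect`.

## eFAST and uncertainty analysis

eFAST uses Saltelli search curves with interference factor $M = 4$, the
factor of interest at the maximum admissible frequency
$\lfloor (n-1)/2M \rfloor$ and complementary factors cycled over
$1..\lfloor \omega_{max}/2M \rfloor$, an independent random phase per factor
and curve, and five replications of $n = 1000$ model evaluations per
factor. First-order indices come from the spectral power at the target
frequency and its first $M$ harmonics, total-order indices from the
complement of the low-frequency spectrum. The implementation is validated
against analytic Sobol indices of an additive model and of the Ishigami
function at the 0.05 level. eFAST simulations start from the *nominal*
calibrated state so that indices are time-resolved along the perturbation
transient (whether influence is early — volume — or late — intakes — is
itself informative); the Monte-Carlo uncertainty analysis instead starts
each draw at *its own* steady state, so the envelope portrays the
physiological spread of attainable potassium levels. Both conventions are
per-design and documented rather than interchangeable.

## Inter-individual variability estimation

The contract of the IIV module is parameter-recovery, not estimator
identity: the implementation is a MAP-EM scheme (iterative per-subject MAP
with a Laplace approximation around the mode, followed by the
shrinkage-corrected moment update
$\Omega_j \leftarrow \text{mean}_i[(\hat z_{ij}-\mu_j)^2 + V_{ijj}]$, where
$V_i$ is the subject's marginal posterior variance). The correction term is
what keeps weakly informed variances from collapsing to the shrunken spread
of the modes. Random effects are log-normal for positive parameters and
additive normal for the hyperaldosteronism effect (its range spans
negatives); for the additive effect the reported "CV%" is the standard
deviation of the effect itself, i.e. of the $(1+\text{hyperaldo})$
multiplier around neutral. $\Omega$ is diagonal, population means stay
fixed at the nominal values by default, the residual model is additive
Gaussian with the SD re-estimated each iteration (floor 0.005 mEq/L), and
the clinical ranges are hard bounds. The likelihood curvature is cached per
subject (refreshed mid-run) so that later EM iterations only pay for the
mode search, which is warm-started from the previous iteration.

Recovery at small CVs is limited by study design, not by the updater: with
one potassium lab per day, parameters sharing the steady-state-level
channel (intake, receptor abundance, sodium intake, hyperaldosteronism) are
mutually confounded, and a 5% CV sitting next to a 36% CV on the same
channel cannot be resolved at n = 20 subjects. The packaged recovery
experiments therefore follow the classic single-factor design — one
parameter carries the variability, the estimator is asked for exactly that
magnitude — at the three magnitudes of interest (5%, 18%, 36%), assigning
each magnitude to a parameter whose data channel can carry it (intake for
the smallest, volume and hyperaldosteronism for the larger ones), with labs
drawn two hours after the morning administrations where the kinetic
information is richest. The default prior IIV set used for forecasting when
estimation is skipped is the historical one: sodium intake 5.2%, ECF volume
18%, hyperaldosteronism 36%, receptor abundance and potassium intake capped
at 80% (raw historical values of 131% exceed the cap).

## Sequential MAP forecasting

Day zero is the first day with a potassium measurement. That single value,
combined with priors $(\theta, \Omega)$ and the covariates (GFR with
proportional nephron scaling, measured sodium as the sodium normal value),
anchors a MAP fit of all five parameters with the model evaluated at its
drug-free equilibrium after a 3000-minute offset; the equilibrium state
supplies the initial values of the state variables. The ECF volume is
estimated only at day zero and frozen afterwards — its influence is
greatest immediately after a perturbation, so later windows carry little
information about it.

From the next midnight, splits alternate at 00:00 and 11:00 (the morning
ward-round time). A split re-estimates the four free parameters only if a
new observation arrived since the last successful update, taking the
previous estimates as prior modes ($\theta' = \eta$) with $\Omega$
maintained, and in every case simulates the following 24 h under the
*planned* regimen on a 5-minute grid; observations falling in that window
are matched to the nearest grid time. Days without measurements are pure
simulation. The model state is carried forward from split to split ("final
values become the next day's initial values"); a re-estimation re-simulates
only the window since the last successful update under the candidate
parameters, and a failed update leaves the state at the last successful
update so the window is retried at the next split. The MAP objective is a
Gaussian likelihood (additive residual SD 0.2 mEq/L by default) plus the
transform-scale normal prior, minimized by bounded L-BFGS-B from five
deterministic starts spread at 0, ±0.5 and ±1 prior SDs around the prior
mode (tolerance $10^{-8}$ on the objective scale via `factr`). If a
predicted trajectory leaves the clinical plausibility band (2–8 mEq/L by
default), $\Omega$ is halved (on the SD scale) and the split re-estimated,
up to three times — the guard that reins in implausible individual
response estimates after surprising post-dose values.

Timestamps are minutes since admission midnight, so "midnight" and "11 am"
are per-patient clock times and the scheme is timezone-free. An observation
arriving between 11:00 and midnight waits for the midnight split, matching
the two-split design. Whether the residual model should be proportional
rather than additive is unresolved in the source; additive is the default
here and the objective accepts any residual SD, so a proportional variant
only requires scaling the observations.

## The synthetic EHR generator

`generate_cohort()` emulates the pilot sample: nine inpatients newly
initiating spironolactone (start day 1–3, 25/50/100 mg once daily at 08:00
planned), four with oral potassium supplementation (2 × 20 mEq/day),
stays targeting a median of 10.2 days, one potassium lab per day at
07:00 ± 60 min, sodium and GFR labs with 20% missingness (completed by
last-observation-carried-forward with standards 140 mEq/L and 100 mL/min
for leading gaps), additive lab error of 0.15 mEq/L, and a 45-minute SD
(truncated at ±3 h) jitter between planned and actual administration
times. Individual parameters are drawn with the historical IIV magnitudes,
truncated to the clinical ranges. Stays are drawn as quantiles of a
log-normal (sdlog 0.35) with a small multiplicative jitter and random
assignment to patients — stratification keeps the *cohort median* on the
10.2-day target across seeds, which a plain log-normal sample of nine would
not. The generative truth (individual parameters, true course, actual
administration times) lives in a `truth` block that the forecasting
pipeline never reads and that the event-table export writes only to a
separate `*_truth.csv` sidecar.

The generator emulates structure, not clinical reality: there are no
comedication effects on potassium (ACE-inhibitor and diuretic flags are
descriptive strata only), no circadian or intra-individual potassium
fluctuation beyond white lab noise, no informative lab scheduling, and the
data-generating model is the forecasting model itself. Passing end-to-end
tests on this cohort therefore demonstrates that the pipeline is correctly
wired and well-calibrated under its own assumptions — a necessary
condition — and says nothing about predictive performance on real
patients, where model misspecification dominates.

## Numerical choices

* `lsoda` with `rtol 1e-8 / atol 1e-10` for reported simulations; dose
  events are discrete state additions with solver restarts. Estimation
  objectives use `rtol 1e-6` — well below the residual noise scale — and
  place observation times on the solver grid rather than interpolating
  (interpolation error masquerades as inter-individual variability in
  noise-free recovery experiments).
* Non-negativity is enforced by construction of the rate laws (first-order
  outflows, saturating MCD reabsorption, the floor on the MCD modulation at
  0.05) and audited post hoc with a $10^{-6}$ excursion tolerance.
* Degenerate inputs: zero-width uncertainty ranges are legal (the envelope
  collapses onto the nominal trajectory); a locally inert parameter inside
  a collinearity subset is an error, not a silent zero column; relative
  sensitivity of a parameter whose nominal value is zero is refused.
* Deterministic tie-breaks: parameter ranking breaks magnitude ties
  alphabetically; MAP multi-starts are a fixed spread, not random draws, so
  forecasts are reproducible without seed plumbing.
* Problem sizes in the shipped tests: eFAST at the published design
  (n = 1000, 5 replications), the pilot cohort at its published size
  (9 patients), IIV recovery at 20 subjects × 20 replicates per magnitude,
  and the jitter experiment at 20 paired replicates per jitter level —
  each scaled to what a laptop runs in minutes, which is also the scale
  the analysis was designed at.

## Known limitations

* The rate laws are a calibrated reconstruction; absolute transients may
  differ from the original model even where qualitative behaviors match.
* Aldosterone regulation omits angiotensin II and ACTH by design,
  following the reference model's scope; sodium homeostasis is rudimentary
  (a direct intake effect on aldosterone production).
* The collinearity of sodium intake with the hyperaldosteronism effect is
  structural; their individual estimates are prior-dominated and only
  their combination is data-driven.
* MAP forecasting propagates no posterior uncertainty (no credible bands);
  $\Omega$ shrinkage under the plausibility guard is a heuristic, not an
  inference.
* The 80% IIV cap and the clinical bounds are operational safeguards whose
  values are conventions, exposed as configuration.
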