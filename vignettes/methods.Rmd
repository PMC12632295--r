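---
title: "Modelling differentiation therapy in glioblastoma: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling differentiation therapy in glioblastoma: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`gbmtwin` simulates glioblastoma (GBM) growth and treatment as a digital
twin built around the cancer-stem-cell hypothesis: a small population of
glioma stem cells (GSCs) sustains the tumour, resists radiotherapy, and can
be pushed towards a harmless post-mitotic fate by a differentiation agent
(BMP4) delivered by engineered mesenchymal stem cells (AMSCs). This
vignette explains the model, the parameters that matter, the stochastic
patient layer, the calibration and trial machinery, and the design
decisions taken where the science left the choice open.

## The hierarchy model

The tumour is a hierarchy of compartments: GSC density $s$, progenitor
cells (PCs) $v_1,\dots,v_{n-1}$ with finite remaining replicative capacity,
and terminally differentiated cells (TDCs) $v_n$ that no longer divide.
With total density $N = s + \sum_i v_i$ and carrying capacity $K$
(normalised to 1, so every density is a fraction of the saturation size),
the deterministic core is

$$
\begin{aligned}
\dot s &= (2P_s - 1)\, m_s s \left(1 - \tfrac{N}{K}\right) - \delta_s s,\\
\dot v_1 &= 2 r_1 (1 - P_s)\, m_s s \left(1 - \tfrac{N}{K}\right)
  - m_1 v_1 \left(1 - \tfrac{N}{K}\right) - \delta_1 v_1,\\
\dot v_i &= 2 r_i (1 - P_s)\, m_s s \left(1 - \tfrac{N}{K}\right)
  + 2 m_{i-1} v_{i-1} \left(1 - \tfrac{N}{K}\right)
  - m_i v_i \left(1 - \tfrac{N}{K}\right) - \delta_i v_i,
  \quad 2 \le i \le n - 1,\\
\dot v_n &= 2 r_n (1 - P_s)\, m_s s \left(1 - \tfrac{N}{K}\right)
  + 2 m_{n-1} v_{n-1} \left(1 - \tfrac{N}{K}\right) - \delta_n v_n.
\end{aligned}
$$

A dividing GSC self-renews with probability $P_s$ and differentiates with
probability $1 - P_s$, placing both daughters into compartment $i$ with
weight $r_i$. PCs divide at rate $m_i = m_{is} m_s$ (one shared ratio
$m_{is}$ for all proliferative compartments) and advance one compartment
per division; TDCs only die. Death rates are tied together as
$\delta_i = \delta_{is}\delta_s$ and $\delta_n = \delta_{ns}\delta_i$. The
proliferative capacity is fixed at $n = 10$.

Two limits anchor the implementation and its tests: with $P_s \equiv 1$
the system collapses to a logistic equation for $s$ (checked against the
closed form to $10^{-6}$ relative error), and at $N = K$ every
proliferation term vanishes.

## BMP4 delivery and response

AMSCs decay exponentially after implantation (optionally replenished by an
infusion) and secrete BMP4, which decays and is taken up by GSCs:

$$
\dot m = u(t) - \delta_m m, \qquad
\dot B = C m - u_B B s - \delta_B B .
$$

All delivery rates are treated as per-day quantities. This is a deliberate
unit decision: with $\delta_m = \delta_B = 0.5$/day a carrier bolus
produces a BMP4 peak at 48 hours and carrier persistence of about two
weeks, matching the reported in-vivo kinetics, whereas a per-year reading
(the unit printed alongside these symbols in the published ranges) is
orders of magnitude too slow to reproduce either. The release and uptake
rates $C$ and $u_B$ enter the same kinetic balance and are kept on the same
per-day footing; `parameter_ranges(kinetics_unit = "year")` switches the
whole block to the literal label for sensitivity checks. The slow rates
($m_s$, $\delta_s$), by contrast, are read as printed (per year) and
divided by 365 at load.

BMP4 acts through two response curves:

* **Self-renewal.** $P_s(B) = P_s^{\min} + (P_s^{\max} -
  P_s^{\min})/(1 + \psi B)$ — maximal without BMP4, approaching
  $P_s^{\min}$ as concentration or the per-line sensitivity $\psi$
  (per ng/mL) grows.
* **Differentiation depth.** The distribution $r$ is a unit triangle
  $\Lambda$ over compartment indices, $r_i \propto \Lambda(i - \theta)$
  with centre $\theta = 1 + \varphi B$. Without BMP4 this reduces exactly
  to $r_1 = 1$ (perfect hierarchy); increasing $\varphi B$ pushes GSC
  daughters into later compartments, and any triangle mass past
  compartment $n$ is assigned to the TDC compartment (differentiation
  straight to a post-mitotic state). The centre convention $1 + \varphi B$
  rather than the bare $\varphi B$ is a deliberate choice: it is the only
  affine centring that restores the perfect hierarchy at $B = 0$ and it
  reproduces the two published worked examples (peak compartment 6 at
  $\varphi = 0.0494$ and 9 at $\varphi = 0.0787$, both at 100 ng/mL).

## Radiotherapy and resection

A fraction of $d$ Gy multiplies each compartment by the linear-quadratic
survival $\exp(-\Pi(\alpha d + \beta d^2))$ with $\beta = \alpha/10$ fixed
(exposed read-only on the parameter object). The protection multiplier
$\Pi$ is $\eta$ for GSCs (reported estimate 0.1376), 1 for proliferative
PCs, and $\mu$ for TDCs (reported estimate 0.5), so irradiation enriches
the stem fraction — the modelled basis of radio-resistance. Effects are
instantaneous; no dose-rate, repair or proliferation coupling is modelled.
Resection multiplies every cellular compartment by $1 - 0.917$, the
literature estimate of the average resected volume fraction, leaving
proportions and the chemical species unchanged.

The standard-of-care schedule is: resection at detection, then 30
fractions of 2 Gy starting 30 days later in a 5-days-on/2-days-off
pattern (60 Gy over six weeks, last fraction 69 days after resection).
The single-dose arm adds a carrier bolus $m_0$ at resection; the
continuous arm infuses the same total amount at constant rate over the
resection-to-last-fraction window, so the arms are dose-matched.

## In-vitro assays and calibration

Each cell line is summarised by its measured doubling time (fixing
$m_s = \ln 2 / \mathrm{DT}$) and three fitted parameters
$(\alpha, \psi, \varphi)$. Both assays are simulated from a pure GSC seed
at $10^{-4} K$, far from crowding (outputs shift by under 0.1% across
seeding densities $10^{-5}$–$10^{-3} K$):

* **Clonogenic radiotherapy assay.** 48 h in a constant 100 ng/mL BMP4
  bath (media exchange; the delivery equations are bypassed) or in control
  stem-cell media, then one fraction. Control media holds $P_s \equiv 1$;
  the BMP4 arm uses the response curve with assay-specific bounds
  $P_s^{\max} = 1$, $P_s^{\min} = 0$, so an insensitive line
  ($\psi = 0$) reproduces the control arm exactly. The readout is the
  surviving fraction of *proliferative* cells (GSCs plus non-terminal
  PCs) immediately post-dose, self-normalised at 0 Gy — a colony can only
  come from a cell that can still divide.
* **Proliferation assay.** Seven days, control versus constant bath;
  readout is the ratio of total day-7 densities. With PCs twice as fast
  as GSCs (the assay default $m_{is} = 2$), moderate differentiation
  depth accelerates growth while large $\varphi$ (daughters near the TDC
  compartment) shrinks it, which is how the model accommodates cell lines
  that grow either more or less under BMP4.

In vitro, $\alpha$ is referenced to the population the control arm
measures — pure GSCs — so control survival is exactly
$\exp(-(\alpha d + \alpha d^2/10))$, PCs are $1/\eta$ times more sensitive
and TDCs $\mu/\eta$. This is the same relative radiosensitivity structure
as the in-vivo operator, renormalised to the observable; it also makes
$\alpha$ sharply identifiable from the steep control curve (the
GSC-protected normalisation would flatten it to ~0.76 survival at 6 Gy and
blow up the recovery error of $\alpha$ several-fold).

Calibration minimises a combined least-squares loss — survival residuals
from the radiotherapy assay plus log-ratio residuals from the
proliferation assay, each block divided by its observation count so
neither dominates — under bounds $\alpha \in [0.01, 1]$,
$\psi \in [0, 0.5]$, $\varphi \in [0, 0.2]$. The optimiser anchors
$\alpha$ with a one-dimensional profile on the closed-form control block,
screens a fixed Latin hypercube of $(\psi, \varphi)$ starts (plus the
origin) at that anchor, and polishes the best three jointly with
L-BFGS-B. A negligible ridge, $10^{-4}(\psi^2 + \varphi^2)$, resolves
directions the data leave flat — $\varphi$ carries no information when
$\psi \approx 0$ because no differentiation occurs — towards
insensitivity, so unresponsive lines calibrate to $(\psi, \varphi) =
(0, 0)$. Measured recovery from sextuplicate assays with 5% multiplicative
noise: median relative errors of roughly 3% ($\alpha$), 13% ($\psi$) and
1% ($\varphi$) over 20 replicate datasets; noiseless recovery is within
0.1%.

The synthetic-assay generator perturbs model predictions with mean-one
multiplicative lognormal noise (default CV 5%, six replicates, 0 Gy
renormalised to mean 1), emulating count/fluorescence readouts. It does
not emulate plating-efficiency drift, edge effects, or between-passage
variability, so calibration tests demonstrate identifiability under the
model's own noise assumptions, not robustness to real-world assay
artefacts.

## Virtual patients

A patient is a parameter vector drawn by Latin hypercube from the
published uniform ranges (wide by intent, to cover patient heterogeneity
rather than estimate a population distribution). Derived quantities:
$\alpha = \alpha_s m_s$ with $m_s$ in its printed per-year unit (giving
$\alpha \in [0.01, 0.9]$/Gy, on the scale of the fitted cell-line
values), and $\beta = \alpha/10$.

Tumours start from $s(0) = 10^{-5}$, $v = 0$ — a microscopic pure-GSC
seed; the initial condition is not stated in the source material and this
is a declared default. Detection and death are stochastic: both hazards
are shifted logistics in total density,
$\lambda(N) = \lambda_{\max} / (1 + e^{-m(N - N_d)})$, with
$\lambda_{\max} = 1$/day, steepness 100 (detection) and 20 (death), and
half-maximal thresholds 0.2 and 0.7 — hence detections cluster just below
$N = 0.2$ and deaths around 0.6–0.7. Hazards are evaluated on a daily
grid with per-step probability $1 - e^{-\lambda \Delta t}$, which is
exact for piecewise-constant rates and never exceeds 1 (the first-order
$\lambda \Delta t$ form can, at $\lambda_{\max}\Delta t = 1$). The death
hazard is active from the start, not only after detection; with the
detection threshold far below the death threshold this has no practical
effect. Simulations run to $t_{\max} = 3650$ days; survivors are censored,
never dropped, and a censored patient's survival time is the censored
duration.

Within a patient, all treatment arms share the growth trajectory, the
detection draw and (for schedule comparisons) the death draws, so
differences are attributable to treatment alone and a patient with no
BMP4 response ties exactly across arms. Under these paired draws,
continuous delivery was at least as good as the dose-matched single bolus
for every one of 200 sampled patients — the single dose decays (half-life
1.4 days) long before the final radiotherapy fractions, while the
infusion keeps self-renewal suppressed through the whole course.

### Dose levels

The carrier amount equivalent to the in-vitro exposure is unknown, so the
dose levels are calibrated against the response curve rather than copied
from anywhere: the "high" dose yields a quasi-steady plateau of 10 ng/mL
during the continuous window for median kinetics, placing $\psi B$ at
order 1 for the median sensitivity — the middle of the response's dynamic
range, where patient-to-patient differences in $\psi$ translate into
outcome differences. (A plateau at the full 100 ng/mL assay concentration
saturates $P_s$ at $P_s^{\min}$ for essentially the entire sampled $\psi$
range, which erases the sensitivity structure the analysis is built to
expose.) The "low" dose is one tenth of the high dose.

## Trials, endpoint and sensitivity analysis

The trial endpoint per patient is the days-gained fold change,
DGFC = treated survival / control survival, computed on paired arms. The
global sensitivity analysis regresses DGFC on the sampled parameters, each
scaled to unit sample standard deviation; a parameter is called
significant when the 95% confidence interval of its standardised slope
excludes zero. Partial (added-variable) regressions are provided, with the
Frisch–Waugh–Lovell identity asserted to $10^{-10}$ as a correctness
check. On a 1000-patient cohort at the high dose the seven significant
parameters are $\psi$, $\eta$, $C$, $m_s$, $\alpha_s$, $P_s^{\max}$ and
$P_s^{\min}$, with $\psi$ and $\eta$ carrying the two largest standardised
slopes, and good responders (DGFC > 1.2) have higher mean $\psi$ and
$m_s$ than poor responders (DGFC < 1.1).

Virtual trials compare a control arm with continuous delivery on the same
patients (20 per arm by default), by a two-sided unpaired log-rank test at
$\alpha = 0.05$; "success" additionally requires the treated arm's median
survival to be no worse. Two statistical facts about this design, both
measured and worth knowing:

* **The paired design is conservative.** Because both arms contain the
  same patients — and, separately, because Latin hypercube cohorts are
  variance-balanced and therefore far more alike than iid samples — the
  unpaired log-rank's variance is overestimated and null p-values pile up
  near 1. Nominal 5% type-I behaviour is recovered exactly when both arms
  are independent iid-uniform cohorts
  (`run_virtual_trial(paired_patients = FALSE, sampler = "iid")`), which
  is how the engine's calibration is verified.
* **Power at trial scale is limited by heterogeneity.** Control survival
  within a full-range cohort spans roughly 300–3500 days, so a consistent
  within-patient benefit of order 1.2–2x is hard for an unpaired rank
  test to detect at $n = 20$; stratifying the test by patient flips to
  the opposite extreme (nearly everything significant, because nearly
  every patient benefits at least slightly). Success fractions of the
  stratified cohorts should therefore be read together with the
  underlying p-value ordering, which does follow the expected pattern
  (sensitive/fast < unstratified < insensitive/slow in median p).

Cohort stratification splits the $m_s$ range [10, 90] into [10, 50] and
[50, 90] and the $\psi$ range [0, 0.2] into [0, 0.1] and [0.1, 0.2],
yielding four stratified cohorts plus the unstratified one.

## Numerical choices

The coupled system is integrated with a stiff-capable adaptive solver
(lsoda) at `rtol = 1e-8`, `atol = 1e-10`, with values in
$(-10^{-12}, 0)$ floored to zero after each segment. Integration restarts
at every scheduled event so instantaneous operators apply between smooth
segments; splitting a trajectory at an arbitrary time changes it by less
than $10^{-8}$ relative error. The right-hand side is compiled C for
speed; an R reference implementation of the rate equations is exported and
tested against it. Problem sizes used by the shipped checks — 200 patients
for the schedule-dominance property, 1000 for the sensitivity cohort,
20 trials x 20 patients per stratified cohort, 200 null trials, 20
replicate calibration datasets — are the package's chosen defaults and
keep a full run in the tens of minutes on a single core.

## Known limitations

The model is spatially homogeneous: no infiltration gradients, no
microenvironment or immune coupling, uniform drug exposure. Delivery
kinetics ignore carrier migration. Radiotherapy has no repair or re-oxygen
dynamics, chemotherapy is absent, and repeat resection is out of scope.
The in-vitro layer predicts colony-forming ability from instantaneous
post-dose composition rather than simulating the 14-day outgrowth, so
fitted sensitivities are defined relative to that convention. Parameter
ranges are uniform and independent; correlations between patient
parameters (e.g. proliferation and radiosensitivity beyond the
$\alpha = \alpha_s m_s$ link) are not modelled.
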