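---
title: "Methods: coupled PK/PD and mechano-chemo-biological bone remodeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled PK/PD and mechano-chemo-biological bone remodeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteopkpd)
```

## The model

`osteopkpd` simulates a single material point of bone tissue as four
coupled sub-models advanced on a daily grid.

**Cell populations.** Responding osteoblasts $B_r$, active osteoblasts
$B_a$ and active osteoclasts $C$ (pM) follow the Lemaire-lineage balance

$$\frac{dB_r}{dt} = D_R\,\pi_{TGF\beta} - \frac{f_0 d_B}{\pi_{TGF\beta}}B_r,
\qquad
\frac{dB_a}{dt} = \frac{f_0 d_B}{\pi_{TGF\beta}}B_r - k_B B_a,
\qquad
\frac{dC}{dt} = D_C\,\pi_{RANK\text{-}L}\,\iota(c_b) - D_A\,\pi_{TGF\beta}\,C,$$

with $\pi_{TGF\beta} = (C + f_0 C_s)/(C + C_s)$. TGF-$\beta$, released
by resorption, recruits osteoblast progenitors but *retards* their
maturation and drives osteoclast apoptosis; this is why suppressing
osteoclasts also depresses the formation arm after a transient burst of
osteoblast maturation. All binding reactions (OPG and denosumab
competing with RANK for RANK-L; PTH receptor occupancy) are treated as
pseudo-steady because molecular binding equilibrates much faster than
cell populations turn over:

$$\pi_{RANK\text{-}L} =
\frac{(k_3/k_4)_{\mathrm{eff}}\,K_L^P\,\pi_{PTH} B_a}
{1 + (k_3/k_4)_{\mathrm{eff}} K + (k_1/k_2)\,O + C_d/K_D},
\qquad O = \frac{K_O^P}{k_O \pi_{PTH}} B_r .$$

**Mechanics.** Daily loading enters as the cycle-weighted stimulus
$\xi = (\sum_i N_i \bar\varepsilon_i^m)^{1/m}$ with
$\bar\varepsilon = \sqrt{2u/E}$ ($= \sigma/E$ for uniaxial stress). The
inhibitory signal $S = \frac{\xi}{\xi + c}(1-d)^{a v_b}$ saturates with
the stimulus and is blocked by microdamage (damage interrupts the
osteocyte communication network, more severely in dense bone). The
RANK/RANK-L pair is the mechano-sensitive reaction: its binding and
unbinding rates shift by $e^{\pm\gamma(1-S)\hat S_v}$, so the ratio
entering $\pi_{RANK\text{-}L}$ gains $e^{2\gamma(1-S)\hat S_v}$, with
$\gamma = v_b/v_{b0}$ and $\hat S_v$ the normalized specific surface
(the quintic $32.3v_b - 93.9v_b^2 + 134v_b^3 - 101v_b^4 + 28.8v_b^5$
over 4.17 mm²/mm³, which peaks near $v_b \approx 0.34$ and nearly
vanishes in compact bone). Underloading ($S < \tfrac12$) therefore
tilts the pathway toward resorption, overload protects, and the
specific surface sets how much remodeling the microstructure can host.

**Drugs.** Subcutaneous denosumab follows a two-compartment
target-mediated model: a first-order depot feeds total plasma drug
$C_{tot}$, the free fraction is the quadratic binding root
$C_d = \tfrac12(C_{tot}-R_{ss}-K_D+\sqrt{(C_{tot}-R_{ss}-K_D)^2 +
4K_D C_{tot}})$, and serum NTX is an indirect-response biomarker with
production inhibited by $C_d$. Free drug competes for RANK-L through
$C_d/K_D$ (nM over nM). Intravenous ibandronate follows a
four-compartment mass balance (plasma, two peripheral, bone); the
bone-compartment concentration $c_b$ (µg/l) drives both the urinary-CTX
indirect response (Hill exponent 1.92, IC$_{50}$ 0.37 µg/l) and the
inhibition $\iota(c_b) = 1 - I_{max} c_b/(IC_{50}+c_b)$ of osteoclast
differentiation.

**Tissue.** The volume-fraction balance is
$dv_b/dt = k_{form}B_a - k_{res}C$. Each newly formed packet enters at
ash fraction $\alpha_0 = 0.45$ and mineralizes exponentially toward
$\alpha_{max} = 0.7$; pre-existing bone continues from
$\alpha_{ini} = 0.6$ along the same curve. Resorption removes bone at
the current mean ash fraction. Fatigue damage accumulates through
nonlinear damage-versus-cycles closed forms tied to the strain-life
laws $N_f = K_i/((E/E^*)\bar\varepsilon^{\delta_i})$ (compression
$\delta_c = 10.3$, $K_c = 9.333\times10^{40}$; tension
$\delta_t = 14.1$ with a calcium-dependent coefficient
$K_t = 10^7(\varepsilon_u/\beta)^{\delta_t}$,
$\log_{10}\varepsilon_u = 25.425 - 11.341\log_{10}[Ca]$), and is
repaired as resorption removes cracked tissue,
$\dot d_{rep} = \dot v_R d / v_b$. Stiffness closes the loop:
$E = 84370\,v_b^{2.58}\bar\alpha^{2.74}(1-d)$ MPa.

## Parameters that matter

All constants live in one registry, `bone_parameters()`, with dotted-path
overrides (`set_parameter(p, "denosumab.K_D", 3e-12)`) and bit-exact
JSON round-tripping for provenance. Choices a user is most likely to
touch:

* **Dosing schedule** — dose and interval. Defaults follow the drugs'
  standard regimens: denosumab 6-monthly (mg/kg subcutaneous),
  ibandronate quarterly (mg intravenous).
* **`k_res_scale`** (volume fraction per pM per day, default
  `r default_k_res_scale()`): the absolute turnover magnitude, the one
  quantity the model structure leaves free. The ratio
  $k_{form}/k_{res}$ is always pinned to $C_0/B_{a,0}$ so every
  scenario starts at homeostasis; the magnitude was calibrated once, by
  bisection, so that the trabecular (1.0 g/cm³) equilibrium arm under
  1.0 mg/kg denosumab gains 53% bone volume over 3000 days. Every other
  reported number is a prediction at that fixed value.
* **`denosumab.molar_mass`** (147 000 g/mol): converts mg/kg doses to
  nM; an IgG2-scale default, exposed because the dose unit conversion
  is not otherwise determined.
* **`ibandronate.I_max_cell`** (1) and the reuse of the biomarker
  IC$_{50}$ (0.37 µg/l) in the osteoclast inhibition: the cell-level
  potency of the bisphosphonate is not separately identified, so the
  biomarker values stand in; both are configurable.
* **`mechano.kappa_years`** (6): the secondary mineralization period,
  interpreted as the time constant of the exponential ash kinetics. The
  alternative reading (a rate of 6/year) would complete mineralization
  in days, contradicting the multi-year character of secondary
  mineralization.
* **`chemical.d_B`** (0.7/day): the responsive-osteoblast
  differentiation rate; the flux constant in the balance is
  $f_0 d_B = 0.035$/day, the Lemaire-lineage convention, which is what
  reproduces the canonical steady state ($B_r \approx 7.7\times10^{-4}$,
  $B_a \approx 7.3\times10^{-4}$, $C \approx 9.1\times10^{-4}$ pM
  before mechano-modulation).
* **`chemical.K_L_P`** ($3\times10^6$ RANK-L per cell): the tabulated
  source value; with the occasionally-quoted $3\times10^{-6}$ the
  RANK-L occupancy is $O(10^{-13})$ and the osteoclast pool collapses,
  so the positive exponent is the only reading consistent with the
  model's own steady state.

## Scenario conditions

`bone_scenario()` fixes one run: bone type as apparent density
($v_b = \rho/(1.41 + 1.29\bar\alpha)$, so 0.5/1.0/2.05 g/cm³ map to
$v_b \approx$ 0.229/0.458/0.939 at $\bar\alpha = 0.6$), a load mode
(disuse $\xi = 0$; equilibrium $\xi = \xi^* = 0.0025$; overload
$k\,\xi^*$; or constant uniaxial stress with the strain recomputed daily
from the current modulus), 10 000 load cycles per day (500 for
mandible-type runs), and a horizon of 3000 days for remodeling studies
(90–180 days for biomarker-only runs). Initial cell populations always
come from the drug-free stationary state under the equilibrium
stimulus, solved per bone type because the specific surface enters the
modulated binding ratio. These are the study conditions; they are not
adjusted per run.

## Numerical choices

* **Operator splitting, Δt = 1 day** between sub-models
  (PK → mechanics → signaling → tissue). Drug PK is independent of the
  tissue state, so the full exposure trajectory is integrated up front
  with `deSolve::lsoda` (rtol 1e-10), dose administrations as
  integrator events; the remodeling loop reads the same-day value, and
  an integration test asserts there is no lag between the two.
* **Cell ODEs**: classical RK4 with 10 sub-daily steps and the day's
  coupling coefficients frozen; the populations' rates are at most
  ~14/day, so the scheme is far inside its stability region. Two
  auxiliary states accumulate $\int B_a\,dt$ and $\int C\,dt$ so the
  daily volume increments are integrals, not endpoint approximations.
  Halving the sub-step moves 3000-day endpoints by well under 0.2%
  (tested).
* **Mineral bookkeeping**: because the packet kinetics are exponential,
  the volume-averaged ash fraction admits an exact incremental
  recursion on the aggregate "mineral deficit"
  $D = \sum_j v_j(\alpha_{max} - \alpha_j)$ — aging decays $D$ at rate
  $\kappa$, resorption removes a proportional share, formation adds
  $\Delta v_F(\alpha_{max}-\alpha_0)$ — with per-day ordering
  age → resorb → form. This is algebraically identical to explicit
  per-packet bookkeeping (the test suite checks agreement with a
  brute-force packet oracle to 1e-8 at 200 random checkpoints) at O(1)
  memory, so no packet-merging horizon is needed. The microcrack
  correction to the mixing integral is bounded by
  $h = 3.4\times10^{-4}d$ in volume and is omitted from the average (it
  would otherwise push $\bar\alpha$ outside its physical bounds);
  microcrack density itself is reported as $k\,d$.
* **Damage bookkeeping**: the closed-form damage curves and the
  strain-life laws are kept mutually consistent by constructing their
  coefficients from the same severity $(E/E^*)\bar\varepsilon^\delta$,
  so $d(N_f) = 1$ holds identically; daily blocks use equivalent-cycle
  inversion (invert the current damage to a consumed life fraction at
  today's strain, add today's cycles, re-evaluate), which makes
  accumulation path-consistent under slowly varying strain. Strains in
  the fatigue laws are microstrain; the conversion happens at the
  tissue-module boundary. $E^*$ is the undamaged cortical modulus at
  the current ash fraction, so $E/E^* = (v_b/0.939)^{2.58}(1-d)$.
  The compression law degenerates at
  $(E/E^*)\bar\varepsilon \approx 6093$ µε where its exponent crosses
  zero; the implementation switches to the linear (Miner) limit inside
  a 1e-9 neighbourhood. The tension law is valid below
  $(E/E^*)\bar\varepsilon \approx 4766$ µε and errors out beyond.
* **Steady state**: the stationary cell balance reduces analytically to
  one scalar equation in $C$ (both osteoblast pools and OPG follow in
  closed form from $\pi_{TGF\beta}$); a damped Newton iteration from
  the Lemaire-scale fixed point (relative tolerance 1e-12, bracketing
  fallback) makes initialization deterministic and
  guess-independent (tested from 0.5x and 2x guesses).
* **Clamps**: $v_b$ is kept in [0.01, 0.99]; when the upper bound is
  reached the recorded formation increment is reduced so the
  formed/resorbed history stays exactly consistent with the state
  (volume bookkeeping is asserted to 1e-12). Damage is clamped to
  [0, 1]; an invalid logarithm argument in the damage closed forms is
  treated as failure ($d = 1$).
* **Problem sizes**: the shipped studies are single-point runs of 3000
  days (biomarker runs 90–180 days); a full dose-response grid is
  ~10 runs and completes in well under a minute.

## What the simulations do and do not show

The scenario library emulates controlled constant-protocol studies:
fixed daily load cycles, exactly periodic dosing, homogeneous material
point, population-average parameters. It does not emulate spatial
heterogeneity (no finite-element coupling), inter-individual PK
variability, load-history variability, or drug effects on the organic
matrix — so agreement in these runs demonstrates internal consistency
of the coupled model under idealized conditions, not patient-level
prediction.

Three structural behaviours of the model are worth knowing before
interpreting dose-response output:

* **Denosumab responses saturate in dose.** With $K_D = 3\times10^{-12}$
  M, free drug exceeds $K_D$ by 3–4 orders of magnitude for every
  clinical dose, so $\pi_{RANK\text{-}L}$ is almost fully suppressed at
  0.3 mg/kg and above; what grading remains comes from the washout tail
  at the lowest doses. Published clinical dose-response curves are
  considerably more graded than target-mediated suppression of this
  affinity allows.
* **Ibandronate effects are episodic.** The four-compartment PK clears
  the bone compartment with an effective half-life of a few weeks —
  which is what lets the urinary-CTX biomarker return to baseline
  within ~90 days of a dose — so osteoclast inhibition largely switches
  off between quarterly doses. A model in which the skeletal pool
  persisted for years (as bisphosphonate retention does clinically)
  would produce much larger cumulative volume gains at the same doses;
  with this PK the biomarker recovery and a persistent remodeling
  effect cannot both hold.
* **Suppressing resorption also suppresses formation.** Through the
  TGF-$\beta$ coupling, collapsing the osteoclast pool settles
  $B_a$ at roughly a quarter of baseline, so the maximal growth rate
  under full suppression is formation-limited and nearly
  dose-independent.

These are properties of the governing equations at their tabulated
parameter values, not numerical artifacts; the acceptance suite records
where they place the simulated percentages relative to their published
counterparts.

## Known limitations

Isotropic stiffness only; a single (RANK/RANK-L/OPG + PTH + TGF-$\beta$)
signaling axis with no osteocyte mechanosensing; tension/compression
selected globally per scenario (mixed stress states are a spatial-model
concern); no parameter estimation from patient data. The dosing-interval
and overload studies inherit all of the structural behaviours listed
above.
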