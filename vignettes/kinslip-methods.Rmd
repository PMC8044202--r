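---
title: "Methods: the kinslip walking–slipping motor model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the kinslip walking–slipping motor model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinslip)
```

# The model

`kinslip` describes a dimeric kinesin-8 motor that walks hand-over-hand
along one microtubule protofilament with step size $d = 8$ nm and, with a
small probability per ATPase cycle, falls into a weak-binding state in
which both heads carry ADP and the dimer slips along the lattice.

Load $F$ is signed and positive toward the plus end, so an opposing
(assisting-minus) load is negative and stall occurs at $F = -F_S$ with
$F_S > 0$.

## Walking

After each step the detached, ADP-bearing head rebinds from an
intermediate position either to the front or to the rear binding site.
The forward choice is biased by the neck-linker docking energy $E_{NL}$
(in $k_BT$ units) and by the work done by the load over a characteristic
distance $d^{(+)}$:

$$P_E = \frac{e^{E_{NL}} e^{\beta F d^{(+)}}}{e^{E_{NL}} e^{\beta F d^{(+)}} + 1},
\qquad \beta = 1/k_BT .$$

The trailing and leading heads hydrolyze ATP at bare rates $k^{(+)}$ and
$k^{(-)}$; ADP release has rate $k_D$ and ATP binding rate
$k_{bT}[\mathrm{ATP}]$. The effective per-head ATPase rates $k_T$ and
$k_L$ are $P_E$-weighted mixtures of inverse sums of the branch waiting
times (see `atpase_rates()`); at saturating ATP the ATP-binding time drops
out, and the finite-ATP forms converge *exactly* to the saturating forms
as $[\mathrm{ATP}] \to \infty$. The no-slip velocity is the net stepping
flux times the lattice spacing,

$$v_0 = \left[P_E k_T - (1 - P_E) k_L\right] d .$$

## Slipping

With probability $P_{II}$ per cycle (hydrolysis in the bound head beating
ADP release in the fresh head; `period2_probability()`) the motor enters
the weak-binding period, which occupies a lifetime fraction $F_{II}$ of
the cycle (`period2_fraction()`; equal to $P_{II}$ at saturating ATP).
While weakly bound, the dimer hops by $d$ at rates
$v_{II}^{(0)} e^{\pm\beta F \delta}$ with $\delta = d/2$, giving the slip
velocity

$$v_{II} = v_{II}^{(0)}\left[e^{\beta F \delta} - e^{-\beta F \delta}\right] d$$

and the total velocity $v = v_0 + P_{II} F_{II}\, v_{II}$. A slip episode
ends by ADP release followed by ATP binding; its mean duration is the
slipping time

$$\tau_S = \frac{k_D + k_{bD}[\mathrm{ADP}] + k_{bT}[\mathrm{ATP}]}
                {k_D\, k_{bT}[\mathrm{ATP}]} \;\xrightarrow{[\mathrm{ATP}]\to\infty}\; 1/k_D .$$

Stepping ratios (forward over backward step fluxes) come in three
flavors: walking only (`stepping_ratio_no_slip()`), walking plus hops
(`stepping_ratio_with_slip()`), and the pure-hopping regime with
saturating ADP and no ATP, where the ratio is the Boltzmann factor
$e^{2\beta F\delta}$ (`stepping_ratio_adp_only()`).

## Simplified force–velocity form

When ADP release is much faster than hydrolysis
($k_D \gg k^{(\pm)}$), the no-slip curve collapses to a four-parameter
form in the unloaded stepping ratio $r_0 = (k^{(+)}/k^{(-)})e^{E_{NL}}$
and the stall force $F_S$:

$$v_0 = \frac{r_0^{\,1 + F/F_S} - 1}{r_0^{\,1 + F/F_S} + k^{(+)}/k^{(-)}}\, k^{(+)} d .$$

**Sign convention of the exponent.** With the forward-positive load
convention used throughout the package, the exponent must be
$1 + F/F_S$: it makes the velocity vanish exactly at $F = -F_S$ (a
backward load) and rise toward the forward plateau $k^{(+)} d$ under
forward load. Writing $1 - F/F_S$ would place the stall at a *forward*
load, contradicting the model's own stall condition
$e^{E_{NL}} e^{-\beta F_S d^{(+)}} k^{(+)} = k^{(-)}$.

# Parameters

| field | meaning | units | Kip3 preset |
|---|---|---|---|
| `k_D` | ADP release rate | s⁻¹ | 400 |
| `k_plus` | trailing-head hydrolysis + Pi release | s⁻¹ | 22 |
| `k_minus` | leading-head hydrolysis + Pi release | s⁻¹ | 45 |
| `E_NL` | neck-linker docking energy | $k_BT$ | 1.1 |
| `d_plus` | forward distance parameter | nm | 1.7 |
| `d_minus` | backward distance parameter (stored only) | nm | 1.7 |
| `v_II0` | unloaded slip hop rate | s⁻¹ | 45 |
| `k_bT` | ATP binding rate | µM⁻¹s⁻¹ | 1 |
| `k_bD` | ADP binding rate | µM⁻¹s⁻¹ | 0 |
| `d` | lattice spacing | nm | 8 |
| `kBT` | thermal energy | pN·nm | 4.1 |

`delta = d/2` is derived, not free. `k_bD` defaults to 0 because ATP
binding strongly outcompetes ADP binding; it only matters when modelling
added ADP. Saturating ATP is a symbolic limit selected with
`atp = "saturating"` (stored internally as `Inf`), so limit expressions
are evaluated directly rather than approximated by a large concentration.

# The simulator

Three modes, all requiring an explicit seed (`sim_config()`), all
restoring the caller's RNG state, and all bit-reproducible for identical
inputs.

**Flux mode (canonical oracle).** Forward and backward walking steps are
independent Poisson processes at the analytic flux rates $P_E k_T$ and
$(1-P_E)k_L$. Slip episodes form an alternating renewal process:
exponential gaps at opening rate $\lambda = P_{II} F_{II} / \tau_S$,
exponential durations of mean $\tau_S$, and hops inside each episode at
rates $v_{II}^{(0)} e^{\pm\beta F\delta}$. This construction makes the
stationary slip time-fraction equal $P_{II} F_{II}$ (to first order in
that small fraction) while the mean episode duration equals the slipping
time — so the mean velocity, the stepping ratio, and the episode
statistics all match the closed forms in expectation by construction.
An alternative construction that opens an episode with probability
$P_{II}$ per completed cycle would give a slip time-fraction
$P_{II}\, k\, \tau_S$, which is *not* $P_{II} F_{II}$ at finite ATP; we
deliberately use the rate form so the simulator is a faithful Monte-Carlo
oracle for the analytic total velocity.

**Mechanistic mode.** An explicit continuous-time Markov chain over the
two-head pathway: at each resolution of the intermediate state the bound
head holds ATP and the rebinding head ADP; the bound head's hydrolysis
races the fresh head's ADP release, and winning that race opens the
weak-binding period (duration = ADP-release plus ATP-binding waiting
times). This mode does not use the closed forms at all, so it serves as a
physical cross-check of the analytic approximations; agreement with the
closed-form velocity is at the ~10% level, reflecting genuine
approximations (branch-time bookkeeping, correlations between successive
cycles) in the analytic expressions.

**Slip-only mode.** Pure biased hopping — the no-ATP, saturating-ADP
regime.

# Estimation recipe

From a no-slip force–velocity curve at saturating ATP
(`estimate_motor_parameters()`):

1. $k^{(+)}, k^{(-)}$ from the mean plateau velocities over the extreme
   fraction of the load range, divided by $d$;
2. $E_{NL}$ by inverting the reduced unloaded-velocity form
   $v_0(0) = \frac{e^{E_{NL}} k^{(+)} - k^{(-)}}{e^{E_{NL}} + 1} d$;
3. $F_S$ from the interpolated zero crossing (median of crossings if
   noise produces several);
4. $d^{(+)}$ by inverting the stall relation,
   $d^{(+)} = k_BT\,[E_{NL} + \ln(k^{(+)}/k^{(-)})]/F_S$.

$k_D$ is not identifiable from force–velocity data and is fixed
(default 400 s⁻¹). The ATP binding rate is calibrated separately from the
half-velocity ATP concentration (`calibrate_k_bT()`, a scalar root solve
on $\log_{10} k_{bT} \in [-3, 3]$), and the slip hop rate from slip-only
velocity data by closed-form weighted least squares (`estimate_v_II0()`).

**Why a 5% plateau window.** The approach of $|v_0|/d$ to its backward
asymptote $k^{(-)}$ is slow: on a $[-10, 10]$ pN grid the mean over the
extreme-10% window $[-10, -8]$ pN is still ~11% below $k^{(-)}$, which by
itself would break a 10% recovery target. The default window is therefore
the extreme 5% of the load range (bias ≈ 9% for $k^{(-)}$, ≈ 2% for
$k^{(+)}$), configurable via `plateau_frac`. Because the recipe *inverts*
the reduced unloaded form, feeding its estimates back through that form
reproduces the input unloaded velocity exactly; the optional
full-expression least-squares refinement (`refine = TRUE`, Nelder–Mead on
log-scaled parameters) recovers the generating truth to ~10⁻⁵ relative on
noiseless data.

# Numerical choices

* The forward-binding probability is computed in log-odds form via
  `stats::plogis()`, so extreme loads degrade gracefully to 0/1 without
  overflow.
* `stall_force()` brackets the root on $[-3, 0]$ pN (widening once to
  $[-20, 0]$), bisects to a velocity tolerance of $10^{-6}$ nm/s, and
  refuses to report a stall when the unloaded velocity is not positive.
* Stepping ratios return `Inf` as a sentinel when the backward flux
  underflows to zero, so curve scans never abort.
* Flux-mode event streams are generated vectorized (Poisson counts +
  sorted uniforms) for speed; mechanistic mode is an explicit event loop
  with geometric array growth.
* Default problem sizes in examples and tests — $10^4$–$10^5$ cycles or
  hops, 20 velocity blocks, 200–1000 MSD segments — are this package's
  own choices, sized so statistical checks at three standard errors run
  in seconds.

# Synthetic data

`generate_fv_fixture()` evaluates one of the analytic velocities
(no-slip, total, or slip-only) on a load grid and adds seeded Gaussian
noise. It emulates a single-molecule force–velocity experiment with known
ground truth, and exists for round-trip tests of the estimation recipe —
its output is labelled synthetic in its metadata and must not be mistaken
for measurements. The shipped `inst/extdata/synthetic_fv_kip3.csv` was
produced this way (noise SD 2 nm/s, fixed seed).

# Known inconsistency: the slip diffusion constant

`slip_diffusion_constant()` reports the conventional one-hop relation
$D = v_{II}^{(0)} d^2 / 2$ (1440 nm²/s for the Kip3 preset). The slip hop
process itself, however, has hops in *each* direction at rate
$v_{II}^{(0)}$ when unloaded, so its mean-squared displacement grows at
$2 v_{II}^{(0)} d^2$ — twice $2D$. Both relations are implemented exactly
as stated, and the test suite contains one deliberately failing test that
asserts their mutual consistency at the 10% level; it fails by the
structural factor of 2, documenting the discrepancy instead of silently
redefining either quantity. The simulator's variance growth is verified
against the hop-process value $2 v_{II}^{(0)} d^2$ separately.

# Limitations

* One motor, one protofilament; no detachment/run-length statistics, no
  multi-motor or crowding effects.
* `d_minus` is stored but enters no expression (the load-sharing factor
  already assumes it equals `d_plus`).
* The walking stepping ratios are defined at saturating ATP; at finite
  ATP only velocities, the slip ratio, and the slipping time are exposed.
* The mechanistic mode is a cross-check, not a calibrated alternative:
  its ~10% deviation from the closed forms is expected and documented,
  not a bug.
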