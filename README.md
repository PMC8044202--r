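# kinslip

Closed-form model, parameter estimation, and stochastic simulation of
processive walking interrupted by stick–slip for kinesin-8 molecular motors
(Kip3-type), in R.

Kinesin-8 motors walk hand-over-hand along a microtubule protofilament,
hydrolyzing one ATP per 8-nm step. Occasionally the motor enters a
weak-binding state in which both heads carry ADP; during this short "slip"
period the dimer diffuses along the lattice as a biased hopping process
before re-engaging. `kinslip` implements:

* **Core model** — closed-form expressions for the force- and ATP-dependent
  walking velocity, forward/backward stepping ratios, slip velocity, mean
  slipping time, stall force (closed-form seed and full root solve), and the
  slip-state diffusion constant. Saturating ATP is handled as a symbolic
  limit (never a large finite concentration), and the finite-ATP
  expressions converge exactly to the limit forms.
* **Estimation** — a four-parameter recipe that reads the catalytic rates
  off the velocity plateaus of a force–velocity curve, inverts the unloaded
  velocity for the neck-linker docking energy, interpolates the stall force
  from the zero crossing, and inverts the stall relation for the forward
  distance parameter; plus a separate calibration of the ATP-binding rate
  from the half-velocity ATP concentration and a closed-form fit of the
  slip hop rate.
* **Simulator** — seeded stochastic trajectory generation in three modes:
  `flux` (Poisson fluxes at the analytic rates; matches the closed forms in
  expectation by construction), `mechanistic` (an explicit continuous-time
  Markov chain over the two-head pathway; an independent physical
  cross-check, agreeing with the closed forms at the ~10% level), and
  `slip_only` (pure biased hopping, the no-ATP/saturating-ADP regime).
* **Scans, fixtures, CLI** — deterministic curve scans over (load, ATP)
  grids, synthetic force–velocity data generation with seeded noise, and a
  command-line tool wrapping all of the above.

## Conventions and units

Load `F` is signed and **positive in the forward direction** (toward the
microtubule plus end); stall therefore occurs at a negative load, and stall
*forces* are reported as magnitudes. Rates are s⁻¹, second-order binding
rates µM⁻¹s⁻¹, distances nm, velocities nm/s, energies in units of the
thermal energy `kBT` (default 4.1 pN·nm).

## Worked example

```r
library(kinslip)

p <- motor_preset("kip3_table1")   # calibrated Kip3 parameter set
p
#> Motor parameter set
#>   catalytic: k_D = 400 /s, k+ = 22 /s, k- = 45 /s
#>   energetic: E_NL = 1.1 kBT (kBT = 4.1 pN nm)
#>   geometric: d = 8 nm, d+ = 1.7 nm, d- = 1.7 nm, delta = 4 nm
#>   slip/binding: v_II0 = 45 /s, k_bT = 1 /uM/s, k_bD = 0 /uM/s

# Velocity under 0.5 pN backward load at saturating ATP, with the slip
# contribution broken out:
total_velocity(p, motor_condition(-0.5, "saturating"))
#> Velocity result (1 operating point)
#>        v0    v_slip  v_total
#>  25.87456 -1.609075 24.26549

stall_force(p)                        # root of the no-slip velocity
#> [1] 1.050586
stall_force(p, include_slip = TRUE)   # slip pulls the stall to lower load
#> [1] 0.9745021
stepping_ratio_no_slip(p, 0)          # unloaded forward/backward ratio
#> [1] 1.568589
slipping_time(p, "saturating") * 1000 # mean slip-episode duration, ms
#> [1] 2.5
```

A seeded stochastic trajectory and its summary:

```r
tr <- simulate_motor(p, motor_condition(0, "saturating"),
                     sim_config(seed = 2024, n_cycles = 10000))
summarize_trajectory(tr)
#> Trajectory summary over 158 s
#>   mean velocity: 46.588 +/- 3.215 nm/s (SE, 20 blocks)
#>   walking steps: 2623 forward, 1694 backward
#>   slip: 234 episodes (mean 0.002407 s), 24/33 hops f/b, net -72 nm
#>   empirical stepping ratio: 1.533
```

The analytic unloaded velocity is 47.24 nm/s and the analytic stepping
ratio 1.56; the simulated values above agree within their statistical
errors, and rerunning with the same seed reproduces them bit for bit.

Round-tripping the estimation recipe through noisy synthetic data:

```r
fv <- generate_fv_fixture("kip3_table1", noise_sd = 2, seed = 7)
estimate_motor_parameters(fv)
#> Estimated motor parameters (recipe estimates)
#>   k+ = 21.649 /s, k- = 41.135 /s, E_NL = 1.1206 kBT, d+ = 1.8306 nm
#>   observed stall force: 1.0720 pN; fixed k_D = 400 /s
#>   residual RMS: 8.798 nm/s
```

(Generating truth: k⁺ = 22, k⁻ = 45, E_NL = 1.1, d⁺ = 1.7.)

## Command line

A thin wrapper script ships with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "kinslip.R", package = "kinslip"))')
Rscript "$CLI" compute --force -0.5 --atp saturating
Rscript "$CLI" scan --force-start -2 --force-stop 2 --force-step 0.1 \
        --atp saturating,10 --quantities v0,v_total --out scan.csv
Rscript "$CLI" simulate --seed 7 --cycles 10000 --out traj.tsv --summary s.json
Rscript "$CLI" fixture --noise-sd 2 --seed 7 --out fv.csv
Rscript "$CLI" estimate --data fv.csv --out report.json
```

Every subcommand logs the full parameter set in use to standard error
before doing any work.

## Example data

`inst/extdata/` ships a small **synthetic** force–velocity dataset
(`synthetic_fv_kip3.csv`, generated from the `kip3_table1` preset with
seeded noise — not an experimental measurement) and an example parameter
file (`example_motor.yaml`):

```r
fv <- read_fv_dataset(system.file("extdata", "synthetic_fv_kip3.csv",
                                  package = "kinslip"))
estimate_motor_parameters(fv)
```

## Reproduction

From the repository root:

```sh
R CMD INSTALL --no-docs --no-html --no-help .
Rscript -e 'testthat::test_dir("tests/testthat", package = "kinslip",
                               load_package = "installed")'
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The test suite is deterministic: every stochastic test fixes its seed, and
statistical checks compare simulated quantities to the closed forms within
three standard errors. One acceptance test (the slip-only
mean-squared-displacement bound against twice the reported diffusion
constant) fails by design: the reported diffusion constant follows the
conventional one-hop relation `D = v_II0 d²/2`, while the slip hop process
itself (rates `v_II0 exp(±βFδ)` in each direction) has an unloaded
variance growth rate of `2 v_II0 d²` — a factor-2 inconsistency between
the two published relations that the package documents rather than hides.
See the methods vignette (`vignettes/kinslip-methods.Rmd`) for the full
discussion and all other numerical design choices.

## License

MIT.
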