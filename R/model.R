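# Inverse thermal energy (1/pN nm).
.beta <- function(params) 1 / params$kBT

#' Probability of forward binding from the intermediate position
#'
#' Probability `P_E` that the detached ADP-head moves from the intermediate
#' (INT) position to the *front* binding site rather than the rear one. It is
#' a two-state Boltzmann factor in the neck-linker docking energy `E_NL` and
#' the work `F d_plus` done by the load over the forward distance parameter:
#' \deqn{P_E = \frac{e^{E_{NL}} e^{\beta F d^{(+)}}}{e^{E_{NL}} e^{\beta F d^{(+)}} + 1}.}
#' Computed in log-odds form ([stats::plogis()]), so arbitrarily large |F|
#' degrades gracefully toward 0 or 1 without overflow or `NaN`.
#'
#' @param params A [motor_parameters()] object.
#' @param force Signed load (pN), vectorized; positive = forward.
#' @return Probability in (0, 1), strictly increasing in `force`.
#' @examples
#' binding_probability(motor_preset("kip3_table1"), 0) # ~0.750
#' @export
binding_probability <- function(params, force) {
  validate_motor_parameters(params)
  stats::plogis(params$E_NL + .beta(params) * force * params$d_plus)
}

#' Overall ATPase rates of the trailing and leading heads
#'
#' Effective catalytic rates `k_T` (trailing head, forward neck-linker
#' orientation) and `k_L` (leading head). At saturating ATP these are
#' mixtures, weighted by the forward-binding probability `P_E`, of the bare
#' hydrolysis rate and its harmonic combination with ADP release:
#' \deqn{k_T = k^{(+)} P_E + \frac{k_D k^{(+)}}{k_D + k^{(+)}} (1 - P_E),\qquad
#'       k_L = \frac{k_D k^{(-)}}{k_D + k^{(-)}} P_E + k^{(-)} (1 - P_E).}
#' At finite ATP each branch is the inverse of a sum of mean waiting times
#' that also includes the ATP-binding time `1/(k_bT [ATP])`:
#' \deqn{k_T = P_E \left(\frac{1}{k^{(+)}} + \frac{1}{k_{bT}[ATP]}\right)^{-1}
#'  + (1-P_E)\left(\frac{1}{k_D} + \frac{1}{k_{bT}[ATP]} + \frac{1}{k^{(+)}}\right)^{-1}}
#' and symmetrically for `k_L`. The finite-ATP forms converge exactly to the
#' saturating forms as `[ATP] -> Inf`.
#'
#' @param params A [motor_parameters()] object.
#' @param cond A [motor_condition()]; `[ATP]` must be positive or saturating.
#' @return A list with numeric components `k_T` and `k_L` (s^-1), vectorized
#'   over `cond$force`.
#' @export
atpase_rates <- function(params, cond) {
  validate_motor_parameters(params)
  check_walking_condition(cond)
  P_E <- binding_probability(params, cond$force)
  kp <- params$k_plus
  km <- params$k_minus
  kD <- params$k_D
  if (is_saturating(cond)) {
    k_T <- kp * P_E + (kD * kp / (kD + kp)) * (1 - P_E)
    k_L <- (kD * km / (kD + km)) * P_E + km * (1 - P_E)
  } else {
    tb <- 1 / (params$k_bT * cond$atp) # mean ATP-binding time
    k_T <- P_E / (1 / kp + tb) + (1 - P_E) / (1 / kD + tb + 1 / kp)
    k_L <- P_E / (1 / kD + tb + 1 / km) + (1 - P_E) / (1 / km + tb)
  }
  list(k_T = k_T, k_L = k_L)
}

#' Overall ATPase rate of the motor
#'
#' Sum `k = k_T + k_L` of the trailing- and leading-head rates at one
#' operating point.
#'
#' @inheritParams atpase_rates
#' @return Rate (s^-1), vectorized over `cond$force`.
#' @export
total_atpase_rate <- function(params, cond) {
  r <- atpase_rates(params, cond)
  r$k_T + r$k_L
}

#' Walking velocity without slip
#'
#' Net stepping flux times the lattice spacing,
#' \deqn{v_0 = [P_E k_T - (1 - P_E) k_L]\, d,}
#' with the branch-appropriate (saturating or finite-ATP) head rates.
#' Positive means movement toward the microtubule plus end.
#'
#' @inheritParams atpase_rates
#' @return Signed velocity (nm/s), vectorized over `cond$force`.
#' @examples
#' velocity_no_slip(motor_preset("kip3_table1"),
#'                  motor_condition(0, "saturating")) # ~47.2
#' @export
velocity_no_slip <- function(params, cond) {
  P_E <- binding_probability(params, cond$force)
  r <- atpase_rates(params, cond)
  (P_E * r$k_T - (1 - P_E) * r$k_L) * params$d
}

#' Simplified four-parameter force-velocity relation
#'
#' Reduced closed form of the no-slip velocity valid when ADP release is much
#' faster than hydrolysis (`k_D >> k^(+), k^(-)`):
#' \deqn{v_0 = \frac{r_0^{\,1 + F/F_S} - 1}{r_0^{\,1 + F/F_S} + k^{(+)}/k^{(-)}}\, k^{(+)} d,}
#' where `r0` is the unloaded stepping ratio and `F_S` the stall force. With
#' the forward-positive load convention used throughout, the exponent
#' `1 + F/F_S` makes the velocity vanish exactly at `F = -F_S` and approach
#' `k^(+) d` under large forward load.
#'
#' @param r0 Unloaded stepping ratio (> 1).
#' @param F_S Stall force magnitude (pN, > 0).
#' @param k_plus,k_minus Catalytic rates (s^-1).
#' @param force Signed load (pN), vectorized.
#' @param d Lattice spacing (nm). Default 8.
#' @return Signed velocity (nm/s).
#' @examples
#' sp <- simple_velocity_preset("kip3_simple_fit")
#' velocity_no_slip_simple(sp$r0, sp$F_S, sp$k_plus, sp$k_minus, force = 0)
#' @export
velocity_no_slip_simple <- function(r0, F_S, k_plus, k_minus, force, d = 8) {
  stopifnot(r0 > 1, F_S > 0, k_plus > 0, k_minus > 0, d > 0)
  rx <- r0^(1 + force / F_S)
  (rx - 1) / (rx + k_plus / k_minus) * k_plus * d
}

#' Occurrence probability of the weak-binding period (Period II)
#'
#' Probability, per ATPase cycle, that the motor enters the weakly bound
#' state in which both heads carry ADP and slipping can occur. It is the
#' probability that hydrolysis + Pi release in the strongly bound head beats
#' ADP release in the newly bound head:
#' \deqn{P_{II} = P_E \frac{k^{(+)}}{k^{(+)} + k_D}
#'       + (1 - P_E) \frac{k^{(-)}}{k^{(-)} + k_D}.}
#'
#' @inheritParams binding_probability
#' @return Probability in (0, 1), vectorized over `force`.
#' @export
period2_probability <- function(params, force) {
  P_E <- binding_probability(params, force)
  kp <- params$k_plus
  km <- params$k_minus
  kD <- params$k_D
  P_E * kp / (kp + kD) + (1 - P_E) * km / (km + kD)
}

#' Lifetime fraction of Period II in the ATPase cycle
#'
#' Fraction of the total cycle time spent in the weak-binding period, given
#' that it occurs. At saturating ATP the expression coincides with
#' [period2_probability()]. At finite ATP the weak-binding lifetime `1/k_D`
#' is weighed against the full branch cycle time including ATP binding:
#' \deqn{F_{II} = P_E \frac{1/k_D}{1/(k_{bT}[ATP]) + 1/k^{(+)} + 1/k_D}
#'  + (1-P_E) \frac{1/k_D}{1/(k_{bT}[ATP]) + 1/k^{(-)} + 1/k_D},}
#' which converges to the saturating form as `[ATP] -> Inf`.
#'
#' @inheritParams atpase_rates
#' @return Dimensionless fraction in (0, 1), vectorized over `cond$force`.
#' @export
period2_fraction <- function(params, cond) {
  validate_motor_parameters(params)
  check_walking_condition(cond)
  if (is_saturating(cond)) {
    return(period2_probability(params, cond$force))
  }
  P_E <- binding_probability(params, cond$force)
  kD <- params$k_D
  tb <- 1 / (params$k_bT * cond$atp)
  P_E * (1 / kD) / (tb + 1 / params$k_plus + 1 / kD) +
    (1 - P_E) * (1 / kD) / (tb + 1 / params$k_minus + 1 / kD)
}

#' Slip velocity in the weak-binding state
#'
#' Velocity of the biased hopping (slipping) of the weakly bound dimer, from
#' forward and backward hop rates `v_II0 exp(+/- beta F delta)` over a
#' symmetric periodic potential with `delta = d/2`:
#' \deqn{v_{II} = v_{II}^{(0)} \left[e^{\beta F \delta} - e^{-\beta F \delta}\right] d.}
#' Odd in `F`; zero at no load. This is also the motor velocity in the
#' slip-only regime (saturating ADP, no ATP).
#'
#' @inheritParams binding_probability
#' @return Signed velocity (nm/s), vectorized over `force`.
#' @examples
#' slip_velocity(motor_preset("kip3_table1"), 1) # ~819
#' @export
slip_velocity <- function(params, force) {
  validate_motor_parameters(params)
  x <- .beta(params) * force * params$delta
  params$v_II0 * (exp(x) - exp(-x)) * params$d
}

#' All intermediate fluxes at one operating point
#'
#' Convenience accessor returning `P_E`, `k_T`, `k_L`, `k_total = k_T + k_L`,
#' `P_II` and `F_II` together, with the branch (saturating vs finite ATP)
#' chosen from the condition.
#'
#' @inheritParams atpase_rates
#' @return An object of class `rate_breakdown`: a list of numeric vectors
#'   `P_E`, `k_T`, `k_L`, `k_total`, `P_II`, `F_II`, one element per load in
#'   `cond$force`.
#' @export
rate_breakdown <- function(params, cond) {
  r <- atpase_rates(params, cond)
  out <- list(
    P_E = binding_probability(params, cond$force),
    k_T = r$k_T, k_L = r$k_L, k_total = r$k_T + r$k_L,
    P_II = period2_probability(params, cond$force),
    F_II = period2_fraction(params, cond)
  )
  class(out) <- "rate_breakdown"
  out
}

#' Total velocity including slip
#'
#' Walking velocity plus the slip contribution weighted by the probability
#' and lifetime fraction of the weak-binding period:
#' \deqn{v = v_0 + P_{II} F_{II} v_{II}.}
#'
#' @inheritParams atpase_rates
#' @return An object of class `velocity_result`: a list with components
#'   `v0`, `v_slip = P_II F_II v_II`, `v_total = v0 + v_slip` (all nm/s,
#'   vectorized over `cond$force`) and `breakdown`, the [rate_breakdown()]
#'   used.
#' @examples
#' total_velocity(motor_preset("kip3_table1"), motor_condition(-1, "saturating"))
#' @export
total_velocity <- function(params, cond) {
  br <- rate_breakdown(params, cond)
  v0 <- (br$P_E * br$k_T - (1 - br$P_E) * br$k_L) * params$d
  v_slip <- br$P_II * br$F_II * slip_velocity(params, cond$force)
  out <- list(v0 = v0, v_slip = v_slip, v_total = v0 + v_slip,
              breakdown = br)
  class(out) <- "velocity_result"
  out
}

#' @export
print.velocity_result <- function(x, ...) {
  n <- length(x$v_total)
  cat(sprintf("Velocity result (%d operating point%s)\n", n,
              if (n == 1) "" else "s"))
  df <- data.frame(v0 = x$v0, v_slip = x$v_slip, v_total = x$v_total)
  print(utils::head(df, 10), row.names = FALSE)
  if (n > 10) cat("  ...\n")
  invisible(x)
}

#' Mean slipping time
#'
#' Lifetime of ADP on the microtubule-bound head in the weak-binding state,
#' i.e. the mean duration of a slip episode:
#' \deqn{\tau_S = \frac{k_D + k_{bD}[ADP] + k_{bT}[ATP]}{k_D\, k_{bT}[ATP]},}
#' which tends to `1/k_D` at saturating ATP. The episode ends by ADP release
#' followed by ATP binding; ADP rebinding (rate `k_bD [ADP]`) prolongs it.
#'
#' @param params A [motor_parameters()] object.
#' @param atp ATP concentration (uM, > 0) or `"saturating"` / `Inf`.
#' @param adp ADP concentration (uM). Default 0.
#' @return Time in seconds.
#' @examples
#' slipping_time(motor_preset("kip3_table1"), "saturating") # 1/400 s = 2.5 ms
#' @export
slipping_time <- function(params, atp, adp = 0) {
  validate_motor_parameters(params)
  if (identical(atp, "saturating")) atp <- Inf
  stopifnot(is.numeric(atp), length(atp) == 1L, adp >= 0)
  if (atp == 0) {
    stop("slipping time diverges at [ATP] = 0; the no-ATP regime is the ",
         "slip-only mode")
  }
  if (is.infinite(atp)) {
    return(1 / params$k_D)
  }
  (params$k_D + params$k_bD * adp + params$k_bT * atp) /
    (params$k_D * params$k_bT * atp)
}

#' Stepping ratio without slip (saturating ATP)
#'
#' Ratio of forward to backward walking-step fluxes,
#' \deqn{r_0 = \frac{P_E\, k_T}{(1 - P_E)\, k_L},}
#' with the saturating-ATP head rates. Greater than 1 exactly when the
#' no-slip velocity is positive; equals 1 at stall. If `P_E` reaches 1 (huge
#' forward load or very large `E_NL`) the ratio is `Inf`, returned as a
#' sentinel rather than an error so curve scans never abort.
#'
#' @inheritParams binding_probability
#' @return Dimensionless ratio in (0, Inf], vectorized over `force`.
#' @export
stepping_ratio_no_slip <- function(params, force) {
  validate_motor_parameters(params)
  r <- atpase_rates(params, motor_condition(force, "saturating"))
  P_E <- binding_probability(params, force)
  (P_E * r$k_T) / ((1 - P_E) * r$k_L)
}

#' Stepping ratio including slip (saturating ATP)
#'
#' Forward-to-backward step ratio with slip hops counted on both sides:
#' \deqn{r = \frac{P_E k_T + P_{II} F_{II} v_{II}^{(0)} e^{\beta F \delta}}
#'                {(1 - P_E) k_L + P_{II} F_{II} v_{II}^{(0)} e^{-\beta F \delta}}.}
#' Reduces to [stepping_ratio_no_slip()] when `v_II0 = 0`.
#'
#' @inheritParams binding_probability
#' @return Dimensionless ratio in (0, Inf], vectorized over `force`.
#' @export
stepping_ratio_with_slip <- function(params, force) {
  validate_motor_parameters(params)
  cond <- motor_condition(force, "saturating")
  r <- atpase_rates(params, cond)
  P_E <- binding_probability(params, force)
  w <- period2_probability(params, force) * period2_fraction(params, cond) *
    params$v_II0
  x <- .beta(params) * force * params$delta
  (P_E * r$k_T + w * exp(x)) / ((1 - P_E) * r$k_L + w * exp(-x))
}

#' Stepping ratio in the slip-only regime (saturating ADP, no ATP)
#'
#' With no ATP turnover the motor only hops, and the forward/backward hop
#' ratio is a pure Boltzmann factor in the work per hop:
#' \deqn{r_{II} = e^{2 \beta F \delta}.}
#' Equals 1 at no load; satisfies `r(F) r(-F) = 1`.
#'
#' @inheritParams binding_probability
#' @return Dimensionless ratio, vectorized over `force`.
#' @export
stepping_ratio_adp_only <- function(params, force) {
  validate_motor_parameters(params)
  exp(2 * .beta(params) * force * params$delta)
}

#' Closed-form stall force of the simplified model
#'
#' Seed value for the stall force from the reduced description (valid for
#' `k_D >> k^(+), k^(-)`): the backward load magnitude at which the
#' forward-binding bias exactly compensates the catalytic asymmetry,
#' \deqn{\exp(E_{NL}) \exp(-\beta F_S d^{(+)}) k^{(+)} = k^{(-)},}
#' i.e. `F_S = kBT (E_NL + log(k+/k-)) / d_plus` with the natural logarithm.
#'
#' @param params A [motor_parameters()] object.
#' @return Stall force magnitude (pN).
#' @export
stall_force_closed_form <- function(params) {
  validate_motor_parameters(params)
  params$kBT * (params$E_NL + log(params$k_plus / params$k_minus)) /
    params$d_plus
}

#' Unloaded stepping ratio of the simplified model
#'
#' `r0 = (k+/k-) exp(E_NL)`, the unloaded forward/backward stepping ratio in
#' the reduced (`k_D >> k^(+), k^(-)`) description.
#'
#' @param params A [motor_parameters()] object.
#' @return Dimensionless ratio.
#' @export
simple_form_r0 <- function(params) {
  validate_motor_parameters(params)
  (params$k_plus / params$k_minus) * exp(params$E_NL)
}

#' Stall force by root solving the full velocity expression
#'
#' Magnitude `F_S > 0` of the backward load at which the selected velocity
#' (no-slip `v0`, or total `v` including slip) crosses zero. Solved by
#' bisection on `F` in `[-3, 0]` pN (widened to `[-20, 0]` if needed),
#' seeded conceptually by [stall_force_closed_form()], and iterated until
#' the velocity magnitude at the root is below `tol_v`.
#'
#' @param params A [motor_parameters()] object.
#' @param include_slip If `TRUE`, solve the total velocity (walking + slip);
#'   otherwise the no-slip walking velocity. Default `FALSE`.
#' @param cond Operating condition giving the ATP/ADP concentrations (the
#'   load in it is ignored). Default saturating ATP.
#' @param tol_v Velocity tolerance at the root (nm/s). Default 1e-6.
#' @return Stall force magnitude (pN).
#' @examples
#' stall_force(motor_preset("kip3_table1")) # ~1.05
#' @export
stall_force <- function(params, include_slip = FALSE,
                        cond = motor_condition(0, "saturating"),
                        tol_v = 1e-6) {
  validate_motor_parameters(params)
  vel <- function(F) {
    c2 <- motor_condition(F, if (is_saturating(cond)) "saturating" else
      cond$atp, cond$adp)
    if (include_slip) total_velocity(params, c2)$v_total
    else velocity_no_slip(params, c2)
  }
  if (vel(0) <= 0) {
    stop("velocity at F = 0 is not positive; stall force undefined")
  }
  lo <- -3
  if (vel(lo) >= 0) {
    lo <- -20
    if (vel(lo) >= 0) {
      stop("no sign change of the velocity over [-20, 0] pN: cannot bracket ",
           "a stall force")
    }
  }
  hi <- 0
  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2
    vm <- vel(mid)
    if (abs(vm) < tol_v) break
    if (vm < 0) lo <- mid else hi <- mid
  }
  -mid
}

#' Diffusion constant of the slip state
#'
#' Conventional approximate relation between the unloaded slip hop rate and the
#' diffusion constant of the weakly bound dimer, read dimensionally as one
#' hop of size `d` per diffusion time `t0 = 1/v_II0`:
#' \deqn{D = v_{II}^{(0)} d^2 / 2.}
#' Note this counts a single hop per `t0`; the hop process of
#' [slip_velocity()], with rates `v_II0 exp(+/- beta F delta)` in *each*
#' direction, has an unloaded mean-squared-displacement slope of
#' `2 v_II0 d^2`, twice `2 D`. The conventional relation is kept as the reported
#' quantity; the discrepancy is documented in the methods vignette.
#'
#' @param params A [motor_parameters()] object.
#' @return Diffusion constant (nm^2/s).
#' @examples
#' slip_diffusion_constant(motor_preset("kip3_table1")) # 1440
#' @export
slip_diffusion_constant <- function(params) {
  validate_motor_parameters(params)
  params$v_II0 * params$d^2 / 2
}
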