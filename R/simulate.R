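#' Simulation configuration
#'
#' Settings for one stochastic trajectory: the RNG seed (mandatory, no
#' silent clock seeding), the simulated extent, and the simulation mode.
#'
#' Modes:
#' * `"flux"` (canonical oracle): forward/backward walking steps are Poisson
#'   processes at the analytic flux rates `P_E k_T` and `(1-P_E) k_L`;
#'   slip episodes open at rate `P_II F_II / tau_S`, last an exponential
#'   time of mean `tau_S` ([slipping_time()]), and contain hops at rates
#'   `v_II0 exp(+/- beta F delta)`. Mean velocity, stepping ratio and
#'   episode statistics match the closed forms in expectation by
#'   construction.
#' * `"mechanistic"`: explicit continuous-time Markov chain over the
#'   two-head pathway sub-states (ADP release, ATP binding, the
#'   hydrolysis-vs-release race that opens the weak-binding period). A
#'   physical cross-check of the analytic approximations; agreement with
#'   the closed forms is at the ~10% level, not exact.
#' * `"slip_only"`: pure biased hopping (saturating ADP, no ATP).
#'
#' @param seed Integer RNG seed (required).
#' @param duration Simulated time (s). Give either this or `n_cycles`.
#' @param n_cycles Target number of ATPase cycles (hop count in
#'   `"slip_only"` mode); converted to a duration via the analytic rates.
#' @param mode `"flux"`, `"mechanistic"` or `"slip_only"`.
#' @param record_states If `FALSE`, zero-displacement bookkeeping rows
#'   (episode entry/exit) are omitted from the trajectory.
#' @param blocks Number of blocks for block-averaged velocity standard
#'   errors in [summarize_trajectory()]. Default 20.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed, duration = NULL, n_cycles = NULL,
                       mode = c("flux", "mechanistic", "slip_only"),
                       record_states = TRUE, blocks = 20) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("sim_config requires an explicit integer seed")
  }
  mode <- match.arg(mode)
  if (is.null(duration) && is.null(n_cycles)) {
    stop("give either duration (s) or n_cycles")
  }
  if (!is.null(duration) && duration <= 0) stop("duration must be positive")
  if (!is.null(n_cycles) && n_cycles <= 0) stop("n_cycles must be positive")
  structure(list(seed = as.integer(seed), duration = duration,
                 n_cycles = n_cycles, mode = mode,
                 record_states = isTRUE(record_states),
                 blocks = as.integer(blocks)),
            class = "sim_config")
}

# Run fn() under a fixed seed, restoring the caller's RNG state afterwards.
with_sim_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister")
  fn()
}

new_trajectory <- function(time_s, position_nm, event, duration, params,
                           cond, config) {
  df <- data.frame(time_s = time_s, position_nm = position_nm,
                   event = event, stringsAsFactors = FALSE)
  attr(df, "duration") <- duration
  attr(df, "params") <- params
  attr(df, "cond") <- cond
  attr(df, "config") <- config
  class(df) <- c("kin_trajectory", "data.frame")
  df
}

#' Simulate a motor trajectory
#'
#' Seeded stochastic simulation of the walking-plus-slipping pathway; see
#' [sim_config()] for the available modes. Identical `(params, cond,
#' config)` produce bit-identical trajectories; the caller's RNG state is
#' left untouched.
#'
#' @param params A [motor_parameters()] object.
#' @param cond A [motor_condition()] with a single load value. Walking modes
#'   require ATP (finite positive or saturating); `"slip_only"` ignores the
#'   nucleotide fields.
#' @param config A [sim_config()].
#' @return An object of class `kin_trajectory`: a `data.frame` with columns
#'   `time_s` (strictly increasing), `position_nm` (integer multiples of the
#'   lattice spacing) and `event` (one of `walk-forward`, `walk-backward`,
#'   `periodII-entry`, `slip-hop-forward`, `slip-hop-backward`,
#'   `periodII-exit`), with the total simulated `duration`, the inputs and
#'   the seed attached as attributes.
#' @examples
#' tr <- simulate_motor(motor_preset("kip3_table1"),
#'                      motor_condition(0, "saturating"),
#'                      sim_config(seed = 1, n_cycles = 500))
#' summarize_trajectory(tr)
#' @export
simulate_motor <- function(params, cond, config) {
  validate_motor_parameters(params)
  stopifnot(inherits(cond, "motor_condition"), inherits(config, "sim_config"),
            length(cond$force) == 1L)
  out <- switch(config$mode,
    flux = with_sim_seed(config$seed,
                         function() sim_flux(params, cond, config)),
    mechanistic = with_sim_seed(config$seed,
                                function() sim_mechanistic(params, cond,
                                                           config)),
    slip_only = with_sim_seed(config$seed,
                              function() sim_slip_only(params, cond$force,
                                                       config))
  )
  if (!config$record_states) {
    keep <- !(out$event %in% c("periodII-entry", "periodII-exit"))
    att <- attributes(out)
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "duration") <- att$duration
    attr(out, "params") <- att$params
    attr(out, "cond") <- att$cond
    attr(out, "config") <- att$config
    class(out) <- c("kin_trajectory", "data.frame")
  }
  out
}

#' Simulate pure slipping (saturating ADP, no ATP)
#'
#' Biased hopping on the lattice at forward/backward rates
#' `v_II0 exp(+/- beta F delta)` with hop size `d`. Convenience wrapper
#' around [simulate_motor()] with `mode = "slip_only"`.
#'
#' @param params A [motor_parameters()] object.
#' @param force Signed load (pN).
#' @param config A [sim_config()] (its `mode` is overridden).
#' @return A `kin_trajectory`.
#' @export
simulate_slip_only <- function(params, force, config) {
  config$mode <- "slip_only"
  simulate_motor(params, motor_condition(force, atp = 0), config)
}

# Flux-mode generator: superposed Poisson walking fluxes plus a renewal
# process of slip episodes whose stationary time fraction is P_II * F_II.
sim_flux <- function(params, cond, config) {
  br <- rate_breakdown(params, cond)
  a <- br$P_E * br$k_T
  b <- (1 - br$P_E) * br$k_L
  k <- br$k_total
  T_ <- if (!is.null(config$duration)) config$duration else
    config$n_cycles / k
  tau <- slipping_time(params, if (is_saturating(cond)) "saturating" else
    cond$atp, cond$adp)
  lambda <- br$P_II * br$F_II / tau
  x <- (cond$force * params$delta) / params$kBT
  hf <- params$v_II0 * exp(x)
  hb <- params$v_II0 * exp(-x)

  times <- numeric(0); dpos <- numeric(0); event <- character(0)
  add <- function(t, dp, ev) {
    times <<- c(times, t); dpos <<- c(dpos, dp); event <<- c(event, ev)
  }
  nf <- stats::rpois(1, a * T_)
  if (nf > 0) add(sort(stats::runif(nf, 0, T_)), rep(params$d, nf),
                  rep("walk-forward", nf))
  nb <- stats::rpois(1, b * T_)
  if (nb > 0) add(sort(stats::runif(nb, 0, T_)), rep(-params$d, nb),
                  rep("walk-backward", nb))
  if (lambda > 0) {
    t <- 0
    repeat {
      s <- t + stats::rexp(1, lambda)
      if (s >= T_) break
      L <- stats::rexp(1, 1 / tau)
      e <- min(s + L, T_)
      add(s, 0, "periodII-entry")
      nh <- stats::rpois(1, (hf + hb) * (e - s))
      if (nh > 0) {
        ht <- sort(stats::runif(nh, s, e))
        fwd <- stats::runif(nh) < hf / (hf + hb)
        add(ht, ifelse(fwd, params$d, -params$d),
            ifelse(fwd, "slip-hop-forward", "slip-hop-backward"))
      }
      add(e, 0, "periodII-exit")
      t <- e
    }
  }
  o <- order(times)
  new_trajectory(times[o], cumsum(dpos[o]), event[o], T_, params, cond,
                 config)
}

# Mechanistic CTMC over the two-head pathway. At every resolution of the
# intermediate (INT) state the bound head carries ATP and the rebinding head
# carries ADP; "old" denotes the bound head, "fresh" the rebinding one.
sim_mechanistic <- function(params, cond, config) {
  check_walking_condition(cond)
  P_E <- binding_probability(params, cond$force)
  kp <- params$k_plus; km <- params$k_minus; kD <- params$k_D
  kbTA <- if (is_saturating(cond)) Inf else params$k_bT * cond$atp
  x <- (cond$force * params$delta) / params$kBT
  hf <- params$v_II0 * exp(x)
  hb <- params$v_II0 * exp(-x)

  use_cycles <- !is.null(config$n_cycles)
  T_lim <- if (use_cycles) Inf else config$duration
  n_lim <- if (use_cycles) config$n_cycles else Inf

  cap <- 4096L
  times <- numeric(cap); dpos <- numeric(cap); event <- character(cap)
  n_ev <- 0L
  add <- function(t, dp, ev) {
    if (n_ev == cap) {
      cap <<- cap * 2L
      length(times) <<- cap; length(dpos) <<- cap; length(event) <<- cap
    }
    n_ev <<- n_ev + 1L
    times[n_ev] <<- t; dpos[n_ev] <<- dp; event[n_ev] <<- ev
  }

  t <- 0
  dir_prev <- if (stats::runif(1) < P_E) "front" else "rear"
  n_cyc <- 0
  while (t < T_lim && n_cyc < n_lim) {
    # roles set by the previous resolution
    old_is_trailing <- dir_prev == "front"
    rate_old <- if (old_is_trailing) kp else km
    rate_fresh3 <- if (old_is_trailing) km else kp
    detached_trailing <- NA
    # phase 1: old-head hydrolysis races fresh-head ADP release
    t <- t + stats::rexp(1, rate_old + kD)
    if (stats::runif(1) < rate_old / (rate_old + kD)) {
      # old head detaches while the bound head still holds ADP: Period II
      add(t, 0, "periodII-entry")
      L <- stats::rexp(1, kD) +
        if (is.finite(kbTA)) stats::rexp(1, kbTA) else 0
      nh <- stats::rpois(1, (hf + hb) * L)
      if (nh > 0) {
        ht <- t + sort(stats::runif(nh, 0, L))
        for (j in seq_len(nh)) {
          fwd <- stats::runif(1) < hf / (hf + hb)
          add(ht[j], if (fwd) params$d else -params$d,
              if (fwd) "slip-hop-forward" else "slip-hop-backward")
        }
      }
      t <- t + L
      add(t, 0, "periodII-exit")
      detached_trailing <- old_is_trailing
    } else {
      # fresh head released ADP first; it binds ATP, then both race hydrolysis
      if (is.finite(kbTA)) {
        dt <- stats::rexp(1, rate_old + kbTA)
        t <- t + dt
        if (stats::runif(1) < rate_old / (rate_old + kbTA)) {
          # old detaches while fresh is waiting for ATP; resolution must
          # wait for ATP binding on the bound head
          t <- t + stats::rexp(1, kbTA)
          detached_trailing <- old_is_trailing
        }
      }
      if (is.na(detached_trailing)) {
        t <- t + stats::rexp(1, rate_old + rate_fresh3)
        detached_trailing <- if (stats::runif(1) <
                                 rate_old / (rate_old + rate_fresh3))
          old_is_trailing else !old_is_trailing
      }
    }
    # INT resolution
    dir_new <- if (stats::runif(1) < P_E) "front" else "rear"
    if (detached_trailing && dir_new == "front") {
      add(t, params$d, "walk-forward")
    } else if (!detached_trailing && dir_new == "rear") {
      add(t, -params$d, "walk-backward")
    }
    dir_prev <- dir_new
    n_cyc <- n_cyc + 1
  }
  idx <- seq_len(n_ev)
  new_trajectory(times[idx], cumsum(dpos[idx]), event[idx],
                 duration = t, params, cond, config)
}

sim_slip_only <- function(params, force, config) {
  x <- (force * params$delta) / params$kBT
  hf <- params$v_II0 * exp(x)
  hb <- params$v_II0 * exp(-x)
  if (hf + hb <= 0) stop("v_II0 = 0: no hopping to simulate")
  T_ <- if (!is.null(config$duration)) config$duration else
    config$n_cycles / (hf + hb)
  n <- stats::rpois(1, (hf + hb) * T_)
  times <- sort(stats::runif(n, 0, T_))
  fwd <- stats::runif(n) < hf / (hf + hb)
  cond <- motor_condition(force, atp = 0)
  new_trajectory(times, cumsum(ifelse(fwd, params$d, -params$d)),
                 ifelse(fwd, "slip-hop-forward", "slip-hop-backward"),
                 T_, params, cond, config)
}

#' Summary statistics of a simulated trajectory
#'
#' Mean velocity with a block-averaged standard error, step and hop counts,
#' slip-episode statistics and the empirical forward/backward stepping
#' ratio (walking steps and slip hops pooled).
#'
#' @param traj A `kin_trajectory` from [simulate_motor()].
#' @param blocks Number of equal time blocks for the velocity standard
#'   error; defaults to the value in the trajectory's [sim_config()].
#' @return An object of class `trajectory_summary`: a list with
#'   `mean_velocity` (nm/s), `se_velocity`, `n_forward`, `n_backward`
#'   (walking steps), `n_hop_forward`, `n_hop_backward`,
#'   `n_slip_episodes`, `mean_slip_duration` (s; `NA` if no complete
#'   episode), `net_slip_displacement` (nm), `stepping_ratio` and
#'   `duration` (s).
#' @export
summarize_trajectory <- function(traj, blocks = NULL) {
  stopifnot(inherits(traj, "kin_trajectory"))
  if (nrow(traj) == 0L) stop("empty trajectory: nothing to summarize")
  T_ <- attr(traj, "duration")
  if (is.null(blocks)) {
    cfg <- attr(traj, "config")
    blocks <- if (!is.null(cfg)) cfg$blocks else 20L
  }
  final <- traj$position_nm[nrow(traj)]
  v <- final / T_
  bounds <- seq(0, T_, length.out = blocks + 1)
  pos_at <- c(0, traj$position_nm)[findInterval(bounds, traj$time_s) + 1]
  bv <- diff(pos_at) / diff(bounds)
  se <- stats::sd(bv) / sqrt(blocks)
  cnt <- function(e) sum(traj$event == e)
  entries <- traj$time_s[traj$event == "periodII-entry"]
  exits <- traj$time_s[traj$event == "periodII-exit"]
  ndur <- min(length(entries), length(exits))
  hops_f <- cnt("slip-hop-forward"); hops_b <- cnt("slip-hop-backward")
  fwd <- cnt("walk-forward") + hops_f
  bwd <- cnt("walk-backward") + hops_b
  d <- attr(traj, "params")$d
  out <- list(
    mean_velocity = v,
    se_velocity = se,
    n_forward = cnt("walk-forward"),
    n_backward = cnt("walk-backward"),
    n_hop_forward = hops_f,
    n_hop_backward = hops_b,
    n_slip_episodes = length(entries),
    mean_slip_duration = if (ndur > 0)
      mean(exits[seq_len(ndur)] - entries[seq_len(ndur)]) else NA_real_,
    net_slip_displacement = (hops_f - hops_b) * d,
    stepping_ratio = if (bwd > 0) fwd / bwd else Inf,
    duration = T_,
    blocks = blocks
  )
  class(out) <- "trajectory_summary"
  out
}

#' @export
print.trajectory_summary <- function(x, ...) {
  cat(sprintf("Trajectory summary over %.4g s\n", x$duration))
  cat(sprintf("  mean velocity: %.3f +/- %.3f nm/s (SE, %d blocks)\n",
              x$mean_velocity, x$se_velocity, x$blocks))
  cat(sprintf("  walking steps: %d forward, %d backward\n",
              x$n_forward, x$n_backward))
  cat(sprintf("  slip: %d episodes (mean %.4g s), %d/%d hops f/b, net %.0f nm\n",
              x$n_slip_episodes, x$mean_slip_duration, x$n_hop_forward,
              x$n_hop_backward, x$net_slip_displacement))
  cat(sprintf("  empirical stepping ratio: %.4g\n", x$stepping_ratio))
  invisible(x)
}

#' Mean-squared-displacement growth rate of a trajectory
#'
#' Splits the trajectory into equal time segments and returns the variance
#' of per-segment displacements divided by the segment duration: for a
#' diffusive process this estimates the slope of the mean-squared
#' displacement about the drift, `2 D_eff`.
#'
#' @param traj A `kin_trajectory`.
#' @param n_segments Number of segments. Default 200.
#' @return Slope estimate (nm^2/s).
#' @export
msd_slope <- function(traj, n_segments = 200) {
  stopifnot(inherits(traj, "kin_trajectory"), n_segments >= 2)
  T_ <- attr(traj, "duration")
  bounds <- seq(0, T_, length.out = n_segments + 1)
  pos_at <- c(0, traj$position_nm)[findInterval(bounds, traj$time_s) + 1]
  disp <- diff(pos_at)
  stats::var(disp) / (T_ / n_segments)
}

#' Write a trajectory as delimited text
#'
#' Tab-separated columns `time_s`, `position_nm`, `event`, preceded by
#' `# key: value` metadata lines recording the package version, the seed
#' and mode, the operating condition and the full parameter set.
#'
#' @param traj A `kin_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "kin_trajectory"))
  p <- attr(traj, "params"); cond <- attr(traj, "cond")
  cfg <- attr(traj, "config")
  pfields <- setdiff(names(unclass(p)), NULL)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# kinslip_version: %s", as.character(utils::packageVersion("kinslip"))),
    sprintf("# mode: %s", cfg$mode),
    sprintf("# seed: %d", cfg$seed),
    sprintf("# duration_s: %.12g", attr(traj, "duration")),
    sprintf("# force_pN: %g", cond$force),
    sprintf("# atp_uM: %s", if (is.infinite(cond$atp)) "saturating" else
      cond$atp),
    sprintf("# adp_uM: %g", cond$adp),
    sprintf("# params: %s", paste(sprintf("%s=%g", pfields,
                                          unlist(unclass(p)[pfields])),
                                  collapse = " "))
  ), con)
  utils::write.table(as.data.frame(traj), con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a trajectory summary as JSON
#'
#' @param summary A [summarize_trajectory()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_summary <- function(summary, path) {
  stopifnot(inherits(summary, "trajectory_summary"))
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
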