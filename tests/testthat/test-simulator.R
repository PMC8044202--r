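test_that("sim_config validates its inputs", {
  expect_error(sim_config(duration = 1), "seed")
  expect_error(sim_config(seed = 1), "duration")
  expect_error(sim_config(seed = 1, duration = -1), "positive")
  expect_error(sim_config(seed = 1, n_cycles = 0), "positive")
  expect_error(sim_config(seed = 1, duration = 1, mode = "nope"))
})

test_that("identical seeds give bit-identical trajectories", {
  cfg <- sim_config(seed = 7, n_cycles = 500)
  tr1 <- simulate_motor(kip3, cond_sat0, cfg)
  tr2 <- simulate_motor(kip3, cond_sat0, cfg)
  expect_identical(tr1, tr2)
  tr3 <- simulate_motor(kip3, cond_sat0, sim_config(seed = 8, n_cycles = 500))
  expect_false(identical(tr1$time_s, tr3$time_s))
})

test_that("simulation leaves the caller's RNG state untouched", {
  set.seed(12345)
  before <- .Random.seed
  invisible(simulate_motor(kip3, cond_sat0, sim_config(seed = 3,
                                                       n_cycles = 200)))
  expect_identical(.Random.seed, before)
})

test_that("trajectory invariants hold in every mode", {
  for (mode in c("flux", "mechanistic", "slip_only")) {
    cfg <- sim_config(seed = 11, duration = 20, mode = mode)
    tr <- if (mode == "slip_only") simulate_slip_only(kip3, 0.5, cfg) else
      simulate_motor(kip3, motor_condition(0.5, "saturating"), cfg)
    expect_s3_class(tr, "kin_trajectory")
    expect_false(is.unsorted(tr$time_s))
    expect_true(all(tr$time_s >= 0 & tr$time_s <= attr(tr, "duration")))
    steps <- diff(c(0, tr$position_nm))
    expect_true(all(steps %in% c(-kip3$d, 0, kip3$d)))
    # zero-displacement rows are exactly the episode bookkeeping events
    expect_equal(steps == 0,
                 tr$event %in% c("periodII-entry", "periodII-exit"))
    if (mode == "slip_only") {
      # no walking machinery at all: everything is a hop
      expect_true(all(grepl("^slip-hop", tr$event)))
    } else {
      # slip hops occur only inside open episodes
      depth <- cumsum((tr$event == "periodII-entry") -
                        (tr$event == "periodII-exit"))
      hops <- grepl("^slip-hop", tr$event)
      expect_true(all(depth[hops] == 1))
      expect_true(all(depth %in% c(0, 1)))
    }
  }
})

test_that("record_states = FALSE drops the bookkeeping rows only", {
  cfg_all <- sim_config(seed = 5, duration = 50)
  cfg_min <- sim_config(seed = 5, duration = 50, record_states = FALSE)
  tr_all <- simulate_motor(kip3, cond_sat0, cfg_all)
  tr_min <- simulate_motor(kip3, cond_sat0, cfg_min)
  expect_false(any(tr_min$event %in% c("periodII-entry", "periodII-exit")))
  keep <- !(tr_all$event %in% c("periodII-entry", "periodII-exit"))
  expect_equal(tr_min$time_s, tr_all$time_s[keep])
  expect_equal(tr_min$position_nm, tr_all$position_nm[keep])
})

test_that("summarize_trajectory arithmetic on a hand-built trajectory", {
  tr <- kinslip:::new_trajectory(
    time_s = 1, position_nm = 8, event = "walk-forward",
    duration = 2, params = kip3, cond = cond_sat0,
    config = sim_config(seed = 1, duration = 2))
  s <- summarize_trajectory(tr, blocks = 2)
  expect_equal(s$mean_velocity, 4) # 8 nm over 2 s
  expect_equal(s$n_forward, 1)
  expect_equal(s$n_backward, 0)
  expect_equal(s$n_slip_episodes, 0)
  expect_true(is.na(s$mean_slip_duration))
  expect_equal(s$net_slip_displacement, 0)
  expect_identical(s$stepping_ratio, Inf)
  empty <- kinslip:::new_trajectory(
    time_s = numeric(0), position_nm = numeric(0), event = character(0),
    duration = 1, params = kip3, cond = cond_sat0,
    config = sim_config(seed = 1, duration = 1))
  expect_error(summarize_trajectory(empty), "empty")
})

test_that("slip-only mode matches the biased-hopping closed forms", {
  cfg <- sim_config(seed = 21, n_cycles = 1e5)
  tr <- simulate_slip_only(kip3, 1, cfg)
  s <- summarize_trajectory(tr)
  v_true <- slip_velocity(kip3, 1)
  expect_lt(abs(s$mean_velocity - v_true), 3 * s$se_velocity)
  r_true <- stepping_ratio_adp_only(kip3, 1)
  se_r <- ratio_se(s$stepping_ratio, s$n_hop_forward, s$n_hop_backward)
  expect_lt(abs(s$stepping_ratio - r_true), 3 * se_r)

  tr0 <- simulate_slip_only(kip3, 0, sim_config(seed = 22, n_cycles = 1e5))
  s0 <- summarize_trajectory(tr0)
  expect_lt(abs(s0$mean_velocity), 3 * s0$se_velocity)
  se_r0 <- ratio_se(s0$stepping_ratio, s0$n_hop_forward, s0$n_hop_backward)
  expect_lt(abs(s0$stepping_ratio - 1), 3 * se_r0)
  expect_error(simulate_slip_only(
    motor_parameters(k_D = 400, k_plus = 22, k_minus = 45, E_NL = 1.1,
                     d_plus = 1.7, v_II0 = 0),
    0, cfg), "no hopping")
})

test_that("flux mode matches velocity, ratio and episode-length oracles", {
  cfg <- sim_config(seed = 31, n_cycles = 2e4)
  tr <- simulate_motor(kip3, cond_sat0, cfg)
  s <- summarize_trajectory(tr)
  v_true <- total_velocity(kip3, cond_sat0)$v_total
  expect_lt(abs(s$mean_velocity - v_true), 3 * s$se_velocity)
  r_true <- stepping_ratio_with_slip(kip3, 0)
  nf <- s$n_forward + s$n_hop_forward
  nb <- s$n_backward + s$n_hop_backward
  expect_lt(abs(s$stepping_ratio - r_true),
            3 * ratio_se(s$stepping_ratio, nf, nb))
  tau <- slipping_time(kip3, "saturating")
  expect_gt(s$n_slip_episodes, 10)
  expect_lt(abs(s$mean_slip_duration - tau),
            3 * tau / sqrt(s$n_slip_episodes))

  cond <- motor_condition(-0.5, 10)
  tr2 <- simulate_motor(kip3, cond, sim_config(seed = 32, n_cycles = 2e4))
  s2 <- summarize_trajectory(tr2)
  v2 <- total_velocity(kip3, cond)$v_total
  expect_lt(abs(s2$mean_velocity - v2), 3 * s2$se_velocity)
})

test_that("mechanistic mode agrees with the analytic velocity to ~10%", {
  cfg <- sim_config(seed = 41, n_cycles = 3e4, mode = "mechanistic")
  tr <- simulate_motor(kip3, cond_sat0, cfg)
  s <- summarize_trajectory(tr)
  v_true <- total_velocity(kip3, cond_sat0)$v_total
  expect_lt(abs(s$mean_velocity / v_true - 1), 0.1)
})

test_that("slip-only displacement variance grows at the hop-process rate", {
  cfg <- sim_config(seed = 51, duration = 100)
  tr <- simulate_slip_only(kip3, 0, cfg)
  slope <- msd_slope(tr, n_segments = 1000)
  hop_rate_total <- 2 * kip3$v_II0 # forward + backward at no load
  expect_lt(abs(slope / (hop_rate_total * kip3$d^2) - 1), 0.2)
})

test_that("trajectories and summaries serialize with their metadata", {
  cfg <- sim_config(seed = 61, n_cycles = 300)
  tr <- simulate_motor(kip3, cond_sat0, cfg)
  f <- tempfile(fileext = ".tsv")
  write_trajectory(tr, f)
  lines <- readLines(f)
  expect_true(any(grepl("^# seed: 61$", lines)))
  expect_true(any(grepl("^# mode: flux$", lines)))
  back <- utils::read.table(f, header = TRUE, sep = "\t", comment.char = "#",
                            stringsAsFactors = FALSE)
  expect_equal(back$time_s, tr$time_s)
  expect_equal(back$position_nm, tr$position_nm)
  expect_equal(back$event, tr$event)
  unlink(f)
  s <- summarize_trajectory(tr)
  fs <- tempfile(fileext = ".json")
  write_trajectory_summary(s, fs)
  js <- jsonlite::fromJSON(fs)
  expect_equal(js$mean_velocity, s$mean_velocity)
  expect_equal(js$n_forward, s$n_forward)
  unlink(fs)
})
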