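#' Force-velocity dataset
#'
#' Container for single-molecule style force-velocity observations used by
#' the estimation recipe: one row per operating point, with the signed load,
#' the measured velocity and optionally its standard deviation. Metadata
#' records the ATP condition and whether the velocities include slip.
#'
#' @param force Signed loads (pN).
#' @param velocity Velocities (nm/s).
#' @param sd Optional per-row velocity standard deviations (nm/s).
#' @param atp ATP condition of the measurement: `"saturating"` or uM.
#' @param slip_included Logical: do the velocities include slip episodes?
#' @param preset Optional name of the generating preset (for synthetic data).
#' @return A `data.frame` of class `fv_dataset` with columns `force_pN`,
#'   `velocity_nm_per_s` and optionally `sd_nm_per_s`, plus metadata
#'   attributes `atp`, `slip_included` and `preset`.
#' @export
fv_dataset <- function(force, velocity, sd = NULL, atp = "saturating",
                       slip_included = FALSE, preset = NULL) {
  stopifnot(is.numeric(force), is.numeric(velocity),
            length(force) == length(velocity), length(force) >= 1L)
  if (!all(is.finite(force)) || !all(is.finite(velocity))) {
    stop("fv_dataset requires finite force and velocity values")
  }
  df <- data.frame(force_pN = as.numeric(force),
                   velocity_nm_per_s = as.numeric(velocity))
  if (!is.null(sd)) {
    stopifnot(is.numeric(sd), length(sd) == length(force), all(is.finite(sd)),
              all(sd >= 0))
    df$sd_nm_per_s <- as.numeric(sd)
  }
  df <- df[order(df$force_pN), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "atp") <- if (identical(atp, "saturating")) "saturating" else
    as.numeric(atp)
  attr(df, "slip_included") <- isTRUE(slip_included)
  attr(df, "preset") <- preset
  class(df) <- c("fv_dataset", "data.frame")
  df
}

#' Read a force-velocity dataset from delimited text
#'
#' Expects a header row with columns `force_pN`, `velocity_nm_per_s` and
#' optionally `sd_nm_per_s`; comma or tab delimited (sniffed from the header
#' line). Lines starting with `#` are metadata comments of the form
#' `# key: value`; keys `atp`, `slip_included` and `preset` are recognized.
#'
#' @param path Input file path.
#' @return An [fv_dataset()].
#' @export
read_fv_dataset <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  header <- lines[!grepl("^#", lines)][1]
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(c("force_pN", "velocity_nm_per_s") %in% names(df))) {
    stop("file must have header columns force_pN and velocity_nm_per_s")
  }
  atp <- meta$atp %||% "saturating"
  if (!identical(atp, "saturating")) atp <- as.numeric(atp)
  fv_dataset(df$force_pN, df$velocity_nm_per_s,
             sd = if ("sd_nm_per_s" %in% names(df)) df$sd_nm_per_s,
             atp = atp,
             slip_included = isTRUE(as.logical(meta$slip_included %||% "FALSE")),
             preset = meta$preset)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a force-velocity dataset as delimited text
#'
#' Metadata (`atp`, `slip_included`, `preset`, package version) is embedded
#' as `# key: value` comment lines before the header so that a round trip
#' through [read_fv_dataset()] is lossless.
#'
#' @param data An [fv_dataset()].
#' @param path Output path. Extension `.tsv` selects tab, anything else comma.
#' @return `path`, invisibly.
#' @export
write_fv_dataset <- function(data, path) {
  stopifnot(inherits(data, "fv_dataset"))
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# kinslip_version: %s", as.character(utils::packageVersion("kinslip"))),
    sprintf("# atp: %s", as.character(attr(data, "atp"))),
    sprintf("# slip_included: %s", attr(data, "slip_included")),
    if (!is.null(attr(data, "preset")))
      sprintf("# preset: %s", attr(data, "preset"))
  ), con)
  utils::write.table(as.data.frame(data), con, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Estimate the catalytic rates from the velocity plateaus
#'
#' Under large forward load the forward-binding probability approaches one
#' and the no-slip velocity saturates at `k^(+) d`; under large backward
#' load it saturates at `-k^(-) d`. The rates are therefore estimated as the
#' mean plateau velocity over the extreme fraction of the sampled load
#' range, divided by the lattice spacing.
#'
#' The default plateau window is the extreme 5% of the load range on each
#' side: the approach to the asymptote is slow enough (the residual bias at
#' `|F| = 8--10` pN is several percent of `k^(-)`) that a wider window
#' dilutes the plateau with pre-asymptotic points.
#'
#' @param data An [fv_dataset()] of no-slip velocities spanning large loads
#'   of both signs.
#' @param d Lattice spacing (nm). Default 8.
#' @param plateau_frac Fraction of the load range, at each extreme, treated
#'   as plateau. Default 0.05.
#' @return A list with `k_plus` and `k_minus` (s^-1).
#' @export
estimate_rate_constants <- function(data, d = 8, plateau_frac = 0.05) {
  stopifnot(inherits(data, "fv_dataset"), plateau_frac > 0, plateau_frac < 0.5)
  f <- data$force_pN
  v <- data$velocity_nm_per_s
  if (max(f) <= 0) stop("dataset has no forward (positive) loads: cannot ",
                        "estimate k_plus")
  if (min(f) >= 0) stop("dataset has no backward (negative) loads: cannot ",
                        "estimate k_minus")
  rng <- diff(range(f))
  top <- f >= max(f) - plateau_frac * rng
  bot <- f <= min(f) + plateau_frac * rng
  k_plus <- mean(v[top]) / d
  k_minus <- abs(mean(v[bot])) / d
  if (k_plus <= 0) stop("forward plateau velocity is not positive")
  if (k_minus <= 0) stop("backward plateau velocity is zero")
  list(k_plus = k_plus, k_minus = k_minus)
}

#' Estimate the neck-linker docking energy from the unloaded velocity
#'
#' Inverts the reduced unloaded-velocity form (valid for `k_D` much larger
#' than the catalytic rates, with the lattice-spacing factor restored)
#' \deqn{v_0(0) = \frac{e^{E_{NL}} k^{(+)} - k^{(-)}}{e^{E_{NL}} + 1}\, d}
#' for `E_NL`, giving
#' `exp(E_NL) = (v0/d + k^(-)) / (k^(+) - v0/d)`.
#'
#' @param v0_unloaded Unloaded velocity (nm/s); must lie strictly between
#'   `-k_minus d` and `k_plus d`.
#' @param k_plus,k_minus Catalytic rates (s^-1).
#' @param d Lattice spacing (nm). Default 8.
#' @return `E_NL` in kBT units (`Inf` if `v0_unloaded` is at the upper
#'   boundary).
#' @export
estimate_E_NL <- function(v0_unloaded, k_plus, k_minus, d = 8) {
  stopifnot(k_plus > 0, k_minus > 0, d > 0)
  u <- v0_unloaded / d
  if (u <= -k_minus || u >= k_plus) {
    stop("unloaded velocity must lie strictly inside (-k_minus*d, k_plus*d); ",
         "no finite E_NL reproduces it")
  }
  log((u + k_minus) / (k_plus - u))
}

#' Estimate the forward distance parameter from the stall force
#'
#' Inverts the closed-form stall relation
#' `exp(E_NL) exp(-beta F_S d_plus) k^(+) = k^(-)`:
#' \deqn{d^{(+)} = \frac{k_B T\,[E_{NL} + \ln(k^{(+)}/k^{(-)})]}{F_S}.}
#'
#' @param F_S_observed Observed stall force magnitude (pN, > 0).
#' @param E_NL Docking energy (kBT units).
#' @param k_plus,k_minus Catalytic rates (s^-1).
#' @param kBT Thermal energy (pN nm). Default 4.1.
#' @return `d_plus` in nm.
#' @export
estimate_d_plus <- function(F_S_observed, E_NL, k_plus, k_minus, kBT = 4.1) {
  stopifnot(F_S_observed > 0, k_plus > 0, k_minus > 0, kBT > 0)
  num <- kBT * (E_NL + log(k_plus / k_minus))
  if (num <= 0) {
    stop("E_NL + log(k_plus/k_minus) is not positive: the model cannot ",
         "stall at a positive backward load with these values")
  }
  num / F_S_observed
}

#' Stall force from data: zero crossing of the force-velocity curve
#'
#' Linear interpolation between load points bracketing the sign change of
#' the velocity. If noise produces several crossings, the median of the
#' interpolated crossing loads is used.
#'
#' @param data An [fv_dataset()].
#' @return Stall force magnitude (pN).
#' @export
estimate_stall_force <- function(data) {
  stopifnot(inherits(data, "fv_dataset"))
  f <- data$force_pN
  v <- data$velocity_nm_per_s
  s <- sign(v)
  idx <- which(s[-length(s)] <= 0 & s[-1] > 0)
  idx <- union(idx, which(s[-length(s)] < 0 & s[-1] >= 0))
  if (length(idx) == 0) {
    stop("velocity does not change sign over the sampled loads: no stall ",
         "force in range")
  }
  crossings <- vapply(idx, function(i) {
    f[i] - v[i] * (f[i + 1] - f[i]) / (v[i + 1] - v[i])
  }, numeric(1))
  abs(stats::median(crossings))
}

#' Calibrate the ATP-binding rate from the half-velocity concentration
#'
#' Solves for the second-order ATP binding rate `k_bT` such that the
#' unloaded velocity at the given ATP concentration is the prescribed
#' fraction (default one half) of the saturating-ATP unloaded velocity.
#' Scalar root solve on `log10(k_bT)` over `[1e-3, 1e3]` uM^-1 s^-1 to a
#' relative tolerance of 1e-3.
#'
#' @param params A [motor_parameters()] object; its `k_bT` field is ignored.
#' @param half_velocity_atp ATP concentration (uM) at which the unloaded
#'   velocity equals `ratio` times the saturating value.
#' @param ratio Velocity fraction at `half_velocity_atp`. Default 0.5.
#' @return `k_bT` in uM^-1 s^-1.
#' @examples
#' calibrate_k_bT(motor_preset("kip3_table1"), 10) # close to 1
#' @export
calibrate_k_bT <- function(params, half_velocity_atp, ratio = 0.5) {
  validate_motor_parameters(params)
  stopifnot(half_velocity_atp > 0, ratio > 0, ratio < 1)
  v_sat <- velocity_no_slip(params, motor_condition(0, "saturating"))
  obj <- function(log10_kbT) {
    p2 <- params
    p2$k_bT <- 10^log10_kbT
    velocity_no_slip(p2, motor_condition(0, half_velocity_atp)) /
      v_sat - ratio
  }
  if (obj(-3) * obj(3) > 0) {
    stop("no k_bT in [1e-3, 1e3] uM^-1 s^-1 gives the requested velocity ",
         "fraction at [ATP] = ", half_velocity_atp, " uM")
  }
  root <- stats::uniroot(obj, c(-3, 3), tol = 1e-6)$root
  10^root
}

#' Estimate the slip hop rate from slip-velocity data
#'
#' Single-parameter weighted least squares of the slip-velocity relation
#' `v = v_II0 [exp(beta F delta) - exp(-beta F delta)] d`, which is linear
#' in `v_II0` and so has the closed-form solution
#' `v_II0 = sum(w v s) / sum(w s^2)` with `s(F)` the bracketed shape factor
#' times `d` and weights `w = 1/sd^2` when uncertainties are present.
#'
#' @param data An [fv_dataset()] of slip-only velocities (saturating ADP,
#'   no ATP).
#' @param d Lattice spacing (nm); `delta = d/2`. Default 8.
#' @param kBT Thermal energy (pN nm). Default 4.1.
#' @return `v_II0` in s^-1.
#' @export
estimate_v_II0 <- function(data, d = 8, kBT = 4.1) {
  stopifnot(inherits(data, "fv_dataset"))
  x <- data$force_pN * (d / 2) / kBT
  s <- (exp(x) - exp(-x)) * d
  w <- if ("sd_nm_per_s" %in% names(data) && all(data$sd_nm_per_s > 0)) {
    1 / data$sd_nm_per_s^2
  } else {
    rep(1, nrow(data))
  }
  if (sum(w * s^2) == 0) stop("slip-velocity data carry no load dependence")
  sum(w * data$velocity_nm_per_s * s) / sum(w * s^2)
}

#' Full parameter-estimation recipe from a force-velocity curve
#'
#' Runs the four-step recipe on no-slip force-velocity data:
#' 1. `k_plus`, `k_minus` from the forward/backward velocity plateaus
#'    ([estimate_rate_constants()]);
#' 2. `E_NL` from the unloaded velocity ([estimate_E_NL()]), taking the
#'    measured velocity at the load nearest zero;
#' 3. the stall force from the zero crossing ([estimate_stall_force()]);
#' 4. `d_plus` from the stall relation ([estimate_d_plus()]).
#' Optionally the four estimates seed a least-squares refinement of the full
#' no-slip velocity expression over the whole dataset; the recipe estimates
#' remain the canonical output and the refined values are reported
#' alongside.
#'
#' @param data An [fv_dataset()] of no-slip velocities at saturating ATP.
#' @param k_D ADP release rate, fixed (not estimable from force-velocity
#'   data). Default 400 s^-1.
#' @param d Lattice spacing (nm). Default 8.
#' @param kBT Thermal energy (pN nm). Default 4.1.
#' @param plateau_frac Plateau window for [estimate_rate_constants()].
#' @param refine If `TRUE`, add a least-squares refinement (Nelder-Mead on
#'   log-scaled positive parameters) seeded by the recipe estimates.
#' @return An object of class `estimated_parameters`: a list with the four
#'   estimates, the observed stall force, per-parameter provenance strings,
#'   fit residuals of the recipe estimates, and (if requested) `refined`,
#'   the refined parameter list with its residuals.
#' @export
estimate_motor_parameters <- function(data, k_D = 400, d = 8, kBT = 4.1,
                                      plateau_frac = 0.05, refine = FALSE) {
  stopifnot(inherits(data, "fv_dataset"))
  rates <- estimate_rate_constants(data, d = d, plateau_frac = plateau_frac)
  i0 <- which.min(abs(data$force_pN))
  v0_unloaded <- data$velocity_nm_per_s[i0]
  E_NL <- estimate_E_NL(v0_unloaded, rates$k_plus, rates$k_minus, d = d)
  F_S <- estimate_stall_force(data)
  d_plus <- estimate_d_plus(F_S, E_NL, rates$k_plus, rates$k_minus, kBT = kBT)
  if (min(data$force_pN) > -2 * F_S || max(data$force_pN) < 2 * F_S) {
    warning("load range does not extend to twice the observed stall force ",
            "on both sides; plateau estimates may be biased")
  }
  build <- function(k_plus, k_minus, E_NL, d_plus) {
    motor_parameters(k_D = k_D, k_plus = k_plus, k_minus = k_minus,
                     E_NL = E_NL, d_plus = d_plus, d = d, kBT = kBT)
  }
  resid_of <- function(p) {
    data$velocity_nm_per_s -
      velocity_no_slip(p, motor_condition(data$force_pN, "saturating"))
  }
  est <- list(
    k_plus = rates$k_plus, k_minus = rates$k_minus, E_NL = E_NL,
    d_plus = d_plus, F_S_observed = F_S, k_D = k_D, d = d, kBT = kBT,
    provenance = c(
      k_plus = "mean forward-plateau velocity / d",
      k_minus = "|mean backward-plateau velocity| / d",
      E_NL = "inverted unloaded-velocity closed form",
      d_plus = "stall relation at the interpolated zero crossing"
    ),
    residuals = resid_of(build(rates$k_plus, rates$k_minus, E_NL, d_plus))
  )
  if (refine) {
    obj <- function(theta) {
      p <- build(exp(theta[1]), exp(theta[2]), exp(theta[3]), exp(theta[4]))
      sum(resid_of(p)^2)
    }
    start <- log(c(rates$k_plus, rates$k_minus, max(E_NL, 1e-3), d_plus))
    opt <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-10))
    ref <- as.list(exp(opt$par))
    names(ref) <- c("k_plus", "k_minus", "E_NL", "d_plus")
    ref$rss <- opt$value
    ref$residuals <- resid_of(build(ref$k_plus, ref$k_minus, ref$E_NL,
                                    ref$d_plus))
    est$refined <- ref
  }
  class(est) <- "estimated_parameters"
  est
}

#' @export
print.estimated_parameters <- function(x, ...) {
  cat("Estimated motor parameters (recipe estimates)\n")
  cat(sprintf("  k+ = %.3f /s, k- = %.3f /s, E_NL = %.4f kBT, d+ = %.4f nm\n",
              x$k_plus, x$k_minus, x$E_NL, x$d_plus))
  cat(sprintf("  observed stall force: %.4f pN; fixed k_D = %g /s\n",
              x$F_S_observed, x$k_D))
  cat(sprintf("  residual RMS: %.3f nm/s\n", sqrt(mean(x$residuals^2))))
  if (!is.null(x$refined)) {
    cat(sprintf("  refined: k+ = %.3f, k- = %.3f, E_NL = %.4f, d+ = %.4f (RSS %.4g)\n",
                x$refined$k_plus, x$refined$k_minus, x$refined$E_NL,
                x$refined$d_plus, x$refined$rss))
  }
  invisible(x)
}

#' Write an estimation report as JSON
#'
#' Emits the recipe estimates, provenance notes, fit residual summary and
#' (if present) the refined values.
#'
#' @param est An [estimate_motor_parameters()] result.
#' @param path Output path for the JSON report.
#' @return `path`, invisibly.
#' @export
write_estimation_report <- function(est, path) {
  stopifnot(inherits(est, "estimated_parameters"))
  report <- list(
    kinslip_version = as.character(utils::packageVersion("kinslip")),
    estimates = est[c("k_plus", "k_minus", "E_NL", "d_plus")],
    fixed = list(k_D = est$k_D, d = est$d, kBT = est$kBT),
    F_S_observed = est$F_S_observed,
    provenance = as.list(est$provenance),
    residual_rms = sqrt(mean(est$residuals^2)),
    residuals = est$residuals
  )
  if (!is.null(est$refined)) {
    report$refined <- est$refined[c("k_plus", "k_minus", "E_NL", "d_plus",
                                    "rss")]
  }
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
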