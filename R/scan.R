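.scan_quantities <- c("v0", "v_total", "r0", "r", "r_II", "v_II", "tau_S")

#' Scan specification
#'
#' Describes a family of curve scans: a load grid, a list of ATP conditions
#' and the quantities to evaluate at each point. Quantities:
#' `v0` (no-slip velocity), `v_total` (velocity including slip), `r0`
#' (stepping ratio without slip, saturating ATP only), `r` (stepping ratio
#' with slip, saturating ATP only), `r_II` (slip-only stepping ratio),
#' `v_II` (slip velocity), `tau_S` (mean slipping time, s).
#'
#' @param force_start,force_stop,force_step Load grid (pN); `force_step > 0`.
#' @param atp List/vector of ATP conditions: numbers (uM) and/or
#'   `"saturating"`.
#' @param quantities Character vector from the allowed set above.
#' @param params A [motor_parameters()] object or a preset name.
#' @param adp ADP concentration (uM). Default 0.
#' @return An object of class `scan_spec`.
#' @export
scan_spec <- function(force_start, force_stop, force_step,
                      atp = "saturating", quantities = c("v0", "v_total"),
                      params = "kip3_table1", adp = 0) {
  stopifnot(force_step > 0, force_stop >= force_start)
  bad <- setdiff(quantities, .scan_quantities)
  if (length(bad) > 0) {
    stop("unknown quantity name(s): ", paste(bad, collapse = ", "),
         "; valid names: ", paste(.scan_quantities, collapse = ", "))
  }
  if (is.character(params)) params <- motor_preset(params)
  validate_motor_parameters(params)
  grid <- seq(force_start, force_stop, by = force_step)
  if (length(grid) == 0) stop("empty load grid")
  structure(list(force = grid, atp = as.list(atp),
                 quantities = quantities, params = params, adp = adp),
            class = "scan_spec")
}

#' Evaluate a scan
#'
#' Deterministically evaluates every requested quantity on the full
#' (load, ATP) grid of a [scan_spec()].
#'
#' @param spec A [scan_spec()].
#' @return A long-format `data.frame` with columns `force_pN`, `atp_uM`
#'   (`"saturating"` or the concentration as character), `quantity`, and
#'   `value`, one row per (load, ATP, quantity).
#' @examples
#' run_scan(scan_spec(-1, 1, 1, atp = "saturating", quantities = "v0"))
#' @export
run_scan <- function(spec) {
  stopifnot(inherits(spec, "scan_spec"))
  p <- spec$params
  out <- list()
  for (atp in spec$atp) {
    sat <- identical(atp, "saturating") ||
      (is.numeric(atp) && is.infinite(atp))
    cond <- motor_condition(spec$force, if (sat) "saturating" else
      as.numeric(atp), spec$adp)
    atp_lab <- if (sat) "saturating" else as.character(atp)
    for (q in spec$quantities) {
      if (q %in% c("r0", "r") && !sat) {
        stop("stepping ratios r0 and r are defined at saturating ATP only")
      }
      val <- switch(q,
        v0 = velocity_no_slip(p, cond),
        v_total = total_velocity(p, cond)$v_total,
        r0 = stepping_ratio_no_slip(p, spec$force),
        r = stepping_ratio_with_slip(p, spec$force),
        r_II = stepping_ratio_adp_only(p, spec$force),
        v_II = slip_velocity(p, spec$force),
        tau_S = rep(slipping_time(p, if (sat) "saturating" else
          as.numeric(atp), spec$adp), length(spec$force))
      )
      out[[length(out) + 1L]] <- data.frame(
        force_pN = spec$force, atp_uM = atp_lab, quantity = q,
        value = val, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "params") <- p
  res
}

#' Write a scan table as delimited text
#'
#' Long-format table with a single header line, preceded by `# key: value`
#' comments embedding the package version and the full parameter set used.
#'
#' @param tab A [run_scan()] result.
#' @param path Output path. Extension `.tsv` selects tab, anything else
#'   comma.
#' @return `path`, invisibly.
#' @export
write_scan_table <- function(tab, path) {
  p <- attr(tab, "params")
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kinslip_version: %s",
                     as.character(utils::packageVersion("kinslip"))), con)
  if (!is.null(p)) {
    fields <- names(unclass(p))
    writeLines(sprintf("# params: %s",
                       paste(sprintf("%s=%g", fields,
                                     unlist(unclass(p)[fields])),
                             collapse = " ")), con)
  }
  utils::write.table(as.data.frame(tab), con, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Generate a synthetic force-velocity dataset
#'
#' Evaluates the chosen analytic velocity on a load grid and adds seeded
#' Gaussian noise, producing a synthetic stand-in for single-molecule
#' force-velocity data with known ground-truth parameters (for round-trip
#' tests of the estimation recipe).
#'
#' @param params A [motor_parameters()] object or preset name.
#' @param grid Load grid (pN). Default `seq(-10, 10, by = 0.25)`.
#' @param quantity `"v0"` (no-slip, default), `"v_total"` (with slip) or
#'   `"v_II"` (slip-only).
#' @param atp ATP condition. Default `"saturating"`.
#' @param noise_sd Gaussian velocity noise SD (nm/s, >= 0). Default 0.
#' @param seed RNG seed; required when `noise_sd > 0`.
#' @return An [fv_dataset()] whose metadata records the generating preset.
#' @examples
#' fv <- generate_fv_fixture("kip3_table1", noise_sd = 2, seed = 7)
#' head(fv)
#' @export
generate_fv_fixture <- function(params = "kip3_table1",
                                grid = seq(-10, 10, by = 0.25),
                                quantity = c("v0", "v_total", "v_II"),
                                atp = "saturating", noise_sd = 0,
                                seed = NULL) {
  preset_name <- if (is.character(params)) params else "custom"
  if (is.character(params)) params <- motor_preset(params)
  validate_motor_parameters(params)
  quantity <- match.arg(quantity)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (noise_sd > 0 && is.null(seed)) {
    stop("a seed is required when noise_sd > 0")
  }
  v <- switch(quantity,
    v0 = velocity_no_slip(params, motor_condition(grid, atp)),
    v_total = total_velocity(params, motor_condition(grid, atp))$v_total,
    v_II = slip_velocity(params, grid)
  )
  if (noise_sd > 0) {
    v <- with_sim_seed(seed, function() v + stats::rnorm(length(v), 0,
                                                         noise_sd))
  }
  fv_dataset(grid, v,
             sd = if (noise_sd > 0) rep(noise_sd, length(grid)),
             atp = if (quantity == "v_II") 0 else atp,
             slip_included = quantity == "v_total",
             preset = preset_name)
}
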