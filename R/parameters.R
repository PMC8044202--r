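#' Motor parameter set
#'
#' Bundle of the kinetic and energetic constants that define one kinesin-8
#' motor in the model: the per-head catalytic rates, the neck-linker docking
#' energy, the geometric distance parameters, the slip hop rate and the
#' nucleotide binding rates.
#'
#' Units follow single-molecule convention throughout the package: rates in
#' s^-1, second-order binding rates in uM^-1 s^-1, distances in nm, energies
#' in multiples of the thermal energy `kBT`, and `kBT` itself in pN nm.
#' The slip characteristic distance `delta` is tied to the lattice spacing
#' (`delta = d/2`) and cannot be set independently.
#'
#' @param k_D ADP release rate from the microtubule-bound head (s^-1).
#' @param k_plus ATP hydrolysis + Pi release rate of the trailing head, i.e.
#'   with the neck linker in the forward orientation (s^-1).
#' @param k_minus Same rate for the leading head (backward neck-linker
#'   orientation) (s^-1).
#' @param E_NL Free-energy change of neck-linker docking plus the ATP-induced
#'   conformational change, in units of kBT (dimensionless).
#' @param d_plus Distance parameter for movement of the detached head from the
#'   intermediate (INT) position to the front binding site (nm).
#' @param d_minus Distance parameter for movement to the rear binding site
#'   (nm). Defaults to `d_plus`; it enters no closed-form expression (the
#'   load-sharing factor already embodies `d_minus ~ d_plus`) and is stored
#'   only for forward compatibility.
#' @param v_II0 Unloaded slip hop rate in the weak-binding state (s^-1).
#' @param k_bT Second-order ATP binding rate (uM^-1 s^-1).
#' @param k_bD Second-order ADP binding rate (uM^-1 s^-1). Default 0.
#' @param d Binding-site spacing along a protofilament (nm). Default 8.
#' @param kBT Thermal energy (pN nm). Default 4.1 (about 24 C).
#'
#' @return An object of class `motor_parameters`: a named list with the above
#'   fields plus `delta = d/2`.
#' @seealso [motor_preset()], [read_motor_parameters()]
#' @examples
#' p <- motor_preset("kip3_table1")
#' p$k_plus / p$k_minus
#' @export
motor_parameters <- function(k_D, k_plus, k_minus, E_NL, d_plus,
                             d_minus = d_plus, v_II0 = 0, k_bT = 1,
                             k_bD = 0, d = 8, kBT = 4.1) {
  p <- list(
    k_D = as.numeric(k_D), k_plus = as.numeric(k_plus),
    k_minus = as.numeric(k_minus), E_NL = as.numeric(E_NL),
    d_plus = as.numeric(d_plus), d_minus = as.numeric(d_minus),
    v_II0 = as.numeric(v_II0), k_bT = as.numeric(k_bT),
    k_bD = as.numeric(k_bD), d = as.numeric(d),
    delta = as.numeric(d) / 2, kBT = as.numeric(kBT)
  )
  class(p) <- "motor_parameters"
  validate_motor_parameters(p)
  p
}

#' Validate a motor parameter set
#'
#' Checks positivity/non-negativity constraints and the `delta = d/2` tie.
#' Called by every constructor; exported so user code reading presets from
#' files can re-validate after modification.
#'
#' @param p A `motor_parameters` object.
#' @return `p`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_motor_parameters <- function(p) {
  stopifnot(inherits(p, "motor_parameters"))
  need <- c("k_D", "k_plus", "k_minus", "E_NL", "d_plus", "d_minus",
            "v_II0", "k_bT", "k_bD", "d", "delta", "kBT")
  miss <- setdiff(need, names(p))
  if (length(miss) > 0) {
    stop("motor_parameters is missing fields: ", paste(miss, collapse = ", "))
  }
  num <- vapply(p[need], function(x) is.numeric(x) && length(x) == 1L &&
                  is.finite(x), logical(1))
  if (!all(num)) {
    stop("motor_parameters fields must be finite numeric scalars: ",
         paste(need[!num], collapse = ", "))
  }
  pos <- c("k_D", "k_plus", "k_minus", "k_bT", "d_plus", "d_minus", "d", "kBT")
  bad <- pos[vapply(p[pos], function(x) x <= 0, logical(1))]
  if (length(bad) > 0) {
    stop("motor_parameters fields must be strictly positive: ",
         paste(bad, collapse = ", "))
  }
  nonneg <- c("v_II0", "k_bD", "E_NL")
  bad <- nonneg[vapply(p[nonneg], function(x) x < 0, logical(1))]
  if (length(bad) > 0) {
    stop("motor_parameters fields must be non-negative: ",
         paste(bad, collapse = ", "))
  }
  if (!isTRUE(all.equal(p$delta, p$d / 2))) {
    stop("delta must equal d/2 (it is the half lattice spacing, not a free parameter)")
  }
  invisible(p)
}

# Immutable built-in presets. "kip3_table1" is the Kip3 calibration used
# throughout: ADP release 400/s, trailing/leading hydrolysis 22/45 per s,
# NL docking energy 1.1 kBT, d+ = 1.7 nm, slip hop rate 45/s, ATP binding
# 1 per uM per s.
.kinslip_presets <- function() {
  list(
    kip3_table1 = motor_parameters(
      k_D = 400, k_plus = 22, k_minus = 45, E_NL = 1.1,
      d_plus = 1.7, d_minus = 1.7, v_II0 = 45, k_bT = 1,
      k_bD = 0, d = 8, kBT = 4.1
    )
  )
}

#' Built-in motor parameter presets
#'
#' `"kip3_table1"` is the calibrated Kip3 (budding yeast kinesin-8) parameter
#' set; it is reserved and immutable. The simplified four-parameter
#' force-velocity fit is a different object, see [simple_velocity_preset()].
#'
#' @param name Preset name. Currently `"kip3_table1"`.
#' @return A `motor_parameters` object.
#' @examples
#' motor_preset("kip3_table1")
#' @export
motor_preset <- function(name = "kip3_table1") {
  presets <- .kinslip_presets()
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  }
  presets[[name]]
}

#' Presets for the simplified force-velocity form
#'
#' The reduced four-parameter description of the no-slip force-velocity curve
#' (see [velocity_no_slip_simple()]) uses the unloaded stepping ratio `r0`,
#' the stall force `F_S`, and the two catalytic rates. Two presets ship:
#' * `"kip3_simple_fit"`: the values fitted directly to the Kip3
#'   single-molecule curve (r0 = 1.5, F_S = 1.1 pN, k+ = 23 s^-1,
#'   k- = 2.3 k+).
#' * `"kip3_from_table1"`: the values implied by the full `kip3_table1`
#'   parameter set through the closed forms r0 = (k+/k-) exp(E_NL) and
#'   F_S = kBT (E_NL + log(k+/k-)) / d_plus.
#' The two are close but not identical; both are kept so either curve can be
#' reproduced exactly.
#'
#' @param name `"kip3_simple_fit"` or `"kip3_from_table1"`.
#' @return A named list with fields `r0`, `F_S`, `k_plus`, `k_minus`, `d`.
#' @export
simple_velocity_preset <- function(name = "kip3_simple_fit") {
  tab1 <- motor_preset("kip3_table1")
  presets <- list(
    kip3_simple_fit = list(r0 = 1.5, F_S = 1.1, k_plus = 23,
                           k_minus = 2.3 * 23, d = 8),
    kip3_from_table1 = list(
      r0 = simple_form_r0(tab1),
      F_S = stall_force_closed_form(tab1),
      k_plus = tab1$k_plus, k_minus = tab1$k_minus, d = tab1$d
    )
  )
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  }
  presets[[name]]
}

#' Read a motor parameter set from a JSON or YAML file
#'
#' The file must be a flat mapping of `motor_parameters` field names to
#' numbers. Missing optional fields take the constructor defaults; `delta`
#' may be omitted (it is derived from `d`) and, if present, must equal `d/2`.
#' The name `kip3_table1` is reserved for the built-in preset and cannot be
#' used to ship different values: if the file carries a `name` field equal to
#' a built-in preset name, reading fails.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A `motor_parameters` object.
#' @seealso [write_motor_parameters()]
#' @export
read_motor_parameters <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("unsupported preset file extension '", ext, "' (use json/yaml/yml)")
  )
  if (!is.null(raw$name)) {
    if (raw$name %in% names(.kinslip_presets())) {
      stop("preset name '", raw$name, "' is reserved for the built-in preset")
    }
    raw$name <- NULL
  }
  raw$delta <- NULL # derived
  known <- names(formals(motor_parameters))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown motor_parameters fields in file: ",
         paste(unknown, collapse = ", "))
  }
  do.call(motor_parameters, lapply(raw, as.numeric))
}

#' Write a motor parameter set to a JSON or YAML file
#'
#' @param p A `motor_parameters` object.
#' @param path Output path; format chosen from the extension
#'   (`.json`/`.yaml`/`.yml`).
#' @return `path`, invisibly.
#' @export
write_motor_parameters <- function(p, path) {
  validate_motor_parameters(p)
  x <- unclass(p)
  x$delta <- NULL
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA),
    yaml = ,
    yml = yaml::write_yaml(x, path),
    stop("unsupported preset file extension '", ext, "' (use json/yaml/yml)")
  )
  invisible(path)
}

#' @export
print.motor_parameters <- function(x, ...) {
  cat("Motor parameter set\n")
  cat(sprintf("  catalytic: k_D = %g /s, k+ = %g /s, k- = %g /s\n",
              x$k_D, x$k_plus, x$k_minus))
  cat(sprintf("  energetic: E_NL = %g kBT (kBT = %g pN nm)\n", x$E_NL, x$kBT))
  cat(sprintf("  geometric: d = %g nm, d+ = %g nm, d- = %g nm, delta = %g nm\n",
              x$d, x$d_plus, x$d_minus, x$delta))
  cat(sprintf("  slip/binding: v_II0 = %g /s, k_bT = %g /uM/s, k_bD = %g /uM/s\n",
              x$v_II0, x$k_bT, x$k_bD))
  invisible(x)
}
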