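#' Operating condition: load and nucleotide concentrations
#'
#' One operating point of the motor: the signed external load on the stalk
#' and the ATP/ADP concentrations. Load is positive in the forward direction
#' (toward the microtubule plus end). Saturating ATP is a symbolic limit
#' selected with `atp = "saturating"` (or `Inf`): the limit expressions are
#' used, never a large finite concentration.
#'
#' @param force Signed external load (pN); may be a vector for curve scans.
#' @param atp ATP concentration (uM), or `"saturating"` / `Inf` for the
#'   saturating limit.
#' @param adp ADP concentration (uM). Default 0.
#' @return An object of class `motor_condition`.
#' @examples
#' motor_condition(force = -1, atp = "saturating")
#' motor_condition(force = 0, atp = 10)
#' @export
motor_condition <- function(force = 0, atp = "saturating", adp = 0) {
  if (identical(atp, "saturating")) atp <- Inf
  atp <- as.numeric(atp)
  adp <- as.numeric(adp)
  stopifnot(is.numeric(force), all(is.finite(force)),
            length(atp) == 1L, length(adp) == 1L,
            !is.na(atp), !is.na(adp))
  if (atp < 0) stop("atp must be non-negative")
  if (adp < 0 || !is.finite(adp)) stop("adp must be finite and non-negative")
  structure(list(force = as.numeric(force), atp = atp, adp = adp),
            class = "motor_condition")
}

#' Is a condition in the saturating-ATP limit?
#'
#' @param cond A `motor_condition`.
#' @return `TRUE` if ATP is saturating (symbolic limit), else `FALSE`.
#' @export
is_saturating <- function(cond) {
  stopifnot(inherits(cond, "motor_condition"))
  is.infinite(cond$atp)
}

#' @export
print.motor_condition <- function(x, ...) {
  atp <- if (is.infinite(x$atp)) "saturating" else paste0(x$atp, " uM")
  f <- if (length(x$force) == 1L) sprintf("%g pN", x$force) else
    sprintf("[%g..%g] pN (%d points)", min(x$force), max(x$force),
            length(x$force))
  cat(sprintf("Operating condition: F = %s, [ATP] = %s, [ADP] = %g uM\n",
              f, atp, x$adp))
  invisible(x)
}

# Internal: require ATP turnover to be possible (walking regime).
check_walking_condition <- function(cond) {
  stopifnot(inherits(cond, "motor_condition"))
  if (cond$atp == 0) {
    stop("zero-turnover condition: [ATP] = 0 supports no ATPase cycling; ",
         "use the slip-only regime (simulate_slip_only / slip_velocity) instead")
  }
  invisible(cond)
}
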