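# Physical constants and unit helpers.

#' Gas constant in kcal mol-1 K-1
#'
#' The value used throughout the package (1.9872e-3 kcal mol-1 K-1).
#' @export
R_KCAL <- 1.9872e-3

#' Thermal energy RT in kcal/mol
#'
#' @param temperature Absolute temperature in K.
#' @return RT in kcal/mol.
#' @export
rt_kcal <- function(temperature) {
  stopifnot(is.numeric(temperature))
  if (any(temperature <= 0)) abort("`temperature` must be positive (Kelvin).")
  R_KCAL * temperature
}

#' Convert degrees Celsius to Kelvin
#'
#' @param celsius Temperature in degrees C.
#' @return Temperature in K (offset 273.15).
#' @export
celsius_to_kelvin <- function(celsius) celsius + 273.15

#' Parse concentration strings with unit suffixes
#'
#' Accepts numbers with an optional suffix among M, mM, uM (also written
#' "µM"/"μM"), nM, pM, fM, and normalises to molar. Bare numbers are
#' taken as molar.
#'
#' @param x Character (or numeric) vector, e.g. `"15 nM"`, `"2mM"`, `1e-6`.
#' @return Numeric vector of concentrations in M.
#' @examples
#' parse_conc(c("15 nM", "2 mM", "1.6 fM", "1e-9"))
#' @export
parse_conc <- function(x) {
  if (is.numeric(x)) return(x)
  scale <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12, fM = 1e-15)
  x_clean <- gsub("[µμ]", "u", trimws(x))
  m <- regmatches(x_clean, regexec("^([-+0-9.eE]+)\\s*([mMunpf]?M)?$", x_clean))
  vapply(seq_along(m), function(i) {
    mi <- m[[i]]
    if (length(mi) == 0 || mi[2] == "") {
      abort(sprintf("Cannot parse concentration '%s'.", x[i]))
    }
    val <- suppressWarnings(as.numeric(mi[2]))
    if (is.na(val)) abort(sprintf("Cannot parse concentration '%s'.", x[i]))
    unit <- mi[3]
    if (is.na(unit) || unit == "") return(val)
    if (!unit %in% names(scale)) {
      abort(sprintf("Unknown concentration unit '%s' in '%s'.", unit, x[i]))
    }
    val * scale[[unit]]
  }, numeric(1))
}
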