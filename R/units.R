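#' Parse a physical quantity with a unit suffix
#'
#' Configuration values may carry explicit unit suffixes (\code{"20 nm"},
#' \code{"1000 Pa"}, \code{"9 GPa"}). This parser converts them to the
#' package-internal base unit of the corresponding dimension: nanometres
#' for lengths, pascals for pressures and moduli, unitless otherwise.
#' Bare numbers are taken to be in the base unit already.
#'
#' @param x a number, or a string like \code{"2.5 nm"} or \code{"0.1 GPa"}.
#' @param dimension one of \code{"length"}, \code{"pressure"},
#'   \code{"none"}.
#' @return numeric scalar in base units (nm or Pa).
#' @examples
#' parse_quantity("0.5 um", "length")   # 500 (nm)
#' parse_quantity("1 kPa", "pressure")  # 1000 (Pa)
#' @export
parse_quantity <- function(x, dimension = c("length", "pressure", "none")) {
  dimension <- match.arg(dimension)
  if (is.numeric(x)) {
    if (length(x) != 1L || !is.finite(x))
      stop("quantity must be a finite scalar")
    return(as.numeric(x))
  }
  if (!is.character(x) || length(x) != 1L)
    stop("quantity must be a number or a single string")
  m <- regmatches(x, regexec(
    "^\\s*([-+0-9.eE]+)\\s*([A-Za-z]*)\\s*$", x))[[1]]
  if (length(m) != 3L || m[2] == "")
    stop("cannot parse quantity: ", x)
  val <- as.numeric(m[2])
  if (!is.finite(val)) stop("cannot parse quantity: ", x)
  unit <- m[3]
  if (unit == "") return(val)
  scale <- switch(dimension,
    length = c(nm = 1, um = 1e3, mm = 1e6, m = 1e9)[unit],
    pressure = c(Pa = 1, kPa = 1e3, MPa = 1e6, GPa = 1e9)[unit],
    none = stop("unexpected unit '", unit, "' on dimensionless quantity"))
  if (is.na(scale))
    stop("unknown ", dimension, " unit '", unit, "' in ", x)
  unname(val * scale)
}

# nm -> m
.nm <- function(x) x * 1e-9
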