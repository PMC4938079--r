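#' Unit conversion constants
#'
#' The model works internally in SI units (Pa, m, m^2, m^3/s, s) while
#' clinical data arrive in mmHg, mm, cm^2 and ml/s. These constants are the
#' exact conversion factors used throughout the package.
#'
#' @name units
#' @keywords internal
NULL

## 1 mmHg in Pa, defined via the standard atmosphere (101325 Pa / 760 mmHg)
MMHG_PA <- 101325 / 760

## 1 ml/s in m^3/s
MLS_M3S <- 1e-6

## 1 cm^2 in m^2
CM2_M2 <- 1e-4

#' Convert between clinical and SI units
#'
#' @param x numeric vector.
#' @param unit unit label: one of `"mmHg"`, `"Pa"`, `"ml/s"`, `"m3/s"`,
#'   `"cm2"`, `"m2"`, `"mm"`, `"cm"`, `"m"`, `"m/s"`.
#' @return `to_si()` returns `x` in the SI unit of the same quantity;
#'   `from_si()` is its inverse.
#' @examples
#' to_si(100, "mmHg") / MMHG_PA
#' @export
to_si <- function(x, unit) {
  switch(unit,
    "mmHg" = x * MMHG_PA,
    "Pa"   = x,
    "ml/s" = x * MLS_M3S,
    "m3/s" = x,
    "cm2"  = x * CM2_M2,
    "m2"   = x,
    "mm"   = x * 1e-3,
    "cm"   = x * 1e-2,
    "m"    = x,
    "m/s"  = x,
    stop("unknown unit: ", unit)
  )
}

#' @rdname to_si
#' @export
from_si <- function(x, unit) {
  switch(unit,
    "mmHg" = x / MMHG_PA,
    "Pa"   = x,
    "ml/s" = x / MLS_M3S,
    "m3/s" = x,
    "cm2"  = x / CM2_M2,
    "m2"   = x,
    "mm"   = x * 1e3,
    "cm"   = x * 1e2,
    "m"    = x,
    "m/s"  = x,
    stop("unknown unit: ", unit)
  )
}

## canonical SI unit for each quantity
si_unit_of <- function(quantity) {
  switch(quantity,
    flow = "m3/s", area = "m2", pressure = "Pa",
    stop("unknown quantity: ", quantity)
  )
}

## default clinical unit for each quantity (used when writing files)
clinical_unit_of <- function(quantity) {
  switch(quantity,
    flow = "ml/s", area = "cm2", pressure = "mmHg",
    stop("unknown quantity: ", quantity)
  )
}
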