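#' @name atomicMasses
#' @title Monoisotopic atomic masses and physical constants
#'
#' @description
#' Monoisotopic atomic masses (Da) of the elements handled by the formula
#' arithmetic, plus selected heavy isotopes used as stable-isotope labels,
#' the electron mass and the proton mass. Values follow the IUPAC/CODATA
#' recommendations at the precision relevant for ppm-level accurate-mass
#' work (sub-1e-6 Da for light elements).
#'
#' The proton mass is derived as mass(1H) minus the electron mass, so that
#' protonated-ion m/z values account for the electron correctly.
NULL

# monoisotopic masses of the light (most abundant) isotope, Da
.LIGHT_MASS <- c(
  H  = 1.0078250319,
  C  = 12.0,
  N  = 14.0030740052,
  O  = 15.9949146221,
  S  = 31.97207069,
  P  = 30.97376151,
  F  = 18.99840322,
  Cl = 34.96885271,
  Br = 78.9183376,
  I  = 126.904473,
  Na = 22.98976928,
  K  = 38.96370649,
  Si = 27.97692653,
  B  = 11.0093055,
  Se = 79.9165218,
  Mg = 23.98504170,
  Ca = 39.96259086,
  Fe = 55.93493633,
  Zn = 63.92914201
)

# heavy isotopes supported as labels, Da
.HEAVY_MASS <- c(
  "2H"  = 2.0141017781,
  "3H"  = 3.0160492779,
  "13C" = 13.0033548378,
  "15N" = 15.0001088984,
  "18O" = 17.9991610,
  "34S" = 33.96786690
)

.ELECTRON_MASS <- 0.00054857990907
.PROTON_MASS <- .LIGHT_MASS[["H"]] - .ELECTRON_MASS

# light element corresponding to a heavy-isotope symbol ("13C" -> "C")
.lightOf <- function(isotope) sub("^[0-9]+", "", isotope)

#' Monoisotopic mass of an element or isotope symbol
#'
#' @param symbol character vector of element symbols (`"C"`, `"Cl"`) or
#'   heavy-isotope symbols (`"13C"`, `"2H"`).
#' @return numeric vector of monoisotopic masses in Da.
#' @examples
#' atomicMass(c("C", "13C", "2H"))
#' @export
atomicMass <- function(symbol) {
  tab <- c(.LIGHT_MASS, .HEAVY_MASS)
  bad <- setdiff(symbol, names(tab))
  if (length(bad) > 0L)
    stop("unknown element or isotope symbol: ", paste(bad, collapse = ", "))
  unname(tab[symbol])
}

#' Electron and proton masses
#'
#' @return mass in Da.
#' @rdname atomicMass
#' @export
electronMass <- function() .ELECTRON_MASS

#' @rdname atomicMass
#' @export
protonMass <- function() .PROTON_MASS
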