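#' Construct an ion species
#'
#' Known labels: `"[M+H]+"` (protonation), `"[M-H]-"` (deprotonation),
#' `"cation"` / `"[M]+"` (intact singly charged cation, electron removed)
#' and `"anion"` / `"[M]-"` (intact anion, electron added). Arbitrary
#' species can be built by giving `polarity` and `protonDelta` directly.
#'
#' @param label one of the known adduct labels, or a display label when
#'   `polarity`/`protonDelta` are supplied.
#' @param polarity,protonDelta override the built-in definitions.
#' @return an [IonSpecies-class].
#' @examples
#' ionSpecies("[M+H]+")
#' @export
ionSpecies <- function(label, polarity = NULL, protonDelta = NULL) {
  if (is(label, "IonSpecies")) return(label)
  if (is.null(polarity) || is.null(protonDelta)) {
    known <- list(
      "[M+H]+" = c(1L, 1L), "M+H" = c(1L, 1L),
      "[M-H]-" = c(-1L, -1L), "M-H" = c(-1L, -1L),
      "cation" = c(1L, 0L), "[M]+" = c(1L, 0L),
      "anion" = c(-1L, 0L), "[M]-" = c(-1L, 0L)
    )
    if (!label %in% names(known))
      stop("unknown ion species label: ", label,
           " (supply polarity and protonDelta for custom species)")
    def <- known[[label]]
    polarity <- def[1]; protonDelta <- def[2]
  }
  new("IonSpecies", polarity = as.integer(polarity),
      protonDelta = as.integer(protonDelta), label = label)
}

#' Theoretical m/z of a singly charged ion
#'
#' For protonated/deprotonated species the m/z is the neutral monoisotopic
#' mass plus `protonDelta` proton masses (the proton mass is mass(1H) minus
#' the electron mass, so the electron bookkeeping is built in). For intact
#' cations/anions (`protonDelta` 0) one electron mass is subtracted or
#' added according to polarity.
#'
#' @param f an [ElementalFormula-class] or formula string.
#' @param ion an [IonSpecies-class] or a known adduct label (see
#'   [ionSpecies()]).
#' @return m/z in Th (Da per unit charge).
#' @examples
#' ionMz("C8H12N4O3", "[M+H]+")      # 213.0982
#' ionMz("C9H11ClNO2", "cation")     # 200.0473
#' @export
ionMz <- function(f, ion = "[M+H]+") {
  f <- .asFormula(f)
  ion <- ionSpecies(ion)
  m <- monoisotopicMass(f) + ion@protonDelta * .PROTON_MASS
  if (ion@protonDelta == 0L)
    m <- m - ion@polarity * .ELECTRON_MASS
  if (m <= 0)
    stop("resulting m/z is not positive")
  m
}

#' Construct a stable-isotope label specification
#'
#' @param heavyIsotope heavy-isotope symbol (`"13C"`, `"2H"`; `"D"` is
#'   accepted as an alias for `"2H"`). A compact `"13C:3"` / `"D:9"` string
#'   giving the label count is also accepted, in which case `nLabels` is
#'   taken from the string.
#' @param nLabels number of labeled positions (>= 1).
#' @return an [IsotopeLabel-class].
#' @examples
#' isotopeLabel("13C", 3)
#' isotopeLabel("D:9")
#' @export
isotopeLabel <- function(heavyIsotope, nLabels = 1L) {
  if (is(heavyIsotope, "IsotopeLabel")) return(heavyIsotope)
  if (grepl(":", heavyIsotope, fixed = TRUE)) {
    parts <- strsplit(heavyIsotope, ":", fixed = TRUE)[[1]]
    heavyIsotope <- parts[1]
    nLabels <- as.integer(parts[2])
  }
  if (heavyIsotope == "D") heavyIsotope <- "2H"
  if (heavyIsotope == "T") heavyIsotope <- "3H"
  light <- .lightOf(heavyIsotope)
  new("IsotopeLabel", lightElement = light, heavyIsotope = heavyIsotope,
      nLabels = as.integer(nLabels),
      perLabelDelta = atomicMass(heavyIsotope) - atomicMass(light))
}

#' m/z of an isotope-labeled ion, allowing label loss
#'
#' Computes the ion m/z of a formula carrying `nLabels - labelsLost` heavy
#' substitutions — e.g. the hydroxylation product of d9-bupropion retains
#' eight of nine deuteriums when the reaction displaces one.
#'
#' @param f neutral formula of the (unlabeled) species.
#' @param ion an [IonSpecies-class] or adduct label.
#' @param label an [IsotopeLabel-class] or compact string (`"D:9"`).
#' @param labelsLost number of labels lost (0 <= labelsLost <= nLabels).
#' @return m/z in Th.
#' @examples
#' labeledMz("C8H12N4O3", "[M+H]+", "D:3")          # 216.1170
#' labeledMz("C13H18ClNO2", "[M+H]+", "D:9", 1)     # 264.1601
#' @export
labeledMz <- function(f, ion, label, labelsLost = 0L) {
  label <- isotopeLabel(label)
  labelsLost <- as.integer(labelsLost)
  if (labelsLost < 0L || labelsLost > label@nLabels)
    stop("labelsLost must be between 0 and nLabels (", label@nLabels, ")")
  retained <- label@nLabels - labelsLost
  ionMz(substituteLabel(.asFormula(f), label, retained), ion)
}

#' Signed relative mass error in parts per million
#'
#' @param observed observed m/z (vectorized).
#' @param theoretical theoretical m/z (> 0).
#' @return `(observed - theoretical) / theoretical * 1e6`.
#' @examples
#' ppmError(213.0981, 213.0982)
#' @export
ppmError <- function(observed, theoretical) {
  if (any(theoretical <= 0))
    stop("theoretical m/z must be > 0")
  (observed - theoretical) / theoretical * 1e6
}
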