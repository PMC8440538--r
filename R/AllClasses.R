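#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' ElementalFormula: an elemental composition with optional heavy-isotope labels
#'
#' Represents a neutral elemental composition as total atom counts per
#' element, plus a count of heavy-isotope substitutions per isotope
#' (substitutions, not additions: `counts` holds the total number of atoms
#' of each element, light and heavy together, and `labels` says how many of
#' them carry the heavy isotope).
#'
#' @slot counts named integer vector, element symbol -> total atom count.
#' @slot labels named integer vector, heavy-isotope symbol (e.g. `"2H"`,
#'   `"13C"`) -> number of substituted atoms.
#'
#' @seealso [parseFormula()], [monoisotopicMass()], [formulaString()]
#' @export
setClass("ElementalFormula",
  representation(counts = "integer", labels = "integer"),
  prototype(counts = setNames(integer(0), character(0)),
            labels = setNames(integer(0), character(0)))
)

setValidity("ElementalFormula", function(object) {
  cnt <- object@counts
  lab <- object@labels
  if (length(cnt) && (is.null(names(cnt)) || any(names(cnt) == "")))
    return("all element counts must be named")
  if (any(cnt < 0L)) return("element counts must be >= 0")
  if (any(lab < 0L)) return("label counts must be >= 0")
  if (length(cnt)) {
    bad <- setdiff(names(cnt), names(.LIGHT_MASS))
    if (length(bad)) return(paste0("unknown element symbol: ",
                                   paste(bad, collapse = ", ")))
  }
  if (length(lab)) {
    bad <- setdiff(names(lab), names(.HEAVY_MASS))
    if (length(bad)) return(paste0("unknown isotope symbol: ",
                                   paste(bad, collapse = ", ")))
    for (iso in names(lab)) {
      light <- .lightOf(iso)
      have <- if (light %in% names(cnt)) cnt[[light]] else 0L
      if (lab[[iso]] > have)
        return(sprintf("%d x %s labels exceed the %d %s atoms available",
                       lab[[iso]], iso, have, light))
    }
  }
  TRUE
})

#' IonSpecies: a singly charged ionized form of a neutral molecule
#'
#' Describes how a neutral formula is observed in the mass spectrometer:
#' protonation/deprotonation (`protonDelta` of +1 for \[M+H\]+, -1 for
#' \[M-H\]-) or an intact (pre-charged) cation/anion (`protonDelta` 0).
#' Only singly charged species are supported.
#'
#' @slot polarity integer, +1 or -1.
#' @slot protonDelta integer, number of protons added (may be negative).
#' @slot label character, display label such as `"[M+H]+"`.
#'
#' @seealso [ionSpecies()], [ionMz()]
#' @export
setClass("IonSpecies",
  representation(polarity = "integer", protonDelta = "integer",
                 label = "character"))

setValidity("IonSpecies", function(object) {
  if (!object@polarity %in% c(1L, -1L)) return("polarity must be +1 or -1")
  if (length(object@label) != 1L) return("label must be a single string")
  TRUE
})

#' IsotopeLabel: a stable-isotope labeling scheme
#'
#' Describes an isotopically labeled precursor: which light element is
#' substituted, by which heavy isotope, how many positions are labeled, and
#' the mass added per substitution (heavy minus light monoisotopic mass).
#'
#' @slot lightElement character, e.g. `"H"`.
#' @slot heavyIsotope character, e.g. `"2H"`.
#' @slot nLabels integer >= 1.
#' @slot perLabelDelta numeric, Da added per substitution.
#'
#' @seealso [isotopeLabel()], [labeledMz()], [pairLabeled()]
#' @export
setClass("IsotopeLabel",
  representation(lightElement = "character", heavyIsotope = "character",
                 nLabels = "integer", perLabelDelta = "numeric"))

setValidity("IsotopeLabel", function(object) {
  if (!object@heavyIsotope %in% names(.HEAVY_MASS))
    return(paste0("unsupported heavy isotope: ", object@heavyIsotope))
  if (.lightOf(object@heavyIsotope) != object@lightElement)
    return("heavy isotope does not match the light element")
  if (object@nLabels < 1L) return("nLabels must be >= 1")
  expect <- atomicMass(object@heavyIsotope) - atomicMass(object@lightElement)
  if (abs(object@perLabelDelta - expect) > 1e-7)
    return("perLabelDelta inconsistent with the atomic-mass table")
  TRUE
})

#' XenoFeatureTable: an aligned MS1 feature table with sample metadata
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one `intensity`
#' assay (features x samples; `NA` = not detected / missing), feature m/z
#' and retention time (seconds) in `rowData`, sample metadata (group,
#' time point, label state, biofluid, replicate, ...) in `colData`, and
#' the chromatographic method (`"HILIC+"` or `"C18-"`) in `metadata`.
#'
#' @seealso [XenoFeatureTable()], [readFeatureTable()]
#' @export
setClass("XenoFeatureTable", contains = "SummarizedExperiment")

setValidity("XenoFeatureTable", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("mz", "rt") %in% colnames(rd)))
    return("rowData must carry 'mz' and 'rt'")
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    return("an 'intensity' assay is required")
  if (any(!is.finite(rd$mz)) || any(rd$mz <= 0))
    return("all feature m/z must be finite and > 0")
  if (any(!is.finite(rd$rt)) || any(rd$rt < 0))
    return("all retention times must be finite and >= 0")
  if (anyDuplicated(rownames(object)))
    return("feature identifiers (rownames) must be unique")
  if (anyDuplicated(colnames(object)))
    return("sample identifiers (colnames) must be unique")
  x <- SummarizedExperiment::assay(object, "intensity")
  if (any(x < 0, na.rm = TRUE))
    return("intensities must be non-negative (use NA for missing)")
  method <- S4Vectors::metadata(object)$method
  if (is.null(method) || !method %in% c("HILIC+", "C18-"))
    return("metadata()$method must be 'HILIC+' or 'C18-'")
  TRUE
})
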