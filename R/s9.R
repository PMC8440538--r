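#' Time-trend filter for S9 incubation time courses
#'
#' Flags features whose MS1 intensity rises with incubation time, the
#' signature of enzymatic product formation: for each feature, replicate
#' intensities are averaged per time point (missing treated as 0), the
#' Pearson correlation of averaged intensity against time in hours is
#' computed, and the feature passes iff `r > rMin` and its time-0
#' intensity does not exceed `t0Threshold` ("not detected at time 0").
#' Features with zero intensity variance have undefined correlation and
#' fail.
#'
#' @param x a [XenoFeatureTable-class] whose `sampleData` carries a
#'   numeric `time_h` column; at least 3 distinct time points required.
#' @param rMin Pearson correlation threshold (default 0.9).
#' @param t0Threshold maximum allowed averaged intensity at time 0
#'   (default 0, i.e. strictly absent).
#' @return `data.frame` with columns `feature_id`, `r`, `detected_at_t0`,
#'   `passes`.
#' @export
timeTrendFilter <- function(x, rMin = 0.9, t0Threshold = 0) {
  sd <- sampleData(x)
  if (!"time_h" %in% colnames(sd) || any(is.na(sd$time_h)))
    stop("every sample needs a time_h value in the sample metadata")
  times <- sort(unique(sd$time_h))
  if (length(times) < 3L)
    stop("need at least 3 distinct time points, got ", length(times))
  avg <- averageByGroup(x, "time_h", missingAsZero = TRUE)
  avg <- avg[, as.character(times), drop = FALSE]
  r <- apply(avg, 1L, function(v) {
    if (stats::sd(v) == 0) NA_real_ else stats::cor(v, times)
  })
  t0 <- if (0 %in% times) avg[, as.character(times[times == 0][1])] else
    rep(0, nrow(avg))
  detected0 <- t0 > t0Threshold
  data.frame(feature_id = rownames(avg), r = r, detected_at_t0 = detected0,
             passes = !is.na(r) & r > rMin & !detected0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Annotate time-trend-passing features with expected metabolites
#'
#' Matches the m/z of each passing feature against the ion m/z of every
#' rule-enumerated biotransformation product of a parent xenobiotic. A
#' feature may match several products; all matches within `ppmTol` are
#' reported, sorted by absolute ppm error.
#'
#' @param x the [XenoFeatureTable-class] the trend results came from.
#' @param trend result of [timeTrendFilter()] (only rows with
#'   `passes == TRUE` are annotated), or a character vector of feature ids.
#' @param parent parent formula ([ElementalFormula-class] or string).
#' @param rules rule table ([transformationRules()]).
#' @param depth enumeration depth (default 2: e.g. hydroxylation then
#'   conjugation).
#' @param adduct ion species for the expected products.
#' @param ppmTol mass-match tolerance in ppm (default 3).
#' @param includeParent also match features against the parent itself.
#' @return `data.frame` with columns `feature_id`, `mz`, `rt`, `formula`,
#'   `chain`, `theoretical_mz`, `ppm`.
#' @export
annotateExpected <- function(x, trend, parent,
                             rules = transformationRules(), depth = 2L,
                             adduct = "[M+H]+", ppmTol = 3,
                             includeParent = FALSE) {
  ids <- if (is.character(trend)) trend else
    trend$feature_id[trend$passes]
  products <- enumerateProducts(parent, rules = rules, depth = depth)
  if (includeParent) {
    parent <- .asFormula(parent)
    products <- rbind(data.frame(chain = "parent",
                                 formula = formulaString(parent),
                                 mass = monoisotopicMass(parent),
                                 n_steps = 0L), products)
  }
  if (!nrow(products) || !length(ids))
    return(data.frame(feature_id = character(0), mz = numeric(0),
                      rt = numeric(0), formula = character(0),
                      chain = character(0), theoretical_mz = numeric(0),
                      ppm = numeric(0)))
  products$theoretical_mz <- vapply(products$formula,
                                    function(f) ionMz(f, adduct), 0.0,
                                    USE.NAMES = FALSE)
  mz <- featureMz(x)[ids]
  rt <- featureRt(x)[ids]
  out <- list()
  for (i in seq_along(ids)) {
    ppm <- ppmError(mz[i], products$theoretical_mz)
    hit <- which(abs(ppm) <= ppmTol)
    if (!length(hit)) next
    hit <- hit[order(abs(ppm[hit]))]
    out[[length(out) + 1L]] <- data.frame(
      feature_id = ids[i], mz = unname(mz[i]), rt = unname(rt[i]),
      formula = products$formula[hit], chain = products$chain[hit],
      theoretical_mz = products$theoretical_mz[hit], ppm = ppm[hit],
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(feature_id = character(0), mz = numeric(0),
                      rt = numeric(0), formula = character(0),
                      chain = character(0), theoretical_mz = numeric(0),
                      ppm = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fraction of expected metabolites recovered from an incubation screen
#'
#' @param expected `data.frame` with columns `parent` and `formula`
#'   (canonical strings) listing the literature-expected metabolites per
#'   parent xenobiotic.
#' @param annotated result of [annotateExpected()] (possibly concatenated
#'   over parents, with a `parent` column added; when absent, all rows are
#'   pooled).
#' @return list with `per_parent` (`data.frame`: parent, n_expected,
#'   n_detected, fraction) and `overall` (pooled fraction in \[0, 1\]).
#' @export
coverageReport <- function(expected, annotated) {
  if (!nrow(expected)) stop("expected-metabolite list is empty")
  canon <- function(v) vapply(v, function(f) formulaString(.asFormula(f)),
                              "", USE.NAMES = FALSE)
  expected$formula <- canon(expected$formula)
  if (nrow(annotated)) annotated$formula <- canon(annotated$formula)
  hitKey <- if ("parent" %in% colnames(annotated))
    paste(annotated$parent, annotated$formula) else annotated$formula
  expKey <- if ("parent" %in% colnames(annotated))
    paste(expected$parent, expected$formula) else expected$formula
  detected <- expKey %in% hitKey
  per <- do.call(rbind, lapply(split(detected, expected$parent), function(d)
    data.frame(n_expected = length(d), n_detected = sum(d),
               fraction = mean(d))))
  per <- data.frame(parent = rownames(per), per, row.names = NULL,
                    stringsAsFactors = FALSE)
  list(per_parent = per, overall = mean(detected))
}

#' Build library entries from annotated S9 screen hits
#'
#' Converts annotated, time-trend-passing features into metabolite-library
#' entries. Each entry carries the satisfied evidence criteria:
#' xenobiotic-specific presence, accurate-mass match (within the screen's
#' ppm tolerance) and time-dependent formation — plus an MS2 criterion
#' when a spectrum is supplied. Entries with MS2 are identification level
#' 2 (spectral evidence without an authentic purified standard); entries
#' without spectra are tentative, level 3.
#'
#' @param annotated result of [annotateExpected()].
#' @param x the source [XenoFeatureTable-class] (for method and RT).
#' @param precursor name of the parent xenobiotic.
#' @param ms2 optional named list of spectra (names = feature ids) as from
#'   [readMs2()].
#' @param adduct the ion species the annotations were computed under.
#' @return a library `data.frame` (see [readLibrary()]), one row per
#'   distinct annotated feature using its best (lowest |ppm|) annotation.
#' @export
buildLibraryEntries <- function(annotated, x, precursor, ms2 = NULL,
                                adduct = "[M+H]+") {
  if (!nrow(annotated)) return(.emptyLibrary())
  best <- annotated[order(annotated$feature_id, abs(annotated$ppm)), ]
  best <- best[!duplicated(best$feature_id), , drop = FALSE]
  hasMs2 <- !is.null(ms2) & best$feature_id %in% names(ms2)
  crit <- ifelse(hasMs2,
                 "specific_presence;mass_match;time_dependence;ms2",
                 "specific_presence;mass_match;time_dependence")
  data.frame(
    precursor = precursor,
    metabolite_name = paste0(precursor, " metabolite (", best$chain, ")"),
    formula = best$formula,
    adduct = if (is(adduct, "IonSpecies")) adduct@label else adduct,
    theoretical_mz = best$theoretical_mz,
    method = chromMethod(x),
    rt = best$rt,
    ms2_id = ifelse(hasMs2, best$feature_id, NA_character_),
    evidence = crit,
    msi_level = ifelse(hasMs2, 2L, 3L),
    stringsAsFactors = FALSE)
}
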