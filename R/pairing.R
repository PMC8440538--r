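#' Pair features across unlabeled and stable-isotope-labeled experiments
#'
#' For every time-trend-passing feature of the unlabeled experiment,
#' searches the labeled experiment for a co-eluting feature at the m/z
#' expected when `k` heavy labels are retained, for each `k` from
#' `nLabels - maxLabelLoss` up to `nLabels`. Deuterium labels can be lost
#' during biotransformation (the d9 to d8 hydroxylation case), so the
#' search spans a window of retained-label counts; 13C labels sit on the
#' carbon skeleton and are retained by default.
#'
#' The ppm tolerance is evaluated against the expected labeled m/z (the
#' larger mass), two-sided. For each (feature, k) the best candidate by
#' |ppm| is kept; one feature may pair at several k values (all reported:
#' the ambiguity is chemically meaningful, reflecting label position).
#'
#' @param unlabeled,labeled the two [XenoFeatureTable-class] objects.
#' @param unlabeledIds,labeledIds feature ids that passed
#'   [timeTrendFilter()] in each experiment (character vectors or
#'   trend-filter result frames).
#' @param label an [IsotopeLabel-class] or compact string (`"13C:3"`).
#' @param maxLabelLoss maximum labels lost; defaults to 0 for carbon
#'   (`13C`) and nitrogen labels and to `nLabels` for hydrogen labels.
#' @param rtTol co-elution tolerance in seconds (default 5).
#' @param ppmTol mass tolerance in ppm (default 3).
#' @return `data.frame` with columns `unlabeled_feature_id`,
#'   `labeled_feature_id`, `labels_retained`, `delta_mz_observed`,
#'   `delta_rt`, `ppm_error`.
#' @export
pairLabeled <- function(unlabeled, labeled, unlabeledIds, labeledIds,
                        label, maxLabelLoss = NULL, rtTol = 5, ppmTol = 3) {
  label <- isotopeLabel(label)
  if (is.null(maxLabelLoss))
    maxLabelLoss <- if (label@lightElement == "H") label@nLabels else 0L
  maxLabelLoss <- as.integer(maxLabelLoss)
  if (maxLabelLoss > label@nLabels)
    stop("maxLabelLoss exceeds the number of labels (", label@nLabels, ")")
  uIds <- if (is.character(unlabeledIds)) unlabeledIds else
    unlabeledIds$feature_id[unlabeledIds$passes]
  lIds <- if (is.character(labeledIds)) labeledIds else
    labeledIds$feature_id[labeledIds$passes]
  uMz <- featureMz(unlabeled)[uIds]; uRt <- featureRt(unlabeled)[uIds]
  lMz <- featureMz(labeled)[lIds];   lRt <- featureRt(labeled)[lIds]
  ks <- seq(label@nLabels - maxLabelLoss, label@nLabels)
  out <- list()
  for (i in seq_along(uIds)) {
    for (k in ks) {
      expMz <- uMz[i] + k * label@perLabelDelta
      ppm <- ppmError(lMz, expMz)
      drt <- lRt - uRt[i]
      hit <- which(abs(ppm) <= ppmTol & abs(drt) <= rtTol)
      if (!length(hit)) next
      best <- hit[which.min(abs(ppm[hit]))]
      out[[length(out) + 1L]] <- data.frame(
        unlabeled_feature_id = uIds[i],
        labeled_feature_id = lIds[best],
        labels_retained = k,
        delta_mz_observed = unname(lMz[best] - uMz[i]),
        delta_rt = unname(drt[best]),
        ppm_error = unname(ppm[best]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(unlabeled_feature_id = character(0),
                      labeled_feature_id = character(0),
                      labels_retained = integer(0),
                      delta_mz_observed = numeric(0), delta_rt = numeric(0),
                      ppm_error = numeric(0)))
  do.call(rbind, out)
}

#' Partition time-trend hits into label-specific and nonspecific features
#'
#' Features with at least one labeled counterpart (an isotope pair) are
#' specific reaction products of the test compound; the rest are
#' nonspecific background that merely rose with incubation time. The
#' partition is exhaustive and disjoint.
#'
#' @param passingIds feature ids passing the time-trend filter in the
#'   unlabeled experiment (character vector or trend-filter frame).
#' @param pairs result of [pairLabeled()].
#' @return list with character vectors `specific` and `nonspecific`.
#' @export
filterNonspecific <- function(passingIds, pairs) {
  ids <- if (is.character(passingIds)) passingIds else
    passingIds$feature_id[passingIds$passes]
  specific <- intersect(ids, unique(pairs$unlabeled_feature_id))
  list(specific = specific, nonspecific = setdiff(ids, specific))
}

#' Peak-intensity ratio between two isomeric features
#'
#' Ratio of replicate-averaged intensities of two features at a stated
#' time point (or over stated samples) — e.g. comparing the two
#' hydroxylation isomers formed from a labeled precursor. A zero
#' denominator is reported as infinite and flagged.
#'
#' @param x a [XenoFeatureTable-class].
#' @param featureA,featureB feature ids (numerator, denominator).
#' @param timeH restrict to samples at this `time_h` (default: all).
#' @return list with `ratio`, `intensity_a`, `intensity_b`,
#'   `infinite` flag.
#' @export
isomerRatio <- function(x, featureA, featureB, timeH = NULL) {
  m <- intensityMatrix(x)
  keep <- rep(TRUE, ncol(m))
  if (!is.null(timeH)) {
    sd <- sampleData(x)
    if (!"time_h" %in% colnames(sd)) stop("no time_h metadata")
    keep <- sd$time_h == timeH
    if (!any(keep)) stop("no samples at time_h = ", timeH)
  }
  a <- mean(ifelse(is.na(m[featureA, keep]), 0, m[featureA, keep]))
  b <- mean(ifelse(is.na(m[featureB, keep]), 0, m[featureB, keep]))
  list(ratio = if (b == 0) Inf else a / b,
       intensity_a = a, intensity_b = b, infinite = b == 0)
}
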