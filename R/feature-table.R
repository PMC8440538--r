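#' Construct an aligned MS1 feature table
#'
#' @param mz numeric vector of feature m/z values (> 0).
#' @param rt numeric vector of retention times in seconds (>= 0).
#' @param intensities numeric matrix, features x samples; `NA` marks a
#'   missing (not detected) intensity. Row and column names, if absent,
#'   are taken from `featureIds` and `sampleData$sample_id`.
#' @param sampleData `data.frame` of per-sample metadata with one row per
#'   column of `intensities`; recognised columns include `sample_id`,
#'   `group`, `time_h`, `label_state`, `biofluid`, `replicate`.
#' @param method chromatographic method, `"HILIC+"` or `"C18-"`.
#' @param featureIds optional character vector of unique feature ids;
#'   defaults to `F0001`, `F0002`, ...
#' @return a [XenoFeatureTable-class].
#' @examples
#' tab <- XenoFeatureTable(
#'   mz = c(181.0720, 213.0982), rt = c(31, 31),
#'   intensities = matrix(c(1e5, 2e5, NA, 3e5), nrow = 2,
#'                        dimnames = list(NULL, c("s1", "s2"))),
#'   sampleData = data.frame(sample_id = c("s1", "s2"), time_h = c(0, 24)),
#'   method = "HILIC+")
#' @export
XenoFeatureTable <- function(mz, rt, intensities, sampleData,
                             method = c("HILIC+", "C18-"),
                             featureIds = NULL) {
  method <- match.arg(method)
  intensities <- as.matrix(intensities)
  if (is.null(featureIds)) {
    featureIds <- if (!is.null(rownames(intensities))) rownames(intensities)
    else sprintf("F%04d", seq_len(nrow(intensities)))
  }
  sampleData <- as.data.frame(sampleData)
  ids <- if ("sample_id" %in% colnames(sampleData)) sampleData$sample_id
  else colnames(intensities)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(ncol(intensities)))
  if (is.null(colnames(intensities))) colnames(intensities) <- ids
  intensities <- intensities[, match(ids, colnames(intensities)), drop = FALSE]
  rownames(intensities) <- featureIds
  rownames(sampleData) <- ids
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensities),
    rowData = S4Vectors::DataFrame(mz = as.numeric(mz), rt = as.numeric(rt),
                                   row.names = featureIds),
    colData = S4Vectors::DataFrame(sampleData),
    metadata = list(method = method))
  new("XenoFeatureTable", se)
}

#' @describeIn XenoFeatureTable feature m/z values (named by feature id).
#' @param x a [XenoFeatureTable-class].
#' @export
featureMz <- function(x) {
  setNames(SummarizedExperiment::rowData(x)$mz, rownames(x))
}

#' @describeIn XenoFeatureTable feature retention times in seconds.
#' @export
featureRt <- function(x) {
  setNames(SummarizedExperiment::rowData(x)$rt, rownames(x))
}

#' @describeIn XenoFeatureTable the intensity matrix (`NA` = missing).
#' @export
intensityMatrix <- function(x) {
  SummarizedExperiment::assay(x, "intensity")
}

#' @describeIn XenoFeatureTable sample metadata as a `data.frame`.
#' @export
sampleData <- function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
}

#' @describeIn XenoFeatureTable the chromatographic method string.
#' @export
chromMethod <- function(x) {
  S4Vectors::metadata(x)$method
}

setMethod("show", "XenoFeatureTable", function(object) {
  cat("XenoFeatureTable (", chromMethod(object), "): ",
      nrow(object), " features x ", ncol(object), " samples\n", sep = "")
  rd <- SummarizedExperiment::rowData(object)
  cat(sprintf("  m/z %.4f-%.4f, RT %.0f-%.0f s\n",
              min(rd$mz), max(rd$mz), min(rd$rt), max(rd$rt)))
  cd <- colnames(SummarizedExperiment::colData(object))
  if (length(cd)) cat("  sample metadata:", paste(cd, collapse = ", "), "\n")
})

#' Average technical/biological replicate intensities per group
#'
#' Collapses columns of the intensity matrix by a grouping column of the
#' sample metadata (e.g. `time_h` or `subject_id`), averaging available
#' intensities. With `missingAsZero = TRUE` missing values are counted as
#' zero (not detected) before averaging, matching how presence/absence is
#' treated in trend filtering.
#'
#' @param x a [XenoFeatureTable-class].
#' @param by name of a `sampleData(x)` column.
#' @param missingAsZero replace `NA` with 0 before averaging.
#' @return a features x groups matrix; column names are the group values.
#' @export
averageByGroup <- function(x, by, missingAsZero = TRUE) {
  sd <- sampleData(x)
  if (!by %in% colnames(sd))
    stop("no '", by, "' column in the sample metadata")
  m <- intensityMatrix(x)
  if (missingAsZero) m[is.na(m)] <- 0
  groups <- sd[[by]]
  lev <- unique(groups)
  out <- vapply(lev, function(g)
    rowMeans(m[, groups == g, drop = FALSE], na.rm = !missingAsZero),
    numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m), dimnames = list(rownames(m), as.character(lev)))
  out
}
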