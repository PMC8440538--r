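#' Read an aligned feature table from delimited text
#'
#' Expects the de-facto mzMine2/apLCMS export shape: a header row with
#' `feature_id`, `mz`, `rt`, then one column per sample; blank cells are
#' missing intensities. Sample metadata is read from a second delimited
#' file keyed by `sample_id`.
#'
#' @param path feature-table file (CSV by default).
#' @param sampleMetadataPath sample metadata file with a `sample_id`
#'   column; samples default to the table's intensity columns when absent.
#' @param method chromatographic method recorded on the table.
#' @param sep field separator.
#' @param rtUnit `"s"` (default) or `"min"`; minute-scale retention times
#'   are converted to seconds on read.
#' @return a [XenoFeatureTable-class].
#' @seealso [writeFeatureTable()]
#' @export
readFeatureTable <- function(path, sampleMetadataPath = NULL,
                             method = c("HILIC+", "C18-"), sep = ",",
                             rtUnit = c("s", "min")) {
  method <- match.arg(method)
  rtUnit <- match.arg(rtUnit)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("feature_id", "mz", "rt")
  if (!all(need %in% colnames(tab)[seq_len(3)]))
    stop("malformed header: first columns must be feature_id, mz, rt")
  if (anyDuplicated(tab$feature_id))
    stop("duplicate feature_id: ",
         paste(unique(tab$feature_id[duplicated(tab$feature_id)]),
               collapse = ", "))
  sampleCols <- setdiff(colnames(tab), need)
  m <- as.matrix(tab[, sampleCols, drop = FALSE])
  if (!is.numeric(m))
    stop("intensity columns contain non-numeric values")
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative intensity at feature '%s', sample '%s'",
                 tab$feature_id[neg[1, 1]], sampleCols[neg[1, 2]]))
  rt <- tab$rt * if (rtUnit == "min") 60 else 1
  sampleData <- if (!is.null(sampleMetadataPath)) {
    sd <- utils::read.table(sampleMetadataPath, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
    if (!"sample_id" %in% colnames(sd))
      stop("sample metadata must have a sample_id column")
    missing <- setdiff(sampleCols, sd$sample_id)
    if (length(missing))
      stop("samples without metadata: ", paste(missing, collapse = ", "))
    sd[match(sampleCols, sd$sample_id), , drop = FALSE]
  } else data.frame(sample_id = sampleCols)
  XenoFeatureTable(mz = tab$mz, rt = rt, intensities = m,
                   sampleData = sampleData, method = method,
                   featureIds = tab$feature_id)
}

#' Write a feature table (and optionally its sample metadata)
#'
#' @param x a [XenoFeatureTable-class].
#' @param path output file for the feature table.
#' @param sampleMetadataPath optional output file for the sample metadata.
#' @param sep field separator.
#' @export
writeFeatureTable <- function(x, path, sampleMetadataPath = NULL, sep = ",") {
  out <- data.frame(feature_id = rownames(x), mz = featureMz(x),
                    rt = featureRt(x), check.names = FALSE)
  out <- cbind(out, as.data.frame(intensityMatrix(x), check.names = FALSE))
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  if (!is.null(sampleMetadataPath))
    utils::write.table(sampleData(x), sampleMetadataPath, sep = sep,
                       row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read / write a metabolite library
#'
#' A library records enzyme-generated (or precursor) metabolites: the
#' precursor compound, a broad metabolite name, elemental formula (may be
#' empty), adduct, theoretical m/z, chromatographic method, retention time
#' (seconds), an optional MS2 spectrum id, the satisfied evidence criteria
#' (`;`-separated flags) and the identification level. On read, every
#' entry with a formula is checked for internal consistency: its stored
#' theoretical m/z must agree with the m/z computed from formula + adduct
#' within 3 ppm.
#'
#' @param path CSV file with columns `precursor`, `metabolite_name`,
#'   `formula`, `adduct`, `theoretical_mz`, `method`, `rt`, and optionally
#'   `ms2_id`, `evidence`, `msi_level`.
#' @return `data.frame` of validated library entries.
#' @export
readLibrary <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(formula = "character"))
  if (nrow(tab) == 0L) return(.emptyLibrary())
  need <- c("precursor", "metabolite_name", "formula", "adduct",
            "theoretical_mz", "method", "rt")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("library missing columns: ", paste(miss, collapse = ", "))
  for (opt in c("ms2_id", "evidence")) if (!opt %in% colnames(tab))
    tab[[opt]] <- NA_character_
  if (!"msi_level" %in% colnames(tab)) tab$msi_level <- NA_integer_
  validateLibrary(tab)
  tab
}

.emptyLibrary <- function() {
  data.frame(precursor = character(0), metabolite_name = character(0),
             formula = character(0), adduct = character(0),
             theoretical_mz = numeric(0), method = character(0),
             rt = numeric(0), ms2_id = character(0), evidence = character(0),
             msi_level = integer(0), stringsAsFactors = FALSE)
}

#' @rdname readLibrary
#' @param entries a library `data.frame`.
#' @export
validateLibrary <- function(entries) {
  if (!all(entries$method %in% c("HILIC+", "C18-")))
    stop("library method must be 'HILIC+' or 'C18-'")
  hasF <- !is.na(entries$formula) & nzchar(entries$formula)
  for (i in which(hasF)) {
    theo <- ionMz(entries$formula[i], entries$adduct[i])
    err <- ppmError(entries$theoretical_mz[i], theo)
    if (abs(err) > 3)
      stop(sprintf(
        "library entry '%s' (%s): theoretical_mz %.4f is %.1f ppm from %s %s",
        entries$metabolite_name[i], entries$precursor[i],
        entries$theoretical_mz[i], err, entries$formula[i],
        entries$adduct[i]))
  }
  invisible(entries)
}

#' @rdname readLibrary
#' @export
writeLibrary <- function(entries, path) {
  validateLibrary(entries)
  utils::write.csv(entries, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read / write MS2 peak lists
#'
#' A plain-text multi-spectrum format: each spectrum starts with a header
#' line `"> <id> <precursor m/z>"` followed by one `mz intensity` pair per
#' line. Peaks are sorted by m/z on read.
#'
#' @param path peak-list file.
#' @return a named list of spectra; each spectrum is a `data.frame` with
#'   columns `mz`, `intensity` and attribute `precursor_mz`.
#' @export
readMs2 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) return(list())
  out <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    hdr <- strsplit(trimws(sub("^>\\s*", "", lines[heads[i]])), "\\s+")[[1]]
    id <- hdr[1]
    prec <- if (length(hdr) > 1) as.numeric(hdr[2]) else NA_real_
    body <- lines[seq(heads[i] + 1L, bounds[i + 1L] - 1L)]
    body <- body[!grepl("^>", body)]
    peaks <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"),
                                   function(p) as.numeric(p[1:2])))
    sp <- data.frame(mz = peaks[, 1], intensity = peaks[, 2])
    sp <- sp[order(sp$mz), , drop = FALSE]
    rownames(sp) <- NULL
    if (any(sp$intensity < 0)) stop("negative MS2 intensity in spectrum ", id)
    attr(sp, "precursor_mz") <- prec
    out[[id]] <- sp
  }
  out
}

#' @rdname readMs2
#' @param spectra named list of spectra as returned by [readMs2()].
#' @export
writeMs2 <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(spectra)) {
    sp <- spectra[[id]]
    prec <- attr(sp, "precursor_mz")
    writeLines(sprintf("> %s %s", id,
                       if (is.null(prec) || is.na(prec)) "" else
                         format(prec, digits = 10)), con)
    writeLines(sprintf("%.6f %.6g", sp$mz, sp$intensity), con)
  }
  invisible(path)
}

#' Quality-control check against reference m/z and retention times
#'
#' Compares observed QC compounds to their reference values: a compound
#' passes iff the retention-time deviation is within `rtTol` seconds and
#' the mass error is within `ppmTol` ppm. The per-compound report lists
#' each failure with its deviation.
#'
#' @param observed `data.frame` with columns `mz`, `rt` (and optionally
#'   `compound`), one row per QC compound.
#' @param reference `data.frame` with columns `mz`, `rt`, aligned row by
#'   row with `observed`.
#' @param rtTol retention-time tolerance in seconds (default 8).
#' @param ppmTol mass-accuracy tolerance in ppm (default 5).
#' @return `data.frame` with columns `compound`, `ppm`, `delta_rt`,
#'   `pass_mass`, `pass_rt`, `pass`.
#' @export
qcCheck <- function(observed, reference, rtTol = 8, ppmTol = 5) {
  if (nrow(observed) != nrow(reference))
    stop("observed and reference QC lists differ in length")
  ppm <- ppmError(observed$mz, reference$mz)
  drt <- observed$rt - reference$rt
  compound <- if ("compound" %in% colnames(observed)) observed$compound
  else if ("compound" %in% colnames(reference)) reference$compound
  else sprintf("qc%02d", seq_len(nrow(observed)))
  data.frame(compound = compound, ppm = ppm, delta_rt = drt,
             pass_mass = abs(ppm) <= ppmTol, pass_rt = abs(drt) <= rtTol,
             pass = abs(ppm) <= ppmTol & abs(drt) <= rtTol,
             stringsAsFactors = FALSE)
}

#' Detection call for a (possibly missing) intensity
#'
#' A feature is called detected in a sample iff its intensity is present
#' (not `NA`) and strictly greater than `minIntensity`. Both missing and
#' zero intensities are "not detected"; the default floor of 0 means any
#' positive signal counts.
#'
#' @param x numeric vector of intensities (may contain `NA`).
#' @param minIntensity detection floor (>= 0, default 0).
#' @return logical vector.
#' @export
detectionCall <- function(x, minIntensity = 0) {
  stopifnot(minIntensity >= 0)
  !is.na(x) & x > minIntensity
}
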