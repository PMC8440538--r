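#' Match a study feature table against a metabolite library
#'
#' Reports every (feature, library entry) pair on the same chromatographic
#' method whose m/z agrees within `ppmTol` ppm and whose retention time
#' co-elutes within `rtTol` seconds. When several features match one
#' entry they are ranked by |ppm| then |delta RT|.
#'
#' @param x a [XenoFeatureTable-class].
#' @param library a library `data.frame` (see [readLibrary()]).
#' @param ppmTol mass tolerance in ppm (default 3).
#' @param rtTol retention-time tolerance in seconds (default 5). Use
#'   `Inf` for mass-only lookups (entries whose RT is not comparable).
#' @return `data.frame` with columns `entry` (library row index),
#'   `precursor`, `metabolite_name`, `feature_id`, `ppm_error`,
#'   `delta_rt`, `rank`.
#' @export
matchLibrary <- function(x, library, ppmTol = 3, rtTol = 5) {
  lib <- library[library$method == chromMethod(x), , drop = FALSE]
  mz <- featureMz(x); rt <- featureRt(x)
  out <- list()
  for (j in seq_len(nrow(lib))) {
    ppm <- ppmError(mz, lib$theoretical_mz[j])
    drt <- rt - lib$rt[j]
    rtOk <- if (is.finite(rtTol)) abs(drt) <= rtTol else rep(TRUE, length(drt))
    hit <- which(abs(ppm) <= ppmTol & rtOk)
    if (!length(hit)) next
    hit <- hit[order(abs(ppm[hit]), abs(drt[hit]))]
    out[[length(out) + 1L]] <- data.frame(
      entry = as.integer(rownames(lib))[j] %||% j,
      precursor = lib$precursor[j],
      metabolite_name = lib$metabolite_name[j],
      feature_id = names(mz)[hit],
      ppm_error = unname(ppm[hit]),
      delta_rt = unname(drt[hit]),
      rank = seq_along(hit),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(entry = integer(0), precursor = character(0),
                      metabolite_name = character(0),
                      feature_id = character(0), ppm_error = numeric(0),
                      delta_rt = numeric(0), rank = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a) || all(is.na(a))) b else a

#' Presence / relative-abundance matrix of matched metabolites
#'
#' Builds a (precursor: metabolite) x sample matrix from library matches:
#' a logical detection matrix (intensity present and above
#' `minIntensity`) and a min-max scaled relative-abundance matrix, scaled
#' across each row using the maximum and minimum observed peak intensity
#' of that metabolite (a constant row scales to 1 where detected). Rows
#' are grouped (ordered) by precursor.
#'
#' @param matches result of [matchLibrary()]. Each metabolite uses its
#'   best-ranked feature.
#' @param x the matched [XenoFeatureTable-class].
#' @param minIntensity detection floor (default 0).
#' @return list with `detected` (logical matrix), `relative` (numeric
#'   matrix, `NA` where not detected), `precursor` (character vector per
#'   row).
#' @export
presenceMatrix <- function(matches, x, minIntensity = 0) {
  if (!nrow(matches))
    return(list(detected = matrix(FALSE, 0, ncol(x),
                                  dimnames = list(NULL, colnames(x))),
                relative = matrix(NA_real_, 0, ncol(x),
                                  dimnames = list(NULL, colnames(x))),
                precursor = character(0)))
  best <- matches[matches$rank == 1L, , drop = FALSE]
  best <- best[order(best$precursor, best$metabolite_name), , drop = FALSE]
  m <- intensityMatrix(x)
  inten <- m[best$feature_id, , drop = FALSE]
  rownames(inten) <- paste(best$precursor, best$metabolite_name, sep = ": ")
  det <- !is.na(inten) & inten > minIntensity
  rel <- t(apply(inten, 1L, function(v) {
    v[is.na(v)] <- NA
    obs <- v[!is.na(v)]
    if (!length(obs)) return(v)
    rng <- range(obs)
    if (rng[1] == rng[2]) ifelse(is.na(v), NA, 1)
    else (v - rng[1]) / (rng[2] - rng[1])
  }))
  dimnames(rel) <- dimnames(inten)
  rel[!det] <- NA
  list(detected = det, relative = rel, precursor = best$precursor)
}

#' Assign orthogonal-criteria confidence levels to library matches
#'
#' Evaluates, per (matched metabolite, sample) with a detection, the
#' orthogonal identification criteria: accurate-mass match (within the
#' matching ppm window), retention-time co-elution (within the RT
#' window), exposure-specific presence (the metabolite is detected only
#' in samples with documented exposure to its precursor — assessable only
#' when exposure records are supplied), co-occurrence (at least one other
#' related metabolite of the same precursor detected in the same sample),
#' and an MS2 spectral match where spectra were compared. The confidence
#' level is derived from the number of satisfied criteria: three or more
#' give level 1, exactly two level 2, exactly one level 3. Criteria that
#' cannot be assessed (`NA`) are excluded from the count.
#'
#' @param matches result of [matchLibrary()] (best-ranked rows are used).
#' @param presence result of [presenceMatrix()] on the same matches.
#' @param exposures optional `data.frame` with columns `sample_id`,
#'   `precursor` listing documented exposures; `NULL` when no records
#'   exist (the flag is then not assessed).
#' @param ms2Results optional `data.frame` with columns
#'   `metabolite_name`, `match` (logical) from [ms2Match()] comparisons.
#' @param rtTol co-elution window in seconds used for the RT criterion
#'   (default 5); matches whose `delta_rt` is missing or outside the
#'   window (mass-only lookups) do not earn the RT criterion.
#' @return `data.frame` with one row per detection: `precursor`,
#'   `metabolite_name`, `sample_id`, `feature_id`, `ppm_error`,
#'   `delta_rt`, the five criteria columns, `n_criteria` and
#'   `confidence_level`.
#' @export
assignConfidence <- function(matches, presence, exposures = NULL,
                             ms2Results = NULL, rtTol = 5) {
  best <- matches[matches$rank == 1L, , drop = FALSE]
  best <- best[order(best$precursor, best$metabolite_name), , drop = FALSE]
  det <- presence$detected
  out <- list()
  for (i in seq_len(nrow(best))) {
    rowName <- paste(best$precursor[i], best$metabolite_name[i], sep = ": ")
    samples <- colnames(det)[det[rowName, ]]
    if (!length(samples)) next
    sameprec <- which(presence$precursor == best$precursor[i])
    exposure <- if (is.null(exposures)) NA else {
      expSamples <- exposures$sample_id[exposures$precursor ==
                                          best$precursor[i]]
      onlyExposed <- all(colnames(det)[det[rowName, ]] %in% expSamples)
      samples %in% expSamples & onlyExposed
    }
    coocc <- vapply(samples, function(s) {
      others <- setdiff(sameprec, match(rowName, rownames(det)))
      length(others) > 0 && any(det[others, s])
    }, logical(1))
    ms2 <- if (is.null(ms2Results)) NA else {
      j <- match(best$metabolite_name[i], ms2Results$metabolite_name)
      if (is.na(j)) NA else ms2Results$match[j]
    }
    out[[length(out) + 1L]] <- data.frame(
      precursor = best$precursor[i],
      metabolite_name = best$metabolite_name[i],
      sample_id = samples,
      feature_id = best$feature_id[i],
      ppm_error = best$ppm_error[i],
      delta_rt = best$delta_rt[i],
      mass_match = TRUE,
      rt_coelution = is.finite(best$delta_rt[i]) &&
        abs(best$delta_rt[i]) <= rtTol,
      exposure_specific = exposure,
      co_occurrence = unname(coocc),
      ms2_match = ms2,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(precursor = character(0),
                      metabolite_name = character(0),
                      sample_id = character(0), feature_id = character(0),
                      ppm_error = numeric(0), delta_rt = numeric(0),
                      mass_match = logical(0), rt_coelution = logical(0),
                      exposure_specific = logical(0),
                      co_occurrence = logical(0), ms2_match = logical(0),
                      n_criteria = integer(0),
                      confidence_level = integer(0)))
  res <- do.call(rbind, out)
  flags <- res[, c("mass_match", "rt_coelution", "exposure_specific",
                   "co_occurrence", "ms2_match")]
  res$n_criteria <- apply(flags, 1L, function(f) sum(f, na.rm = TRUE))
  res$confidence_level <- confidenceLevel(res$n_criteria)
  rownames(res) <- NULL
  res
}

#' Map a count of satisfied orthogonal criteria to a confidence level
#'
#' Three or more satisfied criteria constitute level 1 confidence, exactly
#' two level 2, exactly one level 3; zero criteria yield `NA` (no
#' identification).
#'
#' @param nCriteria integer vector of satisfied-criterion counts.
#' @return integer vector of levels (1, 2, 3 or `NA`).
#' @export
confidenceLevel <- function(nCriteria) {
  ifelse(nCriteria >= 3L, 1L,
         ifelse(nCriteria == 2L, 2L,
                ifelse(nCriteria == 1L, 3L, NA_integer_)))
}

#' Cosine similarity between two MS2 spectra
#'
#' Fragment peaks are greedily matched within a ppm tolerance (largest
#' intensity products first, each peak used once) and the cosine score is
#' computed over the matched intensity pairs relative to the total
#' intensity norms. A score of 1 means identical spectra; disjoint peak
#' sets score 0.
#'
#' @param observed,reference spectra: `data.frame`s with `mz`,
#'   `intensity` (see [readMs2()]); must be non-empty.
#' @param fragmentPpmTol fragment matching tolerance in ppm (default 10).
#' @param minCosine score threshold for calling a spectral match
#'   (default 0.7).
#' @return list with `score` and logical `match`.
#' @export
ms2Match <- function(observed, reference, fragmentPpmTol = 10,
                     minCosine = 0.7) {
  if (!nrow(observed) || !nrow(reference))
    stop("MS2 spectra must be non-empty")
  cand <- expand.grid(i = seq_len(nrow(observed)),
                      j = seq_len(nrow(reference)))
  cand$ppm <- abs(ppmError(observed$mz[cand$i], reference$mz[cand$j]))
  cand <- cand[cand$ppm <= fragmentPpmTol, , drop = FALSE]
  cand$prod <- observed$intensity[cand$i] * reference$intensity[cand$j]
  cand <- cand[order(-cand$prod), , drop = FALSE]
  usedI <- logical(nrow(observed)); usedJ <- logical(nrow(reference))
  dot <- 0
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (usedI[i] || usedJ[j]) next
    usedI[i] <- TRUE; usedJ[j] <- TRUE
    dot <- dot + cand$prod[k]
  }
  score <- dot / sqrt(sum(observed$intensity^2) * sum(reference$intensity^2))
  list(score = score, match = score >= minCosine)
}

#' Pathway-positive samples from a presence matrix
#'
#' A sample is called positive for a precursor's pathway when at least
#' `minMetabolites` related entries of that precursor are detected in it
#' (default 2, i.e. co-occurrence of more than one related xenobiotic).
#'
#' @param presence result of [presenceMatrix()].
#' @param minMetabolites minimum detected related entries (default 2).
#' @return named list, precursor -> character vector of positive samples.
#' @export
pathwayPositives <- function(presence, minMetabolites = 2L) {
  det <- presence$detected
  lapply(split(seq_len(nrow(det)), presence$precursor), function(rows) {
    counts <- colSums(det[rows, , drop = FALSE])
    colnames(det)[counts >= minMetabolites]
  })
}

#' Cross-biofluid concordance of pathway detections
#'
#' Counts, per precursor pathway, how many individuals are positive in
#' both biofluids, in either one only, or in neither — detection of the
#' same related xenobiotics in a second biofluid provides additional
#' identification confidence.
#'
#' @param presenceA,presenceB [presenceMatrix()] results for the two
#'   biofluids; their sample identifiers must match.
#' @param minMetabolites passed to [pathwayPositives()].
#' @return `data.frame` with columns `precursor`, `both`, `only_a`,
#'   `only_b`, `neither`.
#' @export
crossBiofluidConcordance <- function(presenceA, presenceB,
                                     minMetabolites = 2L) {
  sa <- colnames(presenceA$detected); sb <- colnames(presenceB$detected)
  if (!setequal(sa, sb))
    stop("sample identifiers differ between the two biofluids")
  posA <- pathwayPositives(presenceA, minMetabolites)
  posB <- pathwayPositives(presenceB, minMetabolites)
  precs <- union(names(posA), names(posB))
  do.call(rbind, lapply(precs, function(p) {
    a <- posA[[p]] %||% character(0)
    b <- posB[[p]] %||% character(0)
    data.frame(precursor = p,
               both = length(intersect(a, b)),
               only_a = length(setdiff(a, b)),
               only_b = length(setdiff(b, a)),
               neither = length(sa) - length(union(a, b)),
               stringsAsFactors = FALSE)
  }))
}
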