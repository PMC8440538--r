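#' Simulation configuration for synthetic feature tables
#'
#' Bundles the knobs shared by the synthetic generators. The defaults
#' emulate the study designs the package targets: S9 incubations sampled
#' at 0/2/6/24 h with duplicate biological replicates, retention times
#' across an 18-300 s gradient span, log-normal peak intensities, mild
#' instrument jitter and a small missing-value rate. Identical seeds give
#' identical output.
#'
#' @param seed integer RNG seed.
#' @param nBackground number of nonspecific background features.
#' @param ppmJitterSd Gaussian m/z jitter, ppm (applied once per feature,
#'   as in an aligned table).
#' @param rtJitterSd Gaussian retention-time jitter, seconds.
#' @param missingRate probability a background intensity is missing.
#' @param intensityMeanLog,intensitySdLog log-normal intensity model
#'   (natural-log scale) for planted and background features.
#' @param noiseSdLog per-observation multiplicative log-normal noise.
#' @param timePointsH incubation time points, hours.
#' @param nReplicates biological replicates per time point.
#' @param k first-order product-formation rate, per hour.
#' @param parentDecay first-order parent decline rate, per hour
#'   (substrate consumption).
#' @param rtRange retention-time span, seconds.
#' @param subjectLoading shared subject-factor loading inducing
#'   parent-metabolite correlation in cohort simulations (0 = independent
#'   log-normals).
#' @return a list of class `xenoSimConfig`.
#' @export
simConfig <- function(seed = 1L, nBackground = 100L, ppmJitterSd = 0.5,
                      rtJitterSd = 1, missingRate = 0.05,
                      intensityMeanLog = 13, intensitySdLog = 1,
                      noiseSdLog = 0.3, timePointsH = c(0, 2, 6, 24),
                      nReplicates = 2L, k = 0.15, parentDecay = 0.02,
                      rtRange = c(18, 300), subjectLoading = 1) {
  stopifnot(missingRate >= 0, missingRate <= 1, ppmJitterSd >= 0,
            rtJitterSd >= 0, noiseSdLog >= 0, nBackground >= 0,
            length(rtRange) == 2, rtRange[1] < rtRange[2])
  structure(list(seed = as.integer(seed), nBackground = as.integer(nBackground),
                 ppmJitterSd = ppmJitterSd, rtJitterSd = rtJitterSd,
                 missingRate = missingRate,
                 intensityMeanLog = intensityMeanLog,
                 intensitySdLog = intensitySdLog, noiseSdLog = noiseSdLog,
                 timePointsH = timePointsH,
                 nReplicates = as.integer(nReplicates), k = k,
                 parentDecay = parentDecay, rtRange = rtRange,
                 subjectLoading = subjectLoading),
            class = "xenoSimConfig")
}

# draw n m/z values uniformly over `range`, rejecting any within
# ppmWindow of a forbidden m/z (avoids accidental matches/twins)
.sampleMzAvoid <- function(n, range = c(85, 1275), forbidden = numeric(0),
                           ppmWindow = 10) {
  out <- numeric(0)
  while (length(out) < n) {
    cand <- stats::runif(n - length(out), range[1], range[2])
    if (length(forbidden)) {
      ok <- vapply(cand, function(m)
        all(abs((m - forbidden) / forbidden * 1e6) > ppmWindow), logical(1))
      cand <- cand[ok]
    }
    out <- c(out, cand)
  }
  out
}

# apply per-feature m/z jitter (ppm) given config
.jitterMz <- function(mz, cfg) {
  mz * (1 + stats::rnorm(length(mz), 0, cfg$ppmJitterSd) * 1e-6)
}

#' Simulate an S9 incubation time course
#'
#' Emits an aligned feature table emulating an S9 enzyme incubation: the
#' parent xenobiotic declines mildly with time (substrate consumption),
#' each planted biotransformation product follows first-order formation
#' `1 - exp(-k t)` (exactly zero at time 0), and background features are
#' time-independent. Planted feature m/z values are the theoretical ion
#' m/z plus Gaussian ppm jitter; duplicate biological replicates are
#' emitted per time point.
#'
#' @param parent parent formula (string or [ElementalFormula-class]).
#' @param chains list of rule chains (each a character vector of rule
#'   names from `rules`) defining the planted products.
#' @param config a [simConfig()].
#' @param adduct ion species of all planted features.
#' @param rules rule table used to resolve chain names.
#' @return list with `table` (a [XenoFeatureTable-class]) and `truth`
#'   (`data.frame`: `feature_id`, `role`, `formula`, `chain`,
#'   `theoretical_mz`, `rt`).
#' @export
simulateS9 <- function(parent, chains, config = simConfig(),
                       adduct = "[M+H]+", rules = transformationRules()) {
  set.seed(config$seed)
  parent <- .asFormula(parent)
  prodFormulas <- lapply(chains, function(ch) {
    f <- parent
    for (rule in ch) f <- applyTransformation(f, rule, rules = rules)
    f
  })
  theo <- c(ionMz(parent, adduct),
            vapply(prodFormulas, function(f) ionMz(f, adduct), 0.0))
  nP <- length(theo)
  truth <- data.frame(
    feature_id = sprintf("P%03d", seq_len(nP)),
    role = c("parent", rep("product", nP - 1L)),
    formula = c(formulaString(parent),
                vapply(prodFormulas, formulaString, "")),
    chain = c("", vapply(chains, paste, "", collapse = " > ")),
    theoretical_mz = theo, stringsAsFactors = FALSE)
  rtTrue <- stats::runif(nP, config$rtRange[1], config$rtRange[2])
  truth$rt <- rtTrue
  bgMz <- .sampleMzAvoid(config$nBackground, forbidden = theo)
  mz <- c(.jitterMz(theo, config), bgMz)
  rt <- c(rtTrue + stats::rnorm(nP, 0, config$rtJitterSd),
          stats::runif(config$nBackground, config$rtRange[1],
                       config$rtRange[2]))
  rt <- pmax(rt, 0)
  ids <- c(truth$feature_id, sprintf("B%04d", seq_len(config$nBackground)))
  times <- rep(config$timePointsH, each = config$nReplicates)
  reps <- rep(seq_len(config$nReplicates), length(config$timePointsH))
  sampleData <- data.frame(sample_id = sprintf("t%g_r%d", times, reps),
                           time_h = times, replicate = reps)
  amp <- exp(stats::rnorm(nP, config$intensityMeanLog, config$intensitySdLog))
  bgAmp <- exp(stats::rnorm(config$nBackground, config$intensityMeanLog,
                            config$intensitySdLog))
  m <- matrix(0, nrow = length(ids), ncol = nrow(sampleData),
              dimnames = list(ids, sampleData$sample_id))
  for (j in seq_len(nrow(sampleData))) {
    t <- times[j]
    m[1L, j] <- amp[1L] * exp(-config$parentDecay * t)
    if (nP > 1L)
      m[2:nP, j] <- amp[2:nP] * (1 - exp(-config$k * t))
    m[(nP + 1L):(nP + config$nBackground), j] <- bgAmp
  }
  if (config$noiseSdLog > 0) {
    noise <- matrix(exp(stats::rnorm(length(m), 0, config$noiseSdLog)),
                    nrow = nrow(m))
    zero <- m == 0
    m <- m * noise
    m[zero] <- 0
  }
  if (config$missingRate > 0) {
    drop <- matrix(stats::runif(length(m)) < config$missingRate,
                   nrow = nrow(m))
    drop[seq_len(nP), ] <- FALSE       # planted truths stay observable
    m[drop] <- NA
  }
  tab <- XenoFeatureTable(mz = mz, rt = rt, intensities = m,
                          sampleData = sampleData, method = "HILIC+",
                          featureIds = ids)
  list(table = tab, truth = truth)
}

#' Simulate paired unlabeled / isotope-labeled S9 experiments
#'
#' The unlabeled table is an [simulateS9()] run; the labeled table
#' mirrors it with every planted feature mass-shifted by its retained
#' label count times the per-label mass difference, co-eluting within the
#' retention-time jitter. Background features are drawn independently in
#' each table and rejection-sampled away from every label-shifted twin
#' position, so no background feature has a shifted counterpart.
#'
#' @param parent parent formula of the unlabeled compound.
#' @param label an [IsotopeLabel-class] or compact string (`"13C:3"`).
#' @param chains list of rule chains for planted products.
#' @param labelsRetained integer vector, labels retained by each product
#'   (the labeled parent itself retains all labels).
#' @param config a [simConfig()].
#' @param adduct ion species.
#' @param rules rule table.
#' @return list with `unlabeled`, `labeled` (tables) and `truth`
#'   (`data.frame` adding `labels_retained` and `labeled_mz`).
#' @export
simulateLabelPair <- function(parent, label, chains, labelsRetained,
                              config = simConfig(), adduct = "[M+H]+",
                              rules = transformationRules()) {
  label <- isotopeLabel(label)
  if (length(labelsRetained) != length(chains))
    stop("labelsRetained must align with chains")
  if (any(labelsRetained > label@nLabels | labelsRetained < 0))
    stop("labelsRetained must be in [0, nLabels]")
  unlab <- simulateS9(parent, chains, config = config, adduct = adduct,
                      rules = rules)
  truth <- unlab$truth
  truth$labels_retained <- c(label@nLabels, as.integer(labelsRetained))
  truth$labeled_mz <- truth$theoretical_mz +
    truth$labels_retained * label@perLabelDelta
  # forbidden positions: any feature of the unlabeled table shifted by any
  # plausible retained-label count (either table must not provide a twin)
  uMz <- featureMz(unlab$table)
  shifts <- (0:label@nLabels) * label@perLabelDelta
  forbidden <- as.numeric(outer(uMz, shifts, "+"))
  set.seed(config$seed + 1L)
  nP <- nrow(truth)
  labMz <- c(.jitterMz(truth$labeled_mz, config),
             .sampleMzAvoid(config$nBackground, forbidden = forbidden))
  labRt <- c(truth$rt + stats::rnorm(nP, 0, config$rtJitterSd),
             stats::runif(config$nBackground, config$rtRange[1],
                          config$rtRange[2]))
  labRt <- pmax(labRt, 0)
  m <- intensityMatrix(unlab$table)
  # regenerate intensities for the labeled run (independent replicates,
  # same kinetics)
  sim2 <- simulateS9(parent, chains,
                     config = {cfg <- config; cfg$seed <- config$seed + 2L
                               cfg},
                     adduct = adduct, rules = rules)
  m2 <- intensityMatrix(sim2$table)
  ids <- rownames(m2)
  labTab <- XenoFeatureTable(mz = labMz, rt = labRt, intensities = m2,
                             sampleData = sampleData(sim2$table),
                             method = "HILIC+", featureIds = ids)
  list(unlabeled = unlab$table, labeled = labTab, truth = truth)
}

#' Default xenobiotic pathways for cohort simulation
#'
#' A small built-in panel of precursor-metabolite pathways (elemental
#' compositions derived from the package's transformation rules) used to
#' emulate exposure cohorts: nicotine (cotinine, hydroxycotinine,
#' nicotine glucuronide), naphthalene (naphthol sulfate, naphthol
#' glucuronide) and five drugs (bupropion, acetaminophen, metoprolol,
#' carvedilol, warfarin) each with characteristic phase I/II products.
#'
#' @param nExposed optional named integer vector overriding the number of
#'   exposed samples per precursor.
#' @return list of pathway descriptions (fields `precursor`, `parent`,
#'   `metabolites` = `data.frame(name, formula)`, `nExposed`).
#' @export
defaultCohortPathways <- function(nExposed = NULL) {
  pw <- list(
    list(precursor = "nicotine", parent = "C10H14N2",
         metabolites = data.frame(
           name = c("cotinine", "hydroxycotinine", "nicotine glucuronide"),
           formula = c("C10H12N2O", "C10H12N2O2", "C16H22N2O6")),
         nExposed = 7L),
    list(precursor = "naphthalene", parent = "C10H8",
         metabolites = data.frame(
           name = c("naphthol sulfate", "naphthol glucuronide"),
           formula = c("C10H8O4S", "C16H16O7")),
         nExposed = 4L),
    list(precursor = "bupropion", parent = "C13H18ClNO",
         metabolites = data.frame(
           name = c("hydroxybupropion", "hydrobupropion"),
           formula = c("C13H18ClNO2", "C13H20ClNO")),
         nExposed = 6L),
    list(precursor = "acetaminophen", parent = "C8H9NO2",
         metabolites = data.frame(
           name = c("acetaminophen glucuronide", "acetaminophen sulfate"),
           formula = c("C14H17NO8", "C8H9NO5S")),
         nExposed = 10L),
    list(precursor = "metoprolol", parent = "C15H25NO3",
         metabolites = data.frame(
           name = c("hydroxymetoprolol", "desmethylmetoprolol"),
           formula = c("C15H25NO4", "C14H23NO3")),
         nExposed = 8L),
    list(precursor = "carvedilol", parent = "C24H26N2O4",
         metabolites = data.frame(
           name = c("hydroxycarvedilol", "desmethylcarvedilol"),
           formula = c("C24H26N2O5", "C23H24N2O4")),
         nExposed = 6L),
    list(precursor = "warfarin", parent = "C19H16O4",
         metabolites = data.frame(
           name = c("hydroxywarfarin", "dihydrowarfarin"),
           formula = c("C19H16O5", "C19H18O4")),
         nExposed = 5L))
  names(pw) <- vapply(pw, `[[`, "", "precursor")
  if (!is.null(nExposed))
    for (p in names(nExposed)) pw[[p]]$nExposed <- as.integer(nExposed[[p]])
  pw
}

#' Simulate an exposure cohort with planted xenobiotic pathways
#'
#' Emits one aligned feature table per biofluid over a shared set of
#' samples. For each pathway, a random subset of samples is "exposed":
#' in those samples the parent and its metabolites get correlated
#' log-normal intensities (a shared per-sample factor on the log scale
#' induces the parent-metabolite correlation); unexposed samples have the
#' pathway features missing. Background features appear everywhere with
#' independent log-normal intensities and the configured missing rate,
#' and are rejection-sampled away from all planted m/z so no accidental
#' matches arise. The exposed subset of each pathway is shared across
#' biofluids (the same individuals carry the exposure in plasma and
#' urine).
#'
#' @param pathways list of pathway descriptions (see
#'   [defaultCohortPathways()]).
#' @param nSamples number of cohort samples (default 120).
#' @param biofluids character vector of biofluid names.
#' @param config a [simConfig()].
#' @param adduct ion species of all planted features.
#' @return list with `tables` (named list of [XenoFeatureTable-class]),
#'   `truth` (`data.frame`: per biofluid/pathway/feature: `feature_id`,
#'   `precursor`, `name`, `formula`, `theoretical_mz`, `rt`),
#'   `exposed` (named list, precursor -> exposed sample ids) and
#'   `library` (reference library `data.frame` usable with
#'   [matchLibrary()]).
#' @export
simulateCohort <- function(pathways = defaultCohortPathways(),
                           nSamples = 120L, biofluids = c("plasma", "urine"),
                           config = simConfig(), adduct = "[M+H]+") {
  set.seed(config$seed)
  nSamples <- as.integer(nSamples)
  sampleIds <- sprintf("S%03d", seq_len(nSamples))
  for (pw in pathways)
    if (pw$nExposed > nSamples)
      stop("nExposed exceeds nSamples for ", pw$precursor)
  exposed <- lapply(pathways, function(pw)
    sort(sample(sampleIds, pw$nExposed)))
  names(exposed) <- vapply(pathways, `[[`, "", "precursor")
  # planted features: shared composition and rt across biofluids
  plant <- do.call(rbind, lapply(pathways, function(pw) {
    data.frame(precursor = pw$precursor,
               name = c(pw$precursor, pw$metabolites$name),
               formula = c(formulaString(.asFormula(pw$parent)),
                           pw$metabolites$formula),
               stringsAsFactors = FALSE)
  }))
  plant$theoretical_mz <- vapply(plant$formula,
                                 function(f) ionMz(f, adduct), 0.0,
                                 USE.NAMES = FALSE)
  plant$rt <- stats::runif(nrow(plant), config$rtRange[1], config$rtRange[2])
  lib <- data.frame(precursor = plant$precursor,
                    metabolite_name = plant$name, formula = plant$formula,
                    adduct = if (is(adduct, "IonSpecies")) adduct@label else
                      adduct,
                    theoretical_mz = plant$theoretical_mz,
                    method = "HILIC+", rt = plant$rt,
                    ms2_id = NA_character_,
                    evidence = "specific_presence;mass_match;time_dependence",
                    msi_level = 3L, stringsAsFactors = FALSE)
  tables <- list()
  truth <- list()
  for (fluid in biofluids) {
    nP <- nrow(plant)
    ids <- sprintf("%s_P%03d", substr(fluid, 1, 2), seq_len(nP))
    mz <- .jitterMz(plant$theoretical_mz, config)
    rt <- plant$rt + stats::rnorm(nP, 0, config$rtJitterSd)
    bgMz <- .sampleMzAvoid(config$nBackground,
                           forbidden = plant$theoretical_mz)
    bgRt <- stats::runif(config$nBackground, config$rtRange[1],
                         config$rtRange[2])
    allIds <- c(ids, sprintf("%s_B%04d", substr(fluid, 1, 2),
                             seq_len(config$nBackground)))
    m <- matrix(NA_real_, nrow = length(allIds), ncol = nSamples,
                dimnames = list(allIds, sampleIds))
    subjFactor <- stats::rnorm(nSamples)   # shared within sample
    for (i in seq_len(nP)) {
      ex <- exposed[[plant$precursor[i]]]
      idx <- match(ex, sampleIds)
      m[i, idx] <- exp(config$intensityMeanLog +
                         config$subjectLoading * subjFactor[idx] +
                         stats::rnorm(length(idx), 0, config$intensitySdLog))
    }
    bgAmp <- exp(stats::rnorm(config$nBackground, config$intensityMeanLog,
                              config$intensitySdLog))
    for (b in seq_len(config$nBackground)) {
      v <- bgAmp[b] * exp(stats::rnorm(nSamples, 0,
                                       max(config$noiseSdLog, 1e-12)))
      if (config$missingRate > 0)
        v[stats::runif(nSamples) < config$missingRate] <- NA
      m[nP + b, ] <- v
    }
    tables[[fluid]] <- XenoFeatureTable(
      mz = c(pmax(mz, 1e-6), bgMz), rt = pmax(c(rt, bgRt), 0),
      intensities = m,
      sampleData = data.frame(sample_id = sampleIds, biofluid = fluid),
      method = "HILIC+", featureIds = allIds)
    truth[[fluid]] <- data.frame(biofluid = fluid, feature_id = ids,
                                 plant, stringsAsFactors = FALSE,
                                 row.names = NULL)
  }
  list(tables = tables, truth = do.call(rbind, truth), exposed = exposed,
       library = lib)
}
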