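# Independent brute-force atom-sum oracle for monoisotopic masses.
# Uses its own copy of the CODATA/IUPAC constants and sums one atom at a
# time, so it shares no code path with the package's vectorized sum.
.oracleTab <- c(
  H = 1.00782503207, C = 12, N = 14.0030740048, O = 15.9949146196,
  S = 31.97207100, P = 30.97376163, Cl = 34.96885268, F = 18.99840322,
  Br = 78.9183371, Na = 22.9897692809, K = 38.96370668, I = 126.904473,
  Si = 27.9769265325
)
.oracleHeavy <- c("2H" = 2.0141017778, "13C" = 13.0033548378,
                  "15N" = 15.0001088982, "18O" = 17.9991610,
                  "34S" = 33.96786690)

oracleMass <- function(counts, labels = integer(0)) {
  m <- 0
  for (el in names(counts)) {
    for (i in seq_len(counts[[el]])) m <- m + .oracleTab[[el]]
  }
  for (iso in names(labels)) {
    light <- sub("^[0-9]+", "", iso)
    for (i in seq_len(labels[[iso]]))
      m <- m + .oracleHeavy[[iso]] - .oracleTab[[light]]
  }
  m
}

# random plausible organic formula as a counts vector
randomFormulaCounts <- function() {
  c(C = sample(1:30, 1), H = sample(1:50, 1), N = sample(0:5, 1),
    O = sample(0:10, 1), S = sample(0:2, 1), Cl = sample(0:2, 1),
    P = sample(0:1, 1))
}

countsToString <- function(counts) {
  counts <- counts[counts > 0]
  paste0(names(counts), counts, collapse = "")
}

# tiny in-memory feature table builder
makeTable <- function(mz, rt, intensities, sampleData, method = "HILIC+",
                      ids = NULL) {
  XenoFeatureTable(mz = mz, rt = rt, intensities = intensities,
                   sampleData = sampleData, method = method,
                   featureIds = ids)
}
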