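test_that("formula parsing handles plain, deuterated and bracketed input", {
  f <- parseFormula("C8H12N4O3")
  expect_equal(f@counts, c(C = 8L, H = 12L, N = 4L, O = 3L))
  expect_length(f@labels, 0)

  f2 <- parseFormula("C7H8N4O2")
  expect_equal(f2@counts, c(C = 7L, H = 8L, N = 4L, O = 2L))

  # deuterium shorthand: substitutions count toward the H total
  d3 <- parseFormula("C8H9D3N4O3")
  expect_equal(d3@counts, c(C = 8L, H = 12L, N = 4L, O = 3L))
  expect_equal(d3@labels, c("2H" = 3L))

  c13 <- parseFormula("C5[13C]3H10N4O2")
  expect_equal(c13@counts[["C"]], 8L)
  expect_equal(c13@labels, c("13C" = 3L))

  expect_error(parseFormula("C8Xx2"), "unknown element")
  expect_error(parseFormula("[99Q]2"), "unknown isotope|cannot parse")
})

test_that("canonical writer round-trips through the parser", {
  set.seed(42)
  for (i in 1:50) {
    counts <- randomFormulaCounts()
    s <- countsToString(counts)
    f <- parseFormula(s)
    expect_identical(formulaString(parseFormula(formulaString(f))),
                     formulaString(f))
  }
  # labeled round trip
  f <- parseFormula("C8H9D3N4O3")
  expect_identical(formulaString(parseFormula(formulaString(f))),
                   formulaString(f))
  expect_identical(formulaString(f), "C8H9[2H]3N4O3")
})

test_that("label substitutions exceeding available atoms are rejected", {
  expect_error(substituteLabel("CH4", isotopeLabel("2H"), 5), "exceed")
  # deuterium shorthand adds to the H total, so CH2D3 is a valid C1H5 species
  expect_identical(parseFormula("CH2D3")@counts[["H"]], 5L)
})

test_that("monoisotopic mass agrees with a brute-force atom-sum oracle", {
  expect_equal(monoisotopicMass(parseFormula("")), 0)
  expect_equal(monoisotopicMass("C8H12N4O3"),
               oracleMass(c(C = 8, H = 12, N = 4, O = 3)), tolerance = 1e-9)
  # the glucuronidation mass delta
  expect_equal(monoisotopicMass("C6H8O6"), 176.03209, tolerance = 1e-5)

  set.seed(1)
  for (i in 1:1000) {
    counts <- randomFormulaCounts()
    expect_equal(monoisotopicMass(countsToString(counts)),
                 oracleMass(counts), tolerance = 1e-6)
  }
})

test_that("labeled masses agree with the oracle's substitution arithmetic", {
  expect_equal(monoisotopicMass("C8H9D3N4O3"),
               oracleMass(c(C = 8, H = 12, N = 4, O = 3), c("2H" = 3)),
               tolerance = 1e-6)
  expect_equal(monoisotopicMass("C5[13C]3H10N4O2"),
               oracleMass(c(C = 8, H = 10, N = 4, O = 2), c("13C" = 3)),
               tolerance = 1e-6)
})

test_that("ion m/z reproduces reported accurate masses", {
  # unreported caffeine metabolite, printed 213.0981
  expect_lt(abs(ppmError(213.0981, ionMz("C8H12N4O3", "[M+H]+"))), 1)
  # paraxanthine
  expect_equal(ionMz("C7H8N4O2", "[M+H]+"), 181.0720, tolerance = 1e-4)
  # intact fragment cation: matches only with electron subtraction
  expect_equal(ionMz("C9H11ClNO2", "cation"), 200.0473, tolerance = 1e-4)
  expect_gt(abs(ppmError(monoisotopicMass("C9H11ClNO2"),
                         ionMz("C9H11ClNO2", "cation"))), 2)
})

test_that("protonated and deprotonated ions differ by two proton masses", {
  set.seed(7)
  for (i in 1:20) {
    s <- countsToString(randomFormulaCounts())
    expect_equal(ionMz(s, "[M+H]+") - ionMz(s, "[M-H]-"), 2 * protonMass(),
                 tolerance = 1e-7)
  }
})

test_that("labeled ion m/z handles retention and loss of labels", {
  # d3 and 13C3 forms of the caffeine metabolite
  expect_equal(labeledMz("C8H12N4O3", "[M+H]+", "D:3"), 216.1170,
               tolerance = 1e-4)
  expect_lt(abs(ppmError(216.1080,
                         labeledMz("C8H12N4O3", "[M+H]+", "13C:3"))), 3)
  # d9-bupropion hydroxylation loses one deuterium -> d8 product
  expect_lt(abs(ppmError(264.1600,
                         labeledMz("C13H18ClNO2", "[M+H]+", "D:9", 1))), 3)
  # all labels lost == unlabeled, exactly
  expect_identical(labeledMz("C8H12N4O3", "[M+H]+", "D:3", 3),
                   ionMz("C8H12N4O3", "[M+H]+"))
  expect_error(labeledMz("C8H12N4O3", "[M+H]+", "D:3", 4), "labelsLost")
})

test_that("transformations apply element-wise with impossibility pruning", {
  out <- applyTransformation("C8H10N4O2", "+O+H2")
  expect_identical(formulaString(out), "C8H12N4O3")
  # identity rule
  expect_identical(formulaString(applyTransformation("C8H10N4O2", "")),
                   "C8H10N4O2")
  # demethylation of ethane twice is fine, a third time impossible
  f <- applyTransformation(applyTransformation("C2H6", "-CH2"), "-CH2")
  expect_error(applyTransformation(f, "-CH2"), "impossible")
})

test_that("rule names resolve against the shipped table", {
  rules <- transformationRules()
  expect_identical(
    formulaString(applyTransformation("C8H10N4O2", "hydroxylation")),
    "C8H10N4O3")
  expect_equal(rules$mass_delta[rules$name == "glucuronidation"],
               176.03209, tolerance = 1e-5)
  expect_equal(rules$mass_delta[rules$name == "13C-isotopologue"],
               1.003355, tolerance = 1e-6)
})

test_that("oxidation+reduction and hydration are mass-equivalent", {
  rules <- transformationRules()
  d1 <- rules$mass_delta[rules$name == "oxidation-reduction"]
  d2 <- rules$mass_delta[rules$name == "hydration"]
  expect_equal(d1, d2, tolerance = 1e-9)
  expect_equal(d1, 18.01056, tolerance = 1e-5)
})

test_that("product enumeration reaches chained conjugates and is monotone", {
  # bupropion: hydroxylation and reduction products
  b <- enumerateProducts("C13H18ClNO", depth = 2)
  expect_true(all(c("C13H18ClNO2", "C13H20ClNO") %in% b$formula))
  # naphthalene: hydroxy then sulfate / glucuronide chains
  n <- enumerateProducts("C10H8", depth = 2)
  expect_true(all(c("C10H8O4S", "C16H16O7") %in% n$formula))
  # hand-derived chain masses
  expect_equal(n$mass[n$formula == "C10H8O4S"],
               oracleMass(c(C = 10, H = 8, O = 4, S = 1)), tolerance = 1e-6)

  # depth-1 products are bounded by the number of rules
  rules <- transformationRules()
  p1 <- enumerateProducts("C8H10N4O2", rules, depth = 1)
  expect_lte(nrow(p1), sum(rules$phase %in% c("I", "II")))
  # output grows monotonically with depth
  p2 <- enumerateProducts("C8H10N4O2", rules, depth = 2)
  p3 <- enumerateProducts("C8H10N4O2", rules, depth = 3)
  expect_true(all(p1$formula %in% p2$formula))
  expect_true(all(p2$formula %in% p3$formula))
})

test_that("composed chain mass deltas are additive", {
  rules <- transformationRules()
  parent <- "C13H18ClNO"
  prods <- enumerateProducts(parent, rules, depth = 2)
  m0 <- monoisotopicMass(parent)
  for (i in seq_len(nrow(prods))) {
    steps <- strsplit(prods$chain[i], " > ", fixed = TRUE)[[1]]
    deltas <- rules$mass_delta[match(steps, rules$name)]
    expect_equal(prods$mass[i] - m0, sum(deltas), tolerance = 1e-9)
  }
})

test_that("ppm error is signed relative deviation", {
  expect_equal(ppmError(213.0981, 213.0982), -0.4692672, tolerance = 1e-4)
  expect_identical(ppmError(256.1099, 256.1099), 0)
  expect_equal(ppmError(200.0479, 200.0473), 2.999291, tolerance = 1e-4)
  expect_error(ppmError(100, 0), "> 0")
})
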