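cohortTable <- function(m, mz, rt = NULL) {
  makeTable(mz = mz, rt = rt %||% rep(60, length(mz)), intensities = m,
            sampleData = data.frame(sample_id = colnames(m)),
            ids = rownames(m))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("association recovers linear and block-structured children", {
  set.seed(21)
  n <- 120
  parent <- rlnorm(n, 12, 1)
  m <- rbind(parent = parent,
             scaled = 2 * parent,
             block = ifelse(seq_len(n) <= 7, parent, 0),
             noise = rlnorm(n, 12, 1))
  colnames(m) <- sprintf("S%03d", seq_len(n))
  # give the block structure to the parent too (exposure-like)
  m["parent", 8:n] <- m["parent", 8:n] * 0 + m["parent", 8:n]
  tab <- cohortTable(m, mz = c(240.1, 256.1, 260.1, 300.5))
  a <- associate(tab, "parent")
  expect_equal(a$r[a$feature_id == "scaled"], 1, tolerance = 1e-12)
  # independent random child stays below the threshold
  expect_false("noise" %in% a$feature_id)
  expect_false("parent" %in% a$feature_id)
})

test_that("a block-exposed metabolite correlates with its block parent", {
  set.seed(22)
  n <- 120
  exposedIdx <- 1:7
  parent <- rep(0, n); parent[exposedIdx] <- rlnorm(7, 13, 0.3)
  child <- rep(0, n); child[exposedIdx] <- parent[exposedIdx] *
    exp(rnorm(7, 0, 0.1))
  m <- rbind(p = parent, c = child)
  colnames(m) <- sprintf("S%03d", seq_len(n))
  tab <- cohortTable(m, mz = c(163.1230, 179.1179))
  a <- associate(tab, "p")
  expect_gt(a$r[a$feature_id == "c"], 0.9)
})

test_that("pls1 association ranks features like Pearson for one response", {
  set.seed(23)
  n <- 60
  parent <- rlnorm(n, 12, 1)
  m <- rbind(p = parent,
             strong = parent * exp(rnorm(n, 0, 0.1)),
             weak = parent * exp(rnorm(n, 0, 1.5)),
             none = rlnorm(n, 12, 1))
  colnames(m) <- sprintf("S%03d", seq_len(n))
  tab <- cohortTable(m, mz = c(100, 116, 130, 150))
  ap <- associate(tab, "p", method = "pearson", rThreshold = 0)
  al <- associate(tab, "p", method = "pls1", rThreshold = 0)
  expect_identical(ap$feature_id[1], al$feature_id[1])
  # the strongly coupled feature dominates, the uncoupled one trails
  expect_identical(al$feature_id[3], "none")
})

test_that("pls1 scores agree with an independent PLS implementation", {
  set.seed(30)
  n <- 50
  parent <- rlnorm(n, 12, 1)
  m <- rbind(p = parent,
             a = parent * exp(rnorm(n, 0, 0.3)),
             b = rlnorm(n, 12, 1),
             c = parent * exp(rnorm(n, 0, 1)))
  colnames(m) <- sprintf("S%02d", seq_len(n))
  tab <- cohortTable(m, mz = c(100, 116, 150, 276))
  al <- associate(tab, "p", method = "pls1", rThreshold = 0)
  fit <- suppressMessages(mixOmics::pls(t(m[-1, ]), m["p", ], ncomp = 1))
  latent <- fit$variates$X[, 1]
  oracle <- vapply(rownames(m)[-1], function(f) cor(m[f, ], latent), 0.0)
  ours <- al$r[match(names(oracle), al$feature_id)]
  # latent-variable sign is arbitrary; align before comparing
  s <- sign(sum(ours * oracle))
  expect_equal(ours, unname(s * oracle), tolerance = 1e-8)
})

test_that("zero-variance parents are rejected", {
  m <- rbind(p = rep(5, 10), c = rlnorm(10))
  colnames(m) <- sprintf("S%03d", 1:10)
  tab <- cohortTable(m, mz = c(100, 120))
  expect_error(associate(tab, "p"), "variance")
  expect_error(associate(tab, "missing"), "not in the table")
})

test_that("mass-difference filter annotates hydroxylation edges", {
  assoc <- data.frame(feature_id = c("hydroxy", "unmatched"),
                      mz = c(256.1099, 250.0000), rt = c(85, 90),
                      r = c(0.8, 0.9), stringsAsFactors = FALSE)
  edges <- massShiftEdges(240.1150, assoc)
  expect_true("hydroxy" %in% edges$child_feature_id)
  hyd <- edges[edges$child_feature_id == "hydroxy", ]
  expect_identical(hyd$rule, "hydroxylation")
  expect_equal(hyd$delta_mz, 256.1099 - 240.1150, tolerance = 1e-9)
  expect_lt(abs(hyd$ppm_error_of_delta), 3)
  # delta matching no rule: no edge
  expect_false("unmatched" %in% edges$child_feature_id)
})

test_that("adduct/isotope deltas match in both directions, chemistry signed", {
  rules <- transformationRules()
  parentMz <- 300
  # 13C spacing below and above the parent both match
  assoc <- data.frame(feature_id = c("up", "down"),
                      mz = c(300 + 1.003355, 300 - 1.003355),
                      rt = 60, r = 0.9)
  edges <- massShiftEdges(parentMz, assoc, rules)
  expect_setequal(edges$child_feature_id, c("up", "down"))
  # glucuronidation only adds mass: a child below the parent cannot match
  assocNeg <- data.frame(feature_id = "below",
                         mz = 300 - 176.03209, rt = 60, r = 0.9)
  e2 <- massShiftEdges(parentMz, assocNeg, rules)
  expect_false("glucuronidation" %in% e2$rule)
})

test_that("edge pruning is monotone in both thresholds", {
  set.seed(24)
  n <- 40
  parent <- rlnorm(n, 12, 1)
  mzs <- c(240.1150, 240.1150 + 15.99491, 240.1150 + 176.03209,
           240.1150 + 79.95681)
  m <- rbind(p = parent,
             a = parent * exp(rnorm(n, 0, 0.3)),
             b = parent * exp(rnorm(n, 0, 0.8)),
             c = parent * exp(rnorm(n, 0, 1.5)))
  colnames(m) <- sprintf("S%03d", seq_len(n))
  tab <- cohortTable(m, mz = mzs)
  edgesAt <- function(rThr, ppm) {
    a <- associate(tab, "p", rThreshold = rThr)
    if (!nrow(a)) return(character(0))
    massShiftEdges(mzs[1], a, ppmTol = ppm)$child_feature_id
  }
  base <- edgesAt(0.2, 3)
  expect_true(all(edgesAt(0.5, 3) %in% base))
  expect_true(all(edgesAt(0.2, 1) %in% base))
  expect_true(all(edgesAt(0.8, 0.5) %in% edgesAt(0.5, 1)))
})

test_that("network building yields per-parent stars with attributes", {
  set.seed(25)
  n <- 60
  p1 <- rlnorm(n, 12, 1); p2 <- rlnorm(n, 12, 1)
  m <- rbind(p1 = p1, m1 = p1 * exp(rnorm(n, 0, 0.2)),
             p2 = p2, m2 = p2 * exp(rnorm(n, 0, 0.2)))
  colnames(m) <- sprintf("S%03d", seq_len(n))
  tab <- cohortTable(m, mz = c(240.1150, 256.1099, 152.0706, 328.1026))
  parents <- data.frame(feature_id = c("p1", "p2"),
                        name = c("bupropion", "acetaminophen"))
  g <- buildNetwork(tab, parents)
  comp <- igraph::components(g)
  expect_equal(comp$no, 2)
  # each component contains its parent
  memb <- comp$membership
  expect_false(memb[["p1"]] == memb[["p2"]])
  expect_identical(memb[["p1"]], memb[["m1"]])
  expect_identical(memb[["p2"]], memb[["m2"]])
  expect_identical(igraph::E(g)$rule,
                   c("hydroxylation", "glucuronidation"))

  expect_error(buildNetwork(tab, data.frame(feature_id = "nope",
                                            name = "x")), "absent")
})

test_that("a metabolite shared by two parents is flagged ambiguous", {
  set.seed(26)
  n <- 60
  shared <- rlnorm(n, 12, 0.5)
  m <- rbind(p1 = shared * exp(rnorm(n, 0, 0.05)),
             p2 = shared * exp(rnorm(n, 0, 0.05)),
             mx = shared * exp(rnorm(n, 0, 0.05)))
  colnames(m) <- sprintf("S%03d", seq_len(n))
  # both parents sit one hydroxylation below the shared child
  tab <- cohortTable(m, mz = c(240.1150, 240.1150, 256.1099))
  parents <- data.frame(feature_id = c("p1", "p2"), name = c("a", "b"))
  g <- buildNetwork(tab, parents)
  expect_equal(igraph::components(g)$no, 1)
  anno <- igraph::V(g)$annotation[igraph::V(g)$name == "mx"]
  expect_match(anno, "ambiguous")
})

test_that("network export writes GraphML and edge CSV", {
  set.seed(27)
  n <- 30
  p <- rlnorm(n, 12, 1)
  m <- rbind(p = p, c = p * exp(rnorm(n, 0, 0.2)))
  colnames(m) <- sprintf("S%03d", seq_len(n))
  tab <- cohortTable(m, mz = c(240.1150, 256.1099))
  g <- buildNetwork(tab, data.frame(feature_id = "p", name = "bupropion"))
  gml <- tempfile(fileext = ".graphml"); csv <- tempfile(fileext = ".csv")
  el <- writeNetwork(g, gml, csv)
  expect_true(file.exists(gml))
  expect_match(readLines(gml, n = 2)[2], "graphml", fixed = TRUE)
  back <- read.csv(csv)
  expect_identical(nrow(back), nrow(el))
  expect_true("rule" %in% colnames(back))
})
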