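#' Associate features with a parent xenobiotic across samples
#'
#' Scores every feature's association with a parent feature's intensity
#' profile across samples (missing intensities treated as 0). Two scores
#' are offered: plain Pearson correlation, and `"pls1"`, a one-component
#' partial-least-squares score for a single parent response — the weight
#' vector is proportional to the feature-parent covariances, and each
#' feature's association is its correlation with the first latent
#' variable. For a single response the PLS-derived ordering coincides
#' with Pearson up to scaling; both are exposed because metabolome-wide
#' association tools in this field report the PLS variant.
#'
#' @param x a [XenoFeatureTable-class] (>= 3 samples).
#' @param parentFeatureId feature id of the parent compound; its
#'   intensity must vary across samples.
#' @param method `"pearson"` (default) or `"pls1"`.
#' @param rThreshold association threshold (default 0.4); features with
#'   `|r|` strictly above it are returned.
#' @return `data.frame` with columns `feature_id`, `mz`, `rt`, `r`,
#'   sorted by decreasing `|r|`; the parent itself is excluded.
#' @export
associate <- function(x, parentFeatureId, method = c("pearson", "pls1"),
                      rThreshold = 0.4) {
  method <- match.arg(method)
  m <- intensityMatrix(x)
  if (!parentFeatureId %in% rownames(m))
    stop("parent feature '", parentFeatureId, "' not in the table")
  if (ncol(m) < 3L) stop("need at least 3 samples")
  m[is.na(m)] <- 0
  y <- m[parentFeatureId, ]
  if (stats::sd(y) == 0) stop("parent feature has zero intensity variance")
  X <- m[setdiff(rownames(m), parentFeatureId), , drop = FALSE]
  r <- if (method == "pearson") {
    apply(X, 1L, function(v) if (stats::sd(v) == 0) NA_real_ else
      stats::cor(v, y))
  } else {
    # one-component PLS on autoscaled data: w ~ Z'y, t = Zw,
    # score = cor(x_j, t); with a single response the weights are the
    # feature-response correlations, so the ordering tracks Pearson
    sds <- apply(X, 1L, stats::sd)
    Z <- (X - rowMeans(X)) / ifelse(sds == 0, 1, sds)
    yc <- (y - mean(y)) / stats::sd(y)
    w <- as.numeric(Z %*% yc)
    Xc <- Z
    if (all(w == 0)) rep(NA_real_, nrow(X)) else {
      w <- w / sqrt(sum(w^2))
      tt <- as.numeric(t(Xc) %*% w)
      apply(X, 1L, function(v) if (stats::sd(v) == 0) NA_real_ else
        stats::cor(v, tt))
    }
  }
  keep <- which(!is.na(r) & abs(r) > rThreshold)
  out <- data.frame(feature_id = rownames(X)[keep],
                    mz = unname(featureMz(x)[rownames(X)[keep]]),
                    rt = unname(featureRt(x)[rownames(X)[keep]]),
                    r = unname(r[keep]), stringsAsFactors = FALSE)
  out[order(-abs(out$r)), , drop = FALSE]
}

#' Mass-difference filter: turn associations into biotransformation edges
#'
#' Applies the reaction-based mass-difference filter to parent-associated
#' features: the observed mass shift (child m/z minus parent m/z) is
#' compared against every rule's mass delta, and an edge is kept only
#' when a rule matches within `ppmTol` ppm (evaluated on the child m/z).
#' Sign policy follows chemical directionality: phase I/II rule deltas
#' are matched as signed (conjugations only add mass, dealkylations only
#' remove it), while `adduct/isotope` deltas (isotopologue spacing,
#' adduct exchange) are matched in both directions.
#'
#' @param parentMz m/z of the parent feature.
#' @param associated result of [associate()].
#' @param rules rule table (see [transformationRules()]).
#' @param ppmTol delta-match tolerance in ppm on the child m/z
#'   (default 3).
#' @param maxAbsDelta ignore shifts larger than this (Da; default `Inf`).
#' @return `data.frame` of edges: `child_feature_id`, `child_mz`, `r`,
#'   `delta_mz`, `rule`, `rule_phase`, `ppm_error_of_delta`.
#' @export
massShiftEdges <- function(parentMz, associated,
                           rules = transformationRules(), ppmTol = 3,
                           maxAbsDelta = Inf) {
  out <- list()
  for (i in seq_len(nrow(associated))) {
    childMz <- associated$mz[i]
    delta <- childMz - parentMz
    if (abs(delta) > maxAbsDelta) next
    for (j in seq_len(nrow(rules))) {
      signs <- if (rules$phase[j] == "adduct/isotope") c(1, -1) else 1
      for (s in signs) {
        expChild <- parentMz + s * rules$mass_delta[j]
        ppm <- ppmError(childMz, expChild)
        if (abs(ppm) <= ppmTol) {
          out[[length(out) + 1L]] <- data.frame(
            child_feature_id = associated$feature_id[i],
            child_mz = childMz, r = associated$r[i], delta_mz = delta,
            rule = rules$name[j], rule_phase = rules$phase[j],
            ppm_error_of_delta = ppm, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(child_feature_id = character(0), child_mz = numeric(0),
                      r = numeric(0), delta_mz = numeric(0),
                      rule = character(0), rule_phase = character(0),
                      ppm_error_of_delta = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build a reaction-based biotransformation network
#'
#' For each parent xenobiotic feature, associates features across samples
#' ([associate()]) and keeps mass-shift-matching edges
#' ([massShiftEdges()]); the per-parent stars are united into one graph.
#' Nodes carry m/z, RT and an annotation (parent name or matched rule);
#' edges carry the rule name and association score. Features reached from
#' more than one parent are flagged ambiguous.
#'
#' @param x a [XenoFeatureTable-class].
#' @param parents `data.frame` with columns `feature_id`, `name` mapping
#'   parent features to compound names; every id must be in the table.
#' @param rules rule table.
#' @param rThreshold association threshold (default 0.4).
#' @param ppmTol delta tolerance in ppm (default 3).
#' @param method association method (see [associate()]).
#' @param maxAbsDelta largest delta considered (Da).
#' @return an [igraph::igraph] graph; also carries a
#'   `components` attribute summary accessible via
#'   [igraph::components()].
#' @export
buildNetwork <- function(x, parents, rules = transformationRules(),
                         rThreshold = 0.4, ppmTol = 3,
                         method = "pearson", maxAbsDelta = Inf) {
  missing <- setdiff(parents$feature_id, rownames(x))
  if (length(missing))
    stop("parent feature(s) absent from table: ",
         paste(missing, collapse = ", "))
  mz <- featureMz(x); rt <- featureRt(x)
  edges <- list()
  for (i in seq_len(nrow(parents))) {
    pid <- parents$feature_id[i]
    assoc <- associate(x, pid, method = method, rThreshold = rThreshold)
    if (!nrow(assoc)) next
    es <- massShiftEdges(mz[[pid]], assoc, rules = rules, ppmTol = ppmTol,
                         maxAbsDelta = maxAbsDelta)
    if (!nrow(es)) next
    es$parent_feature_id <- pid
    es$parent_name <- parents$name[i]
    edges[[length(edges) + 1L]] <- es
  }
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, nrow(parents),
                            name = parents$feature_id,
                            mz = unname(mz[parents$feature_id]),
                            rt = unname(rt[parents$feature_id]),
                            annotation = paste0("parent: ", parents$name),
                            is_parent = TRUE)
  if (length(edges)) {
    edges <- do.call(rbind, edges)
    childIds <- setdiff(unique(edges$child_feature_id), parents$feature_id)
    if (length(childIds)) {
      nParents <- vapply(childIds, function(id)
        length(unique(edges$parent_feature_id[edges$child_feature_id == id])),
        0L)
      anno <- vapply(childIds, function(id) {
        rules_ <- unique(edges$rule[edges$child_feature_id == id])
        paste(rules_, collapse = "|")
      }, "")
      anno[nParents > 1L] <- paste0(anno[nParents > 1L], " (ambiguous)")
      g <- igraph::add_vertices(g, length(childIds), name = childIds,
                                mz = unname(mz[childIds]),
                                rt = unname(rt[childIds]),
                                annotation = anno, is_parent = FALSE)
    }
    g <- igraph::add_edges(
      g, rbind(edges$parent_feature_id, edges$child_feature_id),
      rule = edges$rule, rule_phase = edges$rule_phase, r = edges$r,
      delta_mz = edges$delta_mz)
  }
  g
}

#' Export a biotransformation network
#'
#' @param g graph from [buildNetwork()].
#' @param graphmlPath optional GraphML output path.
#' @param edgeCsvPath optional plain edge-list CSV output path.
#' @return invisibly, the edge list `data.frame`.
#' @export
writeNetwork <- function(g, graphmlPath = NULL, edgeCsvPath = NULL) {
  el <- igraph::as_data_frame(g, what = "edges")
  if (!is.null(graphmlPath))
    igraph::write_graph(g, graphmlPath, format = "graphml")
  if (!is.null(edgeCsvPath))
    utils::write.csv(el, edgeCsvPath, row.names = FALSE)
  invisible(el)
}
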