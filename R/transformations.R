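#' Biotransformation rule table
#'
#' Loads a table of named biotransformations, each a signed element-count
#' delta written as a signed formula string (`"+O"`, `"-CH2"`, `"+C6H8O6"`,
#' `"+O+H2"`; bracketed isotopes such as `"+[13C]"` denote heavy-isotope
#' substitutions). The monoisotopic mass shift of each rule is derived from
#' the atomic-mass table, never stored.
#'
#' The default table covers common phase I reactions (hydroxylation,
#' reduction, dehydrogenation, hydration, dihydrodiol formation,
#' demethylation), phase II conjugations (methylation, glucuronidation,
#' sulfation, acetylation, glutathione conjugation) and ionization-side
#' deltas (13C isotopologue spacing, sodium adduct exchange) flagged with
#' phase `"adduct/isotope"` so that chemistry can be separated from
#' ionization artifacts downstream.
#'
#' @param path optional path to a user TSV with columns `name`, `delta`,
#'   `phase`; defaults to the table shipped with the package.
#' @return a `data.frame` with columns `name`, `delta`, `phase`,
#'   `mass_delta` (Da).
#' @examples
#' transformationRules()
#' @export
transformationRules <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "transformations.tsv", package = "xenoID",
                        mustWork = TRUE)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("name", "delta", "phase")
  if (!all(need %in% colnames(tab)))
    stop("rule table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$name))
    stop("duplicate rule names in ", path)
  tab$mass_delta <- vapply(tab$delta,
                           function(d) .deltaMass(.parseDelta(d)), 0.0,
                           USE.NAMES = FALSE)
  tab
}

# resolve a rule reference (name in `rules`, or a raw delta string)
.resolveDelta <- function(rule, rules = NULL) {
  if (!is.null(rules) && rule %in% rules$name)
    rule <- rules$delta[match(rule, rules$name)]
  .parseDelta(rule)
}

#' Apply a biotransformation to a formula
#'
#' Adds the rule's signed element delta to the formula. A transformation
#' that would drive any atom count (or labeled-atom count) negative is
#' chemically impossible for that formula and raises an error.
#'
#' @param f an [ElementalFormula-class] or formula string.
#' @param rule a rule name from `rules`, or a signed delta string such as
#'   `"+O"` or `"-CH2"`.
#' @param rules rule table used to resolve names (default
#'   [transformationRules()]).
#' @return the transformed [ElementalFormula-class].
#' @examples
#' applyTransformation("C8H10N4O2", "+O+H2")   # caffeine -> C8H12N4O3
#' @export
applyTransformation <- function(f, rule, rules = transformationRules()) {
  f <- .asFormula(f)
  delta <- .resolveDelta(rule, rules)
  counts <- as.numeric(f@counts); names(counts) <- names(f@counts)
  labels <- as.numeric(f@labels); names(labels) <- names(f@labels)
  for (el in names(delta$counts))
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0) +
      delta$counts[[el]]
  for (iso in names(delta$labels))
    labels[iso] <- (if (iso %in% names(labels)) labels[[iso]] else 0) +
      delta$labels[[iso]]
  if (any(counts < 0) || any(labels < 0))
    stop("transformation '", if (is.character(rule)) rule else "",
         "' is chemically impossible for ", formulaString(f),
         " (negative atom count)")
  counts <- counts[counts > 0]
  labels <- labels[labels > 0]
  out <- new("ElementalFormula",
             counts = setNames(as.integer(round(counts)), names(counts)),
             labels = setNames(as.integer(round(labels)), names(labels)))
  validObject(out)
  out
}

#' Enumerate rule-based biotransformation products
#'
#' Breadth-first enumeration of all distinct elemental compositions
#' reachable from a parent by up to `depth` sequential rule applications
#' (e.g. hydroxylation followed by glucuronidation at depth 2). Chemically
#' impossible branches (negative atom counts) are pruned; products are
#' deduplicated by formula, keeping the shortest chain found first. The
#' parent composition itself is not reported as a product.
#'
#' @param parent parent [ElementalFormula-class] or formula string.
#' @param rules rule table (see [transformationRules()]); by default the
#'   `adduct/isotope` rules are excluded from metabolic enumeration via
#'   `phases`.
#' @param depth maximum chain length (>= 1).
#' @param phases which rule phases to enumerate over.
#' @return a `data.frame` with columns `chain` (rule names joined by
#'   `" > "`), `formula` (canonical string), `mass` (neutral monoisotopic,
#'   Da) and `n_steps`.
#' @examples
#' p <- enumerateProducts("C10H8", depth = 2)   # naphthalene
#' subset(p, formula == "C10H8O4S")             # hydroxynaphthalene sulfate
#' @export
enumerateProducts <- function(parent, rules = transformationRules(),
                              depth = 2L, phases = c("I", "II")) {
  parent <- .asFormula(parent)
  depth <- as.integer(depth)
  if (depth < 1L) stop("depth must be >= 1")
  rules <- rules[rules$phase %in% phases, , drop = FALSE]
  parentKey <- formulaString(parent)
  seen <- new.env(parent = emptyenv())
  assign(parentKey, TRUE, envir = seen)
  frontier <- list(list(f = parent, chain = character(0)))
  out <- list()
  for (step in seq_len(depth)) {
    nxt <- list()
    for (node in frontier) {
      for (i in seq_len(nrow(rules))) {
        cand <- tryCatch(
          applyTransformation(node$f, rules$delta[i], rules = NULL),
          error = function(e) NULL)
        if (is.null(cand)) next
        key <- formulaString(cand)
        chain <- c(node$chain, rules$name[i])
        if (!exists(key, envir = seen, inherits = FALSE)) {
          assign(key, TRUE, envir = seen)
          nxt[[length(nxt) + 1L]] <- list(f = cand, chain = chain)
          out[[length(out) + 1L]] <- data.frame(
            chain = paste(chain, collapse = " > "),
            formula = key,
            mass = monoisotopicMass(cand),
            n_steps = length(chain),
            stringsAsFactors = FALSE)
        }
      }
    }
    frontier <- nxt
  }
  if (!length(out))
    return(data.frame(chain = character(0), formula = character(0),
                      mass = numeric(0), n_steps = integer(0)))
  do.call(rbind, out)
}
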