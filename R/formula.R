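#' Parse an elemental formula string
#'
#' Parses a Hill-style formula into an [ElementalFormula-class]. Heavy
#' isotopes may be written in bracket notation (`"[13C]3"`, `"[2H]3"`) or,
#' for deuterium/tritium, with the shorthand symbols `D` and `T`
#' (`"C8H9D3N4O3"`). Bracketed isotopes count toward the total atoms of the
#' corresponding light element and are recorded as substitutions.
#'
#' @param text a single formula string, e.g. `"C8H10N4O2"` (caffeine) or
#'   `"C5[13C]3H10N4O2"` (13C3-caffeine).
#' @return an [ElementalFormula-class].
#' @examples
#' parseFormula("C8H12N4O3")
#' parseFormula("C8H9D3N4O3")    # d3: three of twelve H are deuterium
#' @export
parseFormula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- gsub("[[:space:]]", "", text)
  counts <- integer(0)
  labels <- integer(0)
  pat <- "\\[([0-9]+[A-Z][a-z]?)\\]([0-9]*)|([A-Z][a-z]?)([0-9]*)"
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    m <- regexpr(pat, substr(text, pos, n), perl = TRUE)
    if (m != 1L)
      stop("cannot parse formula at '", substr(text, pos, n), "'")
    tok <- regmatches(substr(text, pos, n), m)
    grp <- regmatches(substr(text, pos, n),
                      regexec(pat, substr(text, pos, n), perl = TRUE))[[1]]
    if (nzchar(grp[2])) {               # bracketed heavy isotope
      iso <- grp[2]
      k <- if (nzchar(grp[3])) as.integer(grp[3]) else 1L
      if (!iso %in% names(.HEAVY_MASS))
        stop("unknown isotope symbol: ", iso)
      light <- .lightOf(iso)
      counts[light] <- (if (light %in% names(counts)) counts[[light]] else 0L) + k
      labels[iso] <- (if (iso %in% names(labels)) labels[[iso]] else 0L) + k
    } else {
      sym <- grp[4]
      k <- if (nzchar(grp[5])) as.integer(grp[5]) else 1L
      if (sym %in% c("D", "T")) {       # deuterium / tritium shorthand
        iso <- if (sym == "D") "2H" else "3H"
        counts["H"] <- (if ("H" %in% names(counts)) counts[["H"]] else 0L) + k
        labels[iso] <- (if (iso %in% names(labels)) labels[[iso]] else 0L) + k
      } else {
        if (!sym %in% names(.LIGHT_MASS))
          stop("unknown element symbol: ", sym)
        counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + k
      }
    }
    pos <- pos + attr(m, "match.length")
  }
  if (length(counts)) counts <- counts[order(names(counts))]
  else counts <- setNames(integer(0), character(0))
  if (length(labels)) labels <- labels[order(names(labels))]
  else labels <- setNames(integer(0), character(0))
  new("ElementalFormula", counts = counts, labels = labels)
}

#' Canonical formula string (Hill order, bracketed isotopes)
#'
#' Writes an [ElementalFormula-class] in Hill order (C first, H second,
#' remaining elements alphabetically). For a labeled element the unlabeled
#' atom count is written first, followed by the bracketed isotope count
#' (`"C5[13C]3H10N4O2"`). Round-trips through [parseFormula()].
#'
#' @param f an [ElementalFormula-class].
#' @return a single string.
#' @export
formulaString <- function(f) {
  stopifnot(is(f, "ElementalFormula"))
  cnt <- f@counts[f@counts > 0L]
  lab <- f@labels[f@labels > 0L]
  els <- names(cnt)
  ord <- if ("C" %in% els) {
    c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  } else sort(els)
  out <- character(0)
  for (el in ord) {
    iso <- names(lab)[vapply(names(lab), .lightOf, "") == el]
    nlab <- if (length(iso)) sum(lab[iso]) else 0L
    nlight <- cnt[[el]] - nlab
    if (nlight > 0L)
      out <- c(out, paste0(el, if (nlight > 1L) nlight else ""))
    for (i in iso)
      out <- c(out, paste0("[", i, "]", if (lab[[i]] > 1L) lab[[i]] else ""))
  }
  paste(out, collapse = "")
}

#' Monoisotopic mass of a formula
#'
#' Sum of atom counts times light-isotope monoisotopic masses, with each
#' heavy-isotope substitution contributing the heavy-minus-light mass
#' difference on top.
#'
#' @param f an [ElementalFormula-class], or a formula string.
#' @return neutral monoisotopic mass in Da.
#' @examples
#' monoisotopicMass("C8H12N4O3")   # 212.0909
#' @export
monoisotopicMass <- function(f) {
  f <- .asFormula(f)
  m <- 0
  if (length(f@counts))
    m <- m + sum(f@counts * .LIGHT_MASS[names(f@counts)])
  if (length(f@labels))
    m <- m + sum(f@labels * (.HEAVY_MASS[names(f@labels)] -
                             .LIGHT_MASS[.lightOf(names(f@labels))]))
  unname(m)
}

# accept strings anywhere a formula is expected
.asFormula <- function(f) {
  if (is(f, "ElementalFormula")) f else parseFormula(f)
}

# signed element/isotope delta from a string like "+O+H2", "-CH2", "+[13C]"
# returns list(counts = named numeric (signed), labels = named numeric (signed))
.parseDelta <- function(text) {
  text <- gsub("[[:space:]]", "", text)
  if (!nzchar(text)) return(list(counts = numeric(0), labels = numeric(0)))
  if (!grepl("^[+-]", text)) text <- paste0("+", text)
  m <- gregexpr("[+-][^+-]+", text, perl = TRUE)[[1]]
  segs <- regmatches(text, gregexpr("[+-][^+-]+", text, perl = TRUE))[[1]]
  if (sum(nchar(segs)) != nchar(text))
    stop("cannot parse delta formula: ", text)
  counts <- numeric(0); labels <- numeric(0)
  for (s in segs) {
    sign <- if (substr(s, 1, 1) == "+") 1 else -1
    f <- parseFormula(substr(s, 2, nchar(s)))
    for (el in names(f@counts))
      counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0) +
        sign * f@counts[[el]]
    for (iso in names(f@labels))
      labels[iso] <- (if (iso %in% names(labels)) labels[[iso]] else 0) +
        sign * f@labels[[iso]]
  }
  list(counts = counts, labels = labels)
}

# monoisotopic mass of a signed delta
.deltaMass <- function(delta) {
  m <- 0
  if (length(delta$counts))
    m <- m + sum(delta$counts * .LIGHT_MASS[names(delta$counts)])
  if (length(delta$labels))
    m <- m + sum(delta$labels * (.HEAVY_MASS[names(delta$labels)] -
                                 .LIGHT_MASS[.lightOf(names(delta$labels))]))
  unname(m)
}

#' Substitute heavy isotopes into a formula
#'
#' Returns the formula with `n` atoms of the label's light element replaced
#' by its heavy isotope. The total atom count is unchanged (substitution,
#' not addition).
#'
#' @param f an [ElementalFormula-class] or formula string.
#' @param label an [IsotopeLabel-class] (see [isotopeLabel()]).
#' @param n number of substitutions; must not exceed the available light
#'   atoms.
#' @return an [ElementalFormula-class].
#' @export
substituteLabel <- function(f, label, n) {
  f <- .asFormula(f)
  stopifnot(is(label, "IsotopeLabel"), n >= 0L)
  n <- as.integer(n)
  if (n == 0L) return(f)
  labels <- f@labels
  iso <- label@heavyIsotope
  labels[iso] <- (if (iso %in% names(labels)) labels[[iso]] else 0L) + n
  new("ElementalFormula", counts = f@counts, labels = labels)
}

setMethod("show", "ElementalFormula", function(object) {
  cat("ElementalFormula:", formulaString(object),
      sprintf("(monoisotopic %.5f Da)\n", monoisotopicMass(object)))
})
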