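#' Monoisotopic atomic masses
#'
#' Masses (Da) of the lightest stable isotope for the elements that occur
#' in small-molecule kinase-inhibitor chemistry, after the IUPAC atomic
#' mass evaluation. Elements outside this set are rejected at parse time.
#'
#' @format named numeric vector, element symbol -> monoisotopic mass in Da.
#' @export
MONOISOTOPIC_MASS <- c(
  H  = 1.00782503207,
  B  = 11.0093054,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  F  = 18.99840322,
  Si = 27.9769265325,
  P  = 30.97376163,
  S  = 31.97207100,
  Cl = 34.96885268,
  Br = 78.9183371,
  I  = 126.904473
)

# mass of a proton (H atom minus one electron), Da — the [M+H]+ adduct mass
PROTON_MASS <- 1.007276466

#' Parse a molecular formula string
#'
#' Parses element-count strings as printed in HRMS lines ("C9H11N4O") into
#' a named count vector of class `mol_formula`. An element symbol with no
#' trailing digits counts as 1; repeated symbols accumulate. Parentheses,
#' hydrates and isotope labels are not supported.
#'
#' @param text a single formula string, e.g. `"C9H11N4O"`.
#' @return a `mol_formula`: named integer vector of element counts, in
#'   Hill order (C, H, then alphabetical; fully alphabetical when no C).
#' @examples
#' parse_formula("C9H11N4O")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text)) {
    fs_stop("formula string is empty", "fragscreen_parse_error")
  }
  rx <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  toks <- regmatches(text, list(rx))[[1]]
  if (sum(attr(rx, "match.length")) != nchar(text)) {
    bad <- substr(gsub("([A-Z][a-z]?)([0-9]*)", "", text), 1, 8)
    fs_stop(sprintf("unparseable token in formula '%s': '%s'", text, bad),
            "fragscreen_parse_error")
  }
  el <- sub("[0-9]*$", "", toks)
  ns <- sub("^[A-Za-z]+", "", toks)
  n <- ifelse(nzchar(ns), suppressWarnings(as.integer(ns)), 1L)
  if (any(n == 0L)) {
    fs_stop(sprintf("zero count for element '%s' in formula '%s'",
                    el[which(n == 0L)[1]], text), "fragscreen_parse_error")
  }
  unknown <- setdiff(el, names(MONOISOTOPIC_MASS))
  if (length(unknown)) {
    fs_stop(sprintf("unknown element symbol '%s' in formula '%s'",
                    unknown[1], text), "fragscreen_parse_error")
  }
  counts <- tapply(n, el, sum)
  mol_formula(structure(as.integer(counts), names = names(counts)))
}

#' Construct a mol_formula from a named count vector
#'
#' @param counts named integer vector, element symbol -> count (> 0).
#'   Zero-count elements are dropped; an empty vector is the empty formula.
#' @return a `mol_formula` in Hill order.
#' @export
mol_formula <- function(counts = integer()) {
  counts <- counts[counts != 0]
  if (length(counts)) {
    if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
      fs_stop("counts must be named by element symbol", "fragscreen_parse_error")
    }
    unknown <- setdiff(names(counts), names(MONOISOTOPIC_MASS))
    if (length(unknown)) {
      fs_stop(sprintf("unknown element symbol '%s'", unknown[1]),
              "fragscreen_parse_error")
    }
    if (any(counts < 0)) fs_stop("negative element count", "fragscreen_parse_error")
    counts <- counts[hill_order(names(counts))]
  }
  structure(as.integer(counts), names = names(counts), class = "mol_formula")
}

# Hill convention: carbon, hydrogen, then other elements alphabetically;
# no carbon -> all elements alphabetically
hill_order <- function(els) {
  if ("C" %in% els) {
    order(match(els, c("C", "H"), nomatch = 3L), els)
  } else {
    order(els)
  }
}

#' Format a molecular formula in Hill order
#'
#' @param x a `mol_formula`.
#' @param ... unused.
#' @return formula string; counts of 1 are omitted. Empty formula -> `""`.
#' @export
format.mol_formula <- function(x, ...) {
  if (!length(x)) return("")
  paste0(names(x), ifelse(unclass(x) == 1L, "", unclass(x)), collapse = "")
}

#' @export
print.mol_formula <- function(x, ...) {
  cat("<formula> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Neutral molecule from a protonated [M+H]+ ion formula
#'
#' HRMS lines report the formula of the observed [M+H]+ ion; the neutral
#' molecule has one hydrogen fewer.
#'
#' @param ion a `mol_formula` (or formula string) for the [M+H]+ ion;
#'   must contain at least one H.
#' @return `mol_formula` of the neutral molecule.
#' @examples
#' neutral_from_protonated("C9H11N4O") # C9H10N4O
#' @export
neutral_from_protonated <- function(ion) {
  ion <- as_mol_formula(ion)
  h <- match("H", names(ion))
  if (is.na(h) || ion[[h]] < 1L) {
    fs_stop("ion formula has no H to remove: not a valid [M+H]+ adduct",
            "fragscreen_adduct_error")
  }
  counts <- unclass(ion)
  counts[h] <- counts[h] - 1L
  mol_formula(counts)
}

as_mol_formula <- function(f) {
  if (inherits(f, "mol_formula")) f else parse_formula(f)
}

#' Heavy-atom count
#'
#' Number of non-hydrogen atoms: the denominator of ligand efficiency.
#'
#' @param f a `mol_formula` or formula string.
#' @return integer count, >= 0.
#' @examples
#' heavy_atom_count("C9H10N4O") # 14
#' @export
heavy_atom_count <- function(f) {
  f <- as_mol_formula(f)
  sum(unclass(f)[names(f) != "H"])
}

#' Monoisotopic m/z of an adduct ion
#'
#' Computes the m/z of the protonated molecular ion from the neutral
#' formula: sum of monoisotopic atomic masses plus the proton mass
#' 1.007276 Da (i.e. the electron mass is subtracted from the H-atom sum,
#' the convention mass spectrometers calibrate against).
#'
#' @param neutral `mol_formula` or string for the neutral molecule. The
#'   empty formula is allowed and yields the bare-proton m/z.
#' @param adduct adduct specification; only `"+H"` is supported.
#' @param charge ion charge; only `+1` is supported.
#' @return m/z in Da (full precision; round at presentation, typically 4 dp).
#' @examples
#' monoisotopic_mz("C9H10N4O") # 191.0927...
#' @export
monoisotopic_mz <- function(neutral, adduct = "+H", charge = 1L) {
  if (!identical(adduct, "+H") || charge != 1L) {
    fs_stop(sprintf("unsupported adduct spec '%s' (charge %s)", adduct, charge),
            "fragscreen_adduct_error")
  }
  neutral <- as_mol_formula(neutral)
  sum(MONOISOTOPIC_MASS[names(neutral)] * unclass(neutral)) + PROTON_MASS
}
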