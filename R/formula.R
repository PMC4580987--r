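#' @keywords internal
#' Monoisotopic isotope masses (Da), principal isotope of each supported
#' element, CODATA/IUPAC values at 6-decimal precision.
.isotope_masses <- c(
  H  = 1.007825,
  C  = 12.000000,
  N  = 14.003074,
  O  = 15.994915,
  F  = 18.998403,
  S  = 31.972071,
  Cl = 34.968853,
  Br = 78.918338,
  Na = 22.989770,
  P  = 30.973762,
  I  = 126.904473
)

# Singly charged adduct mass shifts (Da): proton mass and Na+ (Na minus
# one electron), matching positive/negative-mode ESI conventions.
.adduct_shifts <- c(
  "[M+H]+"  = 1.007276,
  "[M+Na]+" = 22.989218,
  "[M-H]-"  = -1.007276
)

#' Construct a molecular formula from element counts
#'
#' A molecular formula is represented as a named integer vector of
#' element counts. Zero counts are dropped; element symbols must belong
#' to the supported set (H, C, N, O, F, S, Cl, Br, Na, P, I).
#'
#' @param counts named numeric vector of non-negative integer counts.
#' @return an object of class `molecular_formula`.
#' @examples
#' molecular_formula(c(C = 7, H = 7, N = 3))
#' @export
molecular_formula <- function(counts) {
  if (length(counts) == 0) {
    out <- integer(0)
    class(out) <- "molecular_formula"
    return(out)
  }
  if (is.null(names(counts)) || any(names(counts) == "")) {
    stop("element counts must be named by element symbol")
  }
  unknown <- setdiff(names(counts), names(.isotope_masses))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("element counts must be non-negative integers")
  }
  counts <- counts[counts > 0]
  # canonical order: Hill notation (C, H, then alphabetical)
  out <- as.integer(counts[.hill_order(names(counts))])
  names(out) <- .hill_order(names(counts))
  class(out) <- "molecular_formula"
  out
}

.hill_order <- function(symbols) {
  rest <- sort(setdiff(symbols, c("C", "H")))
  c(intersect(c("C", "H"), symbols), rest)
}

#' Parse a Hill-notation molecular formula string
#'
#' @param text formula string such as `"C13H12N4O2"`. Implicit counts
#'   of 1 are allowed (`"CH4"`).
#' @return a `molecular_formula`.
#' @examples
#' parse_formula("C7H7N3")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text) || nchar(text) == 0) {
    stop("formula string must be a single non-empty string")
  }
  tokens <- gregexpr("([A-Z][a-z]?)([0-9]*)", text, perl = TRUE)[[1]]
  matched <- regmatches(text, gregexpr("([A-Z][a-z]?)([0-9]*)", text, perl = TRUE))[[1]]
  if (sum(nchar(matched)) != nchar(text)) {
    stop("unknown element or invalid token in formula: ", text)
  }
  syms <- sub("[0-9]*$", "", matched)
  cnts <- sub("^[A-Za-z]+", "", matched)
  cnts <- ifelse(cnts == "", 1L, as.integer(cnts))
  unknown <- setdiff(syms, names(.isotope_masses))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unique(unknown), collapse = ", "))
  }
  counts <- tapply(cnts, syms, sum)
  molecular_formula(stats::setNames(as.numeric(counts), names(counts)))
}

#' Format a molecular formula in Hill notation
#'
#' @param f a `molecular_formula`.
#' @return a single string; the empty formula formats as `""`.
#' @export
format_formula <- function(f) {
  stopifnot(inherits(f, "molecular_formula"))
  if (length(f) == 0) return("")
  paste0(names(f), ifelse(unclass(f) == 1L, "", unclass(f)), collapse = "")
}

#' @export
print.molecular_formula <- function(x, ...) {
  cat("<molecular_formula> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.molecular_formula <- function(x, ...) format_formula(x)

#' Element-wise sum of two molecular formulas
#'
#' Implements atom conservation of the Huisgen cycloaddition: the
#' triazole product's formula is the sum of the azide and alkyne
#' formulas.
#'
#' @param a,b `molecular_formula` objects.
#' @return a `molecular_formula`.
#' @export
add_formulas <- function(a, b) {
  stopifnot(inherits(a, "molecular_formula"), inherits(b, "molecular_formula"))
  syms <- union(names(a), names(b))
  counts <- vapply(syms, function(s) {
    sum(unclass(a)[s], unclass(b)[s], na.rm = TRUE)
  }, numeric(1))
  molecular_formula(counts)
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of count times the tabulated monoisotopic isotope mass of each
#' element. The empty formula has mass 0.
#'
#' @param f a `molecular_formula` (or a formula string, parsed first).
#' @return mass in Da.
#' @examples
#' monoisotopic_mass(parse_formula("H2O"))  # 18.010565
#' @export
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  stopifnot(inherits(f, "molecular_formula"))
  if (length(f) == 0) return(0)
  sum(unclass(f) * .isotope_masses[names(f)])
}

#' m/z of a singly charged adduct
#'
#' @param mass neutral monoisotopic mass in Da (> 0).
#' @param adduct one of `"[M+H]+"`, `"[M+Na]+"`, `"[M-H]-"`.
#' @return m/z in Th.
#' @examples
#' adduct_mz(235.110947, "[M+H]+")
#' @export
adduct_mz <- function(mass, adduct = "[M+H]+") {
  if (!is.numeric(mass) || any(mass <= 0)) {
    stop("neutral mass must be positive")
  }
  adduct <- gsub("−", "-", adduct)  # tolerate unicode minus
  if (!all(adduct %in% names(.adduct_shifts))) {
    stop("unknown adduct: ", paste(setdiff(adduct, names(.adduct_shifts)), collapse = ", "))
  }
  mass + .adduct_shifts[adduct][[1]]
}

#' Supported element symbols
#' @return character vector of element symbols with tabulated masses.
#' @export
supported_elements <- function() names(.isotope_masses)
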