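#' Enumerate the virtual click-product library
#'
#' Forms the full cross product of azides x alkynes x regiochemistries.
#' The uncatalyzed Huisgen cycloaddition yields both the 1,4- and the
#' 1,5-triazole; the two regioisomers of a pair share a molecular
#' formula (atom conservation) and hence an exact mass, so a 2 x 90
#' library with both regiochemistries enumerates 360 products.
#'
#' @param azides a `reagent_table` (or subset) with role `"azide"`.
#' @param alkynes a `reagent_table` (or subset) with role `"alkyne"`.
#' @param regiochemistries character subset of `c("1,4", "1,5")`.
#' @param adduct adduct used for the `mz` column (default `"[M+H]+"`).
#' @return a data.frame of class `product_library` with columns
#'   `azide_id, alkyne_id, regio, formula, mono_mass, mz`, plus the
#'   attribute `mass_order` (permutation sorting `mono_mass` ascending).
#' @examples
#' lib <- synthetic_reagent_library()
#' prods <- enumerate_products(lib[lib$role == "azide", ],
#'                             lib[lib$role == "alkyne", ])
#' nrow(prods)  # 360
#' @export
enumerate_products <- function(azides, alkynes,
                               regiochemistries = c("1,4", "1,5"),
                               adduct = "[M+H]+") {
  if (any(azides$role != "azide")) stop("azides table contains non-azide roles")
  if (any(alkynes$role != "alkyne")) stop("alkynes table contains non-alkyne roles")
  if (anyDuplicated(c(azides$id, alkynes$id))) {
    stop("duplicate reagent id(s) across the supplied tables")
  }
  regiochemistries <- unique(as.character(regiochemistries))
  if (!all(regiochemistries %in% c("1,4", "1,5")) || length(regiochemistries) == 0) {
    stop("regiochemistries must be a non-empty subset of {'1,4','1,5'}")
  }
  az_f <- lapply(azides$formula, parse_formula)
  al_f <- lapply(alkynes$formula, parse_formula)
  grid <- expand.grid(
    ai = seq_len(nrow(azides)), ki = seq_len(nrow(alkynes)),
    regio = regiochemistries,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  pf <- mapply(function(a, k) format_formula(add_formulas(az_f[[a]], al_f[[k]])),
               grid$ai, grid$ki)
  mono <- vapply(pf, monoisotopic_mass, numeric(1), USE.NAMES = FALSE)
  out <- data.frame(
    azide_id = azides$id[grid$ai],
    alkyne_id = alkynes$id[grid$ki],
    regio = grid$regio,
    formula = pf,
    mono_mass = mono,
    mz = vapply(mono, adduct_mz, numeric(1), adduct = adduct),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "adduct") <- adduct
  attr(out, "mass_order") <- order(out$mono_mass)
  class(out) <- c("product_library", "data.frame")
  out
}

#' Product key strings `azide|alkyne|regio`
#' @param products a `product_library` or compatible data.frame.
#' @return character vector of keys.
#' @export
product_key <- function(products) {
  paste(products$azide_id, products$alkyne_id, products$regio, sep = "|")
}
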