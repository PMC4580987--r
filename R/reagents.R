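#' Build a reagent table
#'
#' Reagents are the building blocks of the in-situ click screen: azide
#' warheads (zinc-binding hydroxamates carrying the azide) and alkyne
#' fragments. Each carries a molecular formula and free-text SAR tags
#' (e.g. linker chemistry, head group).
#'
#' @param id character vector of unique reagent ids.
#' @param role `"azide"` or `"alkyne"`, recycled.
#' @param formula Hill-notation formula strings.
#' @param sar_tags list of character vectors (or `;`-separated strings).
#' @param display_name optional display names (default `id`).
#' @return a data.frame of class `reagent_table` with columns
#'   `id, role, formula, display_name, sar_tags` (tags `;`-separated).
#' @export
reagent_table <- function(id, role, formula, sar_tags = "", display_name = id) {
  id <- as.character(id)
  if (anyDuplicated(id)) {
    stop("duplicate reagent id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  role <- rep_len(as.character(role), length(id))
  if (!all(role %in% c("azide", "alkyne"))) {
    stop("role must be 'azide' or 'alkyne'")
  }
  formula <- rep_len(as.character(formula), length(id))
  # validate formulas eagerly so errors name the offending reagent
  for (i in seq_along(formula)) {
    tryCatch(parse_formula(formula[i]), error = function(e) {
      stop("reagent '", id[i], "': ", conditionMessage(e), call. = FALSE)
    })
  }
  if (is.list(sar_tags)) {
    sar_tags <- vapply(sar_tags, paste, character(1), collapse = ";")
  }
  sar_tags <- rep_len(as.character(sar_tags), length(id))
  out <- data.frame(
    id = id, role = role, formula = formula,
    display_name = rep_len(as.character(display_name), length(id)),
    sar_tags = sar_tags, stringsAsFactors = FALSE
  )
  class(out) <- c("reagent_table", "data.frame")
  out
}

#' Read a reagent library CSV
#'
#' Expected columns: `id,role,formula,display_name,sar_tags` with tags
#' `;`-separated; `display_name` and `sar_tags` optional.
#'
#' @param path CSV file path.
#' @return a `reagent_table`.
#' @export
read_reagent_library <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "role", "formula")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("reagent CSV missing column(s): ", paste(missing, collapse = ", "))
  }
  reagent_table(
    id = df$id, role = df$role, formula = df$formula,
    sar_tags = if ("sar_tags" %in% names(df)) df$sar_tags else "",
    display_name = if ("display_name" %in% names(df)) df$display_name else df$id
  )
}

#' Split the `;`-separated SAR tag field into a list
#' @param reagents a `reagent_table`.
#' @return named list (by reagent id) of character tag vectors.
#' @export
sar_tag_list <- function(reagents) {
  tags <- strsplit(reagents$sar_tags, ";", fixed = TRUE)
  tags <- lapply(tags, function(x) x[nzchar(x)])
  stats::setNames(tags, reagents$id)
}

#' Synthetic reagent library for a 2-azide x 90-alkyne campaign
#'
#' The published screen used two azide-bearing hydroxamate warheads and
#' ninety diverse alkynes whose individual structures live in
#' supplementary material; this generator produces a *synthetic,
#' non-literal* stand-in library with the same shape and the same SAR
#' vocabulary (naphthyl vs phenyl warhead; amide/sulfonamide/ether/alkyl
#' linkers; cycloalkyl/phenyl/heteroaryl/alkyl head groups) so that the
#' full pipeline can be exercised end to end.
#'
#' Alkyne formulas are composed from a propargyl core plus linker and
#' head-group increments, giving chemically plausible compositions in
#' the 100-350 Da range. The library is deterministic (no RNG).
#'
#' @param n_alkynes number of alkynes (default 90).
#' @return a `reagent_table` with 2 azides and `n_alkynes` alkynes.
#' @export
synthetic_reagent_library <- function(n_alkynes = 90) {
  azides <- reagent_table(
    id = c("AZ1", "AZ2"),
    role = "azide",
    formula = c("C14H13N5O2", "C10H11N5O2"),
    sar_tags = list(c("naphthyl"), c("phenyl")),
    display_name = c("naphthyl hydroxamate azide (synthetic)",
                     "phenyl hydroxamate azide (synthetic)")
  )
  linkers <- c(amide_linker = "C2H3NO", sulfonamide_linker = "CH3NO2S",
               ether_linker = "CH2O", alkyl_linker = "C2H4")
  heads <- c(cycloalkyl = "C6H11", phenyl = "C6H5",
             heteroaryl = "C5H4N", alkyl = "C4H9")
  core <- parse_formula("C3H3")  # propargyl core, one open valence each side
  idx <- seq_len(n_alkynes)
  linker_i <- ((idx - 1L) %% length(linkers)) + 1L
  head_i <- (((idx - 1L) %/% length(linkers)) %% length(heads)) + 1L
  # a small homologation so formulas are not all degenerate
  ch2_n <- ((idx - 1L) %/% (length(linkers) * length(heads)))
  formulas <- vapply(idx, function(i) {
    f <- add_formulas(core, parse_formula(linkers[linker_i[i]]))
    f <- add_formulas(f, parse_formula(heads[head_i[i]]))
    if (ch2_n[i] > 0) {
      f <- add_formulas(f, molecular_formula(c(C = ch2_n[i], H = 2 * ch2_n[i])))
    }
    format_formula(f)
  }, character(1))
  alkynes <- reagent_table(
    id = sprintf("ALK%02d", idx),
    role = "alkyne",
    formula = formulas,
    sar_tags = lapply(idx, function(i) {
      c(names(linkers)[linker_i[i]], names(heads)[head_i[i]])
    }),
    display_name = sprintf("alkyne %02d (%s/%s; synthetic)", idx,
                           names(linkers)[linker_i], names(heads)[head_i])
  )
  out <- rbind(azides, alkynes)
  class(out) <- c("reagent_table", "data.frame")
  out
}
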