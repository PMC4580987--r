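# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the isotope table is re-derived from
# high-precision isotope masses, the 4PL oracle is a grid search, and the
# mixture oracle is plain linear algebra.

# High-precision monoisotopic isotope masses (independent of the package's
# 6-decimal table).
oracle_isotopes <- c(
  H = 1.0078250319, C = 12.0, N = 14.0030740052, O = 15.9949146221,
  F = 18.9984031627, S = 31.97207069, Cl = 34.96885271, Br = 78.9183376,
  Na = 22.98976928, P = 30.97376151, I = 126.904473
)

# Atom-count x isotope-mass sum from a Hill-notation string, via an
# independent tokenizer.
oracle_mass <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE)
  toks <- regmatches(formula, m)[[1]]
  syms <- sub("[0-9]*$", "", toks)
  cnts <- as.numeric(ifelse(sub("^[A-Za-z]+", "", toks) == "",
                            1, sub("^[A-Za-z]+", "", toks)))
  sum(cnts * oracle_isotopes[syms])
}

# Random plausible formula string for property tests.
random_formula <- function() {
  els <- sample(names(oracle_isotopes), sample(2:5, 1))
  paste0(els, sample(1:12, length(els), replace = TRUE), collapse = "")
}

# Grid-search 4PL oracle: coarse-to-fine search over (A, B, logC, D),
# independent of any derivative-based optimizer.
oracle_4pl_grid <- function(conc, resp, refine = 3) {
  sse <- function(A, B, logC, D) {
    sum((resp - (A + B / (1 + (10^logC / conc)^D)))^2)
  }
  Ag <- seq(-10, 20, length.out = 7)
  Bg <- seq(50, 150, length.out = 11)
  Cg <- seq(log10(min(conc)), log10(max(conc)), length.out = 25)
  Dg <- seq(0.5, 3, length.out = 11)
  best <- c(A = 0, B = 100, logC = mean(Cg), D = 1); best_sse <- Inf
  for (r in seq_len(refine)) {
    for (A in Ag) for (B in Bg) for (lC in Cg) for (D in Dg) {
      s <- sse(A, B, lC, D)
      if (s < best_sse) { best_sse <- s; best <- c(A = A, B = B, logC = lC, D = D) }
    }
    span <- function(g) diff(range(g)) / (length(g) - 1)
    Ag <- seq(best["A"] - span(Ag), best["A"] + span(Ag), length.out = 7)
    Bg <- seq(best["B"] - span(Bg), best["B"] + span(Bg), length.out = 7)
    Cg <- seq(best["logC"] - span(Cg), best["logC"] + span(Cg), length.out = 9)
    Dg <- seq(best["D"] - span(Dg), best["D"] + span(Dg), length.out = 7)
  }
  list(A = unname(best["A"]), B = unname(best["B"]),
       C = unname(10^best["logC"]), D = unname(best["D"]), sse = best_sse)
}

# Small campaign fixture shared by simulator/deconvolution tests.
make_campaign <- function(n_alkynes = 90, rows = 9, cols = 10) {
  lib <- synthetic_reagent_library(n_alkynes)
  azides <- lib[lib$role == "azide", ]
  alkynes <- lib[lib$role == "alkyne", ]
  design <- build_grid_design(alkynes$id, rows, cols)
  products <- enumerate_products(azides, alkynes)
  list(lib = lib, azides = azides, alkynes = alkynes,
       design = design, products = products)
}
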