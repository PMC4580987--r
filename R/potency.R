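#' Percent inhibition from raw assay signals
#'
#' Scales a raw signal between the vehicle (0% inhibition) and the
#' full-inhibition reference control (100%; e.g. 2 mM EDTA for a zinc
#' metalloprotease).
#'
#' @param signal raw signal(s).
#' @param vehicle_signal vehicle (uninhibited) control signal.
#' @param full_inhibition_signal full-inhibition control signal.
#' @return percent inhibition (vectorized over `signal`).
#' @export
percent_inhibition <- function(signal, vehicle_signal, full_inhibition_signal) {
  if (!is.finite(vehicle_signal) || !is.finite(full_inhibition_signal) ||
      vehicle_signal == full_inhibition_signal) {
    stop("degenerate controls: vehicle and full-inhibition signals must differ")
  }
  100 * (vehicle_signal - signal) / (vehicle_signal - full_inhibition_signal)
}

#' Four-parameter logistic dose-response model
#'
#' The increasing 4PL `y = A + B / (1 + (C/x)^D)` with A the minimum
#' response, B the response range, C the IC50 and D the slope factor.
#'
#' @param x concentration(s), M.
#' @param A,B,C,D model parameters.
#' @return response (% inhibition scale).
#' @export
fourpl <- function(x, A, B, C, D) A + B / (1 + (C / x)^D)

#' Fit a four-parameter logistic dose-response curve
#'
#' Nonlinear least squares on the increasing 4PL, fitted on log10(C)
#' internally for stability. Defaults: start at A = min response,
#' B = range, C = geometric mean concentration, D = 1; bounds
#' A in [-20, 50], B in [0, 200], D in [0.3, 5] (robust for percent
#' inhibition data). Curves whose top response never reaches 50% at the
#' highest tested concentration are flagged censored (`"> max conc"`)
#' and carry no finite IC50.
#'
#' @param conc_M concentrations, M (> 0, >= 4 distinct values; the
#'   assays this models used 8-point curves).
#' @param response_pct percent inhibition at each concentration.
#' @param init optional named list overriding starting values
#'   (`A, B, C, D`).
#' @param bounds optional list with `lower`/`upper` named vectors over
#'   `A, B, logC, D`.
#' @return list of class `fit_4pl`: `A, B, C, D`, `rss`, `converged`,
#'   `censored` (logical), `censor_limit` (max tested conc when
#'   censored), `fitted`, `data`.
#' @export
fit_4pl <- function(conc_M, response_pct, init = NULL, bounds = NULL) {
  if (any(conc_M <= 0)) stop("concentrations must be positive")
  if (length(unique(conc_M)) < 4) {
    stop("need at least 4 distinct concentrations to fit a 4PL")
  }
  df <- data.frame(x = conc_M, y = response_pct)
  start <- list(A = min(df$y), B = max(df$y) - min(df$y),
                logC = log10(exp(mean(log(conc_M)))), D = 1)
  if (!is.null(init)) {
    for (nm in intersect(names(init), c("A", "B", "D"))) start[[nm]] <- init[[nm]]
    if ("C" %in% names(init)) start$logC <- log10(init$C)
  }
  lower <- c(A = -20, B = 0, logC = log10(min(conc_M)) - 3, D = 0.3)
  upper <- c(A = 50, B = 200, logC = log10(max(conc_M)) + 3, D = 5)
  if (!is.null(bounds)) {
    if (!is.null(bounds$lower)) lower[names(bounds$lower)] <- bounds$lower
    if (!is.null(bounds$upper)) upper[names(bounds$upper)] <- bounds$upper
  }
  start$A <- min(max(start$A, lower["A"]), upper["A"])
  start$B <- min(max(start$B, lower["B"]), upper["B"])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A + B / (1 + (10^logC / x)^D),
      data = df, start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  top_observed <- max(response_pct[conc_M == max(conc_M)])
  censored <- top_observed < 50
  if (is.null(fit)) {
    out <- list(A = NA_real_, B = NA_real_, C = NA_real_, D = NA_real_,
                rss = NA_real_, converged = FALSE, censored = censored,
                censor_limit = if (censored) max(conc_M) else NA_real_,
                fitted = NULL, data = df)
    class(out) <- "fit_4pl"
    return(out)
  }
  cf <- stats::coef(fit)
  out <- list(
    A = unname(cf["A"]), B = unname(cf["B"]), C = unname(10^cf["logC"]),
    D = unname(cf["D"]),
    rss = sum(stats::residuals(fit)^2),
    converged = TRUE,
    censored = censored,
    censor_limit = if (censored) max(conc_M) else NA_real_,
    fitted = stats::fitted(fit), data = df
  )
  if (censored) out$C <- NA_real_
  class(out) <- "fit_4pl"
  out
}

#' @export
print.fit_4pl <- function(x, ...) {
  if (x$censored) {
    cat("<fit_4pl> censored: IC50 > ", format(x$censor_limit, digits = 3),
        " M (top response < 50%)\n", sep = "")
  } else if (!x$converged) {
    cat("<fit_4pl> did not converge\n")
  } else {
    cat("<fit_4pl> A=", format(x$A, digits = 3), " B=", format(x$B, digits = 3),
        " IC50=", format(x$C, digits = 4), " M  D=", format(x$D, digits = 3),
        " rss=", format(x$rss, digits = 3), "\n", sep = "")
  }
  invisible(x)
}

#' Cheng-Prusoff conversion of IC50 to Ki
#'
#' For a competitive inhibitor, `Ki = IC50 / (1 + [S]/Km)`. The assays
#' this models ran at `[S]/Km` of 0.35 (Abeta16-23 peptide) and 0.29
#' (insulin), so Ki and IC50 rank compounds nearly identically.
#'
#' @param ic50 IC50 in M (> 0; vectorized).
#' @param s_over_km substrate concentration over Km (>= 0).
#' @return Ki in M.
#' @examples
#' ki_cheng_prusoff(60e-9, 0.35)  # 44.4 nM
#' @export
ki_cheng_prusoff <- function(ic50, s_over_km) {
  if (any(ic50 <= 0, na.rm = TRUE)) stop("ic50 must be positive")
  if (any(s_over_km < 0)) stop("s_over_km must be non-negative")
  ic50 / (1 + s_over_km)
}

#' pIC50 from a molar IC50
#' @param ic50 IC50 in M.
#' @return `-log10(IC50 / 1 M)`.
#' @export
pic50 <- function(ic50) -log10(ic50)

#' Cross-substrate pIC50 regression
#'
#' Ordinary least squares of pIC50 measured with one substrate on
#' pIC50 measured with another, the standard check that SAR is
#' substrate-independent. Censored potencies (`"> limit"`, carried as
#' `NA`) are excluded by default.
#'
#' @param pic50_x,pic50_y paired pIC50 values (NA marks censored).
#' @param censoring `"exclude"` (drop pairs with any NA, default) or
#'   `"error"` (refuse censored input).
#' @return list `slope, intercept, r_squared, n_used`.
#' @export
regress_pic50 <- function(pic50_x, pic50_y, censoring = c("exclude", "error")) {
  censoring <- match.arg(censoring)
  keep <- is.finite(pic50_x) & is.finite(pic50_y)
  if (censoring == "error" && !all(keep)) {
    stop("censored (non-finite) pIC50 pairs present")
  }
  x <- pic50_x[keep]; y <- pic50_y[keep]
  if (length(x) < 3) stop("need at least 3 non-censored pairs")
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = suppressWarnings(summary(fit))$r.squared,
       n_used = length(x))
}
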