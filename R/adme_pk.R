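#' Linear trapezoidal area under a curve
#'
#' The single AUC implementation shared by all time-course summaries
#' (plasma concentration-time AUC, depletion AUC, glycaemia AUC).
#'
#' @param time strictly increasing time points.
#' @param value values at those times.
#' @return the linear trapezoid integral.
#' @export
auc_trapezoid <- function(time, value) {
  if (length(time) != length(value)) stop("time and value lengths differ")
  if (length(time) < 2) return(0)
  if (any(diff(time) <= 0)) stop("times must be strictly increasing")
  sum(diff(time) * (utils::head(value, -1) + utils::tail(value, -1)) / 2)
}

#' Non-compartmental pharmacokinetic analysis
#'
#' Cmax/tmax by direct maximum; AUC(0->t) by the linear trapezoid;
#' terminal rate constant lambda_z by log-linear OLS on the terminal
#' points, choosing among the candidate tails (last n >= 3 positive
#' concentrations after tmax) the one maximizing adjusted R^2;
#' `t_half = ln 2 / lambda_z` and
#' `auc_inf = auc_0_t + C_last / lambda_z`. When fewer than 3 positive
#' post-peak concentrations exist, the extrapolated quantities are
#' reported `NA` rather than fabricated.
#'
#' @param time time points, min (strictly increasing, >= 3).
#' @param conc concentrations (>= 0), any single concentration unit.
#' @return list of class `nca_result`: `cmax, tmax, auc_0_t, lambda_z,
#'   t_half, auc_inf, n_terminal_points, r2_terminal`.
#' @export
nca <- function(time, conc) {
  if (length(time) < 3) stop("need at least 3 time points")
  if (any(diff(time) <= 0)) stop("times must be strictly increasing")
  if (any(conc < 0)) stop("concentrations must be non-negative")
  cmax <- max(conc)
  tmax <- time[which.max(conc)]
  auc_0_t <- auc_trapezoid(time, conc)
  out <- list(cmax = cmax, tmax = tmax, auc_0_t = auc_0_t,
              lambda_z = NA_real_, t_half = NA_real_, auc_inf = NA_real_,
              n_terminal_points = NA_integer_, r2_terminal = NA_real_)
  post <- which(time >= tmax & conc > 0)
  if (cmax > 0 && length(post) >= 3) {
    best <- NULL
    for (n in 3:length(post)) {
      idx <- utils::tail(post, n)
      fit <- stats::lm(log(conc[idx]) ~ time[idx])
      slope <- unname(stats::coef(fit)[2])
      if (!is.finite(slope) || slope >= 0) next
      sm <- suppressWarnings(summary(fit))  # noiseless data: perfect fit
      r2a <- sm$adj.r.squared
      if (is.null(best) || r2a > best$r2a + 1e-12) {
        best <- list(lambda = -slope, n = n, r2 = sm$r.squared, r2a = r2a)
      }
    }
    if (!is.null(best)) {
      out$lambda_z <- best$lambda
      out$t_half <- log(2) / best$lambda
      out$auc_inf <- auc_0_t + conc[length(conc)] / best$lambda
      out$n_terminal_points <- best$n
      out$r2_terminal <- best$r2
    }
  }
  class(out) <- "nca_result"
  out
}

#' @export
print.nca_result <- function(x, ...) {
  cat("<nca> Cmax=", format(x$cmax, digits = 3), " at tmax=", x$tmax,
      "; AUC(0-t)=", format(x$auc_0_t, digits = 4),
      "; t1/2=", format(x$t_half, digits = 3),
      "; AUC(inf)=", format(x$auc_inf, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Microsomal substrate-depletion analysis
#'
#' First-order depletion: `k` is minus the slope of the log
#' percent-remaining versus incubation-time regression and
#' `t_half = 0.693 / k`. Intrinsic clearance follows
#' `CLint = dose / AUCinf` of the fitted exponential concentration
#' curve, normalized per mg of microsomal protein: with initial
#' concentration `dose` the fitted AUCinf is `dose / k`, so
#' `CLint = k / protein_conc`, reported in ul min^-1 mg^-1.
#'
#' @param time incubation times, min.
#' @param pct_remaining percent of compound remaining (> 0, >= 3 points).
#' @param dose initial amount/concentration in the incubation (uM;
#'   default 1).
#' @param protein_conc microsomal protein concentration, mg/ml
#'   (default 0.6).
#' @return list of class `depletion_fit`: `k` (1/min), `t_half` (min;
#'   `Inf` for a stable compound), `auc_inf`, `clint`
#'   (ul min^-1 mg^-1), `r_squared`.
#' @export
microsomal_depletion <- function(time, pct_remaining, dose = 1, protein_conc = 0.6) {
  if (length(time) < 3) stop("need at least 3 points")
  if (any(pct_remaining <= 0)) stop("percent remaining must be positive to take logs")
  fit <- stats::lm(log(pct_remaining) ~ time)
  k <- -unname(stats::coef(fit)[2])
  if (k <= .Machine$double.eps^0.5) {  # no measurable depletion
    out <- list(k = 0, t_half = Inf, auc_inf = Inf, clint = 0,
                r_squared = suppressWarnings(summary(fit))$r.squared,
                protein_conc = protein_conc)
  } else {
    auc_inf <- dose / k  # integral of dose * exp(-k t), concentration x min
    clint <- dose / auc_inf / protein_conc * 1000  # (1/min)/(mg/ml) -> ul/min/mg
    out <- list(k = k, t_half = 0.693 / k, auc_inf = auc_inf, clint = clint,
                r_squared = suppressWarnings(summary(fit))$r.squared,
                protein_conc = protein_conc)
  }
  class(out) <- "depletion_fit"
  out
}

#' @export
print.depletion_fit <- function(x, ...) {
  cat("<depletion_fit> k=", format(x$k, digits = 4), " /min; t1/2=",
      format(x$t_half, digits = 4), " min; CLint=",
      format(x$clint, digits = 4), " ul/min/mg\n", sep = "")
  invisible(x)
}

#' Plasma-stability half-life by one-phase exponential decay
#'
#' Nonlinear regression of `C = C0 * exp(-k t)`; `t_half = 0.693 / k`.
#' When the estimated half-life exceeds the observation window the
#' result is censored and reported as `"> window"` (a flat 24-h profile
#' reports `> 24 h`, the convention for fully stable compounds).
#'
#' @param time time points, min (>= 3).
#' @param conc concentrations (or percent remaining).
#' @return list of class `plasma_halflife`: `k`, `t_half` (min),
#'   `censored` (logical), `window` (max time), `label` (e.g.
#'   `">1440 min"` when censored), `converged`.
#' @export
plasma_halflife <- function(time, conc) {
  if (length(time) < 3) stop("need at least 3 points")
  window <- max(time)
  df <- data.frame(t = time, y = conc)
  c0_start <- max(conc)
  loglin_k <- {
    pos <- conc > 0
    if (sum(pos) >= 2) -unname(stats::coef(stats::lm(log(conc[pos]) ~ time[pos]))[2])
    else NA_real_
  }
  if (is.finite(loglin_k) && loglin_k <= 0) {
    # no measurable decay over the window: censored, fully stable
    out <- list(k = 0, t_half = Inf, censored = TRUE, window = window,
                label = paste0(">", format(window), " min"), converged = TRUE)
    class(out) <- "plasma_halflife"
    return(out)
  }
  k_start <- if (is.finite(loglin_k)) max(loglin_k, 1e-9) else 1e-3
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ C0 * exp(-k * t), data = df,
                      start = list(C0 = c0_start, k = k_start),
                      lower = c(C0 = 0, k = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    # fall back to the log-linear estimate, flagged as non-converged nls
    if (is.finite(loglin_k) && loglin_k > 0) {
      t_half <- 0.693 / loglin_k
      censored <- t_half > window
      out <- list(k = loglin_k, t_half = t_half, censored = censored,
                  window = window,
                  label = if (censored) paste0(">", format(window), " min")
                          else paste0(format(t_half, digits = 4), " min"),
                  converged = FALSE)
    } else {
      out <- list(k = NA_real_, t_half = NA_real_, censored = NA,
                  window = window, label = "fit failed", converged = FALSE)
    }
    class(out) <- "plasma_halflife"
    return(out)
  }
  k <- unname(stats::coef(fit)["k"])
  t_half <- if (k > 0) 0.693 / k else Inf
  censored <- !is.finite(t_half) || t_half > window
  out <- list(
    k = k, t_half = t_half, censored = censored, window = window,
    label = if (censored) paste0(">", format(window), " min")
            else paste0(format(t_half, digits = 4), " min"),
    converged = TRUE
  )
  class(out) <- "plasma_halflife"
  out
}

#' Caco-2 apparent permeability and classification
#'
#' Standard bidirectional-transport definitions:
#' `Papp = (dQ/dt) / (A * C0)` with `dQ/dt` approximated by the
#' receiver amount at the end of incubation over elapsed time, and
#' `recovery = 100 * (donor_end + receiver_end) / donor_start`.
#' Compounds are classified high/low on the apical-to-basolateral Papp
#' against 1.0e-6 cm/s.
#'
#' @param receiver_amount amount in the receiver compartment at `t_end`
#'   (nmol).
#' @param t_end incubation time, s.
#' @param area monolayer surface area, cm^2 (default 0.33, the 24-well
#'   Transwell insert).
#' @param c0_donor initial donor concentration, nmol/cm^3 (= uM).
#' @param donor_amount_end,donor_amount_start optional donor amounts
#'   for recovery.
#' @return Papp in cm/s, plus `recovery_pct` when donor amounts given
#'   (list `papp, recovery_pct`).
#' @export
caco2_papp <- function(receiver_amount, t_end, area = 0.33, c0_donor,
                       donor_amount_end = NULL, donor_amount_start = NULL) {
  if (area <= 0 || c0_donor <= 0 || t_end <= 0) {
    stop("area, c0_donor and t_end must be positive")
  }
  papp <- (receiver_amount / t_end) / (area * c0_donor)
  out <- list(papp = papp)
  if (!is.null(donor_amount_end) && !is.null(donor_amount_start)) {
    if (donor_amount_start <= 0) stop("donor_amount_start must be positive")
    out$recovery_pct <- 100 * (donor_amount_end + receiver_amount) / donor_amount_start
  }
  out
}

#' Assemble a bidirectional permeability result
#'
#' @param papp_ab apical-to-basolateral Papp, cm/s.
#' @param papp_ba basolateral-to-apical Papp, cm/s.
#' @param recovery_pct optional percent recovery.
#' @param threshold classification threshold on A->B Papp, cm/s
#'   (default 1.0e-6).
#' @return list of class `permeability_result`: `papp_ab, papp_ba,
#'   efflux_ratio, recovery_pct, classification` (`"low"`/`"high"`).
#' @export
permeability_result <- function(papp_ab, papp_ba = NA_real_,
                                recovery_pct = NA_real_, threshold = 1.0e-6) {
  efflux <- if (is.finite(papp_ab) && is.finite(papp_ba) && papp_ab > 0) {
    papp_ba / papp_ab
  } else NA_real_
  structure(
    list(papp_ab = papp_ab, papp_ba = papp_ba, efflux_ratio = efflux,
         recovery_pct = recovery_pct,
         classification = if (papp_ab > threshold) "high" else "low"),
    class = "permeability_result"
  )
}

#' Convert between mass and molar concentration units
#'
#' `ug/ml -> uM` multiplies by `1000 / molar_mass`; the inverse
#' divides. Conversions are exact inverses of each other.
#'
#' @param value concentration value(s).
#' @param from,to `"ug/ml"` or `"uM"`.
#' @param molar_mass g/mol (> 0), required when units differ.
#' @return converted value(s).
#' @export
convert_conc <- function(value, from, to, molar_mass) {
  units <- c("ug/ml", "uM")
  if (!(from %in% units) || !(to %in% units)) {
    stop("units must be 'ug/ml' or 'uM'")
  }
  if (from == to) return(value)
  if (missing(molar_mass) || is.null(molar_mass) || !is.finite(molar_mass) ||
      molar_mass <= 0) {
    stop("molar_mass (g/mol) required for unit conversion")
  }
  if (from == "ug/ml") value / molar_mass * 1000 else value * molar_mass / 1000
}
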