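#' Analytic scattering profile of a homogeneous sphere
#'
#' Normalized sphere form factor
#' `I(q) = [3 (sin(qR) - qR cos(qR)) / (qR)^3]^2` with `I(0) = 1` by
#' continuity. Serves as an analytic basis-profile generator standing
#' in for atomic-coordinate scattering calculators when exercising the
#' two-state machinery; a sphere of radius R has `Rg = sqrt(3/5) R`
#' and `Dmax = 2R`.
#'
#' @param radius sphere radius, Angstrom (> 0).
#' @param q scattering-vector grid, 1/Angstrom (strictly increasing,
#'   > 0 allowed to include very small q).
#' @return data.frame of class `scattering_profile` with columns
#'   `q, intensity` (and no `sigma`).
#' @export
sphere_profile <- function(radius, q) {
  if (radius <= 0) stop("radius must be positive")
  x <- q * radius
  amp <- ifelse(x < 1e-4,
                1 - x^2 / 10,           # series: 3(sin x - x cos x)/x^3
                3 * (sin(x) - x * cos(x)) / x^3)
  scattering_profile(q, amp^2)
}

#' Construct a scattering profile
#' @param q scattering vector, 1/Angstrom (strictly increasing).
#' @param intensity intensities.
#' @param sigma optional per-point uncertainties (> 0).
#' @return data.frame of class `scattering_profile`.
#' @export
scattering_profile <- function(q, intensity, sigma = NULL) {
  if (length(q) != length(intensity)) stop("q and intensity lengths differ")
  if (any(diff(q) <= 0)) stop("q grid must be strictly increasing")
  out <- data.frame(q = q, intensity = intensity)
  if (!is.null(sigma)) {
    if (length(sigma) != length(q)) stop("sigma length mismatch")
    if (any(sigma <= 0)) stop("sigma must be positive")
    out$sigma <- sigma
  }
  class(out) <- c("scattering_profile", "data.frame")
  out
}

#' Read a 1-D SAXS profile (3-column whitespace text)
#'
#' Columns `q I [sigma]`; `#` comment lines ignored.
#' @param path file path.
#' @return a `scattering_profile`.
#' @export
read_saxs <- function(path) {
  df <- utils::read.table(path, comment.char = "#", header = FALSE)
  if (ncol(df) < 2) stop("SAXS profile needs at least columns q and I")
  scattering_profile(df[[1]], df[[2]],
                     sigma = if (ncol(df) >= 3) df[[3]] else NULL)
}

#' Write a SAXS profile as whitespace text
#' @param profile a `scattering_profile`.
#' @param path output path.
#' @export
write_saxs <- function(profile, path) {
  cols <- c("q", "intensity", if ("sigma" %in% names(profile)) "sigma")
  utils::write.table(profile[, cols], path, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Guinier fit for the radius of gyration
#'
#' OLS of `ln I` against `q^2` over the low-q Guinier window,
#' `Rg = sqrt(-3 * slope)`. The window is chosen self-consistently:
#' starting from the full grid (or `q < q_start`), the fit is iterated,
#' trimming to `q_max * Rg <= q_rg_max`, until the window stabilizes.
#'
#' @param profile a `scattering_profile` with positive intensities in
#'   the Guinier region.
#' @param q_rg_max Guinier validity limit on `q_max * Rg`
#'   (default 1.3, the conventional globular-particle limit).
#' @param min_points minimum points in the window (default 5).
#' @param max_iter iteration cap for the window search.
#' @return list of class `guinier_result`: `rg` (Angstrom), `i0`,
#'   `q_range`, `n_points`, `r_squared`, `converged`.
#' @export
guinier_fit <- function(profile, q_rg_max = 1.3, min_points = 5, max_iter = 50) {
  q <- profile$q; I <- profile$intensity
  use <- I > 0
  q <- q[use]; I <- I[use]
  if (length(q) < min_points) stop("need at least ", min_points, " positive-intensity points")
  # start from the low-q tenth of the grid (at least min_points) so the
  # initial fit is not polluted by form-factor minima at high q
  idx <- seq_len(max(min_points, ceiling(length(q) / 10)))
  converged <- FALSE
  rg <- NA_real_; i0 <- NA_real_; r2 <- NA_real_
  for (iter in seq_len(max_iter)) {
    fit <- stats::lm(log(I[idx]) ~ I(q[idx]^2))
    slope <- unname(stats::coef(fit)[2])
    if (!is.finite(slope) || slope >= 0) break
    rg <- sqrt(-3 * slope)
    i0 <- exp(unname(stats::coef(fit)[1]))
    r2 <- suppressWarnings(summary(fit))$r.squared
    new_idx <- which(q * rg <= q_rg_max)
    if (length(new_idx) < min_points) new_idx <- seq_len(min_points)
    if (identical(new_idx, idx)) { converged <- TRUE; break }
    idx <- new_idx
  }
  structure(
    list(rg = rg, i0 = i0,
         q_range = range(q[idx]), n_points = length(idx),
         r_squared = r2, converged = converged),
    class = "guinier_result"
  )
}

#' @export
print.guinier_result <- function(x, ...) {
  cat("<guinier> Rg=", format(x$rg, digits = 4), " A; I0=",
      format(x$i0, digits = 4), "; ", x$n_points, " points, q in [",
      format(x$q_range[1], digits = 3), ", ", format(x$q_range[2], digits = 3),
      "]; converged=", x$converged, "\n", sep = "")
  invisible(x)
}

#' Two-state conformational-mixture fit of a SAXS profile
#'
#' Models the observed curve as
#' `s * [f * I_open(q) + (1 - f) * I_closed(q)]` and solves the
#' sigma-weighted least-squares problem in the two linear coefficients
#' `a = s f >= 0`, `b = s (1 - f) >= 0` in closed form (2x2 normal
#' equations with non-negativity handled on the boundary), giving
#' `fraction_open = a / (a + b)` clamped to [0, 1]. The estimate is
#' invariant to the overall scale of the observed profile.
#'
#' @param observed a `scattering_profile` (optionally with `sigma`).
#' @param basis_open,basis_closed basis `scattering_profile`s; if on a
#'   different q grid they are linearly interpolated onto the observed
#'   grid (no extrapolation: observed q must lie within both bases).
#' @return list of class `two_state_fit`: `fraction_open`, `scale`,
#'   `chi2` (sigma-weighted when sigma present, else residual sum of
#'   squares), `residuals`, `degenerate` (TRUE when the two bases are
#'   effectively identical and f is unidentifiable).
#' @export
fit_two_state <- function(observed, basis_open, basis_closed) {
  q <- observed$q
  io <- .interp_basis(basis_open, q)
  ic <- .interp_basis(basis_closed, q)
  y <- observed$intensity
  w <- if ("sigma" %in% names(observed)) 1 / observed$sigma^2 else rep(1, length(y))
  degenerate <- sqrt(sum(w * (io - ic)^2) / sum(w * (io + ic)^2 / 4)) < 1e-8
  # weighted normal equations for y ~ a*io + b*ic, a,b >= 0
  Soo <- sum(w * io * io); Scc <- sum(w * ic * ic); Soc <- sum(w * io * ic)
  Syo <- sum(w * y * io); Syc <- sum(w * y * ic)
  det <- Soo * Scc - Soc^2
  if (!degenerate && det > 0) {
    a <- (Syo * Scc - Syc * Soc) / det
    b <- (Syc * Soo - Syo * Soc) / det
  } else {
    a <- b <- -1  # force boundary handling
  }
  if (a < 0 || b < 0) {
    # best single-basis fits on the boundary of the feasible set
    a1 <- max(Syo / Soo, 0); rss1 <- sum(w * (y - a1 * io)^2)
    b1 <- max(Syc / Scc, 0); rss2 <- sum(w * (y - b1 * ic)^2)
    if (rss1 <= rss2) { a <- a1; b <- 0 } else { a <- 0; b <- b1 }
  }
  s <- a + b
  f <- if (s > 0) a / s else NA_real_
  resid <- y - (a * io + b * ic)
  structure(
    list(fraction_open = f, scale = s, chi2 = sum(w * resid^2),
         residuals = resid, degenerate = degenerate),
    class = "two_state_fit"
  )
}

.interp_basis <- function(basis, q) {
  if (length(basis$q) == length(q) && all(abs(basis$q - q) < 1e-12)) {
    return(basis$intensity)
  }
  if (min(q) < min(basis$q) - 1e-12 || max(q) > max(basis$q) + 1e-12) {
    stop("observed q range extends beyond a basis profile; extrapolation is not allowed")
  }
  stats::approx(basis$q, basis$intensity, xout = q)$y
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat("<two_state_fit> fraction open=", format(x$fraction_open, digits = 4),
      " (closed=", format(1 - x$fraction_open, digits = 4), "); scale=",
      format(x$scale, digits = 4), "; chi2=", format(x$chi2, digits = 4),
      if (x$degenerate) "; DEGENERATE bases" else "", "\n", sep = "")
  invisible(x)
}

#' Radius of gyration and Dmax of an ideal sphere
#' @param radius sphere radius, Angstrom.
#' @return list `rg = sqrt(3/5) * radius`, `dmax = 2 * radius`.
#' @export
sphere_rg <- function(radius) {
  list(rg = sqrt(3 / 5) * radius, dmax = 2 * radius)
}
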