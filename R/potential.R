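#' Surface-potential isotherm
#'
#' Ordered (area-per-lipid, Volta potential) samples recorded alongside a
#' pressure-area compression.
#'
#' @param apl area per lipid, Angstrom^2 (strictly monotone).
#' @param dv surface potential, volts.
#' @param label free-text label.
#' @return object of class `potential_isotherm` (stored in compression
#'   order, decreasing APL).
#' @export
potential_isotherm <- function(apl, dv, label = "") {
  if (length(apl) != length(dv)) abort_input("apl and dv lengths differ")
  if (any(!is.finite(dv))) abort_input("dv must be finite")
  d <- diff(apl)
  if (!(all(d > 0) || all(d < 0))) abort_input("apl must be strictly monotone")
  if (all(d > 0)) { apl <- rev(apl); dv <- rev(dv) }
  structure(data.frame(apl = apl, dv = dv), label = label,
            class = c("potential_isotherm", "data.frame"))
}

#' Apparent dipole moment curve
#'
#' mu_a = dV * A * eps0 per sample, with the molecular area converted from
#' Angstrom^2 to m^2, eps0 = 8.8541878128e-12 F/m, and the result expressed
#' in Debye (1 D = 3.33564e-30 C m). Only the vacuum-permittivity-based
#' apparent moment is computed; the monolayer's own permittivity is treated
#' as unknown.
#'
#' @param iso a [potential_isotherm()].
#' @return object of class `dipole_curve`: data.frame with `apl`
#'   (Angstrom^2) and `mu_a` (Debye).
#' @export
apparent_dipole_moment <- function(iso) {
  mu <- iso$dv * (iso$apl * 1e-20) * .EPS0 / .DEBYE
  structure(data.frame(apl = iso$apl, mu_a = mu),
            class = c("dipole_curve", "data.frame"))
}

#' Critical area of the surface-potential rise
#'
#' The sharp rise of dV during compression is located as the APL of maximum
#' |d(dV)/d(APL)| on the smoothed curve.
#'
#' @param iso a [potential_isotherm()].
#' @param window smoothing window (points) for the local-polynomial fit.
#' @param slope_tol minimum |d(dV)/dAPL| (V per Angstrom^2) for a rise to
#'   count; flat curves return `NA`.
#' @return list with `apl` (Angstrom^2) and `smoothing` descriptor, or
#'   `NA_real_`-valued `apl` for a flat curve.
#' @export
detect_critical_area <- function(iso, window = 11L, slope_tol = 1e-6) {
  a <- iso$apl
  dv <- if (window > 1L) smooth_poly(a, iso$dv, window) else iso$dv
  slope <- finite_diff(a, dv)
  i <- which.max(abs(slope))
  smoothing <- sprintf("local poly, window %d", as.integer(window))
  if (length(i) == 0L || abs(slope[i]) < slope_tol) {
    return(list(apl = NA_real_, smoothing = smoothing))
  }
  apl <- a[i]
  if (i > 1L && i < length(a)) {
    # parabolic sub-grid refinement of the |slope| peak
    y <- abs(slope[(i - 1L):(i + 1L)])
    denom <- y[1L] - 2 * y[2L] + y[3L]
    if (is.finite(denom) && denom < 0) {
      frac <- 0.5 * (y[1L] - y[3L]) / denom
      frac <- max(-0.5, min(0.5, frac))
      apl <- a[i] + frac * (a[i + 1L] - a[i - 1L]) / 2
    }
  }
  list(apl = apl, smoothing = smoothing)
}

#' Maximum apparent dipole moment
#'
#' @param curve a dipole curve from [apparent_dipole_moment()].
#' @return list with `apl`, `mu_a` at the maximum, and `flat` (TRUE when
#'   the curve is constant, in which case the first sample is reported).
#' @export
max_dipole <- function(curve) {
  if (nrow(curve) == 0L) abort_input("empty dipole curve")
  flat <- diff(range(curve$mu_a)) == 0
  i <- if (flat) 1L else which.max(curve$mu_a)
  list(apl = curve$apl[i], mu_a = curve$mu_a[i], flat = flat)
}
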