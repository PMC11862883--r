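#' Surface pressure-area isotherm
#'
#' Ordered (area-per-lipid, surface pressure) samples from a compression
#' run. APL must be strictly monotone; samples are stored in compression
#' order (decreasing APL).
#'
#' @param apl area per lipid, Angstrom^2.
#' @param pi surface pressure, mN/m.
#' @param temperature subphase temperature, degrees C.
#' @param compression_rate barrier speed, mm/min.
#' @param label free-text label.
#' @return object of class `isotherm` (a data.frame with metadata).
#' @export
isotherm <- function(apl, pi, temperature = 36.6, compression_rate = 10,
                     label = "") {
  if (length(apl) != length(pi)) abort_input("apl and pi lengths differ")
  d <- diff(apl)
  if (!(all(d > 0) || all(d < 0))) abort_input("apl must be strictly monotone")
  if (all(d > 0)) { # store in compression order
    apl <- rev(apl); pi <- rev(pi)
  }
  structure(data.frame(apl = apl, pi = pi),
            temperature = temperature, compression_rate = compression_rate,
            label = label, class = c("isotherm", "data.frame"))
}

#' Surface pressure from surface tension
#'
#' pi = gamma_water - gamma, with gamma_water = 72.0 mN/m for the clean
#' air-water interface. Negative pressures are allowed but flagged with a
#' warning (they indicate gamma above the clean-interface value).
#'
#' @param gamma film surface tension, mN/m.
#' @param gamma_water clean-interface tension, mN/m.
#' @return surface pressure, mN/m.
#' @export
surface_pressure_from_tension <- function(gamma, gamma_water = 72.0) {
  p <- gamma_water - gamma
  if (any(p < 0)) warning("negative surface pressure (gamma > gamma_water)")
  p
}

#' Compression modulus curve
#'
#' Cs^-1(A) = -A (dpi/dA), evaluated by local-polynomial smoothing of
#' pi(A) followed by central finite differences (one-sided at the ends).
#' The modulus is the in-plane elastic stiffness of the film; its
#' magnitude classifies the monolayer phase (see [classify_phase()]).
#'
#' @param iso an [isotherm()].
#' @param window odd smoothing window in points; `1` disables smoothing.
#' @param degree local polynomial degree.
#' @return object of class `modulus_curve`: data.frame with columns `apl`,
#'   `pi` (smoothed) and `cs_inv` (mN/m), plus a `smoothing` attribute.
#' @export
compression_modulus <- function(iso, window = 11L, degree = 3L) {
  if (nrow(iso) < 4L) abort_input("need at least 4 samples for Cs^-1")
  a <- iso$apl
  p <- if (window > 1L) smooth_poly(a, iso$pi, window, degree) else iso$pi
  dpda <- finite_diff(a, p)
  structure(data.frame(apl = a, pi = p, cs_inv = -a * dpda),
            smoothing = sprintf("local poly, window %d, degree %d",
                                as.integer(window), as.integer(degree)),
            class = c("modulus_curve", "data.frame"))
}

#' Davies-Rideal monolayer phase from the compression modulus
#'
#' Bands in mN/m: < 12.5 gaseous; 12.5-50 liquid-expanded (LE); 50-100
#' intermediate LE-LC; 100-250 liquid-condensed (LC); > 250 solid. A value
#' on a boundary belongs to the lower band.
#'
#' @param cs_inv compression modulus, mN/m (>= 0); vectorized.
#' @return character vector of phase labels.
#' @export
classify_phase <- function(cs_inv) {
  if (any(cs_inv < 0)) abort_input("Cs^-1 must be >= 0")
  cut(cs_inv, breaks = c(-Inf, 12.5, 50, 100, 250, Inf),
      labels = c("gaseous", "LE", "intermediate LE-LC", "LC", "solid"),
      right = TRUE) |> as.character()
}

#' Lift-off area of a compression isotherm
#'
#' The area per lipid at which the surface pressure first rises above its
#' baseline during compression. The onset is located where the pressure
#' exceeds the detection threshold (default 0.5 mN/m above the baseline,
#' the median pressure over the largest-area decile, since "rises above 0"
#' is not operational against instrument noise); the reported lift-off is
#' then the back-extrapolation of the initial rise (a straight-line fit
#' over pressures between the threshold and `rise_span` above baseline) to
#' the baseline, which removes the systematic late bias of a raw threshold
#' crossing on gently rising isotherms. When fewer than 3 samples fall in
#' the fit window, the interpolated threshold crossing is returned instead.
#'
#' @param iso an [isotherm()].
#' @param pi_threshold absolute detection threshold in mN/m, or `NULL` for
#'   baseline + `delta`.
#' @param delta rise over baseline used when `pi_threshold` is `NULL`.
#' @param rise_span upper edge (mN/m above baseline) of the rising branch
#'   included in the onset fit.
#' @param method "fit" refines the onset by a changepoint regression:
#'   pi(A) = baseline below the lift-off area A0 and
#'   baseline + Cs ln(A0/A) above it (a locally constant compression
#'   modulus), with A0 chosen by least squares over the baseline plus the
#'   early rise. "crossing" returns the interpolated threshold crossing.
#' @return lift-off APL in Angstrom^2, or `NA_real_` when the pressure
#'   never exceeds the threshold (no lift-off; not an error).
#' @export
detect_lift_off <- function(iso, pi_threshold = NULL, delta = 0.5,
                            rise_span = 5, method = c("fit", "crossing")) {
  method <- match.arg(method)
  a <- iso$apl; p <- iso$pi               # compression order: a decreasing
  n_base <- max(3L, ceiling(length(a) / 10))
  baseline <- stats::median(p[seq_len(n_base)])
  if (is.null(pi_threshold)) pi_threshold <- baseline + delta
  above <- which(p > pi_threshold)
  if (length(above) == 0L) return(NA_real_)
  i <- above[1L]
  crossing <- if (i == 1L) a[1L] else {
    f <- (pi_threshold - p[i - 1L]) / (p[i] - p[i - 1L])
    a[i - 1L] + f * (a[i] - a[i - 1L])
  }
  if (method == "crossing") return(crossing)
  # changepoint fit over the baseline and the early rise (pi up to
  # baseline + rise_span); all baseline samples help pin the onset
  over <- which(p > baseline + rise_span)
  last <- if (length(over) > 0L) max(over[1L] - 1L, i) else length(a)
  aw <- a[seq_len(last)]; pw <- p[seq_len(last)]
  if (sum(aw < crossing) < 3L) return(crossing)
  sse <- function(a0) {
    x <- pmax(0, log(a0 / aw))
    fit <- stats::lm.fit(cbind(1, x), pw)
    sum(fit$residuals^2)
  }
  span_a <- max(2, 2 * (crossing - min(aw)) / 3)
  opt <- stats::optimize(sse, lower = crossing - span_a / 2,
                         upper = min(crossing + span_a, max(aw)))
  opt$minimum
}

#' Collapse point of a compression isotherm
#'
#' Collapse is the failure of the two-dimensional film: the pressure stops
#' rising (plateau) or drops (kink) on further compression. Detected as the
#' first sample, after the pressure has exceeded half its maximum, where
#' dpi/dA changes sign or |dpi/dA| falls below `plateau_tol`.
#'
#' @param iso an [isotherm()].
#' @param plateau_tol slope magnitude (mN/m per Angstrom^2) below which the
#'   curve counts as flat.
#' @param window smoothing window passed to the derivative (1 = none).
#' @return list with `pi_coll` (mN/m) and `apl_coll` (Angstrom^2), or
#'   `NULL` when the pressure rises strictly to the end of compression.
#' @export
detect_collapse <- function(iso, plateau_tol = 0.02, window = 1L) {
  a <- iso$apl; p <- iso$pi
  if (window > 1L) p <- smooth_poly(a, p, window)
  dpda <- finite_diff(a, p)
  half <- max(p) / 2
  # during compression a decreases, pressure rises => dp/dA < 0
  cand <- which(p >= half & (dpda >= 0 | abs(dpda) < plateau_tol))
  cand <- cand[cand > which.max(p >= half)]   # strictly after the rise begins
  if (length(cand) == 0L) return(NULL)
  i <- cand[1L]
  list(pi_coll = p[i], apl_coll = a[i])
}

#' Constant-pressure relaxation trace
#'
#' Relative molecular area A/A0 over time while the barriers hold the film
#' at a constant surface pressure setpoint; A0 is the area when the
#' setpoint is first reached.
#'
#' @param t time in seconds, increasing from 0.
#' @param rel_area A/A0, in (0, 1.05].
#' @param setpoint_pi holding pressure, mN/m.
#' @return object of class `relaxation_trace`.
#' @export
relaxation_trace <- function(t, rel_area, setpoint_pi = 30) {
  if (length(t) != length(rel_area)) abort_input("t and rel_area lengths differ")
  if (any(diff(t) <= 0)) abort_input("t must be strictly increasing")
  if (abs(rel_area[1L] - 1) > 0.05) abort_input("rel_area must start at 1")
  if (any(rel_area <= 0 | rel_area > 1.05)) {
    abort_input("rel_area must lie in (0, 1.05]")
  }
  structure(data.frame(t = t, rel_area = rel_area),
            setpoint_pi = setpoint_pi,
            class = c("relaxation_trace", "data.frame"))
}

#' Stability metrics of a constant-pressure relaxation
#'
#' @param trace a [relaxation_trace()].
#' @param floor samples with A/A0 at or below this value are excluded from
#'   the log-linear fit (the logarithm amplifies measurement noise as the
#'   relative area approaches zero).
#' @return list with
#'   `area_loss_fraction` (1 - min A/A0 over the horizon),
#'   `initial_rate` (-d(A/A0)/dt at t -> 0, least squares over the first
#'   10\% of samples, 1/s), and
#'   `exp_constant` (k from the log-linear fit A/A0 = exp(-k t), 1/s).
#' @export
relaxation_metrics <- function(trace, floor = 0.05) {
  t <- trace$t; r <- trace$rel_area
  n0 <- max(3L, ceiling(length(t) * 0.10))
  head_fit <- stats::lm.fit(cbind(1, t[seq_len(n0)]), r[seq_len(n0)])
  ok <- r > floor
  exp_fit <- stats::lm.fit(cbind(1, t[ok]), log(r[ok]))
  list(
    area_loss_fraction = 1 - min(r),
    initial_rate = -unname(head_fit$coefficients[2L]),
    exp_constant = -unname(exp_fit$coefficients[2L])
  )
}
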