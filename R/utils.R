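# Internal helpers: physical constants, RNG scoping, smoothing, derivatives.

# Physical constants (SI)
.AVOGADRO <- 6.02214076e23      # mol^-1
.EPS0 <- 8.8541878128e-12       # F m^-1, vacuum permittivity
.DEBYE <- 3.33564e-30           # C m per Debye
.GAMMA_WATER <- 72.0            # mN m^-1, clean air-water interface

#' @keywords internal
abort_input <- function(msg) stop(msg, call. = FALSE)

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards. Generators never touch
# global RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Local polynomial (Savitzky-Golay style) smoothing on an arbitrary grid
#'
#' Fits a least-squares polynomial of degree `degree` over a moving window
#' of `window` points centred on each sample and evaluates it (and its
#' first derivative if requested) at the sample's abscissa. On a uniform
#' grid this reproduces the Savitzky-Golay filter; it remains exact for
#' polynomials up to `degree` on non-uniform grids.
#'
#' @param x,y numeric vectors of equal length, `x` strictly monotone.
#' @param window odd integer window size (points); `1` disables smoothing.
#' @param degree polynomial degree, < window.
#' @param deriv 0 for the smoothed value, 1 for the first derivative.
#' @return numeric vector, same length as `x`.
#' @keywords internal
smooth_poly <- function(x, y, window = 11L, degree = 3L, deriv = 0L) {
  n <- length(x)
  stopifnot(length(y) == n, deriv %in% c(0L, 1L))
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  window <- min(window, if (n %% 2L == 0L) n - 1L else n)
  degree <- min(as.integer(degree), window - 1L)
  half <- window %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    # keep the window full at the edges (one-sided)
    if (hi - lo + 1L < window) {
      if (lo == 1L) hi <- min(n, window) else lo <- max(1L, n - window + 1L)
    }
    xi <- x[lo:hi] - x[i]
    deg <- min(degree, length(xi) - 1L)
    X <- outer(xi, 0:deg, `^`)
    cf <- tryCatch(qr.coef(qr(X), y[lo:hi]), error = function(e) rep(NA_real_, deg + 1L))
    out[i] <- if (deriv == 0L) cf[1L] else if (deg >= 1L) cf[2L] else 0
  }
  out
}

# First derivative dy/dx by central differences (one-sided at the ends).
finite_diff <- function(x, y) {
  n <- length(x)
  if (n < 2L) abort_input("need at least 2 points for a derivative")
  d <- numeric(n)
  d[1L] <- (y[2L] - y[1L]) / (x[2L] - x[1L])
  d[n] <- (y[n] - y[n - 1L]) / (x[n] - x[n - 1L])
  if (n > 2L) {
    i <- 2:(n - 1L)
    d[i] <- (y[i + 1L] - y[i - 1L]) / (x[i + 1L] - x[i - 1L])
  }
  d
}

# Minimum-image displacement for an orthorhombic box. `d` is a matrix of
# raw displacements (rows = pairs, cols = x,y,z), `box` the edge lengths.
min_image <- function(d, box) {
  for (k in seq_along(box)) {
    d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  }
  d
}
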