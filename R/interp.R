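#' Monotone cubic Hermite node slopes (Fritsch-Carlson scheme)
#'
#' Computes per-node derivatives for a shape-preserving piecewise cubic
#' Hermite interpolant.  Where adjacent secant slopes have opposite signs or
#' either is zero, the node derivative is set to zero; otherwise it is the
#' interval-width weighted harmonic mean of the adjacent secants, which keeps
#' the interpolant monotone on every interval.  End slopes use a one-sided
#' three-point estimate, clipped to preserve shape.
#'
#' @param x strictly increasing abscissae (length >= 2).
#' @param y ordinates.
#' @return numeric vector of node slopes, same length as `x`.
#' @export
fc_slopes <- function(x, y) {
  n <- length(x)
  stopifnot(is.numeric(x), is.numeric(y), length(y) == n, n >= 2)
  if (any(duplicated(x)) || any(diff(x) <= 0))
    stop("abscissae must be strictly increasing (no duplicates)")
  h <- diff(x)
  d <- diff(y) / h                       # secant slopes
  if (n == 2) return(rep(d, 2))
  m <- numeric(n)
  for (i in 2:(n - 1)) {
    d0 <- d[i - 1]; d1 <- d[i]
    if (d0 * d1 <= 0) {
      m[i] <- 0
    } else {
      w1 <- 2 * h[i] + h[i - 1]
      w2 <- h[i] + 2 * h[i - 1]
      m[i] <- (w1 + w2) / (w1 / d0 + w2 / d1)
    }
  }
  m[1] <- .edge_slope(h[1], h[2], d[1], d[2])
  m[n] <- .edge_slope(h[n - 1], h[n - 2], d[n - 1], d[n - 2])
  m
}

# One-sided three-point end-slope estimate with shape-preserving clipping.
.edge_slope <- function(h0, h1, d0, d1) {
  s <- ((2 * h0 + h1) * d0 - h0 * d1) / (h0 + h1)
  if (sign(s) != sign(d0)) return(0)
  if (sign(d0) != sign(d1) && abs(s) > 3 * abs(d0)) return(3 * d0)
  s
}

#' Build an interpolating dose-coefficient curve from a table
#'
#' Interpolation is shape-preserving piecewise cubic Hermite (see
#' [fc_slopes()]) performed by default in log-linear space: abscissa
#' log10(energy/MeV), ordinate the coefficient value on a linear scale.  The
#' published tabulations stop at 0.015 MeV; evaluation below that cutoff
#' returns exactly zero.  No extrapolation is performed above the last node
#' or above 10 MeV.
#'
#' @param table a [coef_table()].
#' @param log_energy interpolate in log10(energy) (default) or linear energy.
#' @param log_value interpolate log(value) instead of the linear value; this
#'   alternative reading of "log-linear" is provided for comparison and
#'   requires strictly positive table values.
#' @return an object of class `dose_curve`.
#' @export
dose_curve <- function(table, log_energy = TRUE, log_value = FALSE) {
  stopifnot(inherits(table, "coef_table"))
  if (nrow(table) < 2) stop("need at least 2 nodes to interpolate")
  x <- if (log_energy) log10(table$energy_MeV) else table$energy_MeV
  y <- table$value
  if (log_value) {
    if (any(y <= 0))
      stop("log_value = TRUE requires strictly positive table values")
    y <- log(y)
  }
  structure(list(
    energy_MeV = table$energy_MeV,
    x = x, y = y, slopes = fc_slopes(x, y),
    log_energy = log_energy, log_value = log_value,
    cutoff_MeV = 0.015,
    geometry = attr(table, "geometry"),
    organ = attr(table, "organ"),
    quantity = attr(table, "quantity")
  ), class = "dose_curve")
}

#' @export
print.dose_curve <- function(x, ...) {
  cat(sprintf(
    "<dose_curve> %s / %s: monotone cubic Hermite on %s(E)%s, %d nodes [%g, %g] MeV\n",
    x$geometry, x$organ,
    if (x$log_energy) "log10" else "linear",
    if (x$log_value) ", log(value)" else "",
    length(x$x), x$energy_MeV[1], x$energy_MeV[length(x$energy_MeV)]))
  invisible(x)
}

#' Evaluate a dose-coefficient curve
#'
#' Exact at the table nodes; zero below the 0.015 MeV cutoff; an error above
#' 10 MeV, above the last node, at non-positive energies, and in the gap
#' between the cutoff and the first node when a table starts above
#' 0.015 MeV (no data are invented there).
#'
#' @param curve a [dose_curve()].
#' @param energy_MeV numeric vector of photon energies (MeV).
#' @return coefficient values, same length as `energy_MeV`.
#' @export
eval_curve <- function(curve, energy_MeV) {
  stopifnot(inherits(curve, "dose_curve"))
  E <- as.numeric(energy_MeV)
  if (anyNA(E)) stop("NA energies")
  if (any(E <= 0)) stop("energies must be positive")
  if (any(E > 10 + 1e-12)) stop("no extrapolation above 10 MeV")
  out <- numeric(length(E))
  below <- E < curve$cutoff_MeV
  emin <- curve$energy_MeV[1]
  emax <- curve$energy_MeV[length(curve$energy_MeV)]
  inside <- !below
  if (any(inside & (E < emin - 1e-12)))
    stop("energy between the 0.015 MeV cutoff and the first table node (",
         emin, " MeV); no data available there")
  if (any(inside & (E > emax * (1 + 1e-12))))
    stop("energy above the last table node (", emax, " MeV); no extrapolation")
  if (any(inside)) {
    xe <- if (curve$log_energy) log10(E[inside]) else E[inside]
    v <- .hermite_eval(curve$x, curve$y, curve$slopes, xe)
    if (curve$log_value) v <- exp(v)
    out[inside] <- v
  }
  out
}

# Piecewise cubic Hermite evaluation at points xe (assumed within range).
.hermite_eval <- function(x, y, m, xe) {
  n <- length(x)
  i <- findInterval(xe, x, rightmost.closed = TRUE)
  i[i < 1] <- 1L
  i[i >= n] <- n - 1L
  h <- x[i + 1] - x[i]
  t <- (xe - x[i]) / h
  t2 <- t * t; t3 <- t2 * t
  h00 <- 2 * t3 - 3 * t2 + 1
  h10 <- t3 - 2 * t2 + t
  h01 <- -2 * t3 + 3 * t2
  h11 <- t3 - t2
  h00 * y[i] + h10 * h * m[i] + h01 * y[i + 1] + h11 * h * m[i + 1]
}

#' @export
predict.dose_curve <- function(object, energy_MeV, ...) {
  eval_curve(object, energy_MeV)
}
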