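# Union-grid composite trapezoid over [lo, hi]:
# grid = breakpoints (spectrum grid, curve nodes, cutoff) + refinement to at
# least `min_panels` panels; f is evaluated on the final grid.
.union_trapz <- function(f, lo, hi, breaks, min_panels = 2000) {
  if (hi <= lo) return(0)
  g <- sort(unique(c(lo, hi, breaks[breaks > lo & breaks < hi],
                     seq(lo, hi, length.out = min_panels + 1))))
  y <- f(g)
  sum(diff(g) * (y[-length(y)] + y[-1])) / 2
}

#' Fold discrete photon lines with a dose-coefficient curve
#'
#' The discrete-emission term of the folding equation:
#' sum_i w_photon * Y_i * d(E_i).  Lines below the 0.015 MeV cutoff
#' contribute exactly zero; lines above 10 MeV are an error (the
#' monoenergetic tabulations stop there).
#'
#' @param lines data frame of photon lines with columns `energy_MeV`,
#'   `yield` (a `type` column, if present, must be all `"photon"`).
#' @param curve a [dose_curve()].
#' @param w a [weighting_config()].
#' @return the partial coefficient (scalar).
#' @export
fold_discrete <- function(lines, curve, w = weighting_config()) {
  stopifnot(inherits(curve, "dose_curve"))
  if (is.null(lines) || nrow(lines) == 0) return(0)
  if (!is.null(lines$type) && !all(lines$type == "photon"))
    stop("fold_discrete handles photon lines; route electrons through electron_dose_curve()")
  if (any(lines$energy_MeV > 10 + 1e-12))
    stop("discrete line above 10 MeV; no extrapolation")
  sum(w$w_photon * lines$yield * eval_curve(curve, lines$energy_MeV))
}

#' Fold a continuous photon spectrum with a dose-coefficient curve
#'
#' Computes integral( Y(E) d(E) dE ) by composite trapezoid on the union of
#' the spectrum grid, the curve's nodes and a refinement to at least
#' `min_panels` panels.  The portion of the spectrum below the 0.015 MeV
#' cutoff contributes zero.  The spectrum density is interpolated linearly
#' between its grid points and is zero outside its grid.
#'
#' @param spectrum a continuous spectrum: list with `grid` (data frame
#'   `energy_MeV`, `yield_per_MeV`), or the grid data frame itself.
#' @param curve a [dose_curve()].
#' @param min_panels minimum number of quadrature panels.
#' @return the partial coefficient (scalar).
#' @export
fold_continuous <- function(spectrum, curve, min_panels = 2000) {
  stopifnot(inherits(curve, "dose_curve"))
  g <- if (is.data.frame(spectrum)) spectrum else spectrum$grid
  if (is.null(g) || nrow(g) < 2 || all(g$yield_per_MeV == 0)) return(0)
  if (any(g$energy_MeV > 10 + 1e-12))
    stop("spectrum grid extends above 10 MeV")
  lo <- max(min(g$energy_MeV), curve$cutoff_MeV)
  hi <- min(max(g$energy_MeV), 10)
  if (hi <= lo) return(0)      # spectrum entirely below the cutoff
  dens <- function(E) {
    v <- stats::approx(g$energy_MeV, g$yield_per_MeV, xout = E,
                       yleft = 0, yright = 0, rule = 2)$y
    v[E < min(g$energy_MeV) | E > max(g$energy_MeV)] <- 0
    v
  }
  f <- function(E) dens(E) * eval_curve(curve, E)
  .union_trapz(f, lo, hi, breaks = c(g$energy_MeV, curve$energy_MeV),
               min_panels = min_panels)
}

#' Effective electron dose-coefficient function via bremsstrahlung
#'
#' Source electrons do not themselves reach a person standing in the field;
#' their only penetrating contribution is the bremsstrahlung generated while
#' they stop in the environmental medium.  For each kernel electron energy
#' E_e this computes d_elec(E_e) = integral( B(k | E_e) d_photon(k) dk ) and
#' interpolates linearly in E_e between kernel grid points.
#'
#' @param photon_curve a [dose_curve()] for the organ and geometry.
#' @param kernel a [brems_kernel()].
#' @param min_panels quadrature refinement per kernel spectrum.
#' @return an object of class `electron_dose_curve`; evaluate it with
#'   [eval_electron_curve()].
#' @export
electron_dose_curve <- function(photon_curve, kernel, min_panels = 2000) {
  stopifnot(inherits(photon_curve, "dose_curve"), inherits(kernel, "brems_kernel"))
  vals <- vapply(seq_along(kernel$electron_energies), function(i) {
    g <- kernel$spectra[[i]]
    if (nrow(g) < 2 || all(g$B_per_MeV == 0)) return(0)
    fold_continuous(data.frame(energy_MeV = g$k_MeV,
                               yield_per_MeV = g$B_per_MeV),
                    photon_curve, min_panels = min_panels)
  }, numeric(1))
  structure(list(electron_energies = kernel$electron_energies, values = vals,
                 medium = kernel$medium, organ = photon_curve$organ,
                 geometry = photon_curve$geometry),
            class = "electron_dose_curve")
}

#' Evaluate an effective electron dose-coefficient curve
#'
#' Linear interpolation in electron energy; energies outside the kernel grid
#' are an error.
#'
#' @param ec an [electron_dose_curve()].
#' @param E_e_MeV electron energies (MeV).
#' @return coefficient values.
#' @export
eval_electron_curve <- function(ec, E_e_MeV) {
  stopifnot(inherits(ec, "electron_dose_curve"))
  r <- range(ec$electron_energies)
  if (any(E_e_MeV < r[1] * (1 - 1e-9)) || any(E_e_MeV > r[2] * (1 + 1e-9)))
    stop("electron energy outside the kernel grid [", r[1], ", ", r[2], "] MeV")
  if (length(ec$electron_energies) == 1L)
    return(rep(ec$values, length(E_e_MeV)))
  stats::approx(ec$electron_energies, ec$values, xout = E_e_MeV, rule = 2)$y
}

#' Nuclide-specific organ coefficients by folding a decay record
#'
#' The full folding engine: discrete photons and spontaneous-fission photon
#' spectra are folded directly with each organ curve; discrete electron
#' lines and continuous beta spectra are routed through the bremsstrahlung
#' kernel (their only penetrating pathway) and then folded.  The result
#' carries the component breakdown per organ.
#'
#' @param record a [decay_record()].
#' @param curves named list of [dose_curve()] objects (one per organ), all of
#'   the same geometry.
#' @param kernel a [brems_kernel()]; required only when the record has
#'   electron emissions.
#' @param w a [weighting_config()].
#' @param min_panels quadrature refinement.
#' @return an object of class `nuclide_result`: data frame with one row per
#'   organ and columns `discrete_photon`, `bremsstrahlung`,
#'   `continuous_photon`, `total`.
#' @export
nuclide_coefficient <- function(record, curves, kernel = NULL,
                                w = weighting_config(), min_panels = 2000) {
  stopifnot(inherits(record, "decay_record"), is.list(curves))
  if (is.null(names(curves)) || any(names(curves) == ""))
    stop("curves must be a named list (organ labels)")
  geoms <- unique(vapply(curves, function(cv) cv$geometry, character(1)))
  if (length(geoms) != 1)
    stop("all curves must share one geometry; got: ",
         paste(geoms, collapse = ", "))
  if (!is.null(kernel) && !is.null(kernel$geometry) &&
      !identical(match_geometry(kernel$geometry), geoms))
    stop("kernel geometry (", kernel$geometry,
         ") does not match curve geometry (", geoms, ")")
  phot <- record$discrete[record$discrete$type == "photon", , drop = FALSE]
  elec <- record$discrete[record$discrete$type == "electron", , drop = FALSE]
  betas <- Filter(function(s) s$type == "electron_beta", record$continuous)
  sfs <- Filter(function(s) s$type == "photon_sf", record$continuous)
  need_kernel <- nrow(elec) > 0 || length(betas) > 0
  if (need_kernel && is.null(kernel))
    stop("record '", record$nuclide,
         "' has electron emissions; a bremsstrahlung kernel is required")
  organs <- names(curves)
  comp <- matrix(0, nrow = length(organs), ncol = 3,
                 dimnames = list(organs, c("discrete_photon", "bremsstrahlung",
                                           "continuous_photon")))
  for (org in organs) {
    cv <- curves[[org]]
    comp[org, "discrete_photon"] <- fold_discrete(phot, cv, w)
    for (sp in sfs)
      comp[org, "continuous_photon"] <- comp[org, "continuous_photon"] +
        fold_continuous(sp, cv, min_panels = min_panels)
    if (need_kernel) {
      ec <- electron_dose_curve(cv, kernel, min_panels = min_panels)
      br <- 0
      if (nrow(elec))
        br <- br + sum(w$w_electron * elec$yield *
                         eval_electron_curve(ec, elec$energy_MeV))
      for (sp in betas) {
        g <- sp$grid
        f <- function(E) {
          v <- stats::approx(g$energy_MeV, g$yield_per_MeV, xout = E,
                             yleft = 0, yright = 0)$y
          v * eval_electron_curve(ec, E)
        }
        lo <- max(min(g$energy_MeV), min(ec$electron_energies))
        hi <- min(max(g$energy_MeV), max(ec$electron_energies))
        if (hi > lo)
          br <- br + w$w_electron *
            .union_trapz(f, lo, hi,
                         breaks = c(g$energy_MeV, ec$electron_energies),
                         min_panels = min_panels)
      }
      comp[org, "bremsstrahlung"] <- br
    }
  }
  out <- as.data.frame(comp)
  out$total <- rowSums(comp)
  structure(out, class = c("nuclide_result", "data.frame"),
            nuclide = record$nuclide, geometry = geoms,
            kernel_id = if (is.null(kernel)) NA_character_ else kernel$medium,
            table_version = as.character(utils::packageVersion("envdose")),
            normalized = FALSE)
}

#' @export
print.nuclide_result <- function(x, ...) {
  cat(sprintf("<nuclide_result> %s, geometry %s (%s)\n", attr(x, "nuclide"),
              attr(x, "geometry"),
              if (isTRUE(attr(x, "normalized"))) "Sv per Gy air kerma"
              else coefficient_unit(attr(x, "geometry"))))
  print.data.frame(signif(as.data.frame(x), 3))
  invisible(x)
}

#' Normalise organ coefficients to air kerma
#'
#' Divides every organ coefficient (and component) by the nuclide's
#' air-kerma rate coefficient, yielding organ equivalent dose per unit air
#' kerma (Sv/Gy), the form usable with measured air-kerma rates.
#'
#' @param result a [nuclide_result()].
#' @param kerma_coeff air-kerma rate coefficient (> 0, same geometry units).
#' @return a `nuclide_result` in Sv/Gy with attribute `normalized = TRUE`.
#' @export
kerma_normalize <- function(result, kerma_coeff) {
  stopifnot(inherits(result, "nuclide_result"))
  if (!is.numeric(kerma_coeff) || length(kerma_coeff) != 1 ||
      !is.finite(kerma_coeff) || kerma_coeff <= 0)
    stop("kerma_coeff must be a positive number")
  out <- result
  out[] <- lapply(as.data.frame(result), function(col) col / kerma_coeff)
  attr(out, "normalized") <- TRUE
  attr(out, "kerma_coeff") <- kerma_coeff
  out
}

#' Detriment-weighted (effective-dose-like) coefficient
#'
#' Tissue-weighting-factor weighted sum over organ coefficients for one
#' individual: sum_T w_T h_T.
#'
#' @param organ_values named numeric vector of organ coefficients, or a
#'   [nuclide_result()] (its `total` column is used).
#' @param w_T named numeric vector of tissue weights.
#' @return scalar coefficient.
#' @export
detriment_weighted <- function(organ_values, w_T) {
  if (inherits(organ_values, "nuclide_result"))
    organ_values <- stats::setNames(organ_values$total, rownames(organ_values))
  if (is.null(names(organ_values)) || is.null(names(w_T)))
    stop("organ values and weights must be named")
  w_T <- w_T[w_T > 0]
  missing <- setdiff(names(w_T), names(organ_values))
  if (length(missing))
    stop("organ coefficient(s) missing for weighted tissue(s): ",
         paste(missing, collapse = ", "))
  sum(w_T * organ_values[names(w_T)])
}

#' Uterus / fetal-total-body ratio report
#'
#' For each nuclide, the ratio of the mother's uterus equivalent dose rate
#' coefficient to the fetal total-body coefficient — the classical
#' uterus-as-fetus-surrogate check.  Ratios are reported rounded to two
#' decimals with the raw value retained; a zero fetal coefficient makes the
#' ratio undefined and is flagged.
#'
#' @param nuclides character vector of nuclide ids.
#' @param mother_uterus named numeric vector (per-nuclide uterus
#'   coefficients).
#' @param fetus_total named numeric vector (per-nuclide fetal total-body
#'   coefficients).
#' @return data frame with columns `nuclide`, `uterus`, `fetus`,
#'   `ratio_raw`, `ratio` (2 dp), `defined`.
#' @export
uterus_fetus_ratio <- function(nuclides, mother_uterus, fetus_total) {
  missing <- setdiff(nuclides, intersect(names(mother_uterus), names(fetus_total)))
  if (length(missing))
    stop("coefficients missing for nuclide(s): ", paste(missing, collapse = ", "))
  u <- as.numeric(mother_uterus[nuclides])
  f <- as.numeric(fetus_total[nuclides])
  defined <- f > 0
  raw <- ifelse(defined, u / f, NA_real_)
  data.frame(nuclide = nuclides, uterus = u, fetus = f,
             ratio_raw = raw, ratio = round(raw, 2), defined = defined)
}
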