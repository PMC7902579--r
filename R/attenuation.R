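# Physical constants
.ME_MEV <- 0.510998950          # electron rest energy, MeV
.RE_CM <- 2.8179403262e-13      # classical electron radius, cm
.NA_AVOGADRO <- 6.02214076e23
.MEV_TO_J <- 1.602176634e-13

# Total Klein-Nishina cross-section per electron (cm^2), closed form.
.sigma_kn <- function(E_MeV) {
  k <- E_MeV / .ME_MEV
  a <- 1 + 2 * k
  2 * pi * .RE_CM^2 * (
    (1 + k) / k^2 * (2 * (1 + k) / a - log(a) / k) +
      log(a) / (2 * k) - (1 + 3 * k) / a^2
  )
}

# Klein-Nishina differential cross-section in cos(theta), per electron
# (cm^2 per unit cos(theta)).
.kn_diff <- function(E_MeV, costh) {
  k <- E_MeV / .ME_MEV
  eps <- 1 / (1 + k * (1 - costh))
  pi * .RE_CM^2 * eps^2 * (eps + 1 / eps - (1 - costh^2))
}

# Energy-transfer Klein-Nishina cross-section per electron (cm^2), by fine
# numeric integration of dsigma/dcos * (1 - eps).
.sigma_kn_tr <- function(E_MeV, n = 4001) {
  vapply(E_MeV, function(E) {
    k <- E / .ME_MEV
    cth <- seq(-1, 1, length.out = n)
    eps <- 1 / (1 + k * (1 - cth))
    f <- .kn_diff(E, cth) * (1 - eps)
    sum(diff(cth) * (f[-n] + f[-1])) / 2
  }, numeric(1))
}

# Per-material composition helpers: electrons per gram and weighted Z powers.
.comp_sums <- function(material) {
  w <- material$composition / 100
  el <- .element_data[names(w), ]
  list(
    z_over_a = sum(w * el$Z / el$A),          # electrons per amu
    z45_over_a = sum(w * el$Z^4.5 / el$A),
    z2_over_a = sum(w * el$Z^2 / el$A)
  )
}

# Calibration constants of the synthetic partial coefficients (cm^2/g):
# photoelectric anchored to dry air at 0.01 MeV, pair production to dry air
# at 10 MeV.
.PE_CONST <- 7.04e-9
.PAIR_CONST <- 2.205e-4

#' Synthetic photon attenuation table for a material
#'
#' Generates mass attenuation coefficients (cm2/g) from closed-form physics:
#' incoherent scattering from the free-electron Klein-Nishina cross-section,
#' photoelectric absorption from a calibrated Z^4.5/E^3 law, and pair
#' production from a calibrated Z^2 law above 1.022 MeV.  Coherent
#' scattering and binding corrections are deliberately omitted.  This is a
#' synthetic stand-in for library attenuation data and is labelled as such;
#' user tables in the same format can be loaded with [load_attenuation()].
#'
#' @param material a [material_spec()].
#' @param energies energy grid (MeV), default log-spaced over 0.002-10 MeV.
#' @return an `attenuation_table`: data frame with columns `energy_MeV`,
#'   `pe`, `incoh`, `pair`, `total` (cm2/g) and a `medium` attribute.
#' @export
synthetic_attenuation <- function(material,
                                  energies = 10^seq(log10(0.002), 1,
                                                    length.out = 90)) {
  stopifnot(inherits(material, "material_spec"))
  cs <- .comp_sums(material)
  incoh <- cs$z_over_a * .NA_AVOGADRO * .sigma_kn(energies)
  pe <- .PE_CONST * cs$z45_over_a / energies^3
  pair <- ifelse(energies > 1.022,
                 .PAIR_CONST * cs$z2_over_a *
                   pmax(0, energies - 1.022)^1.85 / energies, 0)
  out <- data.frame(energy_MeV = energies, pe = pe, incoh = incoh,
                    pair = pair, total = pe + incoh + pair)
  structure(out, class = c("attenuation_table", "data.frame"),
            medium = material$name, density_gcm3 = material$density_gcm3)
}

#' Load an attenuation table from CSV
#'
#' Columns: `energy_MeV`, `pe`, `incoh`, `pair`, `total` (cm2/g).  Partial
#' coefficients are interpolated log-log during transport.
#'
#' @param path CSV path.
#' @param medium medium label.
#' @param density_gcm3 bulk density used to convert to linear coefficients.
#' @return an `attenuation_table`.
#' @export
load_attenuation <- function(path, medium, density_gcm3) {
  df <- utils::read.csv(path, header = TRUE)
  need <- c("energy_MeV", "pe", "incoh", "pair", "total")
  if (!all(need %in% names(df)))
    stop("attenuation CSV needs columns: ", paste(need, collapse = ", "))
  structure(df[need], class = c("attenuation_table", "data.frame"),
            medium = medium, density_gcm3 = density_gcm3)
}

#' Write an attenuation table to CSV
#' @param att an `attenuation_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_attenuation <- function(att, path) {
  utils::write.csv(as.data.frame(att), path, row.names = FALSE)
  invisible(path)
}

# Log-log interpolator over an attenuation table; errors outside the grid.
# Returns a function(E) -> matrix with columns pe, incoh, pair, total.
.att_fun <- function(att) {
  E <- att$energy_MeV
  lx <- log(E)
  cols <- c("pe", "incoh", "pair", "total")
  force(att)
  function(energy) {
    if (any(energy < E[1] * (1 - 1e-9)) || any(energy > E[length(E)] * (1 + 1e-9)))
      stop("missing attenuation data at energy outside [",
           E[1], ", ", E[length(E)], "] MeV")
    le <- log(pmin(pmax(energy, E[1]), E[length(E)]))
    i <- findInterval(le, lx, rightmost.closed = TRUE)
    i[i < 1] <- 1L; i[i >= length(E)] <- length(E) - 1L
    t <- (le - lx[i]) / (lx[i + 1] - lx[i])
    out <- sapply(cols, function(cl) {
      y0 <- att[[cl]][i]; y1 <- att[[cl]][i + 1]
      ok <- y0 > 0 & y1 > 0
      v <- ifelse(ok, exp((1 - t) * log(pmax(y0, 1e-300)) +
                            t * log(pmax(y1, 1e-300))),
                  (1 - t) * y0 + t * y1)   # linear when a zero is involved
      v
    })
    if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                         dimnames = list(NULL, cols))
    out
  }
}

#' Synthetic mass energy-transfer coefficient table
#'
#' (mu_tr/rho)(E) in cm2/g for converting a photon fluence spectrum to air
#' kerma: Klein-Nishina energy-transfer scattering plus full-energy
#' photoelectric transfer plus the pair-production kinetic fraction
#' (E - 1.022)/E.  Synthetic, consistent with [synthetic_attenuation()];
#' a measured conversion table can be loaded with [load_mu_tr_table()].
#'
#' @param material a [material_spec()] (typically air).
#' @param energies energy grid (MeV).
#' @return data frame with columns `energy_MeV`, `mu_tr_rho`.
#' @export
synthetic_mu_tr_table <- function(material,
                                  energies = 10^seq(log10(0.002), 1,
                                                    length.out = 90)) {
  stopifnot(inherits(material, "material_spec"))
  cs <- .comp_sums(material)
  incoh_tr <- cs$z_over_a * .NA_AVOGADRO * .sigma_kn_tr(energies)
  pe <- .PE_CONST * cs$z45_over_a / energies^3
  pair <- ifelse(energies > 1.022,
                 .PAIR_CONST * cs$z2_over_a *
                   pmax(0, energies - 1.022)^1.85 / energies *
                   (energies - 1.022) / energies, 0)
  data.frame(energy_MeV = energies, mu_tr_rho = pe + incoh_tr + pair)
}

#' Load a fluence-to-kerma conversion table from CSV
#'
#' Columns `energy_MeV`, `mu_tr_rho` (cm2/g).
#'
#' @param path CSV path.
#' @return data frame.
#' @export
load_mu_tr_table <- function(path) {
  df <- utils::read.csv(path, header = TRUE)
  if (!all(c("energy_MeV", "mu_tr_rho") %in% names(df)))
    stop("mu_tr CSV needs columns energy_MeV, mu_tr_rho")
  df
}

# Log-log scalar interpolator for a (energy, value) table.
.loglog_fun <- function(E, y) {
  lx <- log(E); ly <- log(pmax(y, 1e-300))
  function(energy) {
    le <- log(pmin(pmax(energy, E[1]), E[length(E)]))
    i <- findInterval(le, lx, rightmost.closed = TRUE)
    i[i < 1] <- 1L; i[i >= length(E)] <- length(E) - 1L
    t <- (le - lx[i]) / (lx[i + 1] - lx[i])
    exp((1 - t) * ly[i] + t * ly[i + 1])
  }
}
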