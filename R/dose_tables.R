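GEOMETRIES <- c("ground", "submersion")

#' Normalise an exposure-geometry label
#'
#' Two idealised exposure scenarios are supported: `"ground"`, an infinite
#' plane source buried at an areal-mass depth of 0.5 g cm-2 in soil
#' (first-year surface roughness after airborne deposition), and
#' `"submersion"`, a semi-infinite uniformly contaminated air volume.
#' Longer aliases (`"ground_plane_0p5gcm2"`, `"air_submersion"`) are
#' accepted.
#'
#' @param geometry character scalar.
#' @return `"ground"` or `"submersion"`.
#' @export
match_geometry <- function(geometry) {
  stopifnot(is.character(geometry), length(geometry) == 1L)
  g <- switch(geometry,
    ground = , ground_plane_0p5gcm2 = , soil = "ground",
    submersion = , air_submersion = , cloud = "submersion",
    stop("unknown geometry '", geometry, "'; use 'ground' or 'submersion'")
  )
  g
}

#' Units of a coefficient for a given geometry
#'
#' Ground-plane coefficients are per unit areal activity (Sv s-1 Bq-1 m2),
#' submersion coefficients per unit activity concentration (Sv s-1 Bq-1 m3).
#' Air-kerma analogues carry Gy in place of Sv.
#'
#' @param geometry `"ground"` or `"submersion"`.
#' @param quantity `"equivalent_dose_rate"` or `"kerma_rate"`.
#' @return character unit string.
#' @export
coefficient_unit <- function(geometry, quantity = "equivalent_dose_rate") {
  g <- match_geometry(geometry)
  base <- if (identical(quantity, "kerma_rate")) "Gy" else "Sv"
  per <- if (g == "ground") "m2" else "m3"
  paste0(base, " s-1 Bq-1 ", per)
}

#' Construct a monoenergetic coefficient table
#'
#' A `coef_table` holds one organ's (or air kerma's) monoenergetic dose rate
#' coefficients versus photon energy, for one exposure geometry.  Energies
#' must be strictly increasing and lie in \[0.015, 10\] MeV; values must be
#' non-negative; at least two nodes are required.
#'
#' @param energy_MeV numeric vector of node energies (MeV).
#' @param value numeric vector of coefficients (geometry units).
#' @param geometry exposure geometry, see [match_geometry()].
#' @param organ organ/quantity label (e.g. `"total_body"`, `"air_kerma"`).
#' @param quantity `"equivalent_dose_rate"` or `"kerma_rate"`.
#' @return an object of class `coef_table` (a data frame with attributes).
#' @export
coef_table <- function(energy_MeV, value, geometry, organ,
                       quantity = c("equivalent_dose_rate", "kerma_rate")) {
  quantity <- match.arg(quantity)
  geometry <- match_geometry(geometry)
  if (!is.numeric(energy_MeV) || !is.numeric(value))
    stop("energy and value must be numeric")
  if (length(energy_MeV) != length(value))
    stop("energy and value lengths differ")
  if (length(energy_MeV) < 2L)
    stop("a coefficient table needs at least 2 nodes")
  if (anyNA(energy_MeV) || anyNA(value))
    stop("NA values are not allowed in a coefficient table")
  if (any(diff(energy_MeV) <= 0))
    stop("energies must be strictly increasing")
  if (any(energy_MeV < 0.015 - 1e-12) || any(energy_MeV > 10 + 1e-12))
    stop("energies must lie within [0.015, 10] MeV")
  if (any(value < 0))
    stop("coefficient values must be non-negative")
  out <- data.frame(energy_MeV = as.numeric(energy_MeV),
                    value = as.numeric(value))
  structure(out, class = c("coef_table", "data.frame"),
            geometry = geometry, organ = organ, quantity = quantity)
}

#' @export
print.coef_table <- function(x, ...) {
  cat(sprintf("<coef_table> %s / %s (%s), %d nodes over [%g, %g] MeV\n",
              attr(x, "geometry"), attr(x, "organ"),
              coefficient_unit(attr(x, "geometry"), attr(x, "quantity")),
              nrow(x), x$energy_MeV[1], x$energy_MeV[nrow(x)]))
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("...", nrow(x) - 4, "more nodes\n")
  invisible(x)
}

#' Read a coefficient table from CSV
#'
#' The CSV dialect is fixed: comma-separated, `.` decimal point, `E`
#' exponent, UTF-8, one header row, two columns (`energy_MeV`, `value`).
#'
#' @inheritParams coef_table
#' @param path file path.
#' @return a [coef_table()].
#' @export
load_coef_table <- function(path, geometry, organ,
                            quantity = c("equivalent_dose_rate", "kerma_rate")) {
  quantity <- match.arg(quantity)
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty file: ", path)
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("table file has a header but no rows: ", path)
  if (ncol(df) < 2) stop("expected two columns (energy_MeV, value) in ", path)
  coef_table(df[[1]], df[[2]], geometry = geometry, organ = organ,
             quantity = quantity)
}

#' Write a coefficient table to CSV
#'
#' Values are serialised in scientific notation with enough digits that
#' [load_coef_table()] recovers the table bit-identically.
#'
#' @param table a [coef_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_coef_table <- function(table, path) {
  stopifnot(inherits(table, "coef_table"))
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write to ", path)
  on.exit(close(con))
  writeLines("energy_MeV,value", con)
  writeLines(sprintf("%.12g,%.17E", table$energy_MeV, table$value), con)
  invisible(path)
}

.fixture_env <- new.env(parent = emptyenv())

.read_fixture <- function(name) {
  if (!is.null(.fixture_env[[name]])) return(.fixture_env[[name]])
  path <- system.file("extdata", name, package = "envdose", mustWork = TRUE)
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  .fixture_env[[name]] <- df
  df
}

#' Packaged monoenergetic coefficient tables
#'
#' Returns the packaged digitisation of the published monoenergetic
#' coefficient tables: fetal organ equivalent dose rate coefficients for the
#' ground-plane (29 energies, 0.015-10 MeV) and air-submersion (20 energies)
#' geometries, and the air-kerma rate coefficients at 1 m height for both
#' geometries.  Values are exactly as printed (3 significant figures); the
#' submersion tables have gaps in the energy grid which are left to the
#' interpolation layer.
#'
#' @param geometry `"ground"` or `"submersion"`.
#' @param organ one of [builtin_organs()] for the geometry, or `"air_kerma"`.
#' @return a [coef_table()].
#' @export
builtin_table <- function(geometry, organ) {
  g <- match_geometry(geometry)
  if (identical(organ, "air_kerma")) {
    df <- .read_fixture(paste0("air_kerma_", g, ".csv"))
    return(coef_table(df$energy_MeV, df$value, g, "air_kerma",
                      quantity = "kerma_rate"))
  }
  df <- .read_fixture(paste0("fetus_", g, ".csv"))
  if (!organ %in% names(df)[-1])
    stop("no packaged table for organ '", organ, "' in geometry '", g,
         "'; available: ", paste(c(names(df)[-1], "air_kerma"), collapse = ", "))
  coef_table(df$energy_MeV, df[[organ]], g, organ)
}

#' Organs available in the packaged tables
#'
#' @param geometry `"ground"` or `"submersion"`.
#' @param include_air_kerma also list `"air_kerma"`.
#' @return character vector of organ labels.
#' @export
builtin_organs <- function(geometry = "ground", include_air_kerma = FALSE) {
  g <- match_geometry(geometry)
  df <- .read_fixture(paste0("fetus_", g, ".csv"))
  out <- names(df)[-1]
  if (include_air_kerma) out <- c(out, "air_kerma")
  out
}

#' Packaged nuclide-specific coefficient summary
#'
#' Per-nuclide air-kerma rate, detriment-weighted dose rate and uterus
#' equivalent dose rate coefficients of the pregnant phantom, together with
#' the fetal total-body equivalent dose rate coefficients, for both exposure
#' geometries (135 selected radionuclides; progeny are not included).
#'
#' @return a data frame with columns `nuclide`, and for each geometry
#'   (`_ground`, `_submersion`) the columns `ka`, `detriment`, `uterus`,
#'   `fetus`.
#' @export
builtin_nuclide_table <- function() {
  .read_fixture("nuclide_coefficients.csv")
}

#' Construct a material specification
#'
#' @param name material label.
#' @param density_gcm3 bulk density in g cm-3.
#' @param composition named numeric vector of element weight percentages
#'   (must sum to 100 within 0.1).
#' @return an object of class `material_spec`.
#' @export
material_spec <- function(name, density_gcm3, composition) {
  stopifnot(is.numeric(density_gcm3), density_gcm3 > 0)
  if (is.null(names(composition)) || any(names(composition) == ""))
    stop("composition must be a named vector of element weight percent")
  if (abs(sum(composition) - 100) > 0.1)
    stop("element weight fractions must sum to 100 +/- 0.1 (got ",
         sum(composition), ")")
  unknown <- setdiff(names(composition), rownames(.element_data))
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  structure(list(name = name, density_gcm3 = density_gcm3,
                 composition = composition),
            class = "material_spec")
}

#' @export
print.material_spec <- function(x, ...) {
  cat(sprintf("<material_spec> %s, %g g/cm3\n", x$name, x$density_gcm3))
  print(x$composition)
  invisible(x)
}

# Z and A for the elements appearing in the reference media.
.element_data <- data.frame(
  Z = c(1, 6, 7, 8, 13, 14, 18, 26),
  A = c(1.008, 12.011, 14.007, 15.999, 26.982, 28.085, 39.948, 55.845),
  row.names = c("H", "C", "N", "O", "Al", "Si", "Ar", "Fe")
)

#' Reference environmental media
#'
#' Dry air (1.2e-3 g cm-3) and a standard mineral soil (1.0 g cm-3) with the
#' elemental weight fractions used for the environmental-field calculations.
#'
#' @return a list with `material_spec` elements `air` and `soil`.
#' @export
reference_materials <- function() {
  list(
    air = material_spec("air", 1.2e-3,
      c(C = 0.01, N = 75.53, O = 23.18, Ar = 1.28)),
    soil = material_spec("soil", 1.0,
      c(H = 2.2, O = 57.5, Al = 8.5, Si = 26.2, Fe = 5.6))
  )
}
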