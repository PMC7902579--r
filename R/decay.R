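DISCRETE_TYPES <- c("photon", "electron")
CONTINUOUS_TYPES <- c("electron_beta", "photon_sf")

#' Construct a radionuclide decay record
#'
#' Holds the emissions of one nuclide per nuclear transformation: discrete
#' photon/electron lines (energy in MeV, yield per decay) and continuous
#' spectra (beta electrons, spontaneous-fission photons) tabulated as yield
#' densities in MeV-1 per decay.  Progeny are never included; coefficients
#' folded from a record apply to the indicated nuclide only.
#'
#' @param nuclide nuclide identifier, e.g. `"Cs-137"`.
#' @param discrete data frame with columns `type` (`"photon"`/`"electron"`),
#'   `energy_MeV` (> 0) and `yield` (>= 0); may have zero rows.
#' @param continuous list of continuous spectra, each a list with elements
#'   `type` (`"electron_beta"`/`"photon_sf"`) and `grid`, a data frame with
#'   strictly increasing `energy_MeV` and non-negative `yield_per_MeV`.
#' @return an object of class `decay_record`.
#' @export
decay_record <- function(nuclide, discrete = NULL, continuous = list()) {
  if (!is.character(nuclide) || length(nuclide) != 1L || !nzchar(nuclide))
    stop("nuclide must be a non-empty character scalar")
  if (is.null(discrete))
    discrete <- data.frame(type = character(), energy_MeV = numeric(),
                           yield = numeric())
  stopifnot(is.data.frame(discrete))
  need <- c("type", "energy_MeV", "yield")
  if (!all(need %in% names(discrete)))
    stop("discrete must have columns type, energy_MeV, yield")
  discrete <- discrete[need]
  if (nrow(discrete)) {
    if (!all(discrete$type %in% DISCRETE_TYPES))
      stop("discrete$type must be one of: ", paste(DISCRETE_TYPES, collapse = ", "))
    if (any(!is.finite(discrete$energy_MeV)) || any(discrete$energy_MeV <= 0))
      stop("discrete emission energies must be positive and finite")
    if (any(!is.finite(discrete$yield)) || any(discrete$yield < 0))
      stop("discrete emission yields must be non-negative")
  }
  stopifnot(is.list(continuous))
  for (i in seq_along(continuous)) {
    sp <- continuous[[i]]
    if (!is.list(sp) || !all(c("type", "grid") %in% names(sp)))
      stop("continuous[[", i, "]] must be a list with elements type and grid")
    if (!sp$type %in% CONTINUOUS_TYPES)
      stop("continuous[[", i, "]]$type must be one of: ",
           paste(CONTINUOUS_TYPES, collapse = ", "))
    g <- sp$grid
    if (!is.data.frame(g) || !all(c("energy_MeV", "yield_per_MeV") %in% names(g)))
      stop("continuous[[", i, "]]$grid needs columns energy_MeV, yield_per_MeV")
    if (nrow(g) < 2 || any(diff(g$energy_MeV) <= 0))
      stop("continuous[[", i, "]]$grid energies must be strictly increasing (>= 2 points)")
    if (any(g$energy_MeV <= 0))
      stop("continuous[[", i, "]]$grid energies must be positive")
    if (any(!is.finite(g$yield_per_MeV)) || any(g$yield_per_MeV < 0))
      stop("continuous[[", i, "]]$grid densities must be non-negative")
    continuous[[i]] <- list(type = sp$type,
                            grid = g[c("energy_MeV", "yield_per_MeV")])
  }
  structure(list(nuclide = nuclide, discrete = discrete,
                 continuous = continuous),
            class = "decay_record")
}

#' @export
print.decay_record <- function(x, ...) {
  cat(sprintf("<decay_record> %s: %d discrete line(s), %d continuous spectrum(-a)\n",
              x$nuclide, nrow(x$discrete), length(x$continuous)))
  invisible(x)
}

.json_num <- function(x, path) {
  if (is.null(x) || !is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("decay JSON: field ", path, " must be a finite number")
  x
}

#' Parse a decay record from JSON
#'
#' The schema emulates the content of a standard nuclear decay-data
#' compilation:
#' \preformatted{
#' {
#'   "nuclide": "Cs-137",
#'   "discrete":   [{"type": "photon", "energy_MeV": 0.6617, "yield": 0.851}],
#'   "continuous": [{"type": "electron_beta",
#'                   "grid": [{"energy_MeV": 0.01, "yield_per_MeV": 1.2}, ...]}]
#' }
#' }
#' Validation errors report the JSON path of the offending field.
#'
#' @param path path to a JSON file.
#' @return a [decay_record()].
#' @export
parse_decay_json <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$nuclide) || !is.character(obj$nuclide))
    stop("decay JSON: field $.nuclide must be a string")
  disc <- obj$discrete %||% list()
  rows <- lapply(seq_along(disc), function(i) {
    d <- disc[[i]]
    p <- sprintf("$.discrete[%d]", i)
    if (is.null(d$type) || !d$type %in% DISCRETE_TYPES)
      stop("decay JSON: field ", p, ".type must be 'photon' or 'electron'")
    e <- .json_num(d$energy_MeV, paste0(p, ".energy_MeV"))
    if (e <= 0) stop("decay JSON: field ", p, ".energy_MeV must be > 0")
    y <- .json_num(d$yield, paste0(p, ".yield"))
    if (y < 0) stop("decay JSON: field ", p, ".yield must be >= 0")
    data.frame(type = d$type, energy_MeV = e, yield = y)
  })
  discrete <- if (length(rows)) do.call(rbind, rows) else NULL
  cont <- obj$continuous %||% list()
  continuous <- lapply(seq_along(cont), function(i) {
    sp <- cont[[i]]
    p <- sprintf("$.continuous[%d]", i)
    if (is.null(sp$type) || !sp$type %in% CONTINUOUS_TYPES)
      stop("decay JSON: field ", p, ".type must be 'electron_beta' or 'photon_sf'")
    if (is.null(sp$grid) || !length(sp$grid))
      stop("decay JSON: field ", p, ".grid must be a non-empty array")
    g <- do.call(rbind, lapply(seq_along(sp$grid), function(j) {
      q <- sprintf("%s.grid[%d]", p, j)
      data.frame(
        energy_MeV = .json_num(sp$grid[[j]]$energy_MeV, paste0(q, ".energy_MeV")),
        yield_per_MeV = .json_num(sp$grid[[j]]$yield_per_MeV,
                                  paste0(q, ".yield_per_MeV")))
    }))
    if (any(g$yield_per_MeV < 0))
      stop("decay JSON: field ", p, ".grid yield_per_MeV must be >= 0")
    list(type = sp$type, grid = g)
  })
  decay_record(obj$nuclide, discrete, continuous)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialise a decay record to JSON
#'
#' Round-trips through [parse_decay_json()] semantically unchanged.
#'
#' @param record a [decay_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_decay_json <- function(record, path) {
  stopifnot(inherits(record, "decay_record"))
  disc <- lapply(seq_len(nrow(record$discrete)), function(i)
    list(type = record$discrete$type[i],
         energy_MeV = record$discrete$energy_MeV[i],
         yield = record$discrete$yield[i]))
  cont <- lapply(record$continuous, function(sp)
    list(type = sp$type,
         grid = lapply(seq_len(nrow(sp$grid)), function(j)
           list(energy_MeV = sp$grid$energy_MeV[j],
                yield_per_MeV = sp$grid$yield_per_MeV[j]))))
  jsonlite::write_json(list(nuclide = record$nuclide, discrete = disc,
                            continuous = cont),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Generate a synthetic nuclide for testing
#'
#' Creates a reproducible random decay record: discrete lines with energies
#' uniform in log-energy over `energy_range` and yields uniform in (0, 1\],
#' and beta branches with an allowed-shape spectrum
#' N(E) proportional to p E_tot (Emax - E)^2 (Fermi function approximated as
#' 1), tabulated on a 40-point grid and normalised to a sampled per-decay
#' branch yield.
#'
#' @param seed integer seed (record is a pure function of seed + spec).
#' @param n_lines number of discrete lines.
#' @param energy_range range for discrete line energies (MeV), within (0, 10].
#' @param n_beta number of continuous beta branches.
#' @param beta_endpoint_range range for beta endpoint energies (MeV).
#' @param p_electron probability that a discrete line is an electron rather
#'   than a photon.
#' @return a [decay_record()].
#' @export
synth_nuclide <- function(seed, n_lines = 3, energy_range = c(0.02, 3),
                          n_beta = 1, beta_endpoint_range = c(0.1, 2),
                          p_electron = 0.3) {
  stopifnot(length(energy_range) == 2, length(beta_endpoint_range) == 2)
  if (n_lines + n_beta == 0)
    stop("empty spec: need at least one discrete line or beta branch")
  if (energy_range[1] <= 0 || energy_range[2] > 10 ||
      beta_endpoint_range[1] <= 0 || beta_endpoint_range[2] > 10)
    stop("spec energy ranges must lie within (0, 10] MeV")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  discrete <- NULL
  if (n_lines > 0) {
    E <- 10^runif(n_lines, log10(energy_range[1]), log10(energy_range[2]))
    discrete <- data.frame(
      type = ifelse(runif(n_lines) < p_electron, "electron", "photon"),
      energy_MeV = E,
      yield = runif(n_lines))
  }
  continuous <- list()
  me <- 0.510999
  for (b in seq_len(n_beta)) {
    emax <- runif(1, beta_endpoint_range[1], beta_endpoint_range[2])
    yield <- runif(1)
    E <- seq(emax / 400, emax, length.out = 40)
    p <- sqrt(E^2 + 2 * E * me)
    dens <- p * (E + me) * (emax - E)^2
    dens <- dens / .trapz(E, dens) * yield
    continuous[[b]] <- list(type = "electron_beta",
                            grid = data.frame(energy_MeV = E,
                                              yield_per_MeV = dens))
  }
  decay_record(sprintf("SYN-%d", as.integer(seed)), discrete, continuous)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1])) / 2

# ---------------------------------------------------------------------------
# Bremsstrahlung kernels
# ---------------------------------------------------------------------------

#' Construct a bremsstrahlung kernel
#'
#' A kernel gives, for each initial electron energy `E_e` on a grid, the
#' photon spectrum B(k | E_e) in photons MeV-1 emitted while the electron
#' stops in the stated medium (thick-target approximation).  Invariants:
#' B >= 0, B(k | E_e) = 0 for k > E_e, and the radiated energy
#' integral(k B dk) cannot exceed E_e.
#'
#' @param medium medium label (e.g. `"air"`).
#' @param electron_energies increasing vector of initial electron energies
#'   (MeV).
#' @param spectra list (same length) of data frames with columns `k_MeV`
#'   (photon energy, increasing, <= E_e) and `B_per_MeV`.
#' @param geometry optional exposure geometry the kernel is configured for.
#' @return an object of class `brems_kernel`.
#' @export
brems_kernel <- function(medium, electron_energies, spectra, geometry = NULL) {
  stopifnot(is.numeric(electron_energies), length(spectra) == length(electron_energies))
  if (any(diff(electron_energies) <= 0))
    stop("electron energies must be strictly increasing")
  for (i in seq_along(spectra)) {
    g <- spectra[[i]]
    if (!is.data.frame(g) || !all(c("k_MeV", "B_per_MeV") %in% names(g)))
      stop("spectrum ", i, " needs columns k_MeV, B_per_MeV")
    if (any(g$B_per_MeV < 0)) stop("spectrum ", i, ": B must be >= 0")
    if (any(g$k_MeV > electron_energies[i] * (1 + 1e-9)))
      stop("spectrum ", i, ": photon energies exceed the electron energy")
    if (nrow(g) >= 2) {
      if (any(diff(g$k_MeV) <= 0)) stop("spectrum ", i, ": k grid must increase")
      erad <- .trapz(g$k_MeV, g$k_MeV * g$B_per_MeV)
      if (erad > electron_energies[i] * (1 + 1e-9))
        stop("spectrum ", i, ": radiated energy ", signif(erad, 4),
             " MeV exceeds the electron energy")
    }
  }
  structure(list(medium = medium, electron_energies = electron_energies,
                 spectra = spectra, geometry = geometry),
            class = "brems_kernel")
}

#' @export
print.brems_kernel <- function(x, ...) {
  cat(sprintf("<brems_kernel> medium %s, %d electron energies [%g, %g] MeV\n",
              x$medium, length(x$electron_energies),
              min(x$electron_energies), max(x$electron_energies)))
  invisible(x)
}

#' Kramers-like default bremsstrahlung kernel
#'
#' Builds a thick-target kernel with the classical 1/k photon spectrum,
#' truncated at the electron energy and at a low-energy bound `k_min`, and
#' scaled so that the tabulated radiated-energy integral equals
#' `Y_rad(E_e) * E_e` exactly, where `Y_rad` is the supplied radiative yield
#' (fraction of the electron energy converted to bremsstrahlung).  This is a
#' documented approximation standing in for measured thick-target spectra; a
#' kernel tabulated from such spectra can be loaded with
#' [load_brems_kernel()] instead.
#'
#' @param medium a [material_spec()] or medium label.
#' @param yield_table data frame with columns `E_e_MeV` and `Y_rad` (each
#'   yield in \[0, 1\]).
#' @param k_min low-energy truncation of the 1/k spectrum (MeV).
#' @param n_k number of (log-spaced) photon grid points per electron energy.
#' @param geometry optional geometry tag.
#' @return a [brems_kernel()].
#' @export
kramers_kernel <- function(medium, yield_table, k_min = 0.002, n_k = 200,
                           geometry = NULL) {
  stopifnot(is.data.frame(yield_table),
            all(c("E_e_MeV", "Y_rad") %in% names(yield_table)))
  if (any(yield_table$Y_rad < 0 | yield_table$Y_rad > 1))
    stop("radiative yields must lie in [0, 1]")
  label <- if (inherits(medium, "material_spec")) medium$name else medium
  Ee <- yield_table$E_e_MeV
  spectra <- lapply(seq_along(Ee), function(i) {
    e <- Ee[i]; y <- yield_table$Y_rad[i]
    if (y == 0 || e <= k_min) {
      k <- c(k_min, max(e, k_min * (1 + 1e-6)))
      return(data.frame(k_MeV = k, B_per_MeV = c(0, 0)))
    }
    k <- exp(seq(log(k_min), log(e), length.out = n_k))
    B <- 1 / k
    erad <- .trapz(k, k * B)
    data.frame(k_MeV = k, B_per_MeV = B * (y * e / erad))
  })
  brems_kernel(label, Ee, spectra, geometry = geometry)
}

#' Default radiative-yield table for a medium
#'
#' A simple linear approximation Y_rad(E) = min(1, 3e-4 * Zbar * E) with
#' Zbar the electron-fraction-weighted mean atomic number; for air this
#' gives about 0.2% at 1 MeV, the magnitude quoted for thick-target
#' bremsstrahlung of beta particles in air.  Synthetic, documented stand-in
#' for measured radiative yields.
#'
#' @param material a [material_spec()].
#' @param energies electron energies (MeV) at which to tabulate.
#' @return data frame with columns `E_e_MeV`, `Y_rad`.
#' @export
radiative_yield_table <- function(material,
                                  energies = 10^seq(log10(0.015), 1, length.out = 25)) {
  stopifnot(inherits(material, "material_spec"))
  w <- material$composition / 100
  el <- .element_data[names(w), ]
  zbar <- sum(w * el$Z^2 / el$A) / sum(w * el$Z / el$A)
  data.frame(E_e_MeV = energies, Y_rad = pmin(1, 3e-4 * zbar * energies))
}

#' Load a bremsstrahlung kernel from CSV
#'
#' Long format with header `E_e_MeV,k_MeV,B_per_MeV`: one row per photon
#' grid point, grouped by electron energy.
#'
#' @param path CSV path.
#' @param medium medium label.
#' @param geometry optional geometry tag.
#' @return a [brems_kernel()].
#' @export
load_brems_kernel <- function(path, medium = "user", geometry = NULL) {
  df <- utils::read.csv(path, header = TRUE)
  if (!all(c("E_e_MeV", "k_MeV", "B_per_MeV") %in% names(df)))
    stop("kernel CSV needs columns E_e_MeV, k_MeV, B_per_MeV")
  Ee <- sort(unique(df$E_e_MeV))
  spectra <- lapply(Ee, function(e) {
    g <- df[df$E_e_MeV == e, c("k_MeV", "B_per_MeV")]
    g[order(g$k_MeV), ]
  })
  brems_kernel(medium, Ee, spectra, geometry = geometry)
}

#' Write a bremsstrahlung kernel to CSV
#'
#' @param kernel a [brems_kernel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_brems_kernel <- function(kernel, path) {
  stopifnot(inherits(kernel, "brems_kernel"))
  rows <- do.call(rbind, lapply(seq_along(kernel$electron_energies), function(i)
    cbind(E_e_MeV = kernel$electron_energies[i], kernel$spectra[[i]])))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Weighting configuration
# ---------------------------------------------------------------------------

#' Radiation and tissue weighting configuration
#'
#' Photons and electrons both carry radiation weighting factor 1, so
#' equivalent and absorbed dose rate coefficients coincide numerically; the
#' weights are exposed for completeness.  Tissue weights, when supplied as a
#' full set, must sum to 1.
#'
#' @param w_photon,w_electron radiation weighting factors.
#' @param tissue_weights optional named numeric vector of tissue weighting
#'   factors.
#' @param full_set if `TRUE` (default when `tissue_weights` is given),
#'   require the tissue weights to sum to 1.
#' @return an object of class `weighting_config`.
#' @export
weighting_config <- function(w_photon = 1, w_electron = 1,
                             tissue_weights = NULL, full_set = TRUE) {
  if (!is.null(tissue_weights)) {
    if (is.null(names(tissue_weights)))
      stop("tissue_weights must be named by organ")
    if (any(tissue_weights < 0)) stop("tissue weights must be >= 0")
    if (full_set && abs(sum(tissue_weights) - 1) > 1e-6)
      stop("a full tissue-weight set must sum to 1 (got ",
           sum(tissue_weights), ")")
  }
  structure(list(w_photon = w_photon, w_electron = w_electron,
                 tissue_weights = tissue_weights),
            class = "weighting_config")
}

#' Standard tissue weighting factors
#'
#' The 2007 recommendations' tissue weighting factor set (sums to 1).
#'
#' @return named numeric vector.
#' @export
icrp103_weights <- function() {
  c(red_bone_marrow = 0.12, colon = 0.12, lung = 0.12, stomach = 0.12,
    breast = 0.12, remainder = 0.12, gonads = 0.08, bladder = 0.04,
    oesophagus = 0.04, liver = 0.04, thyroid = 0.04, bone_surface = 0.01,
    brain = 0.01, salivary_glands = 0.01, skin = 0.01)
}
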