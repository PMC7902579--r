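# ---------------------------------------------------------------------------
# Simplified analog photon Monte Carlo of the environmental field: a world
# cylinder of air over soil, an optional ideal-absorber coupling cylinder at
# the origin, and an optional track-length fluence tally.  Photons only;
# secondary electrons are not followed (no environmental bremsstrahlung
# generation), Compton scattering is free-electron Klein-Nishina,
# photoelectric absorbs, pair production absorbs and emits two 0.511 MeV
# annihilation photons.
# ---------------------------------------------------------------------------

#' Coupling-cylinder specification
#'
#' The virtual ideal-absorber cylinder at the air-ground interface on whose
#' surface environmental-field particles are recorded: diameter 2 m / height
#' 2.5 m for the ground geometry, 0.6 m / 2 m for submersion.
#'
#' @param geometry `"ground"` or `"submersion"` for the standard sizes, or
#'   `NULL` with explicit dimensions.
#' @param diameter,height explicit dimensions in m.
#' @return an object of class `coupling_cylinder`.
#' @export
coupling_cylinder <- function(geometry = NULL, diameter = NULL, height = NULL) {
  if (!is.null(geometry)) {
    g <- match_geometry(geometry)
    if (g == "ground") { diameter <- 2; height <- 2.5 }
    else { diameter <- 0.6; height <- 2 }
  }
  stopifnot(is.numeric(diameter), diameter > 0, is.numeric(height), height > 0)
  structure(list(radius = diameter / 2, diameter = diameter, height = height),
            class = "coupling_cylinder")
}

#' Environmental-field configuration
#'
#' World geometry defaults: a right circular cylinder of 500 m radius with a
#' 500 m air layer over 1 m of soil.  The standard sources are a plane at an
#' areal-mass depth of 0.5 g cm-2 in the soil (ground contamination) and a
#' uniform air volume up to 1000 m (submersion; capped at the air height).
#' `"beam"` and `"point"` sources are provided for verification runs.
#'
#' @param source `"plane"`, `"volume"`, `"beam"` or `"point"`.
#' @param energy_MeV source photon energy.
#' @param histories number of primary photons.
#' @param seed RNG seed.
#' @param world_radius,air_height,soil_depth world dimensions (m).
#' @param source_depth_gcm2 plane-source depth in areal mass (g cm-2);
#'   converted to length with the soil density.
#' @param source_height volume-source height (m).
#' @param cutoff_MeV photon termination energy (default 2 keV).
#' @param materials list with `material_spec`s `air` and `soil`.
#' @param att_air,att_soil attenuation tables (default synthetic).
#' @param vacuum logical; `TRUE` disables all interactions (mu = 0).
#' @param source_position,source_direction for beam/point sources.
#' @param source_azimuth azimuthal offset added when sampling horizontal
#'   source positions (the field is rotationally invariant; exposed for
#'   verification).
#' @return an object of class `field_config`.
#' @export
field_config <- function(source = c("plane", "volume", "beam", "point"),
                         energy_MeV, histories, seed = 1,
                         world_radius = 500, air_height = 500, soil_depth = 1,
                         source_depth_gcm2 = 0.5, source_height = 1000,
                         cutoff_MeV = 0.002,
                         materials = reference_materials(),
                         att_air = NULL, att_soil = NULL,
                         vacuum = FALSE,
                         source_position = NULL, source_direction = NULL,
                         source_azimuth = 0) {
  source <- match.arg(source)
  stopifnot(is.numeric(energy_MeV), energy_MeV > 0, energy_MeV <= 10)
  if (cutoff_MeV >= energy_MeV)
    stop("cutoff must be below the source energy")
  if (is.null(att_air)) att_air <- synthetic_attenuation(materials$air)
  if (is.null(att_soil)) att_soil <- synthetic_attenuation(materials$soil)
  structure(list(
    source = source, energy_MeV = energy_MeV, histories = histories,
    seed = seed, world_radius = world_radius, air_height = air_height,
    soil_depth = soil_depth, source_depth_gcm2 = source_depth_gcm2,
    source_height = source_height, cutoff_MeV = cutoff_MeV,
    materials = materials, att_air = att_air, att_soil = att_soil,
    vacuum = vacuum, source_position = source_position,
    source_direction = source_direction, source_azimuth = source_azimuth
  ), class = "field_config")
}

#' Sample Compton scattering from the Klein-Nishina distribution
#'
#' Free-electron Klein-Nishina sampling by rejection with a uniform proposal
#' in the scattered-to-incident energy ratio.
#'
#' @param E_MeV incident photon energy (scalar).
#' @param n number of samples.
#' @return list with `eps` (E'/E) and `costh` (scattering-angle cosine).
#' @export
sample_klein_nishina <- function(E_MeV, n) {
  k <- E_MeV / .ME_MEV
  emin <- 1 / (1 + 2 * k)
  ffun <- function(eps) {
    costh <- 1 - (1 / eps - 1) / k
    eps + 1 / eps - 1 + costh^2
  }
  M <- max(ffun(seq(emin, 1, length.out = 64))) * 1.0001
  eps <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    m <- length(need)
    cand <- runif(m, emin, 1)
    acc <- runif(m) * M <= ffun(cand)
    eps[need[acc]] <- cand[acc]
    need <- need[!acc]
  }
  list(eps = eps, costh = 1 - (1 / eps - 1) / k)
}

# Rotate unit vectors (u,v,w) by polar angle acos(costh) about themselves
# with azimuth psi (vectorised).
.rotate_dir <- function(u, v, w, costh, psi) {
  sinth <- sqrt(pmax(0, 1 - costh^2))
  cpsi <- cos(psi); spsi <- sin(psi)
  denom <- sqrt(pmax(1e-300, 1 - w^2))
  straight <- denom < 1e-10
  nu <- u * costh + sinth * (u * w * cpsi - v * spsi) / denom
  nv <- v * costh + sinth * (v * w * cpsi + u * spsi) / denom
  nw <- w * costh - sinth * denom * cpsi
  # near-vertical special case
  nu[straight] <- (sinth * cpsi)[straight]
  nv[straight] <- (sinth * spsi)[straight]
  nw[straight] <- (sign(w) * costh)[straight]
  nrm <- sqrt(nu^2 + nv^2 + nw^2)
  list(u = nu / nrm, v = nv / nrm, w = nw / nrm)
}

.iso_dir <- function(n) {
  w <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(1 - w^2)
  list(u = s * cos(phi), v = s * sin(phi), w = w)
}

# Sample primary source states for a chunk.
.sample_source <- function(cfg, n) {
  if (cfg$source == "beam") {
    p <- cfg$source_position; d <- cfg$source_direction
    if (is.null(p) || is.null(d)) stop("beam source needs position and direction")
    d <- d / sqrt(sum(d^2))
    return(list(x = rep(p[1], n), y = rep(p[2], n), z = rep(p[3], n),
                u = rep(d[1], n), v = rep(d[2], n), w = rep(d[3], n),
                E = rep(cfg$energy_MeV, n)))
  }
  if (cfg$source == "point") {
    p <- cfg$source_position
    if (is.null(p)) stop("point source needs a position")
    dd <- .iso_dir(n)
    return(list(x = rep(p[1], n), y = rep(p[2], n), z = rep(p[3], n),
                u = dd$u, v = dd$v, w = dd$w, E = rep(cfg$energy_MeV, n)))
  }
  r <- cfg$world_radius * sqrt(runif(n))
  phi <- cfg$source_azimuth + runif(n, 0, 2 * pi)
  z <- if (cfg$source == "plane") {
    rep(-cfg$source_depth_gcm2 / cfg$materials$soil$density_gcm3 / 100, n)
  } else {
    runif(n, 0, min(cfg$source_height, cfg$air_height))
  }
  dd <- .iso_dir(n)
  list(x = r * cos(phi), y = r * sin(phi), z = z,
       u = dd$u, v = dd$v, w = dd$w, E = rep(cfg$energy_MeV, n))
}

# Distance to the lateral world boundary (radius R), from inside.
.dist_radial <- function(x, y, u, v, R) {
  a <- u^2 + v^2
  b <- 2 * (x * u + y * v)
  c0 <- x^2 + y^2 - R^2
  t <- rep(Inf, length(x))
  ok <- a > 1e-14
  disc <- b^2 - 4 * a * c0
  root <- (-b + sqrt(pmax(disc, 0))) / (2 * a)
  t[ok & disc > 0 & root > 0] <- root[ok & disc > 0 & root > 0]
  t
}

# Entry distance to the absorber cylinder (radius Rc, z in [0, Hc]) from
# outside; Inf when the ray misses.
.dist_absorber <- function(x, y, z, u, v, w, Rc, Hc) {
  n <- length(x)
  t <- rep(Inf, n)
  # side wall
  a <- u^2 + v^2
  b <- 2 * (x * u + y * v)
  c0 <- x^2 + y^2 - Rc^2
  disc <- b^2 - 4 * a * c0
  ok <- a > 1e-14 & disc > 0 & c0 > 0
  sq <- sqrt(pmax(disc, 0))
  t1 <- (-b - sq) / (2 * a)
  zz <- z + t1 * w
  hit <- ok & t1 > 1e-12 & zz >= 0 & zz <= Hc
  t[hit] <- t1[hit]
  # top lid (from above, moving down)
  tt <- (Hc - z) / w
  rr2 <- (x + tt * u)^2 + (y + tt * v)^2
  hit <- w < 0 & z > Hc & tt > 1e-12 & rr2 <= Rc^2 & tt < t
  t[hit] <- tt[hit]
  # bottom lid (from the soil, moving up)
  tb <- -z / w
  rb2 <- (x + tb * u)^2 + (y + tb * v)^2
  hit <- w > 0 & z < 0 & tb > 1e-12 & rb2 <= Rc^2 & tb < t
  t[hit] <- tb[hit]
  t
}

# Overlap length of segment [0, tmax] along (x,y,z)+(u,v,w)t with the
# cylinder-slab region r < Rt, z in [z1, z2].
.tally_overlap <- function(x, y, z, u, v, w, tmax, Rt, z1, z2) {
  n <- length(x)
  lo <- numeric(n); hi <- pmin(tmax, Inf)
  # z interval
  zlo <- ifelse(abs(w) < 1e-14, ifelse(z >= z1 & z <= z2, 0, Inf),
                pmin((z1 - z) / w, (z2 - z) / w))
  zhi <- ifelse(abs(w) < 1e-14, ifelse(z >= z1 & z <= z2, Inf, -Inf),
                pmax((z1 - z) / w, (z2 - z) / w))
  # radial interval
  a <- u^2 + v^2
  b <- 2 * (x * u + y * v)
  c0 <- x^2 + y^2 - Rt^2
  disc <- b^2 - 4 * a * c0
  vertical <- a <= 1e-14
  inside_r <- c0 < 0
  sq <- sqrt(pmax(disc, 0))
  rlo <- ifelse(vertical, ifelse(inside_r, 0, Inf), (-b - sq) / (2 * a))
  rhi <- ifelse(vertical, ifelse(inside_r, Inf, -Inf), (-b + sq) / (2 * a))
  rlo[!vertical & disc <= 0] <- Inf
  rhi[!vertical & disc <= 0] <- -Inf
  s <- pmax(0, pmax(zlo, rlo))
  e <- pmin(tmax, pmin(zhi, rhi))
  pmax(0, e - s)
}

# Transport one chunk of particles to completion.  Returns crossing /
# escape records and tally sums.
.transport_chunk <- function(cfg, n, cylinder = NULL, tally = NULL,
                             record_escapes = FALSE) {
  st <- .sample_source(cfg, n)
  x <- st$x; y <- st$y; z <- st$z
  u <- st$u; v <- st$v; w <- st$w; E <- st$E
  fa <- .att_fun(cfg$att_air); fs <- .att_fun(cfg$att_soil)
  rho_a <- cfg$materials$air$density_gcm3
  rho_s <- cfg$materials$soil$density_gcm3
  Rw <- cfg$world_radius; Ha <- cfg$air_height; Ds <- cfg$soil_depth
  cross <- list(); esc <- list()
  tal_len <- NULL; tal_kerma <- 0
  if (!is.null(tally)) {
    tal_len <- numeric(length(tally$edges) - 1L)
    mu_tr <- .loglog_fun(tally$mu_tr$energy_MeV, tally$mu_tr$mu_tr_rho)
  }
  guard <- 0L
  while (length(x) && (guard <- guard + 1L) < 10000L) {
    m <- length(x)
    in_air <- z >= 0
    if (cfg$vacuum) {
      mu <- rep(0, m)
      part <- NULL
    } else {
      part <- matrix(0, m, 4, dimnames = list(NULL, c("pe", "incoh", "pair", "total")))
      if (any(in_air)) part[in_air, ] <- fa(E[in_air]) * rho_a * 100
      if (any(!in_air)) part[!in_air, ] <- fs(E[!in_air]) * rho_s * 100
      mu <- part[, "total"]            # per metre
    }
    t_int <- ifelse(mu > 0, -log(runif(m)) / mu, Inf)
    # medium / world plane crossings
    t_change <- rep(Inf, m); t_escape_z <- rep(Inf, m)
    up <- w > 1e-14; dn <- w < -1e-14
    t_change[in_air & dn] <- (0 - z[in_air & dn]) / w[in_air & dn]
    t_escape_z[in_air & up] <- (Ha - z[in_air & up]) / w[in_air & up]
    t_change[!in_air & up] <- (0 - z[!in_air & up]) / w[!in_air & up]
    t_escape_z[!in_air & dn] <- (-Ds - z[!in_air & dn]) / w[!in_air & dn]
    t_rad <- .dist_radial(x, y, u, v, Rw)
    t_abs <- if (is.null(cylinder)) rep(Inf, m)
             else .dist_absorber(x, y, z, u, v, w, cylinder$radius, cylinder$height)
    tmat <- cbind(t_int, t_change, t_escape_z, t_rad, t_abs)
    te <- do.call(pmin, as.data.frame(tmat))
    ev <- max.col(-tmat, ties.method = "first")
    if (!is.null(tally)) {
      ov <- .tally_overlap(x, y, z, u, v, w, te, tally$radius,
                           tally$z1, tally$z2)
      hitters <- ov > 0
      if (any(hitters)) {
        bins <- findInterval(E[hitters], tally$edges, rightmost.closed = TRUE)
        ok <- bins >= 1 & bins < length(tally$edges)
        if (any(ok)) {
          tl <- tapply(ov[hitters][ok], bins[ok], sum)
          tal_len[as.integer(names(tl))] <- tal_len[as.integer(names(tl))] + tl
        }
        tal_kerma <- tal_kerma +
          sum(ov[hitters] * E[hitters] * mu_tr(E[hitters]))
      }
    }
    x <- x + te * u; y <- y + te * v; z <- z + te * w
    alive <- rep(TRUE, m)
    new <- NULL
    # absorber crossings
    hit <- ev == 5L
    if (any(hit)) {
      cross[[length(cross) + 1L]] <- data.frame(
        x = x[hit], y = y[hit], z = z[hit],
        u = u[hit], v = v[hit], w = w[hit],
        energy_MeV = E[hit], weight = 1)
      alive[hit] <- FALSE
    }
    # world escapes
    out <- ev == 3L | ev == 4L
    if (any(out)) {
      if (record_escapes)
        esc[[length(esc) + 1L]] <- data.frame(
          surface = ifelse(ev[out] == 4L, "side",
                           ifelse(w[out] > 0, "top", "bottom")),
          x = x[out], y = y[out], z = z[out],
          u = u[out], v = v[out], w = w[out], energy_MeV = E[out])
      alive[out] <- FALSE
    }
    # medium change: nudge across the interface
    chg <- ev == 2L
    if (any(chg)) {
      x[chg] <- x[chg] + 1e-9 * u[chg]
      y[chg] <- y[chg] + 1e-9 * v[chg]
      z[chg] <- z[chg] + 1e-9 * w[chg]
    }
    # interactions
    ia <- ev == 1L & alive
    if (any(ia)) {
      idx <- which(ia)
      r <- runif(length(idx))
      fr_pe <- part[idx, "pe"] / part[idx, "total"]
      fr_inc <- part[idx, "incoh"] / part[idx, "total"]
      kill_pe <- r < fr_pe
      compton <- !kill_pe & r < fr_pe + fr_inc
      pairp <- !kill_pe & !compton
      alive[idx[kill_pe]] <- FALSE
      if (any(compton)) {
        ci <- idx[compton]
        for (Eu in unique(E[ci])) {
          sel <- ci[E[ci] == Eu]
          kn <- sample_klein_nishina(Eu, length(sel))
          psi <- runif(length(sel), 0, 2 * pi)
          nd <- .rotate_dir(u[sel], v[sel], w[sel], kn$costh, psi)
          u[sel] <- nd$u; v[sel] <- nd$v; w[sel] <- nd$w
          E[sel] <- E[sel] * kn$eps
        }
        dead <- ci[E[ci] < cfg$cutoff_MeV]
        alive[dead] <- FALSE
      }
      if (any(pairp)) {
        pi2 <- idx[pairp]
        alive[pi2] <- FALSE
        dd <- .iso_dir(length(pi2))
        new <- list(
          x = rep(x[pi2], 2), y = rep(y[pi2], 2), z = rep(z[pi2], 2),
          u = c(dd$u, -dd$u), v = c(dd$v, -dd$v), w = c(dd$w, -dd$w),
          E = rep(0.510998950, 2 * length(pi2)))
      }
    }
    keep <- alive
    x <- x[keep]; y <- y[keep]; z <- z[keep]
    u <- u[keep]; v <- v[keep]; w <- w[keep]; E <- E[keep]
    if (!is.null(new)) {
      x <- c(x, new$x); y <- c(y, new$y); z <- c(z, new$z)
      u <- c(u, new$u); v <- c(v, new$v); w <- c(w, new$w); E <- c(E, new$E)
    }
  }
  list(
    crossings = if (length(cross)) do.call(rbind, cross) else NULL,
    escapes = if (length(esc)) do.call(rbind, esc) else NULL,
    tally_len = tal_len, tally_kerma = tal_kerma
  )
}

#' Run the environmental-field Monte Carlo
#'
#' Transports `histories` source photons through the air-over-soil world;
#' photons striking the coupling cylinder are terminated and recorded
#' (energy, direction cosine against the upward vertical, and height for
#' side crossings).
#'
#' @param config a [field_config()].
#' @param cylinder a [coupling_cylinder()], or `NULL` to transport without
#'   an absorber.
#' @param record_escapes also return photons leaving the world.
#' @param chunk_size particles per vectorised transport chunk.
#' @return an object of class `field_run` with elements `crossings` (data
#'   frame: x, y, z, u, v, w, energy_MeV, weight, surface, cos_theta, h),
#'   `escapes`, `n_histories`, `config`, `cylinder`.
#' @export
run_field <- function(config, cylinder = NULL, record_escapes = FALSE,
                      chunk_size = 20000L) {
  stopifnot(inherits(config, "field_config"))
  if (is.null(config$histories) || config$histories < 1)
    stop("histories must be at least 1")
  set.seed(config$seed)
  left <- config$histories
  crossings <- list(); escapes <- list()
  while (left > 0) {
    n <- min(left, chunk_size)
    res <- .transport_chunk(config, n, cylinder = cylinder,
                            record_escapes = record_escapes)
    if (!is.null(res$crossings)) crossings[[length(crossings) + 1L]] <- res$crossings
    if (!is.null(res$escapes)) escapes[[length(escapes) + 1L]] <- res$escapes
    left <- left - n
  }
  crossings <- if (length(crossings)) do.call(rbind, crossings) else
    data.frame(x = numeric(), y = numeric(), z = numeric(), u = numeric(),
               v = numeric(), w = numeric(), energy_MeV = numeric(),
               weight = numeric())
  if (nrow(crossings) && !is.null(cylinder)) {
    r <- sqrt(crossings$x^2 + crossings$y^2)
    on_side <- abs(r - cylinder$radius) < 1e-6 &
      crossings$z > 1e-9 & crossings$z < cylinder$height - 1e-9
    crossings$surface <- ifelse(on_side, "side",
                                ifelse(crossings$z >= cylinder$height / 2,
                                       "lid_top", "lid_bottom"))
    crossings$cos_theta <- crossings$w
    crossings$h <- ifelse(on_side, crossings$z, NA_real_)
  }
  structure(list(
    crossings = crossings,
    escapes = if (length(escapes)) do.call(rbind, escapes) else NULL,
    n_histories = config$histories, config = config, cylinder = cylinder
  ), class = "field_run")
}

#' @export
print.field_run <- function(x, ...) {
  cat(sprintf("<field_run> %d histories, %d cylinder crossings\n",
              x$n_histories, nrow(x$crossings)))
  invisible(x)
}

#' Energy bin edges on the per-decade grid
#'
#' Generates bin edges with mantissas 1.0, 1.5, 2, 3, 4, 5, 6, 7, 8, 9 in
#' every decade, covering \[`emin`, `emax`\].
#'
#' @param emin,emax energy range (MeV).
#' @return increasing numeric vector of edges.
#' @export
decade_energy_edges <- function(emin, emax) {
  stopifnot(emin > 0, emax > emin)
  mant <- c(1, 1.5, 2, 3, 4, 5, 6, 7, 8, 9)
  dec <- seq(floor(log10(emin)) - 1, ceiling(log10(emax)))
  edges <- sort(unique(signif(as.vector(outer(mant, 10^dec)), 12)))
  lo <- max(which(edges <= emin * (1 + 1e-12)))
  hi <- min(which(edges >= emax * (1 - 1e-12)))
  edges[lo:hi]
}

#' Bin coupling-cylinder crossings into phase-space PDFs
#'
#' Builds the discrete probability density functions p_S(cos theta, h, E) on
#' the cylinder side and p_L(cos theta, E) on the lids.  Bin widths: 0.1 in
#' cos theta over \[-1, 1\], 10 cm in height, and the per-decade energy grid
#' of [decade_energy_edges()].  Bins are half-open \[low, high) with the
#' final bin closed; side and lid probabilities jointly sum to 1.
#'
#' @param crossings a `field_run` or its crossings data frame (columns
#'   `surface`, `cos_theta`, `h`, `energy_MeV`).
#' @param cylinder a [coupling_cylinder()] (taken from the run if omitted).
#' @param source_energy_MeV upper end of the energy grid (taken from the run
#'   config if omitted).
#' @param cutoff_MeV lower end of the energy grid.
#' @return an object of class `phase_space_pdf`.
#' @export
bin_phase_space <- function(crossings, cylinder = NULL,
                            source_energy_MeV = NULL, cutoff_MeV = 0.002) {
  if (inherits(crossings, "field_run")) {
    if (is.null(cylinder)) cylinder <- crossings$cylinder
    if (is.null(source_energy_MeV)) source_energy_MeV <- crossings$config$energy_MeV
    if (!is.null(crossings$config$cutoff_MeV)) cutoff_MeV <- crossings$config$cutoff_MeV
    crossings <- crossings$crossings
  }
  if (is.null(cylinder)) stop("a coupling_cylinder is required")
  if (is.null(source_energy_MeV)) stop("source_energy_MeV is required")
  if (is.null(crossings) || nrow(crossings) == 0)
    stop("no crossings to bin")
  if (!all(c("surface", "cos_theta", "energy_MeV") %in% names(crossings)))
    stop("crossings need columns surface, cos_theta, h, energy_MeV")
  if (any(abs(crossings$cos_theta) > 1 + 1e-9))
    stop("invalid crossing: |cos theta| > 1")
  if (any(crossings$energy_MeV > source_energy_MeV * (1 + 1e-9)))
    stop("invalid crossing: recorded energy exceeds the source energy")
  side <- crossings$surface == "side"
  if (any(side & (crossings$h < -1e-9 | crossings$h > cylinder$height + 1e-9)))
    stop("invalid crossing: side height outside the cylinder")
  cos_edges <- (-10:10) / 10
  h_edges <- seq(0, cylinder$height + 1e-12, by = 0.1)
  if (abs(h_edges[length(h_edges)] - cylinder$height) > 1e-9)
    h_edges <- c(h_edges, cylinder$height)
  e_edges <- decade_energy_edges(cutoff_MeV, source_energy_MeV)
  nc <- length(cos_edges) - 1L; nh <- length(h_edges) - 1L
  ne <- length(e_edges) - 1L
  bin_of <- function(xx, edges)
    pmin(pmax(findInterval(xx, edges, rightmost.closed = TRUE), 1L),
         length(edges) - 1L)
  n_tot <- nrow(crossings)
  side_counts <- array(0L, dim = c(nc, nh, ne))
  lid_counts <- array(0L, dim = c(nc, ne))
  if (any(side)) {
    ci <- bin_of(crossings$cos_theta[side], cos_edges)
    hi <- bin_of(crossings$h[side], h_edges)
    ei <- bin_of(crossings$energy_MeV[side], e_edges)
    tb <- table(factor(ci, 1:nc), factor(hi, 1:nh), factor(ei, 1:ne))
    side_counts <- array(as.integer(tb), dim = c(nc, nh, ne))
  }
  if (any(!side)) {
    ci <- bin_of(crossings$cos_theta[!side], cos_edges)
    ei <- bin_of(crossings$energy_MeV[!side], e_edges)
    tb <- table(factor(ci, 1:nc), factor(ei, 1:ne))
    lid_counts <- array(as.integer(tb), dim = c(nc, ne))
  }
  p_side <- side_counts / n_tot
  p_lid <- lid_counts / n_tot
  structure(list(
    side = p_side, lid = p_lid,
    side_counts = side_counts, lid_counts = lid_counts,
    side_se = sqrt(p_side * (1 - p_side) / n_tot),
    lid_se = sqrt(p_lid * (1 - p_lid) / n_tot),
    cos_edges = cos_edges, h_edges = h_edges, energy_edges = e_edges,
    n_total = n_tot, cylinder = cylinder,
    source_energy_MeV = source_energy_MeV
  ), class = "phase_space_pdf")
}

#' @export
print.phase_space_pdf <- function(x, ...) {
  cat(sprintf(
    "<phase_space_pdf> %d crossings; side %.3f / lid %.3f; %d x %d x %d (cos,h,E) side bins\n",
    x$n_total, sum(x$side), sum(x$lid),
    dim(x$side)[1], dim(x$side)[2], dim(x$side)[3]))
  invisible(x)
}

#' Sample particle states from a phase-space PDF
#'
#' Restarts particle histories from the coupling-cylinder surface: bins are
#' drawn with their recorded probabilities, binned attributes uniformly
#' within the bin, and the rotationally ignored coordinates uniformly
#' (position azimuth; lid radius area-uniform; direction azimuth uniform on
#' \[0, 2 pi)).  Lid samples are placed on the top lid for downward
#' directions and on the bottom lid otherwise.
#'
#' @param pdf a [bin_phase_space()] result.
#' @param n number of samples (> 0).
#' @return data frame with columns `x, y, z, u, v, w, energy_MeV, weight,
#'   surface`.
#' @export
sample_phase_space <- function(pdf, n) {
  stopifnot(inherits(pdf, "phase_space_pdf"))
  if (n <= 0) stop("n must be positive")
  probs <- c(as.vector(pdf$side), as.vector(pdf$lid))
  if (abs(sum(probs) - 1) > 1e-9) stop("pdf is not normalised")
  nsid <- length(pdf$side)
  idx <- sample.int(length(probs), n, replace = TRUE, prob = probs)
  dims <- dim(pdf$side)
  out <- data.frame(x = numeric(n), y = numeric(n), z = numeric(n),
                    u = numeric(n), v = numeric(n), w = numeric(n),
                    energy_MeV = numeric(n), weight = 1,
                    surface = character(n), stringsAsFactors = FALSE)
  # binned attributes are uniform within the bin; sampled energies are
  # additionally capped at the source energy (the binning loses where in the
  # top bin the true spectrum ends, but replayed particles must not exceed
  # the source energy)
  ub <- function(edges, i) runif(length(i), edges[i], edges[i + 1])
  ub_energy <- function(edges, i)
    runif(length(i), pmin(edges[i], pdf$source_energy_MeV),
          pmin(edges[i + 1], pdf$source_energy_MeV))
  is_side <- idx <= nsid
  R <- pdf$cylinder$radius
  if (any(is_side)) {
    ii <- idx[is_side] - 1L
    ci <- ii %% dims[1] + 1L
    hi <- (ii %/% dims[1]) %% dims[2] + 1L
    ei <- ii %/% (dims[1] * dims[2]) + 1L
    m <- sum(is_side)
    costh <- ub(pdf$cos_edges, ci)
    h <- ub(pdf$h_edges, hi)
    Ev <- ub_energy(pdf$energy_edges, ei)
    alpha <- runif(m, 0, 2 * pi)
    beta <- runif(m, 0, 2 * pi)
    s <- sqrt(1 - costh^2)
    out$x[is_side] <- R * cos(alpha); out$y[is_side] <- R * sin(alpha)
    out$z[is_side] <- h
    out$u[is_side] <- s * cos(beta); out$v[is_side] <- s * sin(beta)
    out$w[is_side] <- costh
    out$energy_MeV[is_side] <- Ev
    out$surface[is_side] <- "side"
  }
  if (any(!is_side)) {
    ii <- idx[!is_side] - nsid - 1L
    ci <- ii %% dims[1] + 1L
    ei <- ii %/% dims[1] + 1L
    m <- sum(!is_side)
    costh <- ub(pdf$cos_edges, ci)
    Ev <- ub_energy(pdf$energy_edges, ei)
    rho <- R * sqrt(runif(m))
    alpha <- runif(m, 0, 2 * pi)
    beta <- runif(m, 0, 2 * pi)
    s <- sqrt(1 - costh^2)
    top <- costh < 0
    out$x[!is_side] <- rho * cos(alpha); out$y[!is_side] <- rho * sin(alpha)
    out$z[!is_side] <- ifelse(top, pdf$cylinder$height, 0)
    out$u[!is_side] <- s * cos(beta); out$v[!is_side] <- s * sin(beta)
    out$w[!is_side] <- costh
    out$energy_MeV[!is_side] <- Ev
    out$surface[!is_side] <- ifelse(top, "lid_top", "lid_bottom")
  }
  out
}

#' Construct a fluence-spectrum tally result
#'
#' A minimal container for a (binned or discrete) photon fluence-rate
#' spectrum, as consumed by [air_kerma_at_1m()].
#'
#' @param energy_MeV energies (bin representative points).
#' @param fluence fluence rate per energy point (m-2 s-1, per unit source
#'   activity concentration).
#' @return an object of class `fluence_tally`.
#' @export
make_fluence_tally <- function(energy_MeV, fluence) {
  stopifnot(length(energy_MeV) == length(fluence), all(fluence >= 0))
  structure(list(energy_MeV = energy_MeV, fluence = fluence),
            class = "fluence_tally")
}

#' Convert a fluence spectrum to air kerma
#'
#' kerma rate = sum over the spectrum of fluence(E) * E * (mu_tr/rho)(E),
#' with E converted to joule and mu_tr/rho from cm2/g to m2/kg, giving
#' Gy s-1 per unit source activity concentration.
#'
#' @param tally a [make_fluence_tally()] (or the fluence element of a
#'   [run_kerma_field()] result).
#' @param mu_tr_table data frame `energy_MeV`, `mu_tr_rho` (cm2/g),
#'   interpolated log-log.
#' @return kerma rate (scalar).
#' @export
air_kerma_at_1m <- function(tally, mu_tr_table) {
  stopifnot(inherits(tally, "fluence_tally"))
  if (all(tally$fluence == 0)) {
    warning("empty fluence tally; kerma = 0")
    return(0)
  }
  f <- .loglog_fun(mu_tr_table$energy_MeV, mu_tr_table$mu_tr_rho)
  sum(tally$fluence * tally$energy_MeV * .MEV_TO_J *
        f(tally$energy_MeV) * 0.1)
}

#' Monte Carlo air-kerma estimate at 1 m height
#'
#' Runs the environmental-field transport with a track-length fluence
#' estimator in a thin horizontal disc slab centred at `tally_height`.  For
#' the (laterally uniform) infinite-plane and volume fields the slab fluence
#' equals the point fluence at that height, which makes the estimator far
#' more efficient than a small sphere.  The kerma is accumulated exactly per
#' track segment as length * E * (mu_tr/rho)(E); a binned spectrum is
#' returned alongside.  Results are normalised per unit activity
#' concentration: Gy s-1 per Bq m-2 (plane source) or per Bq m-3 (volume
#' source).
#'
#' @param config a [field_config()] with a `"plane"` or `"volume"` source.
#' @param mu_tr_table fluence-to-kerma conversion table (default synthetic
#'   air).
#' @param tally_radius radius of the scoring disc (m).
#' @param tally_height centre height of the scoring slab (m).
#' @param tally_thickness slab thickness (m).
#' @param n_batches batches for the standard-error estimate.
#' @return list with `kerma` (Gy s-1 per Bq m-2 or m-3), `se`, `fluence`
#'   (a `fluence_tally` of the binned spectrum), `n_histories`.
#' @export
run_kerma_field <- function(config, mu_tr_table = NULL,
                            tally_radius = 50, tally_height = 1,
                            tally_thickness = 0.2, n_batches = 20) {
  stopifnot(inherits(config, "field_config"),
            config$source %in% c("plane", "volume"))
  if (config$histories < n_batches)
    stop("histories must be at least n_batches")
  if (is.null(mu_tr_table))
    mu_tr_table <- synthetic_mu_tr_table(config$materials$air)
  set.seed(config$seed)
  edges <- exp(seq(log(config$cutoff_MeV), log(config$energy_MeV * (1 + 1e-9)),
                   length.out = 121))
  tally <- list(radius = tally_radius,
                z1 = tally_height - tally_thickness / 2,
                z2 = tally_height + tally_thickness / 2,
                edges = edges, mu_tr = mu_tr_table)
  vol <- pi * tally_radius^2 * tally_thickness
  src_measure <- if (config$source == "plane") {
    pi * config$world_radius^2                              # m2
  } else {
    pi * config$world_radius^2 * min(config$source_height, config$air_height)
  }
  per_batch <- ceiling(config$histories / n_batches)
  kb <- numeric(0)
  len_tot <- numeric(length(edges) - 1L)
  n_done <- 0
  while (n_done < config$histories) {
    n <- min(per_batch, config$histories - n_done)
    res <- .transport_chunk(config, n, cylinder = NULL, tally = tally)
    kb <- c(kb, res$tally_kerma / n)
    len_tot <- len_tot + res$tally_len
    n_done <- n_done + n
  }
  # exact per-segment kerma: sum(len * E * mu_tr) / V / N * source measure
  conv <- .MEV_TO_J * 0.1 / vol * src_measure
  kerma <- sum(kb * .batch_weights(kb, per_batch, config$histories)) * conv
  se <- stats::sd(kb) / sqrt(length(kb)) * conv
  mids <- sqrt(edges[-1] * edges[-length(edges)])
  flu <- len_tot / vol / config$histories * src_measure
  list(kerma = kerma, se = se,
       fluence = make_fluence_tally(mids, flu),
       n_histories = config$histories)
}

# History-weighted mean over batches (last batch may be smaller).
.batch_weights <- function(kb, per_batch, total) {
  sizes <- rep(per_batch, length(kb))
  if (length(kb)) sizes[length(kb)] <- total - per_batch * (length(kb) - 1L)
  sizes / total
}

#' Write a phase-space PDF to JSON
#'
#' Explicit bin edges and both raw counts and normalised probabilities.
#'
#' @param pdf a [bin_phase_space()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phase_space_json <- function(pdf, path) {
  stopifnot(inherits(pdf, "phase_space_pdf"))
  jsonlite::write_json(list(
    n_total = pdf$n_total,
    source_energy_MeV = pdf$source_energy_MeV,
    cylinder = pdf$cylinder[c("radius", "height")],
    cos_edges = pdf$cos_edges, h_edges = pdf$h_edges,
    energy_edges = pdf$energy_edges,
    side_prob = pdf$side, lid_prob = pdf$lid,
    side_counts = pdf$side_counts, lid_counts = pdf$lid_counts
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a crossing log to CSV
#'
#' Columns x, y, z, u, v, w, energy_MeV, weight (the analog engine always
#' writes unit weight).
#'
#' @param run a `field_run`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_crossings_csv <- function(run, path) {
  stopifnot(inherits(run, "field_run"))
  cols <- c("x", "y", "z", "u", "v", "w", "energy_MeV", "weight")
  utils::write.csv(run$crossings[cols], path, row.names = FALSE)
  invisible(path)
}
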