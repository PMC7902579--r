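# Small-world configurations keep the stochastic suite fast; seeds fixed.

absorber_table <- function(mu = 0.1) {
  structure(data.frame(energy_MeV = c(0.002, 10), pe = mu, incoh = 0,
                       pair = 0, total = mu),
            class = c("attenuation_table", "data.frame"))
}

test_that("synthetic attenuation reproduces known air magnitudes", {
  mats <- reference_materials()
  att <- synthetic_attenuation(mats$air, energies = c(0.1, 0.662, 1, 2))
  # Compton-dominated regime: total mu/rho of air ~ 0.0636 cm2/g at 1 MeV
  expect_equal(att$total[att$energy_MeV == 1], 0.0636, tolerance = 0.02)
  mtr <- synthetic_mu_tr_table(mats$air, energies = 1)
  expect_equal(mtr$mu_tr_rho, 0.0279, tolerance = 0.02)
  expect_true(all(att$pair[att$energy_MeV <= 1.022] == 0))
})

test_that("vacuum transport flies straight to the expected lid bin", {
  fc <- field_config("beam", energy_MeV = 1, histories = 200, seed = 5,
                     vacuum = TRUE, source_position = c(0, 0, 10),
                     source_direction = c(0, 0, -1),
                     world_radius = 40, air_height = 20)
  run <- run_field(fc, cylinder = coupling_cylinder("ground"))
  expect_equal(nrow(run$crossings), 200)
  expect_true(all(run$crossings$surface == "lid_top"))
  expect_true(all(run$crossings$energy_MeV == 1))
  pdf <- bin_phase_space(run)
  expect_equal(sum(pdf$side) + sum(pdf$lid), 1)
  expect_equal(sum(pdf$lid > 0), 1)     # single (cos theta, E) bin
  expect_equal(max(pdf$lid), 1)
})

test_that("fixed seeds reproduce identical runs and PDFs", {
  fc <- field_config("plane", energy_MeV = 0.662, histories = 3000, seed = 42,
                     world_radius = 10, air_height = 10)
  r1 <- run_field(fc, cylinder = coupling_cylinder("ground"))
  r2 <- run_field(fc, cylinder = coupling_cylinder("ground"))
  expect_identical(r1$crossings, r2$crossings)
  p1 <- bin_phase_space(r1); p2 <- bin_phase_space(r2)
  expect_identical(p1$side, p2$side)
  expect_identical(p1$lid, p2$lid)
  expect_error(run_field(field_config("plane", energy_MeV = 1, histories = 0)),
               "at least 1")
})

test_that("pure-absorber slab transmission matches exp(-mu t) within 3 sigma", {
  mu <- 0.1 * 1.2e-3 * 100        # per metre, with the absorber table below
  att <- absorber_table(0.1)
  mats <- reference_materials()
  mats$soil$density_gcm3 <- mats$air$density_gcm3   # same medium below
  fc <- field_config("beam", energy_MeV = 1, histories = 1e5, seed = 3,
                     materials = mats, att_air = att, att_soil = att,
                     source_position = c(0, 0, 9.999),
                     source_direction = c(0, 0, -1),
                     world_radius = 50, air_height = 10, soil_depth = 1e-4)
  run <- run_field(fc, record_escapes = TRUE)
  n_through <- sum(run$escapes$surface == "bottom" &
                     run$escapes$energy_MeV == 1)
  p_exp <- exp(-mu * 10)
  se <- sqrt(p_exp * (1 - p_exp) / 1e5)
  expect_lt(abs(n_through / 1e5 - p_exp), 3 * se)
})

test_that("sampled Klein-Nishina angles follow the analytic distribution", {
  set.seed(17)
  kn <- sample_klein_nishina(0.662, 1e5)
  expect_true(all(kn$eps <= 1 & kn$eps >= 1 / (1 + 2 * 0.662 / 0.510998950)))
  edges <- seq(-1, 1, length.out = 41)
  obs <- table(cut(kn$costh, edges, include.lowest = TRUE))
  mid <- (edges[-1] + edges[-41]) / 2
  dens <- kn_angular_pdf(0.662, mid)
  p <- dens * diff(edges)
  p <- p / sum(p)
  chi <- suppressWarnings(stats::chisq.test(as.vector(obs), p = p))
  expect_gt(chi$p.value, 0.01)
})

test_that("energy never increases along tracks; pair photons only above 1.022", {
  fc <- field_config("plane", energy_MeV = 0.662, histories = 4000, seed = 8,
                     world_radius = 10, air_height = 10)
  run <- run_field(fc, cylinder = coupling_cylinder("ground"),
                   record_escapes = TRUE)
  expect_true(all(run$crossings$energy_MeV <= 0.662 + 1e-12))
  expect_true(all(run$escapes$energy_MeV <= 0.662 + 1e-12))
  # above threshold, annihilation photons appear at exactly 0.511 MeV
  fc2 <- field_config("plane", energy_MeV = 3, histories = 4000, seed = 9,
                      world_radius = 10, air_height = 10)
  run2 <- run_field(fc2, cylinder = coupling_cylinder("ground"))
  expect_true(all(run2$crossings$energy_MeV <= 3 + 1e-12))
})

test_that("an isotropic mid-height point source gives a symmetric side profile", {
  cyl <- coupling_cylinder(diameter = 2, height = 2)
  fc <- field_config("point", energy_MeV = 1, histories = 60000, seed = 12,
                     vacuum = TRUE, source_position = c(4, 0, 1),
                     world_radius = 100, air_height = 50)
  run <- run_field(fc, cylinder = cyl)
  h <- run$crossings$h[run$crossings$surface == "side"]
  expect_gt(length(h), 300)
  n_lo <- sum(h < 1); n_hi <- sum(h > 1)
  p <- n_lo / (n_lo + n_hi)
  se <- sqrt(0.25 / (n_lo + n_hi))
  expect_lt(abs(p - 0.5), 4 * se)
})

test_that("phase-space binning is normalised with half-open decade-grid bins", {
  ee <- decade_energy_edges(0.002, 1)
  expect_true(all(diff(ee) > 0))
  expect_equal(ee[1], 0.002)
  expect_equal(ee[length(ee)], 1.0)
  expect_true(all(c(0.015, 0.15, 0.5, 0.9) %in% ee))
  # one crossing -> single bin with probability 1
  cross <- data.frame(surface = "side", cos_theta = 0.05, h = 0.5,
                      energy_MeV = 0.3, x = 1, y = 0, z = 0.5, u = 0, v = 0,
                      w = 0.05, weight = 1)
  pdf <- bin_phase_space(cross, coupling_cylinder("ground"),
                         source_energy_MeV = 1)
  expect_equal(sum(pdf$side) + sum(pdf$lid), 1)
  expect_equal(sum(pdf$side > 0), 1)
  # half-open: a value exactly on an interior edge goes to the upper bin
  cross2 <- cross; cross2$cos_theta <- 0.1
  pdf2 <- bin_phase_space(cross2, coupling_cylinder("ground"),
                          source_energy_MeV = 1)
  idx <- which(pdf2$side > 0, arr.ind = TRUE)
  expect_equal(unname(idx[1, 1]), 12L)  # [0.1, 0.2) is the 12th cos bin
  # final bin closed: cos theta = 1 stays in the last bin
  cross3 <- cross; cross3$cos_theta <- 1
  pdf3 <- bin_phase_space(cross3, coupling_cylinder("ground"),
                          source_energy_MeV = 1)
  expect_equal(unname(which(pdf3$side > 0, arr.ind = TRUE)[1, 1]), 20L)
  # invalid crossings are rejected
  bad <- cross; bad$h <- 99
  expect_error(bin_phase_space(bad, coupling_cylinder("ground"), 1),
               "outside the cylinder")
  bad2 <- cross; bad2$energy_MeV <- 2
  expect_error(bin_phase_space(bad2, coupling_cylinder("ground"), 1),
               "exceeds the source energy")
})

test_that("uniform cos-theta crossings fill the 20 bins within 4 sigma", {
  set.seed(21)
  n <- 40000
  cross <- data.frame(surface = "side", cos_theta = runif(n, -1, 1),
                      h = runif(n, 0, 2.5), energy_MeV = runif(n, 0.1, 0.9))
  pdf <- bin_phase_space(cross, coupling_cylinder("ground"),
                         source_energy_MeV = 1)
  marg <- apply(pdf$side, 1, sum) * n
  se <- sqrt(n * (1 / 20) * (19 / 20))
  expect_true(all(abs(marg - n / 20) < 4 * se))
})

test_that("phase-space resampling round-trips within multinomial error", {
  fc <- field_config("plane", energy_MeV = 0.662, histories = 20000, seed = 31,
                     world_radius = 10, air_height = 10)
  run <- run_field(fc, cylinder = coupling_cylinder("ground"))
  pdf <- bin_phase_space(run)
  set.seed(77)
  n <- 1e5
  smp <- sample_phase_space(pdf, n)
  expect_equal(nrow(smp), n)
  expect_true(all(smp$weight == 1))
  expect_true(all(abs(smp$u^2 + smp$v^2 + smp$w^2 - 1) < 1e-9))
  # rebin the samples and compare marginal side/lid split and cos marginals
  re <- bin_phase_space(data.frame(
    surface = ifelse(smp$surface == "side", "side", smp$surface),
    cos_theta = smp$w, h = ifelse(smp$surface == "side", smp$z, NA),
    energy_MeV = smp$energy_MeV), pdf$cylinder,
    source_energy_MeV = 0.662)
  p_side <- sum(pdf$side)
  se_side <- sqrt(p_side * (1 - p_side) / n)
  expect_lt(abs(sum(re$side) - p_side), 5 * se_side)
  cm_ref <- apply(pdf$side, 1, sum) + apply(pdf$lid, 1, sum)
  cm_smp <- apply(re$side, 1, sum) + apply(re$lid, 1, sum)
  for (i in 1:20) {
    se_i <- sqrt(max(cm_ref[i], 1e-12) * (1 - cm_ref[i]) / n)
    expect_lt(abs(cm_smp[i] - cm_ref[i]), 6 * se_i + 1e-9)
  }
  # delta pdf -> all samples in that bin
  d <- pdf
  d$side[] <- 0; d$lid[] <- 0
  d$side[5, 3, 2] <- 1
  s2 <- sample_phase_space(d, 500)
  expect_true(all(s2$surface == "side"))
  expect_true(all(s2$w >= d$cos_edges[5] & s2$w <= d$cos_edges[6]))
  expect_true(all(s2$z >= d$h_edges[3] & s2$z <= d$h_edges[4]))
  expect_error(sample_phase_space(pdf, 0), "positive")
})

test_that("side-sample azimuths are uniform (Rayleigh test)", {
  fc <- field_config("plane", energy_MeV = 0.662, histories = 10000, seed = 55,
                     world_radius = 10, air_height = 10)
  pdf <- bin_phase_space(run_field(fc, cylinder = coupling_cylinder("ground")))
  set.seed(99)
  smp <- sample_phase_space(pdf, 2e4)
  phi <- atan2(smp$y[smp$surface == "side"], smp$x[smp$surface == "side"])
  n <- length(phi)
  R2 <- (sum(cos(phi))^2 + sum(sin(phi))^2) / n
  p_rayleigh <- exp(-R2)     # large-sample null distribution
  expect_gt(p_rayleigh, 0.01)
  # direction azimuth as well
  beta <- atan2(smp$v, smp$u)
  R2b <- (sum(cos(beta))^2 + sum(sin(beta))^2) / nrow(smp)
  expect_gt(exp(-R2b), 0.01)
})

test_that("rotating the source about the axis leaves the PDFs unchanged", {
  base <- field_config("plane", energy_MeV = 0.662, histories = 30000,
                       seed = 61, world_radius = 10, air_height = 10)
  rot <- field_config("plane", energy_MeV = 0.662, histories = 30000,
                      seed = 62, world_radius = 10, air_height = 10,
                      source_azimuth = pi / 3)
  p1 <- bin_phase_space(run_field(base, cylinder = coupling_cylinder("ground")))
  p2 <- bin_phase_space(run_field(rot, cylinder = coupling_cylinder("ground")))
  c1 <- apply(p1$side_counts, 1, sum) + apply(p1$lid_counts, 1, sum)
  c2 <- apply(p2$side_counts, 1, sum) + apply(p2$lid_counts, 1, sum)
  keep <- (c1 + c2) >= 10
  expect_gt(sum(keep), 3)
  tab <- rbind(c1[keep], c2[keep])
  chi <- suppressWarnings(stats::chisq.test(tab))
  expect_gt(chi$p.value, 0.01)
})

test_that("the fluence-to-kerma conversion matches the closed form", {
  # imposed uniform parallel fluence of 1 MeV photons
  mu_tr <- data.frame(energy_MeV = c(0.5, 1, 2), mu_tr_rho = c(0.03, 0.0279, 0.026))
  phi <- 1.34
  tal <- make_fluence_tally(1.0, phi)
  got <- air_kerma_at_1m(tal, mu_tr)
  expect_equal(got, phi * 1 * 1.602176634e-13 * 0.0279 * 0.1, tolerance = 1e-12)
  expect_warning(z <- air_kerma_at_1m(make_fluence_tally(1, 0), mu_tr), "empty")
  expect_identical(z, 0)
})

test_that("missing attenuation data at an energy is an error", {
  att <- structure(data.frame(energy_MeV = c(0.05, 2), pe = 0.01, incoh = 0.05,
                              pair = 0, total = 0.06),
                   class = c("attenuation_table", "data.frame"))
  f <- envdose:::.att_fun(att)
  expect_error(f(5), "missing attenuation data")
  expect_error(f(0.01), "missing attenuation data")
  expect_silent(f(c(0.05, 1, 2)))
})
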