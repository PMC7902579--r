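ground_tb <- function() dose_curve(builtin_table("ground", "total_body"))
sub_tb <- function() dose_curve(builtin_table("submersion", "total_body"))

test_that("discrete folding reproduces printed cells and linear combinations", {
  # single 1 MeV line, yield 1, air submersion -> printed total-body cell
  lines <- data.frame(type = "photon", energy_MeV = 1, yield = 1)
  expect_identical(fold_discrete(lines, sub_tb()), 4.29e-14)
  # 0.5/0.5 mix of two ground nodes
  lines2 <- data.frame(energy_MeV = c(0.5, 1), yield = c(0.5, 0.5))
  expect_equal(fold_discrete(lines2, ground_tb()),
               0.5 * 2.91e-16 + 0.5 * 5.83e-16, tolerance = 1e-15)
  expect_identical(fold_discrete(NULL, ground_tb()), 0)
  expect_identical(fold_discrete(data.frame(energy_MeV = numeric(),
                                            yield = numeric()), ground_tb()), 0)
  expect_error(fold_discrete(data.frame(energy_MeV = 11, yield = 1),
                             ground_tb()), "10 MeV")
  # sub-cutoff lines contribute exactly zero
  expect_identical(fold_discrete(data.frame(energy_MeV = 0.01, yield = 5),
                                 ground_tb()), 0)
})

test_that("a yield-1 line at any tabulated energy reproduces the cell", {
  for (g in c("ground", "submersion"))
    for (org in builtin_organs(g, include_air_kerma = TRUE)) {
      tab <- builtin_table(g, org)
      cv <- dose_curve(tab)
      got <- vapply(tab$energy_MeV, function(E)
        fold_discrete(data.frame(energy_MeV = E, yield = 1), cv), numeric(1))
      expect_identical(got, tab$value, label = paste(g, org))
    }
})

test_that("continuous folding matches a 1e5-panel trapezoid oracle", {
  cv <- ground_tb()
  spec <- data.frame(energy_MeV = c(0.5, 1.0), yield_per_MeV = c(1, 1))
  got <- fold_continuous(spec, cv)
  ref <- trapz_oracle(function(E) eval_curve(cv, E), 0.5, 1.0, n = 1e5)
  expect_equal(got, ref, tolerance = 1e-6)
  # halving the panel width changes the default-refinement result < 1e-6
  got2 <- fold_continuous(spec, cv, min_panels = 4000)
  expect_lt(abs(got2 - got) / got, 1e-6)
})

test_that("continuous folding handles cutoffs and degenerate spectra", {
  cv <- ground_tb()
  below <- data.frame(energy_MeV = c(0.003, 0.014), yield_per_MeV = c(10, 10))
  expect_identical(fold_continuous(below, cv), 0)
  zero <- data.frame(energy_MeV = c(0.1, 1), yield_per_MeV = c(0, 0))
  expect_identical(fold_continuous(zero, cv), 0)
  # spectrum straddling the cutoff counts only the part above 0.015
  strad <- data.frame(energy_MeV = c(0.015, 0.1), yield_per_MeV = c(1, 1))
  full <- fold_continuous(strad, cv)
  wide <- fold_continuous(data.frame(energy_MeV = c(0.008, 0.015, 0.1),
                                     yield_per_MeV = c(1, 1, 1)), cv)
  expect_equal(wide, full, tolerance = 1e-9)
})

test_that("electron dose curves behave for degenerate and Kramers kernels", {
  cv <- ground_tb()
  # zero kernel -> identically zero
  z <- brems_kernel("air", c(0.5, 2),
                    list(data.frame(k_MeV = c(0.1, 0.5), B_per_MeV = c(0, 0)),
                         data.frame(k_MeV = c(0.1, 2), B_per_MeV = c(0, 0))))
  ec <- electron_dose_curve(cv, z)
  expect_identical(eval_electron_curve(ec, c(0.5, 1.3, 2)), c(0, 0, 0))
  # narrow near-monochromatic kernel at k ~ E_e with unit photon yield
  eps <- 1e-4
  mono <- brems_kernel("air", 1.0, list(
    data.frame(k_MeV = c(1 - eps, 1), B_per_MeV = c(1 / eps, 1 / eps))))
  ec2 <- electron_dose_curve(cv, mono)
  expect_equal(eval_electron_curve(ec2, 1.0), 1 * eval_curve(cv, 1.0),
               tolerance = 1e-3)
  expect_error(eval_electron_curve(ec2, 2), "outside the kernel grid")
  # Kramers kernel vs fine-quadrature oracle
  mats <- reference_materials()
  kk <- kramers_kernel(mats$air, data.frame(E_e_MeV = 1, Y_rad = 0.002))
  ec3 <- electron_dose_curve(cv, kk)
  g <- kk$spectra[[1]]
  ref <- trapz_oracle(function(k) {
    B <- stats::approx(g$k_MeV, g$B_per_MeV, xout = k, rule = 2)$y
    B * eval_curve(cv, k)
  }, 0.015, 1, n = 1e5)
  expect_equal(eval_electron_curve(ec3, 1), ref, tolerance = 1e-6)
})

test_that("folding is linear in the yields and components sum to the total", {
  mats <- reference_materials()
  kk <- kramers_kernel(mats$air, radiative_yield_table(mats$air))
  curves <- list(total_body = ground_tb(),
                 skin = dose_curve(builtin_table("ground", "skin")))
  for (s in 1:100) {
    rec <- synth_nuclide(s, n_lines = 1 + s %% 4, n_beta = s %% 2,
                         energy_range = c(0.02, 5))
    a <- runif(1, 0.5, 3)
    rec2 <- rec
    rec2$discrete$yield <- rec$discrete$yield * a
    rec2$continuous <- lapply(rec$continuous, function(sp) {
      sp$grid$yield_per_MeV <- sp$grid$yield_per_MeV * a
      sp
    })
    r1 <- nuclide_coefficient(rec, curves, kernel = kk, min_panels = 60)
    r2 <- nuclide_coefficient(rec2, curves, kernel = kk, min_panels = 60)
    expect_equal(r2$total, a * r1$total, tolerance = 1e-9)
    expect_equal(r1$total,
                 r1$discrete_photon + r1$bremsstrahlung + r1$continuous_photon,
                 tolerance = 1e-12)
    expect_true(all(as.matrix(r1[, 1:3]) >= 0))
  }
})

test_that("electron emissions require a kernel and geometries must agree", {
  rec <- decay_record("E-1", data.frame(type = "electron", energy_MeV = 1,
                                        yield = 1))
  expect_error(nuclide_coefficient(rec, list(tb = ground_tb())),
               "kernel is required")
  mixed <- list(a = ground_tb(), b = sub_tb())
  expect_error(nuclide_coefficient(rec, mixed), "share one geometry")
  mats <- reference_materials()
  kk <- kramers_kernel(mats$air, radiative_yield_table(mats$air),
                       geometry = "submersion")
  expect_error(nuclide_coefficient(rec, list(tb = ground_tb()), kernel = kk),
               "does not match")
})

test_that("spontaneous-fission photon spectra fold as continuous photons", {
  sf <- list(type = "photon_sf",
             grid = data.frame(energy_MeV = c(0.1, 0.5, 2),
                               yield_per_MeV = c(2, 1, 0.1)))
  rec <- decay_record("SF-1", continuous = list(sf))
  r <- nuclide_coefficient(rec, list(total_body = ground_tb()))
  expect_gt(r$continuous_photon, 0)
  expect_identical(r$bremsstrahlung, 0)
  expect_equal(r$total, r$continuous_photon)
})

test_that("kerma normalisation divides, errors on non-positive, and inverts", {
  rec <- decay_record("T", data.frame(type = "photon", energy_MeV = 1, yield = 1))
  r <- nuclide_coefficient(rec, list(total_body = ground_tb()))
  ka <- eval_curve(dose_curve(builtin_table("ground", "air_kerma")), 1.0)
  nz <- kerma_normalize(r, ka)
  expect_equal(round(nz["total_body", "total"], 3), 0.706)  # 5.83/8.26
  expect_error(kerma_normalize(r, 0), "positive")
  expect_error(kerma_normalize(r, -1), "positive")
  back <- nz$total * ka
  expect_equal(back, r$total, tolerance = 1e-12)
  r0 <- nuclide_coefficient(decay_record("Z"), list(total_body = ground_tb()))
  expect_identical(kerma_normalize(r0, ka)$total, 0)
})

test_that("detriment weighting is the oracle dot product", {
  expect_equal(detriment_weighted(c(a = 5, b = 5), c(a = 0.5, b = 0.5)), 5)
  expect_equal(detriment_weighted(c(a = 2, b = 4), c(a = 0.5, b = 0.5)), 3)
  expect_error(detriment_weighted(c(a = 1), c(a = 0.5, b = 0.5)),
               "missing.*b")
  set.seed(3)
  for (r in 1:25) {
    n <- sample(3:8, 1)
    v <- stats::setNames(runif(n), paste0("o", 1:n))
    w <- stats::setNames(runif(n), paste0("o", 1:n))
    expect_equal(detriment_weighted(v, w), sum(v * w), tolerance = 1e-12)
  }
})

test_that("uterus/fetus ratios reproduce the published report values", {
  nt <- builtin_nuclide_table()
  uterus <- stats::setNames(nt$uterus_ground, nt$nuclide)
  fetus <- stats::setNames(nt$fetus_ground, nt$nuclide)
  rep <- uterus_fetus_ratio(c("Xe-133", "Te-132"), uterus, fetus)
  expect_equal(rep$ratio[rep$nuclide == "Xe-133"], 1.09)
  expect_equal(rep$ratio[rep$nuclide == "Te-132"], 1.06)
  expect_equal(rep$ratio_raw[rep$nuclide == "Te-132"], 1.26e-16 / 1.19e-16,
               tolerance = 1e-12)
  same <- uterus_fetus_ratio("X", c(X = 2), c(X = 2))
  expect_equal(same$ratio, 1.00)
  undef <- uterus_fetus_ratio("X", c(X = 1), c(X = 0))
  expect_false(undef$defined)
  expect_true(is.na(undef$ratio))
  expect_error(uterus_fetus_ratio("Nope-1", uterus, fetus), "missing")
})
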