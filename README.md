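# envdose

Organ equivalent dose rate coefficients for **external environmental
exposure of a pregnant female and her fetus** (24th week of gestation).

After a release of radioactivity, external photon exposure from
radionuclides deposited on the ground or suspended in air is assessed with
*dose rate coefficients*: organ equivalent dose rate per unit environmental
activity concentration.  This package is for health physicists and dose
assessors who need fetal coefficients for the two standard idealised
geometries:

* **ground contamination** — an infinite plane source at an areal-mass depth
  of 0.5 g cm⁻² in soil (Sv s⁻¹ per Bq m⁻²), and
* **air submersion** — a semi-infinite contaminated air volume
  (Sv s⁻¹ per Bq m⁻³).

## What it computes

Monoenergetic fetal organ and air-kerma coefficient tables are packaged as
published and interpolated with a monotone piecewise cubic Hermite scheme
(Fritsch–Carlson family) in log-energy space, zero below 0.015 MeV.
Nuclide-specific coefficients follow from folding with the nuclide's
emissions:

$$\dot h_T^S = \sum_R w_R \Big[ \sum_i Y_{R,i}\,\dot d_{T,R}^S(E_i)
  + \int_0^\infty Y_R(E)\,\dot d_{T,R}^S(E)\,dE \Big]$$

with discrete yields $Y_{R,i}$ per decay and continuous spectra $Y_R(E)$ in
MeV⁻¹.  Photons fold directly; electrons (lines and beta continua)
contribute only through the thick-target bremsstrahlung they generate while
stopping, via a bremsstrahlung kernel $B(k\,|\,E_e)$.  Results carry a
component breakdown, can be normalised to air kerma (Sv/Gy), weighted into
a detriment-weighted scalar, and compared in the uterus-as-fetus-surrogate
ratio report.  Coefficients are per nuclide only — progeny are never summed
implicitly.

A simplified analog photon Monte Carlo of the air-over-soil environment is
included: it records coupling-cylinder phase-space PDFs
$p_S(\cos\vartheta,h,E)$ / $p_L(\cos\vartheta,E)$, resamples particle
states from them, and estimates the air-kerma rate at 1 m height with a
track-length fluence estimator.  See the methods vignette
(`vignettes/environmental-dose-coefficients.Rmd`) for the physics, the
synthetic cross-section data and the known fidelity gaps.

## Worked example

```r
library(envdose)

# a pure 1 MeV photon emitter, one photon per decay, in a radioactive cloud
rec <- decay_record("LINE-1",
                    data.frame(type = "photon", energy_MeV = 1, yield = 1))
curve <- dose_curve(builtin_table("submersion", "total_body"))
nuclide_coefficient(rec, list(total_body = curve))
#> <nuclide_result> LINE-1, geometry submersion (Sv s-1 Bq-1 m3)
#>            discrete_photon bremsstrahlung continuous_photon    total
#> total_body        4.29e-14              0                 0 4.29e-14
```

The folded total, 4.29e-14 Sv s⁻¹ Bq⁻¹ m³, is exactly the packaged
monoenergetic fetal total-body cell at 1 MeV — a yield-1 single line must
reproduce the table.  Normalising the same emitter's ground-geometry
coefficient by its air-kerma coefficient:

```r
gnd <- nuclide_coefficient(rec,
         list(total_body = dose_curve(builtin_table("ground", "total_body"))))
ka  <- nuclide_coefficient(rec,
         list(air_kerma = dose_curve(builtin_table("ground", "air_kerma"))))$total
kerma_normalize(gnd, ka)["total_body", "total"]
#> [1] 0.7058111
```

i.e. about 0.706 Sv of fetal total-body dose per Gy of air kerma measured
at 1 m.  The surrogate-ratio report from the packaged nuclide summary:

```r
nt <- builtin_nuclide_table()
uterus_fetus_ratio(c("Xe-133", "Te-132", "Cs-137"),
                   setNames(nt$uterus_ground, nt$nuclide),
                   setNames(nt$fetus_ground, nt$nuclide))
#>   nuclide   uterus    fetus ratio_raw ratio defined
#> 1  Xe-133 1.75e-17 1.60e-17  1.093750  1.09    TRUE
#> 2  Te-132 1.26e-16 1.19e-16  1.058824  1.06    TRUE
#> 3  Cs-137 1.15e-19 1.06e-19  1.084906  1.08    TRUE
```

The mother's uterus dose conservatively approximates the fetal total-body
dose to within ~9% for these nuclides.

A command-line interface wrapping the same functions is installed as
`exec/envdose` (subcommands `tables`, `fold`, `simulate`, `ratio`).

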