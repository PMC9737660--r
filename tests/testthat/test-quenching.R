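# Birks voxel model, combined correction factors, fitting, volume
# averaging, corrected-curve reconstruction

test_that("voxel Birks law: unquenched limit, saturation, published-value substitution", {
  p <- birks_params("H-1", 0, 1.5)
  expect_equal(birks_rl(c(10, 100), 2, p), 1.5 * c(10, 100) * 2)
  psat <- birks_params("H-1", 300, 1.13)
  # saturation asymptote RL0/kB' * phi
  expect_equal(birks_rl(1e12, 1, psat), 1.13 / 300e-6, tolerance = 1e-4)
  # published '4 um' proton pair at LET = 45 MeV/cm, phi = 1:
  # direct substitution with the dimensionless kB/rho convention
  expect_equal(birks_rl(45, 1, psat),
               1.13 * 45 / (1 + 300 / 1e6 * 45), tolerance = 1e-12)
  expect_error(birks_rl(-1, 1, psat), "positive")
  expect_error(birks_params("H-1", -1, 1), "kB")
})

test_that("combined eta reduces bit-for-bit to the per-beam closed forms", {
  set.seed(88)
  params <- birks_set(list(
    birks_params("H-1", 300, 1.13), birks_params("He-4", 120, 1.3),
    birks_params("C-12", 1.8, 0.2)))
  for (k in 1:1000) {
    L <- stats::runif(3, 1, 2000)   # H, He, C
    f3 <- stats::runif(3)
    f3 <- f3 / sum(f3)
    # single species (Eq-8 form)
    expect_identical(
      eta_combined(c("H-1" = 1), L[1], params),
      eta_proton(L[1], params))
    # {He, H} -- summation order matched to the printed form (H first)
    f2 <- c(f3[2], 1 - f3[2])
    expect_identical(
      eta_combined(c("H-1" = f2[2], "He-4" = f2[1]), c(L[1], L[2]), params),
      eta_helium(f2[1], L[2], f2[2], L[1], params))
    # {C, He, H}
    expect_identical(
      eta_combined(c("H-1" = f3[3], "He-4" = f3[2], "C-12" = f3[1]),
                   c(L[1], L[2], L[3]), params),
      eta_carbon(f3[1], L[3], f3[2], L[2], f3[3], L[1], params))
  }
})

test_that("eta properties: kB=0 limit, floor, monotonicity in LET, missing species", {
  p0 <- birks_params("He-4", 0, 1.25)
  expect_equal(eta_single(50, p0), 1 / 1.25)
  params <- birks_set(list(birks_params("H-1", 300, 1.13)))
  L <- seq(1, 2000, length.out = 200)
  eta <- eta_single(L, params[["H-1"]])
  expect_true(all(diff(eta) > 0))                  # nondecreasing in LET
  expect_true(all(eta >= 1 / 1.13))                # floor at min(1/RL0)
  expect_error(
    eta_combined(c("He-4" = 1), 100, params, default = NULL),
    "He-4")
})

test_that("energy-recovery identity eta * RL = phi * LET holds per species to 1e-12", {
  set.seed(4)
  for (k in 1:50) {
    p <- birks_params("C-12", stats::runif(1, 0, 5000),
                      stats::runif(1, 0.05, 2))
    L <- stats::runif(1, 1, 3000)
    phi <- stats::runif(1, 0.1, 10)
    expect_equal(eta_single(L, p) * birks_rl(L, phi, p), phi * L,
                 tolerance = 1e-12)
  }
})

test_that("eta on the published carbon Bragg-peak row matches a term-by-term oracle", {
  params <- default_birks_params("grain_4um")
  tab <- load_fluence_tables()
  row <- tab[tab$beam == "C400" & tab$depth_mm == 256.9, ]
  f <- row$fluence_pct / sum(row$fluence_pct)
  names(f) <- row$species
  L <- row$let_kev_um * 10                         # keV/um -> MeV/cm
  got <- eta_combined(f, L, params)
  # independent brute-force summation
  oracle <- 0
  for (i in seq_along(f)) {
    p <- params[[row$species[i]]]
    oracle <- oracle + f[[i]] * (1 + p$kB / 1e6 * L[i]) / p$rl0
  }
  expect_equal(got, oracle, tolerance = 1e-15)
})

test_that("normalized RL curve: entrance convention and eta-based deficit prediction", {
  cfg <- experiment_config(beams = "He150", noise_sigma = 0, seed = 21)
  bd <- synth_experiment(cfg)
  nc <- norm_curve_for(bd, "He150")
  expect_equal(nc$norm$rl_norm[1], nc$mu, tolerance = 1e-12)
  # the quenched peak-to-plateau deficit matches the generator's
  # eta-based forward prediction
  b <- bd$beams$He150
  i <- grid_bin(b$profile$grid, nc$norm$depth_mm)
  pred <- predict_rl_norm(b$profile, bd$truth)[i]
  expect_equal(nc$norm$rl_norm, pred, tolerance = 5e-3)
  # unquenched detector reproduces the normalized reference exactly
  unq <- birks_set(list(birks_params("H-1", 0, 1), birks_params("He-4", 0, 1),
                        birks_params("C-12", 0, 1), birks_params("Li-7", 0, 1)))
  cfgu <- experiment_config(beams = "He150", truth = unq, noise_sigma = 0,
                            seed = 21)
  bdu <- synth_experiment(cfgu)
  ncu <- norm_curve_for(bdu, "He150")
  iu <- grid_bin(bdu$beams$He150$reference$grid, ncu$norm$depth_mm)
  expect_equal(ncu$norm$rl_norm, bdu$beams$He150$reference$dose[iu],
               tolerance = 1e-9)
})

test_that("Birks fit: exact inversion, frozen parameters untouched, LET windowing", {
  cfg <- experiment_config(beams = "H160", truth = proton_truth(),
                           noise_sigma = 0, seed = 31)
  bd <- synth_experiment(cfg)
  nc <- norm_curve_for(bd, "H160")
  fit <- fit_birks(nc$norm, bd$beams$H160$profile, species = "H-1",
                   let_range = c(3, 45))
  expect_equal(fit[["H-1"]]$kB, 3106, tolerance = 1e-3)
  expect_equal(fit[["H-1"]]$rl0, 1.0246, tolerance = 1e-3)
  expect_gte(attr(fit, "r_squared"), 1 - 1e-9)

  # helium fit with frozen proton parameters returns them untouched
  cfg2 <- experiment_config(beams = c("He150"), noise_sigma = 0, seed = 32)
  bd2 <- synth_experiment(cfg2)
  nc2 <- norm_curve_for(bd2, "He150")
  frozen <- birks_set(list(birks_params("H-1", 3106, 1.0246, c(3, 45)),
                           birks_params("Li-7", 3106, 1.0246)))
  fit2 <- fit_birks(nc2$norm, bd2$beams$He150$profile, species = "He-4",
                    let_range = c(20, 240), frozen = frozen)
  expect_identical(fit2[["H-1"]], frozen[["H-1"]])
  expect_equal(fit2[["He-4"]]$kB, 3106, tolerance = 5e-3)
  # too narrow a window
  expect_error(
    fit_birks(nc2$norm, bd2$beams$He150$profile, species = "He-4",
              let_range = c(1e5, 2e5), frozen = frozen),
    "fewer than 4")
})

test_that("Birks fit consistency: bias shrinks as noise shrinks", {
  med_err <- vapply(c(0.01, 0.001, 1e-4), function(sig) {
    errs <- vapply(1:5, function(s) {
      cfg <- experiment_config(beams = "H160", truth = proton_truth(),
                               noise_sigma = sig, seed = 100 + s,
                               measure_all_bins = TRUE)
      bd <- synth_experiment(cfg)
      nc <- norm_curve_for(bd, "H160")
      fit <- fit_birks(nc$norm, bd$beams$H160$profile, species = "H-1",
                       let_range = c(3, 45))
      abs(fit[["H-1"]]$kB - 3106) / 3106
    }, 0)
    stats::median(errs)
  }, 0)
  expect_true(all(diff(med_err) < 0))
  expect_lt(med_err[3], 1e-3)
})

test_that("volume averaging: identity, constants, Gaussian-boxcar oracle, conservation", {
  x <- stats::runif(50)
  expect_warning(got <- volume_average(x, window_mm = 0.1, bin_width = 0.1),
                 "window")
  expect_identical(got, x)
  const <- rep(2.5, 300)
  expect_equal(volume_average(const, window_mm = 1, bin_width = 0.1),
               const)
  # narrow Gaussian: averaged peak matches the closed-form boxcar
  # convolution (probe window 1 mm = 10 bins -> continuous span
  # [-0.5, +0.6] around the centre bin, sigma 2 mm)
  d <- seq(0.05, 59.95, by = 0.1)
  g <- exp(-(d - 30)^2 / (2 * 2^2))
  av <- volume_average(g, window_mm = 1, bin_width = 0.1)
  i0 <- which.max(av)
  lo <- d[i0] - 0.45
  hi <- d[i0] + 0.55
  oracle <- (2 * sqrt(2 * pi) / (hi - lo)) *
    (stats::pnorm((hi - 30) / 2) - stats::pnorm((lo - 30) / 2))
  expect_lt(abs(av[i0] - oracle) / oracle, 1e-3)
  # integral conservation away from edges
  expect_lt(abs(sum(av) - sum(g)) / sum(g), 1e-3)
  # probe-spec dispatch on containers
  dd <- generate_primary_profile(beam_presets("H160"))$dose
  smoothed <- volume_average(dd, probe_spec("single_crystal"))
  expect_lt(max(smoothed$dose), max(dd$dose))     # peak blunted
  pr <- generate_fragment_profile(beam_presets("He150"))
  pav <- volume_average(pr, probe_spec("grain_38um"))
  expect_silent(validate_species_profile(pav))
})

test_that("quench-then-correct: exact single-species inverse; mixed carbon within 5%", {
  # single species: exact to numerical precision
  cfg <- experiment_config(beams = "H160", truth = proton_truth(),
                           noise_sigma = 0, seed = 51)
  bd <- synth_experiment(cfg)
  nc <- norm_curve_for(bd, "H160")
  res <- correct_curve(nc$norm, bd$beams$H160$profile, bd$truth,
                       bd$beams$H160$reference)
  expect_lt(max(abs(res$table$diff_pct_corrected)), 0.1)
  # mixed-species carbon with ground-truth parameters
  cfg2 <- experiment_config(beams = "C290", noise_sigma = 0, seed = 52)
  bd2 <- synth_experiment(cfg2)
  nc2 <- norm_curve_for(bd2, "C290")
  res2 <- correct_curve(nc2$norm, bd2$beams$C290$profile, bd2$truth,
                        bd2$beams$C290$reference)
  expect_lte(abs(res2$metrics$corrected[["peak"]]), 5)
  expect_gt(abs(res2$metrics$uncorrected[["peak"]]), 25)
  # helium mirrors the published improvement pattern (~30% -> ~5%)
  cfg3 <- experiment_config(beams = "He150", noise_sigma = 0, seed = 53)
  bd3 <- synth_experiment(cfg3)
  nc3 <- norm_curve_for(bd3, "He150")
  res3 <- correct_curve(nc3$norm, bd3$beams$He150$profile, bd3$truth,
                        bd3$beams$He150$reference)
  expect_gt(abs(res3$metrics$uncorrected[["peak"]]), 20)
  expect_lte(abs(res3$metrics$corrected[["peak"]]), 5)
})

test_that("Birks parameter sets round-trip through JSON; fixtures load", {
  params <- default_birks_params("grain_38um")
  f <- tempfile(fileext = ".json")
  write_birks_json(params, f)
  back <- read_birks_json(f)
  expect_equal(back[["He-4"]]$kB, 110)
  expect_equal(back[["C-12"]]$rl0, 0.19)
  expect_equal(back[["H-1"]]$let_range, c(3, 45))
  unlink(f)
  tab <- load_birks_tables()
  expect_identical(nrow(tab), 9L)
  eff <- load_entrance_efficiency_table()
  expect_equal(eff$mu_grain_4um[eff$beam == "C290"], 0.73)
})
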