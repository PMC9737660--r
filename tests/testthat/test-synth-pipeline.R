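# synthetic campaign generator, end-to-end pipeline, CLI round trips

test_that("identical seeds give identical bundles; different seeds differ", {
  cfg <- experiment_config(beams = "H160", seed = 77)
  b1 <- synth_experiment(cfg)
  b2 <- synth_experiment(cfg)
  expect_identical(b1$beams$H160$traces, b2$beams$H160$traces)
  expect_identical(reduce_bundle(b1, "H160"), reduce_bundle(b2, "H160"))
  cfg3 <- experiment_config(beams = "H160", seed = 78)
  b3 <- synth_experiment(cfg3)
  expect_false(identical(reduce_bundle(b1, "H160")$delta_rl,
                         reduce_bundle(b3, "H160")$delta_rl))
})

test_that("zero-noise traces reduce exactly to the forward model", {
  cfg <- experiment_config(beams = "He150", noise_sigma = 0, seed = 5)
  bd <- synth_experiment(cfg)
  b <- bd$beams$He150
  meas <- reduce_bundle(bd, "He150")
  i <- grid_bin(b$profile$grid, meas$depth_mm)
  expected <- cfg$counts_per_gy * cfg$entrance_dose_gy *
    predict_rl_norm(b$profile, bd$truth)[i]
  expect_equal(meas$delta_rl, expected, tolerance = 1e-9)
})

test_that("bundle profiles pass the container invariants across random configurations", {
  set.seed(314)
  for (k in 1:20) {
    cfg <- experiment_config(
      beams = sample(c("H160", "He150", "C290", "C400"), 1),
      noise_sigma = stats::runif(1, 0, 0.05),
      entrance_dose_gy = stats::runif(1, 0.1, 10),
      straggling_fraction = stats::runif(1, 0.004, 0.03),
      seed = sample.int(1e6, 1))
    bd <- synth_experiment(cfg)
    for (b in bd$beams) {
      expect_silent(validate_species_profile(b$profile))
      expect_true(all(vapply(b$traces,
                             function(tr) all(tr$counts >= 0), TRUE)))
    }
  }
})

test_that("configuration validation lists every failure", {
  err <- tryCatch(
    experiment_config(noise_sigma = -1, entrance_dose_gy = 0, seed = 2^32),
    error = function(e) conditionMessage(e))
  expect_match(err, "noise_sigma")
  expect_match(err, "entrance_dose_gy")
  expect_match(err, "32-bit")
})

test_that("full pipeline on a zero-noise proton-only world is an exact chain", {
  cfg <- experiment_config(beams = c("H160", "H230"),
                           truth = proton_truth(), noise_sigma = 0,
                           seed = 13)
  bd <- synth_experiment(cfg)
  rep <- run_pipeline(bd, "full")
  expect_equal(rep$params[["H-1"]]$kB, 3106, tolerance = 1e-3)
  expect_equal(rep$params[["H-1"]]$rl0, 1.0246, tolerance = 1e-3)
  for (cr in rep$corrections) {
    expect_lt(max(abs(cr$table$diff_pct_corrected)), 0.1)
  }
})

test_that("full pipeline on the default noisy bundle corrects all beams to within 5% at the peak", {
  for (probe in c("grain_4um", "grain_38um", "single_crystal")) {
    cfg <- experiment_config(beams = c("H160", "He150", "C400"),
                             probe = probe, seed = 2024)
    bd <- synth_experiment(cfg)
    rep <- run_pipeline(bd, "full")
    expect_true(all(abs(rep$metrics$diff_peak_corrected) <= 5),
                label = paste(probe, "corrected peaks",
                              paste(round(rep$metrics$diff_peak_corrected, 2),
                                    collapse = "/")))
    # report schema: exactly the three summary metrics per curve, twice
    expect_identical(
      names(rep$metrics),
      c("beam", "probe", "diff_peak_corrected",
        "diff_plateau_max_corrected", "diff_falloff_max_corrected",
        "diff_peak_uncorrected", "diff_plateau_max_uncorrected",
        "diff_falloff_max_uncorrected"))
  }
})

test_that("pipeline reruns are pure functions of the bundle", {
  cfg <- experiment_config(beams = c("H160", "He150"), seed = 99)
  bd <- synth_experiment(cfg)
  r1 <- run_pipeline(bd, "full")
  r2 <- run_pipeline(bd, "full")
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$params[["He-4"]]$kB, r2$params[["He-4"]]$kB)
})

test_that("fit and correct modes: staging and error contracts", {
  cfg <- experiment_config(beams = c("H160", "He150"), seed = 15)
  bd <- synth_experiment(cfg)
  fit_only <- run_pipeline(bd, "fit")
  expect_null(fit_only$corrections)
  expect_s3_class(fit_only$params, "birks_set")
  corr <- run_pipeline(bd, "correct", params = bd$truth)
  expect_false(is.null(corr$metrics))
  expect_error(run_pipeline(bd, "correct"), "requires params")
  cfg_nop <- experiment_config(beams = "He150", seed = 15)
  expect_error(run_pipeline(synth_experiment(cfg_nop), "full"),
               "proton beam")
})

test_that("CLI: simulate -> fit -> correct -> report round trip on disk", {
  dir <- withr::local_tempdir()
  cfg_file <- file.path(dir, "cfg.yaml")
  writeLines(c("beams: [H160, He150]", "probe: grain_4um",
               "noise_sigma: 0.005", "depth_step_mm: 4.0",
               "seed: 321"), cfg_file)
  out <- file.path(dir, "bundle")
  expect_identical(iq_cli(c("simulate", "--config", cfg_file,
                            "--out", out)), 0L)
  expect_true(file.exists(file.path(out, "H160_profile.csv")))
  expect_identical(
    suppressMessages(iq_cli(c("fit", "--bundle", out, "--species", "He"))),
    0L)
  pfile <- file.path(out, "fitted_params.json")
  expect_true(file.exists(pfile))
  fitted <- read_birks_json(pfile)
  expect_equal(fitted[["He-4"]]$kB, 3106, tolerance = 0.15)
  expect_identical(
    suppressMessages(iq_cli(c("correct", "--bundle", out,
                              "--params", pfile))), 0L)
  expect_true(file.exists(file.path(out, "He150_correction.csv")))
  expect_identical(
    suppressMessages(iq_cli(c("report", "--bundle", out))), 0L)
  metrics <- utils::read.csv(file.path(out, "metrics.csv"))
  expect_true(all(abs(metrics$diff_peak_corrected) < 5))
  # bad input surfaces as a nonzero status, not an R error
  expect_identical(suppressMessages(iq_cli(c("fit", "--bundle", dir))), 1L)
  expect_identical(iq_cli(character(0)), 0L)
})
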