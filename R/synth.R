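# Synthetic measurement campaigns with known ground truth: profiles from
# the beam model, RL traces generated through the Birks forward model plus
# noise, reducible by the signal module and fittable by the quenching
# module.

#' Ground-truth Birks parameters for the synthetic world
#'
#' The synthetic campaigns need a known ground truth. The published
#' entrance relative efficiencies (five beams spanning 4.1 to 135 MeV/cm)
#' pin it: a single probe has one efficiency-vs-LET response
#' (the published efficiency curves collapse onto one curve per probe),
#' so one (kB, RL0) pair per probe, shared by all species, was obtained
#' by regressing `1/mu = (1 + kB' L)/RL0` on the packaged
#' entrance-efficiency table. The regression was run once and the values
#' are frozen here; kB in ug MeV^-1 cm^-2.
#'
#' @param probe One of `"grain_4um"`, `"grain_38um"`, `"single_crystal"`.
#' @return A [birks_set()] with identical parameters for H-1, He-4, C-12
#'   and Li-7 (the only species above trace level in any generated
#'   profile).
#' @export
ground_truth_params <- function(probe = c("grain_4um", "grain_38um",
                                          "single_crystal")) {
  probe <- match.arg(probe)
  pars <- switch(probe,
    grain_4um      = c(kB = 3106, rl0 = 1.0246),
    grain_38um     = c(kB = 3158, rl0 = 0.9736),
    single_crystal = c(kB = 3126, rl0 = 0.7700))
  birks_set(lapply(c("H-1", "He-4", "C-12", "Li-7"), function(sp) {
    birks_params(sp, pars[["kB"]], pars[["rl0"]])
  }))
}

#' Experiment configuration
#'
#' Validated configuration for a synthetic campaign. Defaults describe the
#' reference conditions: the preset beams, a '4 um' droplet probe with its
#' published ground-truth Birks parameters, 1% multiplicative signal
#' noise, 1 Gy entrance dose, traces sampled at 200 Hz with a 1 s
#' irradiation window between 25-sample background segments, and a fixed
#' seed.
#'
#' @param beams Character vector of beam preset names (see
#'   [beam_presets()]), or a named list of [beam_spec()] objects.
#' @param probe Probe type (see [probe_spec()]).
#' @param truth A [birks_set()] of ground-truth parameters (default:
#'   [ground_truth_params()] for `probe`).
#' @param noise_sigma Multiplicative Gaussian noise on the integrated
#'   signal amplitude (default 0.01).
#' @param poisson Also draw each trace sample from a Poisson law.
#' @param entrance_dose_gy Entrance dose per irradiation, Gy.
#' @param sample_rate Trace sampling rate, Hz.
#' @param window_s Irradiation window length, s.
#' @param background_counts Mean background counts per sample.
#' @param counts_per_gy Detector calibration (counts per Gy at reference
#'   quality); also the Co-60 calibration constant of the campaign.
#' @param depth_step_mm Spacing of measured depths in the plateau; every
#'   grid bin is measured within 10 mm of the Bragg peak.
#' @param measure_all_bins Measure every scoring bin instead (used for
#'   recovery studies).
#' @param straggling_fraction Range-straggling sigma fraction.
#' @param seed Integer seed; identical seeds give identical bundles.
#' @return An `experiment_config` object.
#' @export
experiment_config <- function(beams = c("H160", "H230", "He150", "C400"),
                              probe = "grain_4um",
                              truth = ground_truth_params(probe),
                              noise_sigma = 0.01, poisson = FALSE,
                              entrance_dose_gy = 1, sample_rate = 200,
                              window_s = 1, background_counts = 50,
                              counts_per_gy = 1e6, depth_step_mm = 2,
                              measure_all_bins = FALSE,
                              straggling_fraction = 0.012,
                              seed = 20221125) {
  if (is.character(beams)) {
    beams <- stats::setNames(lapply(beams, beam_presets), beams)
  }
  errs <- character()
  if (!all(vapply(beams, inherits, TRUE, "beam_spec"))) {
    errs <- c(errs, "beams must be beam_spec objects or preset names")
  }
  if (!inherits(truth, "birks_set")) {
    errs <- c(errs, "truth must be a birks_set")
  }
  if (noise_sigma < 0) errs <- c(errs, "noise_sigma must be >= 0")
  if (entrance_dose_gy <= 0) errs <- c(errs, "entrance_dose_gy must be > 0")
  if (window_s <= 0 || sample_rate <= 0) {
    errs <- c(errs, "window_s and sample_rate must be > 0")
  }
  if (background_counts < 0) errs <- c(errs, "background_counts must be >= 0")
  if (counts_per_gy <= 0) errs <- c(errs, "counts_per_gy must be > 0")
  if (depth_step_mm <= 0) errs <- c(errs, "depth_step_mm must be > 0")
  if (straggling_fraction < 0) {
    errs <- c(errs, "straggling_fraction must be >= 0")
  }
  if (abs(seed) >= 2^31) errs <- c(errs, "seed must fit a 32-bit integer")
  for (b in beams) {
    if (inherits(b, "beam_spec") &&
        is.null(tryCatch(default_frag_params(b), error = function(e) NULL))) {
      errs <- c(errs, paste0("no fragmentation defaults for beam ",
                             b$field_label))
    }
  }
  if (length(errs) > 0) {
    stop("invalid experiment configuration:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  }
  structure(list(beams = beams, probe = probe, truth = truth,
                 noise_sigma = noise_sigma, poisson = poisson,
                 entrance_dose_gy = entrance_dose_gy,
                 sample_rate = sample_rate, window_s = window_s,
                 background_counts = background_counts,
                 counts_per_gy = counts_per_gy,
                 depth_step_mm = depth_step_mm,
                 measure_all_bins = measure_all_bins,
                 straggling_fraction = straggling_fraction,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

# measured depth layout: plateau every depth_step_mm, every bin within
# 10 mm of the peak, nothing beyond 1.02x range; always includes bin 1
.measured_depths <- function(grid, peak_mm, range_mm, step_mm, all_bins) {
  d <- grid_depths(grid)
  keep <- d <= 1.02 * range_mm
  if (all_bins) return(d[keep])
  coarse <- abs((d - d[1]) %% step_mm) < grid$bin_width / 2
  fine <- abs(d - peak_mm) <= 10
  sort(unique(c(d[1], d[keep & (coarse | fine)])))
}

#' Generate a synthetic measurement bundle
#'
#' For each configured beam: builds the per-species fluence/LET profile
#' and the reference energy-deposition curve from the beam model,
#' evaluates the quenched RL through the Birks forward model with the
#' ground-truth parameters, and emits one RL trace per measured depth
#' (background + rectangular irradiation pulse, multiplicative Gaussian
#' amplitude noise, optional Poisson counting noise). The ground truth is
#' embedded for recovery studies. Identical seeds give identical bundles.
#'
#' @param config An [experiment_config()].
#' @return A `synth_bundle`: list with `config`, `cal` (the campaign
#'   [calibration_constant()]), and per-beam elements each holding
#'   `beam`, `profile`, `reference`, `primary` (the
#'   [generate_primary_profile()] output), `depths_mm`, `traces`,
#'   `delta_rl_true` and `rl_norm_true`.
#' @export
synth_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  n_win <- round(config$window_s * config$sample_rate)
  cal <- calibration_constant(config$probe, config$counts_per_gy)

  beams_out <- lapply(names(config$beams), function(nm) {
    beam <- config$beams[[nm]]
    grid <- grid_for_beam(beam)
    primary <- generate_primary_profile(
      beam, grid, straggling_fraction = config$straggling_fraction)
    profile <- generate_fragment_profile(
      beam, grid, straggling_fraction = config$straggling_fraction)
    reference <- reference_from_profile(
      profile, entrance_dose = config$entrance_dose_gy)
    rl_norm <- predict_rl_norm(profile, config$truth)
    depths <- .measured_depths(grid, primary$peak_depth_mm,
                               primary$range_mm, config$depth_step_mm,
                               config$measure_all_bins)
    i <- grid_bin(grid, depths)
    amp <- config$counts_per_gy * config$entrance_dose_gy * rl_norm[i]
    noise <- if (config$noise_sigma > 0) {
      1 + stats::rnorm(length(amp), 0, config$noise_sigma)
    } else {
      rep(1, length(amp))
    }
    amp_n <- pmax(amp * noise, 0)
    traces <- lapply(seq_along(depths), function(k) {
      base <- rep(config$background_counts, 50 + n_win)
      pulse <- c(rep(0, 25), rep(amp_n[k] / n_win, n_win), rep(0, 25))
      counts <- base + pulse
      if (config$poisson) counts <- stats::rpois(length(counts), counts)
      rl_trace(counts, sample_rate = config$sample_rate,
               window = c(26, 25 + n_win), pre_background = c(1, 25),
               post_background = c(26 + n_win, 50 + n_win))
    })
    list(beam = beam, profile = profile, reference = reference,
         primary = primary, depths_mm = depths, traces = traces,
         delta_rl_true = amp, rl_norm_true = rl_norm[i])
  })
  names(beams_out) <- names(config$beams)
  structure(list(config = config, cal = cal, beams = beams_out,
                 truth = config$truth),
            class = "synth_bundle")
}

#' @export
print.synth_bundle <- function(x, ...) {
  cat(sprintf("<synth_bundle> probe %s, %d beam(s): %s; seed %d\n",
              x$config$probe, length(x$beams),
              paste(names(x$beams), collapse = ", "), x$config$seed))
  invisible(x)
}

#' Reduce a bundle's traces to integrated signals
#'
#' @param bundle A `synth_bundle`.
#' @param beam Beam name within the bundle.
#' @return Data frame with `depth_mm`, `delta_rl`.
#' @export
reduce_bundle <- function(bundle, beam) {
  b <- bundle$beams[[beam]]
  if (is.null(b)) stop("no beam '", beam, "' in bundle", call. = FALSE)
  data.frame(depth_mm = b$depths_mm,
             delta_rl = vapply(b$traces, integrate_trace, 0))
}
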