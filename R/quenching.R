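# Voxelized Birks quenching model, fluence-weighted correction factors,
# kB/RL0 fitting with frozen fragment parameters, probe-volume averaging
# and corrected-curve reconstruction.

# kB is carried in mass units (ug MeV^-1 cm^-2). With water density
# 1 g/cm^3 = 1e6 ug/cm^3 the dimensionless saturation product is
# kB/1e6 * LET[MeV/cm].
.KB_SCALE <- 1e-6

#' Birks parameters for one species
#'
#' The Birks constant kB and the scaling/efficiency factor RL0 of the
#' detector response to one particle species, with the LET range over
#' which the pair is valid.
#'
#' @param species Species label.
#' @param kB Birks constant in ug MeV^-1 cm^-2 (>= 0).
#' @param rl0 Scaling factor (> 0), dimensionless.
#' @param let_range Validity LET range in MeV/cm, `c(lo, hi)`.
#' @param stderr Optional standard errors `c(kB, rl0)`.
#' @return A `birks_params` object.
#' @export
birks_params <- function(species, kB, rl0, let_range = c(0, Inf),
                         stderr = c(NA_real_, NA_real_)) {
  particle_species(species)
  if (kB < 0) stop("kB must be >= 0", call. = FALSE)
  if (rl0 <= 0) stop("rl0 must be > 0", call. = FALSE)
  if (diff(let_range) <= 0) stop("empty LET validity range", call. = FALSE)
  structure(list(species = species, kB = kB, rl0 = rl0,
                 let_range = let_range,
                 stderr = stats::setNames(stderr, c("kB", "rl0"))),
            class = "birks_params")
}

#' @export
print.birks_params <- function(x, ...) {
  cat(sprintf(
    "<birks_params> %s: kB = %.4g ug/MeV/cm^2, RL0 = %.4g (LET %.3g-%.3g MeV/cm)\n",
    x$species, x$kB, x$rl0, x$let_range[1], x$let_range[2]))
  invisible(x)
}

#' A set of per-species Birks parameters
#'
#' @param ... `birks_params` objects.
#' @return A named list of class `birks_set`, keyed by species.
#' @export
birks_set <- function(...) {
  ps <- list(...)
  if (length(ps) == 1 && is.list(ps[[1]]) &&
      !inherits(ps[[1]], "birks_params")) {
    ps <- ps[[1]]
  }
  stopifnot(all(vapply(ps, inherits, TRUE, "birks_params")))
  names(ps) <- vapply(ps, `[[`, "", "species")
  structure(ps, class = "birks_set")
}

#' Reference Birks parameters per probe type
#'
#' The published kB/RL0 pairs for the three probe archetypes ('4 um',
#' '38 um', 'Single Crystal') determined against protons (validity
#' 3-45 MeV/cm), helium (20-240 MeV/cm) and carbon (90-1700 MeV/cm),
#' loaded from the packaged transcription.
#'
#' @param probe One of `"grain_4um"`, `"grain_38um"`, `"single_crystal"`.
#' @return A `birks_set` with species H-1, He-4, C-12.
#' @export
#' @examples
#' default_birks_params("grain_4um")
default_birks_params <- function(probe = c("grain_4um", "grain_38um",
                                           "single_crystal")) {
  probe <- match.arg(probe)
  tab <- load_birks_tables()
  rows <- tab[tab$probe == probe, ]
  birks_set(lapply(seq_len(nrow(rows)), function(i) {
    birks_params(rows$species[i], rows$kB_ug_per_mev_cm2[i], rows$rl0[i],
                 c(rows$let_min_mev_cm[i], rows$let_max_mev_cm[i]),
                 stderr = c(rows$kB_stderr[i], NA))
  }))
}

#' Voxelized Birks light output
#'
#' Light emitted from a voxel: `RL_v = (RL0 * LET / (1 + kB' * LET)) * phi`
#' with `kB' = kB / 1e6` making the product dimensionless for LET in
#' MeV/cm. `kB = 0` recovers the unquenched limit `RL0 * LET * phi`; at
#' large LET the output saturates at `(RL0 / kB') * phi`.
#'
#' @param let Fluence-averaged LET in the voxel, MeV/cm (> 0, vectorized).
#' @param fluence Particle fluence in the voxel (>= 0).
#' @param params A [birks_params()].
#' @return Emitted light `RL_v` (same scale as `fluence * let`).
#' @export
birks_rl <- function(let, fluence, params) {
  if (any(let <= 0)) stop("let must be positive", call. = FALSE)
  if (any(fluence < 0)) stop("fluence must be non-negative", call. = FALSE)
  (params$rl0 * let / (1 + .KB_SCALE * params$kB * let)) * fluence
}

#' Single-species quenching correction factor
#'
#' `eta = (1 + kB' * LET) / RL0`: the ratio of deposited energy to emitted
#' light for one species, exactly inverting [birks_rl()] per voxel
#' (`eta * RL_v = phi * LET`).
#'
#' @param let LET in MeV/cm.
#' @param params A [birks_params()].
#' @return Correction factor (vectorized over `let`).
#' @export
eta_single <- function(let, params) {
  (1 + .KB_SCALE * params$kB * let) / params$rl0
}

#' Fluence-weighted quenching correction factor
#'
#' The combined correction at one depth is the fluence-weighted sum of the
#' per-species factors: `eta = sum_i f_i * (1 + kB_i' * LET_i) / RL0_i`,
#' evaluated per depth. With a single species this reduces to the pure
#' primary form; with \{He, H\} and \{C, He, H\} it reduces to the helium
#' and carbon specializations (see [eta_helium()], [eta_carbon()]).
#' Species without fitted parameters contribute with a configurable
#' default (kB = 0, RL0 = 1); their summed fluence is below 0.1% wherever
#' the published tables apply.
#'
#' @param f Named numeric vector of fluence fractions (summing to 1) or a
#'   matrix with species columns.
#' @param let LET per species in MeV/cm, same shape as `f`.
#' @param params A [birks_set()].
#' @param default A [birks_params()] used for species absent from
#'   `params`, or `NULL` to raise an error listing them.
#' @return eta (scalar, or vector for matrix input).
#' @export
eta_combined <- function(f, let, params,
                         default = birks_params("H-1", 0, 1)) {
  if (is.matrix(f)) {
    species <- colnames(f)
  } else {
    species <- names(f)
    f <- matrix(f, 1, dimnames = list(NULL, species))
    let <- matrix(let, 1)
  }
  if (is.null(species)) stop("species names required on f", call. = FALSE)
  present <- colSums(f > 0) > 0
  missing <- setdiff(species[present], names(params))
  if (length(missing) > 0 && is.null(default)) {
    stop("missing Birks parameters for species: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  eta <- 0
  for (j in seq_along(species)) {
    p <- params[[species[j]]]
    if (is.null(p)) p <- default
    eta <- eta + f[, j] * (1 + .KB_SCALE * p$kB * let[, j]) / p$rl0
  }
  unname(eta)
}

#' Per-beam specializations of the combined correction factor
#'
#' Closed-form correction factors for the three beam families, written out
#' exactly as used to correct the measured curves: protons from the
#' primary alone; helium from the primary plus the H-1 fragment; carbon
#' from the primary plus the H-1 and He-4 fragments. They agree
#' bit-for-bit with [eta_combined()] on the corresponding species sets.
#'
#' @param let_h,let_he,let_c LET of H-1, He-4, C-12 in MeV/cm.
#' @param f_h,f_he,f_c Fluence fractions of H-1, He-4, C-12.
#' @param params A [birks_set()] holding the needed species.
#' @return eta.
#' @export
eta_proton <- function(let_h, params) {
  p <- params[["H-1"]]
  (1 + .KB_SCALE * p$kB * let_h) / p$rl0
}

#' @rdname eta_proton
#' @export
eta_helium <- function(f_he, let_he, f_h, let_h, params) {
  ph <- params[["H-1"]]
  phe <- params[["He-4"]]
  f_h * (1 + .KB_SCALE * ph$kB * let_h) / ph$rl0 +
    f_he * (1 + .KB_SCALE * phe$kB * let_he) / phe$rl0
}

#' @rdname eta_proton
#' @export
eta_carbon <- function(f_c, let_c, f_he, let_he, f_h, let_h, params) {
  ph <- params[["H-1"]]
  phe <- params[["He-4"]]
  pc <- params[["C-12"]]
  f_h * (1 + .KB_SCALE * ph$kB * let_h) / ph$rl0 +
    f_he * (1 + .KB_SCALE * phe$kB * let_he) / phe$rl0 +
    f_c * (1 + .KB_SCALE * pc$kB * let_c) / pc$rl0
}

#' eta profile along a depth grid
#'
#' @param profile A [species_profile()].
#' @param params A [birks_set()].
#' @param default Passed to [eta_combined()].
#' @return Vector of eta per bin.
#' @export
eta_profile <- function(profile, params,
                        default = birks_params("H-1", 0, 1)) {
  eta_combined(profile$fluence_fraction, profile$let_f, params,
               default = default)
}

#' Forward model: normalized quenched RL along a profile
#'
#' The voxel Birks forward model for the normalized 'RL signal': the light
#' emitted from the voxel at depth d is the deposited energy divided by
#' the fluence-weighted correction factor, `RL_v = E_v / eta(d)` with
#' `E_v = phi * sum_i f_i LET_i`, normalized to the entrance deposited
#' energy. For a single species this is exactly the voxelized Birks law
#' `RL_v = RL0 * LET/(1 + kB' LET) * phi`, and by construction the
#' fluence-weighted correction is its exact inverse. An unquenched
#' detector (kB = 0, RL0 = 1) returns exactly the normalized reference
#' curve; the entrance value is the model's relative efficiency
#' `1 / eta(entrance)`.
#'
#' @param profile A [species_profile()] (its `absolute_fluence` supplies
#'   the relative total fluence; 1 if absent).
#' @param params A [birks_set()].
#' @param default Parameters for species absent from `params`.
#' @return Vector of normalized RL per bin.
#' @export
predict_rl_norm <- function(profile, params,
                            default = birks_params("H-1", 0, 1)) {
  phi <- profile$absolute_fluence
  if (is.null(phi)) phi <- rep(1, profile$grid$n_bins)
  e <- phi * rowSums(profile$fluence_fraction * profile$let_f)
  eta <- eta_profile(profile, params, default = default)
  unname(e / eta / e[1])
}

#' Reference energy-deposition curve of a profile
#'
#' Normalized deposited energy per bin, `phi * sum_i f_i LET_i`, scaled to
#' 1 at the entrance bin: the quantity an ideal (unquenched) detector
#' reads, and the reference that quench-then-correct must restore.
#'
#' @param profile A [species_profile()].
#' @param entrance_dose Entrance dose in Gy carried on the curve.
#' @return A normalized [depth_dose()] with source `"reference"`.
#' @export
reference_from_profile <- function(profile, entrance_dose = 1) {
  phi <- profile$absolute_fluence
  if (is.null(phi)) phi <- rep(1, profile$grid$n_bins)
  e <- phi * rowSums(profile$fluence_fraction * profile$let_f)
  depth_dose(profile$grid, e / e[1], source = "reference",
             entrance_dose = entrance_dose)
}

#' Normalized RL curve from measurements
#'
#' Converts depth-resolved integrated RL signals to the normalized
#' 'RL signal' representation used for Birks fitting: the measured signal
#' relative to its entrance value, scaled by the entrance relative
#' efficiency, so the value at the entrance equals `mu_entrance` and an
#' unquenched detector reproduces the normalized reference curve.
#'
#' @param mu_entrance Relative efficiency at the entrance depth.
#' @param measured Data frame with `depth_mm` and `delta_rl`; must include
#'   a point in the entrance bin of `reference`.
#' @param reference A normalized [depth_dose()] (used for alignment and
#'   the entrance convention).
#' @return Data frame with `depth_mm`, `rl_norm`.
#' @export
normalized_rl_curve <- function(mu_entrance, measured, reference) {
  i <- grid_bin(reference$grid, measured$depth_mm)
  ent <- which(i == 1L)
  if (length(ent) == 0) {
    stop("no measurement in the entrance bin; cannot calibrate",
         call. = FALSE)
  }
  rl0 <- mean(measured$delta_rl[ent])
  data.frame(depth_mm = measured$depth_mm,
             rl_norm = measured$delta_rl / rl0 * mu_entrance)
}

#' Fit Birks parameters to a normalized RL curve
#'
#' Nonlinear least-squares fit of the forward model [predict_rl_norm()] to
#' a normalized RL curve, for one free species, with the remaining species
#' frozen (the progressive-freezing scheme: protons first, then helium
#' with frozen H-1, then carbon with frozen H-1 and He-4). Only depths
#' whose primary LET lies inside `let_range` enter the fit, matching the
#' published validity ranges (3-45, 20-240, 90-1700 MeV/cm). Bounded
#' multi-start `nls` (port): kB starts log-spaced, RL0 from the low-LET
#' ratio; bounds kB >= 0, RL0 > 0.
#'
#' @param normalized_rl Data frame with `depth_mm`, `rl_norm` (may combine
#'   several beams when `profile` is a list of matching profiles).
#' @param profile A [species_profile()], or a list of them (one per block
#'   of rows, with `normalized_rl` carrying a `beam` column naming the
#'   list element).
#' @param species Free species label (default: first column of the
#'   profile, the primary).
#' @param let_range LET window in MeV/cm on the free species' LET.
#' @param frozen A [birks_set()] of frozen parameters for the other
#'   species (must include every fragment species carrying > 0.1%
#'   fluence), or `NULL` for a pure single-species fit.
#' @param start_kB Multi-start grid for kB (ug MeV^-1 cm^-2).
#' @return A [birks_set()] containing the fitted species (with standard
#'   errors, `let_range`, and attributes `r_squared`, `n_points`) plus the
#'   frozen parameters untouched.
#' @export
fit_birks <- function(normalized_rl, profile, species = NULL,
                      let_range = c(0, Inf), frozen = NULL,
                      start_kB = c(0.5, 5, 50, 500, 5000)) {
  profiles <- if (inherits(profile, "species_profile")) {
    list(profile)
  } else {
    profile
  }
  if (length(profiles) > 1 && is.null(normalized_rl$beam)) {
    stop("multi-profile fit needs a 'beam' column naming the profile",
         call. = FALSE)
  }
  if (is.null(species)) species <- profiles[[1]]$species[1]
  frozen_set <- if (is.null(frozen)) birks_set(list()) else frozen
  default <- birks_params("H-1", 0, 1)

  # assemble per-point design: free-species (phi f L) and frozen
  # contribution, LET of the free species for windowing
  blocks <- lapply(seq_along(profiles), function(k) {
    pr <- profiles[[k]]
    rows <- if (length(profiles) == 1) {
      seq_len(nrow(normalized_rl))
    } else {
      which(normalized_rl$beam == names(profiles)[k])
    }
    sub <- normalized_rl[rows, ]
    i <- grid_bin(pr$grid, sub$depth_mm)
    phi <- pr$absolute_fluence
    if (is.null(phi)) phi <- rep(1, pr$grid$n_bins)
    e <- phi * rowSums(pr$fluence_fraction * pr$let_f)
    j_free <- match(species, pr$species)
    if (is.na(j_free)) stop("species ", species, " not in profile",
                            call. = FALSE)
    need <- setdiff(pr$species[-j_free], names(frozen_set))
    heavy <- need[colSums(pr$fluence_fraction[i, need, drop = FALSE]) >
                    1e-3 * length(i)]
    if (length(heavy) > 0 && !is.null(frozen)) {
      stop("frozen set missing required fragment species: ",
           paste(heavy, collapse = ", "), call. = FALSE)
    }
    # frozen part of the fluence-weighted correction factor
    eta_frozen <- rep(0, length(i))
    for (j in seq_along(pr$species)[-j_free]) {
      p <- frozen_set[[pr$species[j]]]
      if (is.null(p)) p <- default
      eta_frozen <- eta_frozen + pr$fluence_fraction[i, j] *
        (1 + .KB_SCALE * p$kB * pr$let_f[i, j]) / p$rl0
    }
    data.frame(y = sub$rl_norm,
               L = pr$let_f[i, j_free],
               f_free = pr$fluence_fraction[i, j_free],
               eta_frozen = eta_frozen,
               energy = e[i] / e[1])
  })
  dat <- do.call(rbind, blocks)
  dat <- dat[dat$L >= let_range[1] & dat$L <= let_range[2], ]
  if (nrow(dat) < 4) {
    stop("fewer than 4 depth points with primary LET inside [",
         let_range[1], ", ", let_range[2], "] MeV/cm", call. = FALSE)
  }

  # RL0 start: invert the model at the low-LET end with kB = 0
  lo <- dat[order(dat$L), ][seq_len(max(4, nrow(dat) %/% 10)), ]
  rl0_start <- stats::median(lo$f_free /
                               pmax(lo$energy / lo$y - lo$eta_frozen,
                                    1e-12))
  rl0_start <- min(max(rl0_start, 1e-3), 100)

  best <- NULL
  diags <- character()
  for (kb0 in start_kB) {
    fit <- tryCatch(
      stats::nls(y ~ energy /
                   (eta_frozen + f_free * (1 + .KB_SCALE * kb * L) / rl0),
                 data = dat, start = list(rl0 = rl0_start, kb = kb0),
                 algorithm = "port", lower = c(rl0 = 1e-6, kb = 0),
                 control = stats::nls.control(maxiter = 200)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      diags <- c(diags, conditionMessage(fit))
      next
    }
    if (is.null(best) || deviance(fit) < deviance(best)) best <- fit
  }
  if (is.null(best)) {
    stop("Birks fit failed from every start; residual diagnostics:\n",
         paste(unique(diags), collapse = "\n"), call. = FALSE)
  }
  co <- stats::coef(best)
  se <- tryCatch(sqrt(diag(stats::vcov(best))),
                 error = function(e) c(rl0 = NA_real_, kb = NA_real_))
  ss_res <- sum(stats::resid(best)^2)
  ss_tot <- sum((dat$y - mean(dat$y))^2)
  fitted_p <- birks_params(species, unname(co["kb"]), unname(co["rl0"]),
                           let_range = let_range,
                           stderr = c(unname(se["kb"]), unname(se["rl0"])))
  out <- birks_set(c(list(fitted_p), unclass(frozen_set)))
  attr(out, "r_squared") <- 1 - ss_res / ss_tot
  attr(out, "n_points") <- nrow(dat)
  out
}

#' Probe geometry specification
#'
#' @param type `"single_crystal"` (1 mm crystal along the beam axis),
#'   `"grain_38um"` or `"grain_4um"` (0.2 mm droplets).
#' @return A `probe_spec` with `active_length_mm` and `grain_size_um`.
#' @export
probe_spec <- function(type = c("single_crystal", "grain_38um",
                                "grain_4um")) {
  type <- match.arg(type)
  structure(list(
    type = type,
    active_length_mm = if (type == "single_crystal") 1.0 else 0.2,
    grain_size_um = switch(type, single_crystal = 1000, grain_38um = 38,
                           grain_4um = 4)),
    class = "probe_spec")
}

#' Probe-volume averaging
#'
#' Finite probe volumes average the steep dose and LET gradients along the
#' Bragg curve. This applies a moving-average (boxcar) window equal to the
#' probe's active length along the beam, renormalized at the edges.
#'
#' @param x A numeric vector, a [depth_dose()] or a [species_profile()]
#'   (dose and LET columns are averaged).
#' @param probe A [probe_spec()], or a window length in mm via
#'   `window_mm`.
#' @param bin_width Bin width in mm (taken from the object when present).
#' @param window_mm Explicit window length, mm.
#' @return Same type as `x`, averaged.
#' @export
volume_average <- function(x, probe = NULL, bin_width = NULL,
                           window_mm = NULL) {
  UseMethod("volume_average")
}

#' @export
volume_average.numeric <- function(x, probe = NULL, bin_width = NULL,
                                   window_mm = NULL) {
  if (is.null(window_mm)) window_mm <- probe$active_length_mm
  if (is.null(bin_width)) stop("bin_width required", call. = FALSE)
  k <- round(window_mm / bin_width)
  if (k <= 1) {
    warning("averaging window not longer than one bin; returning input")
    return(x)
  }
  n <- length(x)
  half_l <- (k - 1L) %/% 2L
  half_r <- k - 1L - half_l
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - half_l, 1L)
  hi <- pmin(i + half_r, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' @export
volume_average.depth_dose <- function(x, probe = NULL, bin_width = NULL,
                                      window_mm = NULL) {
  d <- volume_average.numeric(x$dose, probe, x$grid$bin_width, window_mm)
  if (x$normalized) d <- d / d[1]
  depth_dose(x$grid, d, source = x$source, normalized = x$normalized,
             entrance_dose = x$entrance_dose)
}

#' @export
volume_average.species_profile <- function(x, probe = NULL,
                                           bin_width = NULL,
                                           window_mm = NULL) {
  bw <- x$grid$bin_width
  f <- apply(x$fluence_fraction, 2, volume_average.numeric, probe = probe,
             bin_width = bw, window_mm = window_mm)
  l <- apply(x$let_f, 2, volume_average.numeric, probe = probe,
             bin_width = bw, window_mm = window_mm)
  phi <- x$absolute_fluence
  if (!is.null(phi)) {
    phi <- volume_average.numeric(phi, probe, bw, window_mm)
  }
  species_profile(x$grid, x$species, f / rowSums(f), l,
                  absolute_fluence = phi)
}

#' Correct a quenched RL curve and compare with the reference
#'
#' Applies the fluence-weighted correction factor per depth:
#' `corrected(d) = eta(d) * measured(d) / eta(entrance)`, then renormalizes
#' so the corrected entrance equals the reference entrance. Reports the
#' per-depth percent difference against the reference for both the
#' corrected and the uncorrected curve, and three summary metrics: the
#' difference at the Bragg peak, the maximum absolute difference in the
#' plateau, and the maximum absolute difference in the distal falloff
#' (points beyond the 80% distal-dose depth are flagged, not dropped;
#' accuracy there is known to degrade).
#'
#' @param measured Data frame with `depth_mm`, `rl_norm` (from
#'   [normalized_rl_curve()]).
#' @param profile A [species_profile()] on the same grid as `reference`.
#' @param params A [birks_set()].
#' @param reference A normalized [depth_dose()].
#' @param falloff_floor Fraction of the peak dose below which distal
#'   points are excluded from metrics (default 0.1).
#' @return A `correction_result`: list with `table` (depth_mm, eta,
#'   dose_corrected, dose_uncorrected, ref_dose, diff_pct_corrected,
#'   diff_pct_uncorrected, region), and `metrics` for corrected and
#'   uncorrected curves.
#' @export
correct_curve <- function(measured, profile, params, reference,
                          falloff_floor = 0.1) {
  i <- grid_bin(reference$grid, measured$depth_mm)
  eta_all <- eta_profile(profile, params)
  eta <- eta_all[i]
  if (any(!is.finite(eta))) {
    bad <- measured$depth_mm[!is.finite(eta)][1]
    stop("non-finite correction factor at depth ", bad, " mm",
         call. = FALSE)
  }
  ent <- which(i == 1L)
  if (length(ent) == 0) stop("no entrance measurement", call. = FALSE)
  corr_raw <- eta * measured$rl_norm / eta[ent[1]]
  corrected <- corr_raw / mean(corr_raw[ent]) * reference$dose[1]
  uncorrected <- measured$rl_norm / mean(measured$rl_norm[ent]) *
    reference$dose[1]
  ref <- reference$dose[i]
  diff_c <- 100 * (corrected - ref) / ref
  diff_u <- 100 * (uncorrected - ref) / ref

  pk_bin <- which.max(reference$dose)
  pk_depth <- grid_depths(reference$grid)[pk_bin]
  # distal 80% dose depth: first depth beyond the peak where the
  # reference falls below 80% of its maximum
  beyond <- which(seq_along(reference$dose) > pk_bin &
                    reference$dose < 0.8 * reference$dose[pk_bin])
  d80 <- if (length(beyond) > 0) {
    grid_depths(reference$grid)[beyond[1]]
  } else {
    Inf
  }
  region <- ifelse(measured$depth_mm > d80, "falloff",
                   ifelse(abs(measured$depth_mm - pk_depth) <=
                            5 * reference$grid$bin_width, "peak", "plateau"))
  usable <- ref >= falloff_floor * reference$dose[pk_bin]

  metric3 <- function(dv) {
    at_peak <- dv[which.min(abs(measured$depth_mm - pk_depth))]
    plat <- abs(dv[region == "plateau" & measured$depth_mm < pk_depth])
    fall <- abs(dv[region == "falloff" & usable])
    c(peak = at_peak,
      plateau_max = if (length(plat)) max(plat) else NA_real_,
      falloff_max = if (length(fall)) max(fall) else NA_real_)
  }
  structure(list(
    table = data.frame(depth_mm = measured$depth_mm, eta = eta,
                       dose_corrected = corrected,
                       dose_uncorrected = uncorrected, ref_dose = ref,
                       diff_pct_corrected = diff_c,
                       diff_pct_uncorrected = diff_u, region = region),
    metrics = list(corrected = metric3(diff_c),
                   uncorrected = metric3(diff_u)),
    peak_depth_mm = pk_depth, falloff_start_mm = d80),
    class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  m <- x$metrics
  cat("<correction_result>\n")
  cat(sprintf("  Bragg peak at %.2f mm; falloff beyond %.2f mm\n",
              x$peak_depth_mm, x$falloff_start_mm))
  cat(sprintf("  diff vs reference at peak: %+.2f%% corrected, %+.2f%% uncorrected\n",
              m$corrected["peak"], m$uncorrected["peak"]))
  cat(sprintf("  plateau max |diff|: %.2f%% corrected, %.2f%% uncorrected\n",
              m$corrected["plateau_max"], m$uncorrected["plateau_max"]))
  cat(sprintf("  falloff max |diff|: %.2f%% corrected, %.2f%% uncorrected\n",
              m$corrected["falloff_max"], m$uncorrected["falloff_max"]))
  invisible(x)
}

#' Write a correction result as CSV
#'
#' Columns `depth_mm`, `eta`, `dose_corrected`, `dose_uncorrected`,
#' `ref_dose`, `diff_pct_corrected`, `diff_pct_uncorrected`.
#'
#' @param result A `correction_result`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_correction_csv <- function(result, path) {
  utils::write.csv(result$table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read Birks parameter sets as JSON
#'
#' Schema: array of objects with `species`, `kB_ug_per_mev_cm2`, `rl0`,
#' `let_range_mev_cm`, `stderr`.
#'
#' @param params A `birks_set`.
#' @param path File path.
#' @return `path`, invisibly (writer); a `birks_set` (reader).
#' @export
write_birks_json <- function(params, path) {
  arr <- lapply(unclass(params), function(p) {
    list(species = p$species, kB_ug_per_mev_cm2 = p$kB, rl0 = p$rl0,
         let_range_mev_cm = p$let_range,
         stderr = as.list(p$stderr))
  })
  jsonlite::write_json(unname(arr), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_birks_json
#' @export
read_birks_json <- function(path) {
  arr <- jsonlite::read_json(path)
  num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  birks_set(lapply(arr, function(p) {
    birks_params(p$species, p$kB_ug_per_mev_cm2, p$rl0,
                 unlist(p$let_range_mev_cm),
                 stderr = c(num_or_na(p$stderr$kB),
                            num_or_na(p$stderr$rl0)))
  }))
}

#' Load the packaged transcribed parameter tables
#'
#' The published kB/RL0 values per probe and species (with validity LET
#' ranges and kB standard errors), shipped as a plain-text fixture.
#'
#' @return A data frame.
#' @export
load_birks_tables <- function() {
  path <- system.file("extdata", "tables_6_7_8.json", package = "ionquench")
  arr <- jsonlite::read_json(path, simplifyVector = TRUE)
  as.data.frame(arr)
}

#' Load the packaged transcribed fluence / LET rows
#'
#' The printed per-depth fluence-fraction and fluence-averaged-LET rows for
#' the five beams (entrance, end of plateau, Bragg peak, falloff; primary
#' plus two fragments each), transcribed verbatim. Fractions are percent;
#' LET is keV/um.
#'
#' @return A data frame with columns `beam`, `depth_mm`, `species`,
#'   `fluence_pct`, `let_kev_um`.
#' @export
load_fluence_tables <- function() {
  path <- system.file("extdata", "tables_3_4_5.csv", package = "ionquench")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Load the packaged entrance-efficiency table
#'
#' Measured relative luminescence efficiencies at the entrance depth per
#' probe and beam, with one-standard-deviation uncertainties.
#'
#' @return A data frame.
#' @export
load_entrance_efficiency_table <- function() {
  path <- system.file("extdata", "table_2.csv", package = "ionquench")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
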