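# Relative luminescence efficiency against the Co-60 reference and the
# exponential efficiency-vs-LET model.

#' Co-60 calibration constant
#'
#' The counts-per-Gy constant C of a probe, measured against the Co-60
#' reference before and after a campaign. The two values are averaged; a
#' warning is emitted if they differ by more than 3% (material sensitivity
#' drift).
#'
#' @param probe Probe label.
#' @param pre,post Pre- and post-campaign counts/Gy (post defaults to pre).
#' @return A `calibration_constant` object with field `C`.
#' @export
calibration_constant <- function(probe, pre, post = pre) {
  if (pre <= 0 || post <= 0) stop("calibration must be positive", call. = FALSE)
  C <- mean(c(pre, post))
  drift <- abs(post - pre) / C
  if (drift > 0.03) {
    warning(sprintf(
      "pre/post calibrations differ by %.1f%% (sensitivity drift)",
      100 * drift))
  }
  structure(list(probe = probe, C = C, pre = pre, post = post,
                 drift = drift),
            class = "calibration_constant")
}

#' Relative luminescence efficiency
#'
#' Light output per dose of a heavy-charged-particle beam relative to the
#' Co-60 reference: `mu = (rl_hcp / d_hcp) / C`.
#'
#' @param rl_hcp Integrated RL signal, counts.
#' @param d_hcp Absorbed dose in Gy (> 0, in or corrected to the linear
#'   range).
#' @param cal A [calibration_constant()].
#' @return Dimensionless efficiency `mu` (vectorized).
#' @export
relative_efficiency <- function(rl_hcp, d_hcp, cal) {
  if (any(d_hcp <= 0)) stop("d_hcp must be positive", call. = FALSE)
  if (any(rl_hcp < 0)) stop("rl_hcp must be non-negative", call. = FALSE)
  (rl_hcp / d_hcp) / cal$C
}

#' Build an efficiency-vs-LET curve along a Bragg curve
#'
#' Converts depth-resolved integrated RL signals to relative efficiencies
#' (dose at each depth from the reference curve and its entrance dose) and
#' pairs them with the LET at that depth. The LET axis is either the
#' fluence-weighted LET over primary plus fragments (default; the axis on
#' which beams of different species collapse onto a single curve) or the
#' primary species' LET alone.
#'
#' @param measurements Data frame with `depth_mm` and `delta_rl`.
#' @param reference A normalized [depth_dose()] reference curve whose
#'   `entrance_dose` is the physical entrance dose in Gy.
#' @param cal A [calibration_constant()].
#' @param profile A [species_profile()] aligned with the reference grid.
#' @param axis `"weighted"` or `"primary"`.
#' @param beam Beam label attached to the points.
#' @return An `efficiency_curve`: data frame with `beam`, `depth_mm`,
#'   `let_kev_um`, `mu`.
#' @export
build_efficiency_curve <- function(measurements, reference, cal, profile,
                                   axis = c("weighted", "primary"),
                                   beam = "") {
  axis <- match.arg(axis)
  stopifnot(is.data.frame(measurements),
            all(c("depth_mm", "delta_rl") %in% names(measurements)))
  i <- grid_bin(reference$grid, measurements$depth_mm)
  dose <- reference$dose[i] * reference$entrance_dose
  if (any(dose <= 0)) {
    stop("reference dose non-positive at a measured depth (alignment)",
         call. = FALSE)
  }
  ip <- grid_bin(profile$grid, measurements$depth_mm)
  let <- if (axis == "weighted") {
    fluence_weighted_let(profile, measurements$depth_mm)
  } else {
    profile$let_f[ip, 1] / 10
  }
  mu <- relative_efficiency(measurements$delta_rl, dose, cal)
  structure(data.frame(beam = beam, depth_mm = measurements$depth_mm,
                       let_kev_um = let, mu = mu),
            class = c("efficiency_curve", "data.frame"))
}

#' Combine efficiency curves from several beams
#' @param ... `efficiency_curve` objects.
#' @return A combined `efficiency_curve`.
#' @export
combine_efficiency_curves <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  structure(out, class = c("efficiency_curve", "data.frame"))
}

#' Fit the exponential efficiency model
#'
#' Least-squares fit of a three-parameter decay-to-plateau model
#' `mu(L) = y0 + A * exp(-L / tau)` to an efficiency curve (the high-LET
#' flattening motivates the plateau `y0`). Bounded multi-start
#' Gauss-Newton (`nls`, port algorithm) with `y0 >= 0`, `tau > 0`.
#'
#' @param curve An `efficiency_curve` (or data frame with `let_kev_um`,
#'   `mu`), at least 4 points over a nondegenerate LET range.
#' @return A list with `y0`, `A`, `tau`, `r_squared`, `fit` (the `nls`
#'   object).
#' @export
fit_mu_exponential <- function(curve) {
  df <- as.data.frame(curve)[, c("let_kev_um", "mu")]
  df <- df[stats::complete.cases(df), ]
  if (nrow(df) < 4 || diff(range(df$let_kev_um)) <= 0) {
    stop("need >= 4 points spanning a nondegenerate LET range",
         call. = FALSE)
  }
  Lspan <- diff(range(df$let_kev_um))
  y0s <- max(min(df$mu), 1e-6)
  starts <- list(
    list(y0 = 0.8 * y0s, A = max(df$mu) - 0.8 * y0s, tau = Lspan / 3),
    list(y0 = 0.5 * y0s, A = max(df$mu) - 0.5 * y0s, tau = Lspan / 10),
    list(y0 = 1e-3, A = max(df$mu), tau = Lspan),
    list(y0 = 0.9 * y0s, A = max(df$mu), tau = Lspan / 30),
    list(y0 = 0.5 * y0s, A = 2 * max(df$mu), tau = Lspan / 100)
  )
  best <- NULL
  diags <- character()
  for (st in starts) {
    fit <- tryCatch(
      stats::nls(mu ~ y0 + A * exp(-let_kev_um / tau), data = df,
                 start = st, algorithm = "port",
                 lower = c(y0 = 0, A = 1e-12, tau = 1e-9),
                 control = stats::nls.control(maxiter = 200,
                                              warnOnly = FALSE)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      diags <- c(diags, conditionMessage(fit))
      next
    }
    if (is.null(best) || deviance(fit) < deviance(best)) best <- fit
  }
  if (is.null(best)) {
    stop("exponential efficiency fit failed to converge from any start:\n",
         paste(unique(diags), collapse = "\n"), call. = FALSE)
  }
  co <- stats::coef(best)
  ss_res <- sum(stats::resid(best)^2)
  ss_tot <- sum((df$mu - mean(df$mu))^2)
  list(y0 = unname(co["y0"]), A = unname(co["A"]), tau = unname(co["tau"]),
       r_squared = 1 - ss_res / ss_tot, fit = best)
}

#' Write an efficiency curve and its fit
#'
#' CSV with columns `beam`, `depth_mm`, `let_kev_um`, `mu`; fit parameters
#' in a JSON sidecar (`<path>.fit.json`) when supplied.
#'
#' @param curve An `efficiency_curve`.
#' @param path CSV path.
#' @param fit Optional result of [fit_mu_exponential()].
#' @return `path`, invisibly.
#' @export
write_efficiency_csv <- function(curve, path, fit = NULL) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE,
                   quote = FALSE)
  if (!is.null(fit)) {
    jsonlite::write_json(fit[c("y0", "A", "tau", "r_squared")],
                         paste0(path, ".fit.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
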