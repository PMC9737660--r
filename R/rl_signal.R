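# Reduction of RL time series, dose-response slopes, linearity indices and
# linearity correction factors (LCF).

#' RL time-series trace
#'
#' A detector count trace sampled at 200 Hz with an irradiation window and
#' pre/post background segments.
#'
#' @param counts Numeric vector of detector counts per sample (>= 0).
#' @param sample_rate Sampling rate in Hz (default 200).
#' @param window Integer vector `c(first, last)` sample indices of the
#'   irradiation window.
#' @param pre_background,post_background Index ranges `c(first, last)` of
#'   the background segments; must be disjoint from the window.
#' @return An `rl_trace` object.
#' @export
rl_trace <- function(counts, sample_rate = 200, window,
                     pre_background, post_background) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  n <- length(counts)
  segs <- list(window = window, pre = pre_background, post = post_background)
  for (nm in names(segs)) {
    s <- segs[[nm]]
    if (length(s) != 2 || s[1] < 1 || s[2] > n || s[1] > s[2]) {
      stop(nm, " segment out of bounds", call. = FALSE)
    }
  }
  if (max(pre_background[1], window[1]) <= min(pre_background[2], window[2]) ||
      max(post_background[1], window[1]) <= min(post_background[2], window[2])) {
    stop("background segments must be disjoint from the window", call. = FALSE)
  }
  structure(list(counts = counts, sample_rate = sample_rate,
                 window = as.integer(window),
                 pre_background = as.integer(pre_background),
                 post_background = as.integer(post_background)),
            class = "rl_trace")
}

#' Integrate an RL trace to a background-corrected signal
#'
#' The integrated RL signal is the sum of counts over the irradiation
#' window minus the window length times the averaged background, where the
#' background is the mean of `n_background` samples taken from each of the
#' pre- and post-irradiation segments (default 25 + 25 = 50 samples).
#' The result may be negative for noise-only traces.
#'
#' @param trace An [rl_trace()].
#' @param n_background Samples used from each background segment.
#' @return Integrated signal `delta_rl` in counts.
#' @export
integrate_trace <- function(trace, n_background = 25) {
  pre <- trace$pre_background
  post <- trace$post_background
  if (diff(pre) + 1 < n_background || diff(post) + 1 < n_background) {
    stop("background segment shorter than ", n_background, " samples",
         call. = FALSE)
  }
  # last n pre-irradiation samples, first n post-irradiation samples
  pre_i <- (pre[2] - n_background + 1):pre[2]
  post_i <- post[1]:(post[1] + n_background - 1)
  bkg <- mean(trace$counts[c(pre_i, post_i)])
  w <- trace$window
  sum(trace$counts[w[1]:w[2]]) - (w[2] - w[1] + 1) * bkg
}

#' Dose-response point set
#'
#' @param dose_gy Doses in Gy (> 0).
#' @param delta_rl Integrated RL signals in counts.
#' @param probe,beam Labels.
#' @param d0 Calibration dose for the linearity index, Gy (default 1).
#' @return A `dose_response_set` object.
#' @export
dose_response_set <- function(dose_gy, delta_rl, probe = "", beam = "",
                              d0 = 1) {
  stopifnot(length(dose_gy) == length(delta_rl))
  if (any(dose_gy <= 0)) stop("doses must be positive", call. = FALSE)
  if (length(dose_gy) < 2) {
    stop("need at least 2 points for slope fitting", call. = FALSE)
  }
  structure(list(dose_gy = dose_gy, delta_rl = delta_rl, probe = probe,
                 beam = beam, d0 = d0),
            class = "dose_response_set")
}

#' Through-origin dose-response slope
#'
#' Least-squares slope of signal against dose with the line constrained
#' through the origin (zero dose gives zero signal):
#' `s = sum(D * y) / sum(D^2)`, with its standard error.
#'
#' @param set A [dose_response_set()].
#' @return A list with `slope` (counts/Gy), `se`, and `n`.
#' @export
fit_dose_response <- function(set) {
  D <- set$dose_gy
  y <- set$delta_rl
  sd2 <- sum(D^2)
  if (sd2 == 0) stop("degenerate dose set (all doses zero)", call. = FALSE)
  s <- sum(D * y) / sd2
  n <- length(D)
  se <- if (n > 1) sqrt(sum((y - s * D)^2) / (n - 1) / sd2) else NA_real_
  list(slope = s, se = se, n = n)
}

#' Linearity index per dose point
#'
#' Departure of the response from linearity, normalized at the calibration
#' dose D0: `index_i = (y_i / D_i) / (y_0 / D_0)`. The index is exactly 1
#' at D0. If D0 is not a measured dose, the signal there is obtained by
#' linear interpolation between the bracketing doses.
#'
#' @param set A [dose_response_set()].
#' @return A data frame with `dose_gy` and `index`.
#' @export
linearity_index <- function(set) {
  D <- set$dose_gy
  y <- set$delta_rl
  d0 <- set$d0
  o <- order(D)
  if (d0 < min(D) || d0 > max(D)) {
    stop("calibration dose D0 = ", d0,
         " Gy outside the measured dose range", call. = FALSE)
  }
  y0 <- stats::approx(D[o], y[o], xout = d0, ties = "ordered")$y
  sens0 <- y0 / d0
  data.frame(dose_gy = D, index = (y / D) / sens0)
}

#' Linearity correction factor (LCF)
#'
#' A degree 3 or 4 polynomial in dose fitted to the linearity index, with
#' a validity dose range on which it evaluates within (0, 10].
#'
#' @param coefficients Polynomial coefficients in ascending order
#'   (constant first), length `degree + 1`.
#' @param probe,beam Labels.
#' @param validity_range Dose range `c(lo, hi)` in Gy.
#' @return An `lcf` object.
#' @export
linearity_correction <- function(coefficients, probe = "", beam = "",
                                 validity_range) {
  degree <- length(coefficients) - 1L
  if (!degree %in% c(3L, 4L)) {
    stop("LCF degree must be 3 or 4", call. = FALSE)
  }
  x <- structure(list(coefficients = as.numeric(coefficients),
                      degree = degree, probe = probe, beam = beam,
                      validity_range = validity_range),
                 class = "lcf")
  v <- lcf_eval(x, seq(validity_range[1], validity_range[2], length.out = 64))
  if (any(v <= 0 | v > 10)) {
    stop("LCF leaves (0, 10] inside its validity range", call. = FALSE)
  }
  x
}

#' Evaluate an LCF polynomial
#'
#' @param lcf An `lcf` object.
#' @param dose Dose in Gy (no range check; see [apply_lcf()]).
#' @return LCF values.
#' @export
lcf_eval <- function(lcf, dose) {
  drop(outer(dose, 0:lcf$degree, `^`) %*% lcf$coefficients)
}

#' Fit a linearity correction factor
#'
#' Least-squares polynomial (degree 3 or 4) of the linearity index as a
#' function of dose. The validity range is the largest contiguous dose
#' interval, inside the fitted dose range, on which the polynomial stays
#' within (0, 10].
#'
#' @param dose_gy Doses in Gy.
#' @param index Linearity indices at those doses.
#' @param degree Polynomial degree, 3 or 4.
#' @param probe,beam Labels.
#' @return An `lcf` object.
#' @export
fit_lcf <- function(dose_gy, index, degree = 3, probe = "", beam = "") {
  degree <- as.integer(degree)
  if (!degree %in% c(3L, 4L)) stop("degree must be 3 or 4", call. = FALSE)
  if (length(unique(dose_gy)) < degree + 1) {
    stop("need at least ", degree + 1, " distinct doses", call. = FALSE)
  }
  fit <- stats::lm(index ~ stats::poly(dose_gy, degree, raw = TRUE))
  co <- unname(stats::coef(fit))
  rng <- .lcf_validity(co, range(dose_gy))
  linearity_correction(co, probe = probe, beam = beam, validity_range = rng)
}

# largest contiguous subinterval of dose_range where the polynomial is in
# (0, 10]; prefers the interval containing the most calibration mass
.lcf_validity <- function(co, dose_range) {
  x <- seq(dose_range[1], dose_range[2], length.out = 512)
  v <- drop(outer(x, seq_along(co) - 1, `^`) %*% co)
  ok <- v > 0 & v <= 10
  if (!any(ok)) stop("fitted LCF nowhere within (0, 10]", call. = FALSE)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  c(x[starts[best]], x[ends[best]])
}

#' Apply a linearity correction
#'
#' Divides the value by the LCF evaluated at the dose, removing the
#' supralinear over-response so that a corrected linearity index is 1.
#' Extrapolation outside the validity range is refused.
#'
#' @param value Value to correct (Gy or counts).
#' @param lcf An `lcf` object.
#' @param dose Dose in Gy at which the value was acquired.
#' @return Corrected value.
#' @export
apply_lcf <- function(value, lcf, dose) {
  rng <- lcf$validity_range
  if (any(dose < rng[1] - 1e-9 | dose > rng[2] + 1e-9)) {
    stop("dose outside LCF validity range [",
         format(rng[1], digits = 4), ", ", format(rng[2], digits = 4),
         "] Gy; extrapolation refused", call. = FALSE)
  }
  value / lcf_eval(lcf, dose)
}

#' Published linearity-correction polynomials
#'
#' The six LCF polynomials for the '38 um' and 'Single Crystal' probes in
#' the helium and carbon beams, as printed (dose D in Gy, coefficients to
#' 2 decimals; the helium 'Single Crystal' correction is the only
#' degree-4 one). The helium polynomials misbehave for D in Gy over much
#' of the measured range; validity ranges are clamped to where the
#' polynomial stays within (0, 10], and extrapolation is refused rather
#' than guessing an unstated normalization.
#'
#' @return Named list of `lcf` objects.
#' @export
lcf_presets <- function() {
  specs <- list(
    list("single_crystal", "He150", c(3.53, -13.66, 27.46, -24.38, 8.11),
         c(0.3, 10)),
    list("grain_38um", "He150", c(0.66, -1.36, -1.83, 0.82), c(0.3, 10)),
    list("single_crystal", "C400", c(0.99, -0.03, 0.12, -0.03), c(0.1, 60)),
    list("grain_38um", "C400", c(1.01, -0.07, 0.09, -0.02), c(0.1, 60)),
    list("single_crystal", "C290", c(0.99, -0.02, 0.18, -0.06), c(0.5, 60)),
    list("grain_38um", "C290", c(1.03, -0.17, 0.19, -0.05), c(0.5, 60))
  )
  out <- lapply(specs, function(s) {
    rng <- .lcf_validity(s[[3]], s[[4]])
    linearity_correction(s[[3]], probe = s[[1]], beam = s[[2]],
                         validity_range = rng)
  })
  names(out) <- vapply(out, function(l) paste(l$probe, l$beam, sep = "."), "")
  out
}

#' Write / read an RL trace as CSV with a YAML sidecar
#'
#' The trace itself is a two-column CSV (`time_s`, `counts`); the
#' irradiation window and background segment indices go to a YAML sidecar
#' at `<path>.yaml`.
#'
#' @param trace An `rl_trace`.
#' @param path CSV path.
#' @return `path`, invisibly (writer); an `rl_trace` (reader).
#' @export
write_trace_csv <- function(trace, path) {
  n <- length(trace$counts)
  utils::write.csv(data.frame(time_s = (seq_len(n) - 1) / trace$sample_rate,
                              counts = trace$counts),
                   path, row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(sample_rate = trace$sample_rate,
                        window = trace$window,
                        pre_background = trace$pre_background,
                        post_background = trace$post_background),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  rl_trace(df$counts, sample_rate = meta$sample_rate,
           window = unlist(meta$window),
           pre_background = unlist(meta$pre_background),
           post_background = unlist(meta$post_background))
}

#' Write / read a dose-response set as CSV
#'
#' Columns `dose_gy`, `delta_rl`, `probe`, `beam`.
#'
#' @param set A `dose_response_set`.
#' @param path File path.
#' @return `path`, invisibly (writer); a `dose_response_set` (reader).
#' @export
write_dose_response_csv <- function(set, path) {
  utils::write.csv(data.frame(dose_gy = set$dose_gy, delta_rl = set$delta_rl,
                              probe = set$probe, beam = set$beam),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dose_response_csv
#' @export
read_dose_response_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  dose_response_set(df$dose_gy, df$delta_rl, probe = df$probe[1],
                    beam = df$beam[1])
}
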