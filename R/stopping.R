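# Electronic stopping power of liquid water and CSDA range-energy relations.
#
# Relativistic Bethe formula without shell or density-effect corrections,
# liquid water at rho = 1 g/cm^3 with mean excitation energy I = 75 eV.
# Valid down to 1 MeV/u; the residual pathlength of a 1 MeV proton
# (~0.024 mm water) is carried as a constant tail.

.K_BETHE <- 0.307075        # 4 pi N_A r_e^2 m_e c^2, MeV cm^2 / mol
.ME <- 0.51099895           # electron rest mass, MeV
.ZA_WATER <- 10 / 18.0153   # Z/A of water
.I_WATER <- 75e-6           # mean excitation energy, MeV
.E_CUTOFF <- 1              # validity floor, MeV/u
.R_TAIL_MM <- 0.024         # residual range below cutoff, mm water

# proton mass stopping power of water, MeV/cm (rho = 1), vectorized
.bethe_proton <- function(energy_mev) {
  gamma <- 1 + energy_mev / .MASS_PER_U
  beta2 <- 1 - 1 / gamma^2
  .K_BETHE * .ZA_WATER / beta2 *
    (log(2 * .ME * beta2 * gamma^2 / .I_WATER) - beta2)
}

#' Electronic stopping power of liquid water
#'
#' Unrestricted electronic stopping power from the relativistic Bethe
#' formula (no shell or density-effect corrections, I = 75 eV,
#' rho = 1 g/cm^3). Ions scale as Z^2 times the proton value at equal
#' energy per nucleon (equal velocity), with no effective-charge
#' correction.
#'
#' @param energy_per_u Kinetic energy in MeV/u; vectorized. Must be at
#'   least 1 MeV/u, the validity floor of the formula.
#' @param species Species label or [particle_species()] (default proton).
#' @return Stopping power in MeV/cm.
#' @export
#' @examples
#' stopping_power(154.5)            # ~5.33 MeV/cm
#' stopping_power(273.8, "C-12")    # ~133 MeV/cm
stopping_power <- function(energy_per_u, species = "H-1") {
  if (is.character(species)) species <- particle_species(species)
  if (!is.numeric(energy_per_u) || any(!is.finite(energy_per_u))) {
    stop("energy_per_u must be finite numeric", call. = FALSE)
  }
  if (any(energy_per_u < .E_CUTOFF)) {
    stop("energy_per_u below the ", .E_CUTOFF,
         " MeV/u validity floor of the Bethe formula", call. = FALSE)
  }
  species$Z^2 * .bethe_proton(energy_per_u)
}

# Lazily built proton range-energy spline pair on [1, 600] MeV:
#   R_p(E) in mm water, and its inverse E(R).
.range_cache <- new.env(parent = emptyenv())

.range_tables <- function() {
  if (is.null(.range_cache$Rfun)) {
    E <- exp(seq(log(.E_CUTOFF), log(600), length.out = 4000))
    invS <- 1 / .bethe_proton(E)
    R <- c(0, cumsum(diff(E) * (invS[-1] + invS[-length(E)]) / 2)) * 10 +
      .R_TAIL_MM
    .range_cache$Rfun <- stats::splinefun(E, R, method = "hyman")
    .range_cache$Efun <- stats::splinefun(R, E, method = "hyman")
    .range_cache$Rmin <- R[1]
    .range_cache$Rmax <- R[length(R)]
  }
  .range_cache
}

#' CSDA range in water
#'
#' Continuous-slowing-down range: the integral of reciprocal stopping power
#' from the beam's actual energy down to the 1 MeV/u cutoff, plus a small
#' constant tail for the residual pathlength below the cutoff. For an ion
#' of mass number A and charge Z the range is (A/Z^2) times the proton
#' range at the same energy per nucleon.
#'
#' @param beam A [beam_spec()], or a species label combined with
#'   `energy_per_u`.
#' @param energy_per_u Energy in MeV/u when `beam` is a species label.
#' @return Range in mm water.
#' @export
#' @examples
#' csda_range(beam_presets("He150"))  # ~144 mm
csda_range <- function(beam, energy_per_u = NULL) {
  if (inherits(beam, "beam_spec")) {
    sp <- beam$species
    E <- beam$actual_energy
  } else {
    sp <- if (is.character(beam)) particle_species(beam) else beam
    E <- energy_per_u
  }
  if (is.null(E)) stop("energy_per_u required", call. = FALSE)
  if (any(E < .E_CUTOFF)) {
    stop("energy below the ", .E_CUTOFF, " MeV/u validity floor",
         call. = FALSE)
  }
  tb <- .range_tables()
  (sp$A / sp$Z^2) * tb$Rfun(E)
}

#' Range-energy map along a depth grid
#'
#' Inverts the CSDA range to give the residual energy per nucleon of the
#' primary at each depth. Monotone decreasing; equals the actual energy at
#' depth 0 and reaches the 1 MeV/u cutoff one residual-tail short of the
#' full range.
#'
#' @param beam A [beam_spec()].
#' @param grid A [depth_grid()]; defaults to a grid covering 1.1x range.
#' @return A list with `range_mm` (CSDA range), `depth_mm`, and
#'   `energy_per_u` (residual energy; `NA` beyond end of range).
#' @export
range_energy <- function(beam, grid = grid_for_beam(beam)) {
  sp <- beam$species
  tb <- .range_tables()
  AZ2 <- sp$A / sp$Z^2
  R <- csda_range(beam)
  d <- grid_depths(grid)
  res_p <- (R - d) / AZ2                   # proton-equivalent residual range
  alive <- res_p > tb$Rmin
  E <- rep(NA_real_, length(d))
  E[alive] <- pmax(tb$Efun(res_p[alive]), .E_CUTOFF)
  list(range_mm = R, depth_mm = d, energy_per_u = E)
}

#' Residual energy at a single depth
#'
#' @param beam A [beam_spec()].
#' @param depth_mm Depth in mm water.
#' @return Residual energy in MeV/u (`NA` beyond end of range).
#' @export
residual_energy <- function(beam, depth_mm) {
  sp <- beam$species
  tb <- .range_tables()
  AZ2 <- sp$A / sp$Z^2
  R <- csda_range(beam)
  res_p <- (R - depth_mm) / AZ2
  out <- rep(NA_real_, length(depth_mm))
  ok <- res_p > tb$Rmin
  out[ok] <- pmax(tb$Efun(res_p[ok]), .E_CUTOFF)
  out
}
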