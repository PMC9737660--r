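# Particle species registry, beam specifications and the water depth grid.

.SPECIES <- data.frame(
  name = c("H-1", "He-4", "Li-7", "Be-9", "B-10", "C-12", "N-14", "O-16"),
  Z    = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L),
  A    = c(1L, 4L, 7L, 9L, 10L, 12L, 14L, 16L),
  stringsAsFactors = FALSE
)

#' Particle species registry
#'
#' The eight charged species tracked by the beam model: the three possible
#' primaries (H-1, He-4, C-12) and the nuclear fragments scored alongside
#' them (Li-7, Be-9, B-10, N-14, O-16 plus H-1 and He-4 as fragments of
#' heavier primaries).
#'
#' @return A data frame with columns `name`, `Z` (charge number), `A`
#'   (mass number) and `mass_per_nucleon` (MeV/u).
#' @export
#' @examples
#' species_registry()
species_registry <- function() {
  out <- .SPECIES
  out$mass_per_nucleon <- .MASS_PER_U
  out
}

# Velocity convention: kinetic energy per nucleon is converted to beta*gamma
# using the proton rest mass for every species, so that ions at equal E/u
# share beta exactly and stopping power obeys exact Z^2 scaling (no
# effective-charge correction).
.MASS_PER_U <- 938.27208816 # MeV

#' Look up a particle species
#'
#' @param name Species label, e.g. `"H-1"`, `"He-4"`, `"C-12"`.
#' @return A list with fields `name`, `Z`, `A`, `mass_per_nucleon`.
#' @export
particle_species <- function(name) {
  i <- match(name, .SPECIES$name)
  if (is.na(i)) {
    stop("unknown species '", name, "'; registry: ",
         paste(.SPECIES$name, collapse = ", "), call. = FALSE)
  }
  structure(list(name = .SPECIES$name[i], Z = .SPECIES$Z[i], A = .SPECIES$A[i],
                 mass_per_nucleon = .MASS_PER_U),
            class = "particle_species")
}

#' @export
print.particle_species <- function(x, ...) {
  cat(sprintf("<particle_species> %s (Z=%d, A=%d)\n", x$name, x$Z, x$A))
  invisible(x)
}

#' Beam specification
#'
#' A mono-energetic therapy beam. `nominal_energy` is the accelerator label;
#' `actual_energy` is the energy that reproduces the measured reference
#' Bragg curve and is the one used in all calculations.
#'
#' @param species A species label or [particle_species()] object.
#' @param nominal_energy Nominal energy in MeV/u.
#' @param actual_energy Actual energy in MeV/u (defaults to nominal).
#' @param entrance_dose Entrance dose to water in Gy.
#' @param field_label Free-text label, e.g. `"C400"`.
#' @return A `beam_spec` object.
#' @export
beam_spec <- function(species, nominal_energy, actual_energy = nominal_energy,
                      entrance_dose = 1, field_label = "") {
  if (is.character(species)) species <- particle_species(species)
  stopifnot(inherits(species, "particle_species"))
  if (!is.numeric(actual_energy) || actual_energy <= 0) {
    stop("actual_energy must be positive", call. = FALSE)
  }
  if (actual_energy > nominal_energy + 1e-9) {
    stop("actual_energy must not exceed nominal_energy", call. = FALSE)
  }
  structure(list(species = species, nominal_energy = nominal_energy,
                 actual_energy = actual_energy, entrance_dose = entrance_dose,
                 field_label = field_label),
            class = "beam_spec")
}

#' The five reference beams
#'
#' Named presets for the five measurement-campaign beams: 160 and 230 MeV
#' protons, 150 MeV/u helium, 290 and 400 MeV/u carbon, with the actual
#' energies inferred from the measured reference Bragg curves.
#'
#' @param name Optional preset name (`"H160"`, `"H230"`, `"He150"`,
#'   `"C290"`, `"C400"`); if omitted, all five are returned as a list.
#' @return A `beam_spec`, or a named list of all five.
#' @export
#' @examples
#' beam_presets("He150")
beam_presets <- function(name = NULL) {
  all <- list(
    H160  = beam_spec("H-1", 160, 154.5, field_label = "H160"),
    H230  = beam_spec("H-1", 230, 226.5, field_label = "H230"),
    He150 = beam_spec("He-4", 150, 142.6, field_label = "He150"),
    C290  = beam_spec("C-12", 290, 273.8, field_label = "C290"),
    C400  = beam_spec("C-12", 400, 383.2, field_label = "C400")
  )
  if (is.null(name)) return(all)
  if (!name %in% names(all)) {
    stop("unknown beam preset '", name, "'", call. = FALSE)
  }
  all[[name]]
}

#' Depth grid in water
#'
#' Half-open depth bins `[d, d + bin_width)` in water, entrance = first bin.
#' Depths are reported at bin centres.
#'
#' @param n_bins Number of bins.
#' @param bin_width Bin width in mm water (default 0.1, the scoring
#'   resolution of the transport surrogate).
#' @return A `depth_grid` object.
#' @export
depth_grid <- function(n_bins, bin_width = 0.1) {
  stopifnot(is.numeric(bin_width), bin_width > 0, n_bins >= 1)
  structure(list(bin_width = bin_width, n_bins = as.integer(n_bins)),
            class = "depth_grid")
}

#' Grid covering a beam's range
#'
#' Convenience constructor: a 0.1 mm grid from the surface to `cover` times
#' the CSDA range of the beam.
#'
#' @param beam A [beam_spec()].
#' @param bin_width Bin width, mm.
#' @param cover Coverage factor relative to the CSDA range (default 1.1).
#' @return A `depth_grid`.
#' @export
grid_for_beam <- function(beam, bin_width = 0.1, cover = 1.1) {
  R <- csda_range(beam)
  depth_grid(ceiling(cover * R / bin_width), bin_width)
}

#' Bin-centre depths of a grid
#' @param grid A `depth_grid`.
#' @return Numeric vector of depths in mm.
#' @export
grid_depths <- function(grid) {
  (seq_len(grid$n_bins) - 0.5) * grid$bin_width
}

#' Index of the bin containing a depth
#' @param grid A `depth_grid`.
#' @param depth Depth in mm.
#' @return Integer bin index.
#' @export
grid_bin <- function(grid, depth) {
  i <- floor(depth / grid$bin_width) + 1L
  if (any(depth < 0) || any(i > grid$n_bins)) {
    stop("depth outside grid [0, ", grid$n_bins * grid$bin_width, ") mm",
         call. = FALSE)
  }
  pmin(as.integer(i), grid$n_bins)
}

#' @export
print.depth_grid <- function(x, ...) {
  cat(sprintf("<depth_grid> %d bins x %.3g mm = [0, %.4g) mm water\n",
              x$n_bins, x$bin_width, x$n_bins * x$bin_width))
  invisible(x)
}
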