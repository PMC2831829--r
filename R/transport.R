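#' Uniform 1-D spatial grid
#'
#' The modelled cell is a 1-D segment of length `length_um` (default
#' 30 um, the average HeLa cell length) discretised into `n_nodes`
#' equally spaced nodes spanning `[0, L]` (default 300, i.e. 0.1 um
#' resolution).
#'
#' @param length_um Domain length in um (> 0).
#' @param n_nodes Number of nodes (>= 3).
#' @return An object of class `SpatialGrid` with fields `length_um`,
#'   `n_nodes`, `dx` and node coordinates `x`.
#' @export
spatial_grid <- function(length_um = 30, n_nodes = 300) {
  if (!is.numeric(length_um) || length_um <= 0)
    stop("length_um must be > 0", call. = FALSE)
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 3L)
    stop("n_nodes must be >= 3", call. = FALSE)
  dx <- length_um / (n_nodes - 1L)
  structure(list(length_um = length_um, n_nodes = n_nodes, dx = dx,
                 x = seq(0, length_um, length.out = n_nodes)),
            class = "SpatialGrid")
}

#' @export
print.SpatialGrid <- function(x, ...) {
  cat("SpatialGrid: L = ", x$length_um, " um, ", x$n_nodes,
      " nodes, dx = ", signif(x$dx, 4), " um\n", sep = "")
  invisible(x)
}

#' Stokes-Einstein diffusivity from molecular mass
#'
#' Diffusion coefficients are assigned from molecular mass by
#' Stokes-Einstein scaling relative to GFP: the hydrodynamic radius of a
#' globular protein grows as the cube root of its mass, so
#' `D = D_ref * (M_ref / M)^(1/3)` with the cytosolic GFP reference
#' `D_ref = 24 um^2/s` at `M_ref = 27 kDa`.
#'
#' @param mass_kDa Molecular mass(es) in kDa (> 0).
#' @param reference_D Reference diffusivity in um^2/s.
#' @param reference_mass Reference mass in kDa.
#' @return Diffusivity in um^2/s, strictly decreasing in mass.
#' @export
stokes_einstein_diffusivity <- function(mass_kDa, reference_D = 24,
                                        reference_mass = 27) {
  if (!is.numeric(mass_kDa) || any(is.na(mass_kDa)) || any(mass_kDa <= 0))
    stop("mass_kDa must be positive", call. = FALSE)
  reference_D * (reference_mass / mass_kDa)^(1 / 3)
}

#' Assign Stokes-Einstein diffusivities to every species
#'
#' Adds a `diffusivity_um2_s` column to the species table; species flagged
#' `diffusible = FALSE` get zero.
#'
#' @param network A `ReactionNetwork`.
#' @inheritParams stokes_einstein_diffusivity
#' @return The network with diffusivities assigned.
#' @export
assign_diffusivities <- function(network, reference_D = 24, reference_mass = 27) {
  stopifnot(inherits(network, "ReactionNetwork"))
  D <- stokes_einstein_diffusivity(network$species$mass_kDa,
                                   reference_D, reference_mass)
  network$species$diffusivity_um2_s <- ifelse(network$species$diffusible, D, 0)
  network
}

#' Travelling-wave MOMP input
#'
#' One released factor (apoptosome-formation trigger or Smac): local
#' delivery follows a first-order exponential saturation
#' `Cmax * (1 - exp(-k * (t - t_onset(x))))`, where the onset time
#' travels across the cell with velocity `wave_velocity_um_s` from
#' `origin_um`. `onset_smoothing_s` mollifies the onset switch with a
#' softplus ramp of that width so the solver right-hand side stays
#' continuously differentiable; 0 gives the sharp switch.
#'
#' @param target_species Species receiving the input.
#' @param amplitude_uM Total deliverable amount Cmax (uM, >= 0).
#' @param saturation_rate_per_s Local saturation rate k (1/s, > 0).
#' @param wave_velocity_um_s End-to-end MOMP wave velocity (um/s, > 0;
#'   `Inf` for synchronous onset).
#' @param origin_um Point of origin x0 (um).
#' @param onset_smoothing_s Softplus ramp width tau (s, >= 0).
#' @return An object of class `WaveInput`.
#' @export
wave_input <- function(target_species, amplitude_uM, saturation_rate_per_s,
                       wave_velocity_um_s = 0.1, origin_um = 0,
                       onset_smoothing_s = 1) {
  if (!is.numeric(amplitude_uM) || amplitude_uM < 0)
    stop("amplitude_uM must be >= 0", call. = FALSE)
  if (!is.numeric(saturation_rate_per_s) || saturation_rate_per_s <= 0)
    stop("saturation_rate_per_s must be > 0", call. = FALSE)
  if (!is.numeric(wave_velocity_um_s) || wave_velocity_um_s <= 0)
    stop("wave_velocity_um_s must be > 0", call. = FALSE)
  if (!is.numeric(onset_smoothing_s) || onset_smoothing_s < 0)
    stop("onset_smoothing_s must be >= 0", call. = FALSE)
  structure(list(target_species = target_species,
                 amplitude_uM = as.numeric(amplitude_uM),
                 saturation_rate_per_s = as.numeric(saturation_rate_per_s),
                 wave_velocity_um_s = as.numeric(wave_velocity_um_s),
                 origin_um = as.numeric(origin_um),
                 onset_smoothing_s = as.numeric(onset_smoothing_s)),
            class = "WaveInput")
}

#' Default MOMP inputs of a network
#'
#' Builds the [wave_input()] list from the input pseudo-reactions declared
#' in the model file (apoptosome-formation trigger and Smac release).
#'
#' @param network A `ReactionNetwork` with an `inputs` section.
#' @param wave_velocity_um_s,origin_um,onset_smoothing_s Wave geometry
#'   shared by all inputs.
#' @return List of `WaveInput` objects.
#' @export
default_wave_inputs <- function(network, wave_velocity_um_s = 0.1,
                                origin_um = 0, onset_smoothing_s = 1) {
  stopifnot(inherits(network, "ReactionNetwork"))
  if (!length(network$inputs))
    stop("network declares no inputs", call. = FALSE)
  lapply(network$inputs, function(inp)
    wave_input(inp$target, inp$amplitude_uM, inp$saturation_rate_per_s,
               wave_velocity_um_s, origin_um, onset_smoothing_s))
}

#' MOMP onset time at a position
#'
#' `t_onset(x) = (x - x0) / v_wave`: zero at the point of origin and
#' linear in distance, so a 30 um cell with v = 0.1 um/s has its far end
#' delayed by 300 s (5 min) relative to the near end.
#'
#' @param x Position(s) in um.
#' @param input A `WaveInput`.
#' @param length_um Optional domain length for bounds checking.
#' @return Onset time(s) in s.
#' @export
momp_onset_time <- function(x, input, length_um = NULL) {
  stopifnot(inherits(input, "WaveInput"), is.numeric(x))
  if (any(x < 0) || (!is.null(length_um) && any(x > length_um)))
    stop("x outside the modelled domain", call. = FALSE)
  if (is.infinite(input$wave_velocity_um_s)) return(rep(0, length(x)))
  (x - input$origin_um) / input$wave_velocity_um_s
}

## softplus ramp and its derivative; width tau = 0 is the sharp switch
softplus_ramp <- function(u, tau) {
  if (tau <= 0) return(pmax(u, 0))
  z <- u / tau
  ifelse(z > 30, u, ifelse(z < -30, 0, tau * log1p(exp(z))))
}

#' Cumulative delivered input amount
#'
#' Total amount delivered at position `x` by time `t`: zero before the
#' local onset (exactly so for `onset_smoothing_s = 0`), then saturating
#' to `amplitude_uM` as `1 - exp(-k (t - t_onset))`. Monotone
#' non-decreasing in `t` and bounded by the amplitude.
#'
#' @param x Position in um.
#' @param t Time(s) in s (>= 0).
#' @param input A `WaveInput`.
#' @return Delivered amount(s) in uM.
#' @seealso [wave_input_rate()] for the instantaneous influx used in the
#'   solver right-hand side.
#' @export
wave_input_value <- function(x, t, input) {
  stopifnot(inherits(input, "WaveInput"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  u <- t - momp_onset_time(x, input)
  s <- softplus_ramp(u, input$onset_smoothing_s)
  input$amplitude_uM * (1 - exp(-input$saturation_rate_per_s * s))
}

#' Instantaneous input rate
#'
#' Time derivative of [wave_input_value()]; this is the source term added
#' to the target species in the reaction-diffusion right-hand side.
#'
#' @inheritParams wave_input_value
#' @return Influx rate(s) in uM/s.
#' @export
wave_input_rate <- function(x, t, input) {
  stopifnot(inherits(input, "WaveInput"))
  u <- t - momp_onset_time(x, input)
  k <- input$saturation_rate_per_s
  tau <- input$onset_smoothing_s
  s <- softplus_ramp(u, tau)
  ds <- if (tau <= 0) as.numeric(u > 0) else stats::plogis(u / tau)
  input$amplitude_uM * k * exp(-k * s) * ds
}

#' Discrete diffusion operator with zero-flux boundaries
#'
#' Conservative flux-form second difference: interface fluxes
#' `D (c[i+1] - c[i]) / dx` with zero flux through both boundaries, so the
#' node-summed rate is exactly zero for any field (discrete mass
#' conservation) and the interior is second-order accurate.
#'
#' @param field Per-node concentrations (length `n_nodes`).
#' @param D Diffusivity in um^2/s (>= 0).
#' @param grid A [spatial_grid()].
#' @return Per-node rates of change (uM/s).
#' @export
diffusion_operator <- function(field, D, grid) {
  stopifnot(inherits(grid, "SpatialGrid"))
  if (length(field) != grid$n_nodes)
    stop("field length (", length(field), ") does not match grid (",
         grid$n_nodes, " nodes)", call. = FALSE)
  if (!is.numeric(D) || D < 0) stop("D must be >= 0", call. = FALSE)
  flux <- D * diff(field) / grid$dx
  (c(flux, 0) - c(0, flux)) / grid$dx
}
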