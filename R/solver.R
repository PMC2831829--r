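#' Concentration field container
#'
#' Output of [simulate()]: concentrations `c_n(x, t)` for every species
#' over the grid and saved time points.
#'
#' @param values Numeric array `[species, node, time]` in uM.
#' @param species_names Ordered species identifiers.
#' @param x Node coordinates (um).
#' @param times Saved time points (s), strictly increasing.
#' @return An object of class `ConcentrationField`.
#' @export
concentration_field <- function(values, species_names, x, times) {
  stopifnot(length(dim(values)) == 3L,
            dim(values)[1] == length(species_names),
            dim(values)[2] == length(x),
            dim(values)[3] == length(times))
  if (any(diff(times) <= 0)) stop("time_points must be strictly increasing", call. = FALSE)
  dimnames(values) <- list(species_names, NULL, NULL)
  structure(list(values = values, species_names = species_names,
                 x = as.numeric(x), times = as.numeric(times)),
            class = "ConcentrationField")
}

#' @export
print.ConcentrationField <- function(x, ...) {
  cat("ConcentrationField: ", length(x$species_names), " species x ",
      length(x$x), " nodes x ", length(x$times), " times (t = ",
      min(x$times), "..", max(x$times), " s)\n", sep = "")
  invisible(x)
}

#' Extract one species as a node x time matrix
#'
#' @param field A `ConcentrationField`.
#' @param species Species name.
#' @return Numeric matrix (nodes x times).
#' @export
field_species <- function(field, species) {
  stopifnot(inherits(field, "ConcentrationField"))
  if (!species %in% field$species_names)
    stop("species '", species, "' not in field", call. = FALSE)
  m <- field$values[species, , , drop = TRUE]
  matrix(m, nrow = length(field$x), ncol = length(field$times))
}

#' @export
as.data.frame.ConcentrationField <- function(x, row.names = NULL, optional = FALSE,
                                             species = NULL, ...) {
  sp <- if (is.null(species)) x$species_names else species
  out <- do.call(rbind, lapply(sp, function(s) {
    m <- field_species(x, s)
    data.frame(species = s,
               x = rep(x$x, times = length(x$times)),
               t = rep(x$times, each = length(x$x)),
               value = as.vector(m))
  }))
  rownames(out) <- row.names
  out
}

## workspace sizes for lsodes: sparse pattern couples all species within a
## node plus nearest-neighbour diffusion
lsodes_work <- function(ns, nx) {
  neq <- ns * nx
  nnz <- neq * (ns + 3)
  list(lrw = 20000 + 20 * neq + 6 * nnz, liw = 10000 + neq + 2 * nnz)
}

simulate_core <- function(network, grid, inputs, t_end, save_dt, rtol, atol,
                          diffusivity_scale, no_diffusion, hmax = NULL) {
  sp <- network$species$name
  ns <- length(sp)
  ker <- network_kernel(network)
  if (is.null(network$species$diffusivity_um2_s))
    network <- assign_diffusivities(network)
  D <- network$species$diffusivity_um2_s
  D[!network$species$diffusible] <- 0
  scale <- diffusivity_scale
  if (is.null(scale)) scale <- attr(network, "diffusivity_scale")
  if (is.null(scale)) scale <- 1
  if (!is.numeric(scale) || scale <= 0)
    stop("diffusivity scale must be > 0; use no_diffusion = TRUE for the diffusion-free case",
         call. = FALSE)
  D <- if (no_diffusion) rep(0, ns) else D / scale
  nx <- grid$n_nodes

  in_target <- integer(0); in_cmax <- numeric(0); in_k <- numeric(0)
  t_on <- matrix(0, nrow = nx, ncol = 0)
  tau <- 0
  if (length(inputs)) {
    in_target <- vapply(inputs, function(i) {
      j <- match(i$target_species, sp)
      if (is.na(j)) stop("input targets unknown species '", i$target_species, "'",
                         call. = FALSE)
      j
    }, 0L)
    in_cmax <- vapply(inputs, `[[`, 0, "amplitude_uM")
    in_k <- vapply(inputs, `[[`, 0, "saturation_rate_per_s")
    t_on <- vapply(inputs, function(i) momp_onset_time(grid$x, i, grid$length_um),
                   numeric(nx))
    t_on <- matrix(t_on, nrow = nx)
    tau <- max(vapply(inputs, `[[`, 0, "onset_smoothing_s"))
  }

  y0 <- rep(network$species$initial_uM, each = nx)
  times <- seq(0, t_end, by = save_dt)
  if (times[length(times)] < t_end) times <- c(times, t_end)

  rhs <- function(t, y, p) {
    list(rd_network_rhs(t, y, ker$S, ker$k, ker$i1, ker$e1, ker$i2, ker$capmod,
                        ker$isub, ker$icle, D, grid$dx, nx,
                        in_target, in_cmax, in_k, t_on, tau))
  }
  wk <- lsodes_work(ns, nx)
  args <- list(y = y0, times = times, func = rhs, parms = NULL,
               nspec = ns, dimens = nx, method = "lsodes",
               rtol = rtol, atol = atol, lrw = wk$lrw, liw = wk$liw)
  if (!is.null(hmax)) args$hmax <- hmax
  out <- try(do.call(deSolve::ode.1D, args), silent = TRUE)
  if (inherits(out, "try-error"))
    stop("integration failed: ", attr(out, "condition")$message, call. = FALSE)
  if (nrow(out) < length(times)) {
    treached <- out[nrow(out), 1]
    stop("solver did not converge past t = ", signif(treached, 6),
         " s (of ", t_end, " s); the system may be too stiff for the ",
         "requested tolerances - try larger atol or onset smoothing",
         call. = FALSE)
  }
  if (anyNA(out[, -1]) || any(!is.finite(out[, -1])))
    stop("non-finite values in solution; state dump: range of last row = ",
         paste(signif(range(out[nrow(out), -1], na.rm = TRUE), 4), collapse = " .. "),
         call. = FALSE)

  vals <- aperm(array(t(out[, -1, drop = FALSE]), dim = c(nx, ns, nrow(out))),
                c(2, 1, 3))
  concentration_field(vals, sp, grid$x, out[, 1])
}

#' Simulate the reaction-diffusion model
#'
#' Integrates the method-of-lines system
#' `dc_n/dt = D_n d2c_n/dx2 + R_n(c) + input_n(x, t)` with zero-flux
#' boundaries, using a stiff sparse-Jacobian BDF integrator
#' (`deSolve::ode.1D` with `lsodes`; the right-hand side is compiled).
#' Immobile species (`diffusible = FALSE`) get `D = 0`.
#'
#' @param network A `ReactionNetwork` (diffusivities are assigned by
#'   Stokes-Einstein scaling if not present).
#' @param grid A [spatial_grid()].
#' @param inputs List of [wave_input()]s (default: the network's declared
#'   MOMP inputs).
#' @param t_end End time (s).
#' @param save_dt Output save interval (s); delay metrics interpolate
#'   between saves.
#' @param rtol,atol Relative / absolute integration tolerances.
#' @param diffusivity_scale Fold-reduction applied to every diffusivity
#'   (a "100-fold reduction" is `diffusivity_scale = 100`); default the
#'   value recorded on the network by [apply_variant()], else 1.
#' @param no_diffusion If `TRUE`, all diffusivities are set to zero (the
#'   explicit diffusion-free case).
#' @return A [concentration_field()].
#' @export
simulate <- function(network, grid = spatial_grid(),
                     inputs = default_wave_inputs(network),
                     t_end = 3600, save_dt = 1, rtol = 1e-6, atol = 1e-9,
                     diffusivity_scale = NULL, no_diffusion = FALSE) {
  stopifnot(inherits(network, "ReactionNetwork"), inherits(grid, "SpatialGrid"),
            is.numeric(t_end), t_end > 0)
  simulate_core(network, grid, inputs, t_end, save_dt, rtol, atol,
                diffusivity_scale, no_diffusion)
}

#' Simulate the local (diffusion-free, single-point) ODE model
#'
#' Integrates the reaction + input system at a single position: the
#' classical whole-cell ODE model of apoptosis execution. Serves as the
#' no-diffusion oracle for the spatial solver (a spatial run with all
#' `D = 0` equals this solution time-shifted by the local onset time).
#'
#' @inheritParams simulate
#' @param x Position at which the inputs are evaluated (sets the onset
#'   times).
#' @return A [concentration_field()] with a single node.
#' @export
simulate_local_ode <- function(network, inputs = default_wave_inputs(network),
                               x = 0, t_end = 3600, save_dt = 1,
                               rtol = 1e-6, atol = 1e-9) {
  stopifnot(inherits(network, "ReactionNetwork"), t_end > 0)
  sp <- network$species$name
  ns <- length(sp)
  ker <- network_kernel(network)
  in_target <- integer(0); in_cmax <- numeric(0); in_k <- numeric(0)
  t_on <- matrix(0, nrow = 1, ncol = 0); tau <- 0
  if (length(inputs)) {
    in_target <- vapply(inputs, function(i) match(i$target_species, sp), 0L)
    if (anyNA(in_target)) stop("input targets unknown species", call. = FALSE)
    in_cmax <- vapply(inputs, `[[`, 0, "amplitude_uM")
    in_k <- vapply(inputs, `[[`, 0, "saturation_rate_per_s")
    t_on <- matrix(vapply(inputs, function(i) momp_onset_time(x, i), 0), nrow = 1)
    tau <- max(vapply(inputs, `[[`, 0, "onset_smoothing_s"))
  }
  y0 <- network$species$initial_uM
  times <- seq(0, t_end, by = save_dt)
  rhs <- function(t, y, p)
    list(rd_network_rhs(t, y, ker$S, ker$k, ker$i1, ker$e1, ker$i2, ker$capmod,
                        ker$isub, ker$icle, numeric(ns), 1, 1L,
                        in_target, in_cmax, in_k, t_on, tau))
  out <- deSolve::ode(y0, times, rhs, NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (anyNA(out[, -1])) stop("non-finite values in local ODE solution", call. = FALSE)
  vals <- aperm(array(t(out[, -1, drop = FALSE]), dim = c(1, ns, nrow(out))),
                c(2, 1, 3))
  concentration_field(vals, sp, x, out[, 1])
}
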