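## 1-D slab versus radially symmetric 3-D sphere: the error estimate for
## collapsing the cell to one spatial dimension. Both solvers are simple
## finite-volume discretisations of pure diffusion for a single tracer,
## integrated with lsoda; the sphere solver is validated against the
## closed-form eigenfunction series for a constant surface concentration.

#' Cell-centred radial grid for the sphere solver
#'
#' @param radius_um Sphere radius R (> 0).
#' @param n_cells Number of radial shells.
#' @return An object of class `RadialGrid` with shell centres `r` in
#'   (0, R), faces, volumes and spacing `dr`. The centre is handled by
#'   the finite-volume form (zero flux through r = 0), so no division by
#'   zero occurs.
#' @export
radial_grid <- function(radius_um, n_cells = 150) {
  if (!is.numeric(radius_um) || radius_um <= 0) stop("radius_um must be > 0", call. = FALSE)
  n_cells <- as.integer(n_cells)
  dr <- radius_um / n_cells
  faces <- seq(0, radius_um, by = dr)
  structure(list(radius_um = radius_um, n_cells = n_cells, dr = dr,
                 r = faces[-1] - dr / 2, faces = faces,
                 volumes = 4 / 3 * pi * diff(faces^3)),
            class = "RadialGrid")
}

#' Diffusion in a 1-D slab with a boundary input pulse
#'
#' Single tracer diffusing in a slab `[0, L]` (cell-centred grid,
#' zero-flux boundaries). The input is a first-order saturating pulse
#' delivered into the leftmost cell; the total delivered amount
#' equilibrates to a mean concentration `c_eq`.
#'
#' @param D Diffusivity (um^2/s, >= 0).
#' @param L Slab length (um).
#' @param n_cells Spatial cells.
#' @param c_eq Equilibrium (mean) concentration after full delivery (uM).
#' @param pulse_rate_per_s First-order delivery rate of the pulse (1/s);
#'   the default matches the slower (Smac-release-like) MOMP input, the
#'   physiological slow-delivery regime.
#' @param t_end,save_dt Time span and save interval (s).
#' @return A [concentration_field()] with one species `"tracer"` on the
#'   cell-centre coordinates.
#' @export
simulate_slab <- function(D, L = 30, n_cells = 150, c_eq = 1,
                          pulse_rate_per_s = 0.007, t_end = 600, save_dt = 0.5) {
  stopifnot(D >= 0, L > 0, n_cells >= 3)
  dx <- L / n_cells
  xc <- seq(dx / 2, L - dx / 2, by = dx)
  total <- c_eq * L                       # amount per unit cross-section
  rhs <- function(t, y, p) {
    flux <- D * diff(y) / dx
    dy <- (c(flux, 0) - c(0, flux)) / dx
    dy[1] <- dy[1] + total * pulse_rate_per_s * exp(-pulse_rate_per_s * t) / dx
    list(dy)
  }
  out <- deSolve::ode(rep(0, n_cells), seq(0, t_end, by = save_dt), rhs, NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-12)
  vals <- array(t(out[, -1, drop = FALSE]), dim = c(1, n_cells, nrow(out)))
  concentration_field(vals, "tracer", xc, out[, 1])
}

#' Radially symmetric diffusion in a sphere
#'
#' Solves the spherically symmetric diffusion equation (finite-volume
#' radial Laplacian; equivalent to the textbook `2/r` first-derivative
#' form) for a single tracer. Input is either a saturating pulse
#' delivered through the surface shell (`surface = "pulse"`, matching
#' [simulate_slab()]) or a clamped surface concentration
#' (`surface = "fixed"`, the configuration with a closed-form series
#' solution, see [sphere_series_solution()]).
#'
#' @param D Diffusivity (um^2/s, >= 0).
#' @param R Sphere radius (um).
#' @param n_cells Radial shells.
#' @param c_eq Equilibrium concentration after full delivery (uM), for
#'   `surface = "pulse"`.
#' @param pulse_rate_per_s Delivery rate of the pulse (1/s).
#' @param surface `"pulse"` or `"fixed"`.
#' @param c_surface Clamped surface concentration for `surface = "fixed"`.
#' @param t_end,save_dt Time span and save interval (s).
#' @return A [concentration_field()] with species `"tracer"` on shell
#'   centre radii.
#' @export
simulate_sphere_radial <- function(D, R = 30, n_cells = 150, c_eq = 1,
                                   pulse_rate_per_s = 0.007,
                                   surface = c("pulse", "fixed"), c_surface = 1,
                                   t_end = 600, save_dt = 0.5) {
  surface <- match.arg(surface)
  stopifnot(D >= 0, R > 0, n_cells >= 3)
  g <- radial_grid(R, n_cells)
  n <- g$n_cells
  aface <- 4 * pi * g$faces^2             # face areas; zero at the centre
  inner <- aface[2:n]                     # faces between shells
  total <- c_eq * 4 / 3 * pi * R^3
  rhs <- function(t, y, p) {
    flux <- D * inner * diff(y) / g$dr    # outward-positive interior fluxes
    dy <- (c(flux, 0) - c(0, flux)) / g$volumes
    if (surface == "pulse") {
      dy[n] <- dy[n] + total * pulse_rate_per_s * exp(-pulse_rate_per_s * t) / g$volumes[n]
    } else {
      ## clamped concentration half a cell outside the last centre
      dy[n] <- dy[n] + D * aface[n + 1] * (c_surface - y[n]) / (g$dr / 2) / g$volumes[n]
    }
    list(dy)
  }
  out <- deSolve::ode(rep(0, n), seq(0, t_end, by = save_dt), rhs, NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-12)
  vals <- array(t(out[, -1, drop = FALSE]), dim = c(1, n, nrow(out)))
  f <- concentration_field(vals, "tracer", g$r, out[, 1])
  attr(f, "radial_grid") <- g
  f
}

#' Series solution for a sphere with constant surface concentration
#'
#' Closed-form eigenfunction series for diffusion into a sphere of radius
#' `R` with `c(R, t) = C0` and zero initial concentration:
#' `c(r,t)/C0 = 1 + (2R/(pi r)) * sum_n ((-1)^n / n) sin(n pi r / R)
#' exp(-D n^2 pi^2 t / R^2)`. Used as the independent oracle for
#' [simulate_sphere_radial()].
#'
#' @param r Radius (um), 0 < r <= R.
#' @param t Time (s).
#' @param D Diffusivity (um^2/s).
#' @param R Sphere radius (um).
#' @param C0 Surface concentration.
#' @param n_terms Series terms.
#' @return Concentration at (r, t).
#' @export
sphere_series_solution <- function(r, t, D, R, C0 = 1, n_terms = 400) {
  stopifnot(r > 0, r <= R)
  n <- seq_len(n_terms)
  s <- sum((-1)^n / n * sin(n * pi * r / R) * exp(-D * n^2 * pi^2 * t / R^2))
  C0 * (1 + 2 * R / (pi * r) * s)
}

#' Arrival-time comparison between slab and sphere geometries
#'
#' For matched diffusivity, travel distance (`L = R`) and input kinetics,
#' computes the first time each depth reaches a threshold concentration
#' (`threshold_frac` of the equilibrium concentration) in both
#' geometries, and their discrepancy. Depth is distance from the input:
#' `x` in the slab, `R - r` in the sphere.
#'
#' @param slab_field Output of [simulate_slab()]; the slab input sits at
#'   the left boundary, so depth equals `x`.
#' @param sphere_field Output of [simulate_sphere_radial()] with
#'   `surface = "pulse"`.
#' @param threshold_frac Arrival threshold as a fraction of the
#'   equilibrium concentration.
#' @param c_eq Equilibrium concentration used in both runs.
#' @return Data frame with columns `depth_um`, `t_slab_s`, `t_sphere_s`,
#'   `diff_s`, `rel_diff`; the maximum relative discrepancy is attached
#'   as attribute `"max_rel_diff"`.
#' @export
compare_arrival_profiles <- function(slab_field, sphere_field,
                                     threshold_frac = 0.5, c_eq = 1) {
  cs <- field_species(slab_field, "tracer")
  cp <- field_species(sphere_field, "tracer")
  stopifnot(nrow(cs) == nrow(cp))
  thr <- threshold_frac * c_eq
  arrive <- function(trace, times) {
    i <- which(trace >= thr)[1]
    if (is.na(i)) return(NA_real_)
    if (i == 1L) return(times[1])
    stats::approx(trace[(i - 1):i], times[(i - 1):i], thr, ties = "ordered")$y
  }
  depth_slab <- slab_field$x
  rg <- attr(sphere_field, "radial_grid")
  R <- if (!is.null(rg)) rg$radius_um else max(sphere_field$x) + min(sphere_field$x)
  depth_sph <- R - sphere_field$x
  ord <- order(depth_sph)
  t_slab <- vapply(seq_len(nrow(cs)), function(i) arrive(cs[i, ], slab_field$times), 0)
  t_sph <- vapply(ord, function(i) arrive(cp[i, ], sphere_field$times), 0)
  out <- data.frame(depth_um = depth_slab, t_slab_s = t_slab, t_sphere_s = t_sph)
  out$diff_s <- out$t_sphere_s - out$t_slab_s
  out$rel_diff <- abs(out$diff_s) / pmax(out$t_slab_s, out$t_sphere_s)
  attr(out, "max_rel_diff") <- max(out$rel_diff, na.rm = TRUE)
  out
}
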