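#' Distance-versus-time pseudo-colour map
#'
#' Kymograph-style rendering of the simulation output: distance on the
#' vertical axis, time on the horizontal axis, colour indicating percent
#' substrate cleavage (default) or one species' concentration (as percent
#' of its maximum when `percent = TRUE`). In a diffusion-free run
#' iso-cleavage colours slope across distance (the input wave persists);
#' at reference diffusivities the contours are near-vertical
#' (space-homogeneous execution).
#'
#' @param field A `ConcentrationField`.
#' @param what `"cleavage"` or a species name.
#' @param percent Rescale a species map to percent of its maximum.
#' @return A ggplot object.
#' @export
render_heatmap <- function(field, what = "cleavage", percent = TRUE) {
  stopifnot(inherits(field, "ConcentrationField"))
  if (what == "cleavage") {
    m <- substrate_cleavage_fraction(field) * 100
    lab <- "substrate cleavage (%)"
  } else {
    m <- field_species(field, what)
    if (percent && max(m) > 0) {
      m <- m / max(m) * 100
      lab <- paste0(what, " (% of max)")
    } else lab <- paste0(what, " (uM)")
  }
  df <- data.frame(x = rep(field$x, times = length(field$times)),
                   t = rep(field$times, each = length(field$x)),
                   value = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$x, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = lab, limits = if (what == "cleavage") c(0, 100)) +
    ggplot2::labs(x = "time (s)", y = "distance (um)") +
    ggplot2::theme_minimal()
}

#' Near- and far-end cleavage traces
#'
#' @param field A `ConcentrationField`.
#' @return A ggplot object with the substrate-cleavage time courses at
#'   both cell ends.
#' @export
plot_end_traces <- function(field) {
  fr <- substrate_cleavage_fraction(field)
  df <- rbind(data.frame(t = field$times, fraction = fr[1, ], end = "near (x = 0)"),
              data.frame(t = field$times, fraction = fr[nrow(fr), ], end = "far (x = L)"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$fraction,
                                   colour = .data$end)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "substrate cleavage fraction", colour = NULL) +
    ggplot2::theme_minimal()
}
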