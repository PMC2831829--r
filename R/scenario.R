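scenario_defaults <- function() {
  list(
    scenario_id = "reference",
    model_file = NULL,                 # NULL = packaged reconstruction
    grid = list(length_um = 30, n_nodes = 300),
    inputs = list(wave_velocity_um_s = 0.1, origin_um = 0, onset_smoothing_s = 1),
    variants = list(),                 # e.g. list("no_c3_autoprocessing", list(name="rate_scale", value=10))
    diffusivity_scales = 1,            # fold-reductions; may include Inf
    no_diffusion = FALSE,
    thresholds = c(0.01, 0.5),
    t_end = 3600,
    save_dt = 1,
    rtol = 1e-6,
    atol = 1e-9,
    output_dir = NULL                  # NULL = return results only
  )
}

#' Build a scenario configuration
#'
#' A fully serialisable description of one in-silico experiment: model
#' file, grid, MOMP-wave geometry, network variants, diffusivity scales,
#' thresholds and solver settings. Unspecified fields take the reference
#' defaults (L = 30 um, 300 nodes, v_wave = 0.1 um/s, scale 1).
#'
#' @param ... Named fields overriding the defaults (see
#'   `apoptowave:::scenario_defaults()`).
#' @return An object of class `ScenarioConfig`.
#' @export
scenario_config <- function(...) {
  cfg <- scenario_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  for (n in names(over)) {
    if (is.list(cfg[[n]]) && !is.null(names(cfg[[n]])) && is.list(over[[n]]) &&
        n != "variants") {
      sub <- over[[n]]
      bad <- setdiff(names(sub), names(cfg[[n]]))
      if (length(bad))
        stop("unknown config keys in '", n, "': ", paste(bad, collapse = ", "),
             call. = FALSE)
      cfg[[n]][names(sub)] <- sub
    } else cfg[[n]] <- over[[n]]
  }
  validate_scenario_config(cfg)
}

validate_scenario_config <- function(cfg) {
  ## coerce numeric fields (YAML 1.1 reads dot-less exponents as strings)
  num <- function(x) if (is.null(x)) x else as.numeric(unlist(x))
  for (f in c("diffusivity_scales", "thresholds", "t_end", "save_dt",
              "rtol", "atol"))
    cfg[[f]] <- num(cfg[[f]])
  cfg$grid <- lapply(cfg$grid, as.numeric)
  cfg$inputs <- lapply(cfg$inputs, as.numeric)
  if (any(unlist(cfg$diffusivity_scales) == 0))
    stop("diffusivity scale 0 is not meaningful; set no_diffusion = TRUE for the diffusion-free case",
         call. = FALSE)
  if (any(unlist(cfg$diffusivity_scales) < 0))
    stop("diffusivity scales must be positive", call. = FALSE)
  if (any(unlist(cfg$thresholds) <= 0 | unlist(cfg$thresholds) >= 1))
    stop("thresholds must be in (0, 1)", call. = FALSE)
  if (cfg$t_end <= 0) stop("t_end must be > 0", call. = FALSE)
  structure(cfg, class = "ScenarioConfig")
}

#' Load a scenario configuration file
#'
#' @param path YAML file with any subset of the scenario fields; unknown
#'   keys are an error, missing keys take defaults.
#' @return A validated `ScenarioConfig`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  if (is.null(doc)) doc <- list()
  do.call(scenario_config, doc)
}

#' Save a scenario configuration file
#'
#' The saved file round-trips: `load_config(save_config(cfg, f))` equals
#' `cfg`, and re-running it reproduces every exported number.
#'
#' @param config A `ScenarioConfig`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "ScenarioConfig"))
  out <- unclass(config)
  out <- out[!vapply(out, is.null, FALSE)]
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

scenario_network <- function(cfg) {
  params <- if (is.null(cfg$model_file)) reference_parameters() else read_model(cfg$model_file)
  net <- build_reference_network(params)
  net <- assign_diffusivities(net)
  if (length(cfg$variants)) net <- apply_variants(net, cfg$variants)
  net
}

#' Run a scenario end-to-end
#'
#' Deterministic pipeline: builds the network (with variants), the grid
#' and the MOMP inputs from the configuration, simulates at every
#' requested diffusivity scale, computes the delay table, and (when
#' `config$output_dir` is set) writes the delay table, a provenance copy
#' of the configuration, cleavage kymographs and a log.
#'
#' @param config A `ScenarioConfig`.
#' @param keep_fields Keep the simulated fields in the returned object
#'   (they can be large); default `TRUE`.
#' @return List with `delays` (delay table), `fields` (named by scale)
#'   and `config`.
#' @export
run_scenario <- function(config, keep_fields = TRUE) {
  stopifnot(inherits(config, "ScenarioConfig"))
  net <- scenario_network(config)
  grid <- spatial_grid(config$grid$length_um, config$grid$n_nodes)
  inputs <- default_wave_inputs(net,
                                wave_velocity_um_s = config$inputs$wave_velocity_um_s,
                                origin_um = config$inputs$origin_um,
                                onset_smoothing_s = config$inputs$onset_smoothing_s)
  scales <- if (config$no_diffusion) Inf else unlist(config$diffusivity_scales)
  outdir <- config$output_dir
  if (!is.null(outdir) && !dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    message(msg)
    if (!is.null(outdir)) cat(msg, "\n", file = file.path(outdir, "run.log"),
                              append = TRUE, sep = "")
  }
  fields <- list()
  delays <- NULL
  for (s in scales) {
    t0 <- proc.time()[3]
    field <- simulate(net, grid, inputs, t_end = config$t_end,
                      save_dt = config$save_dt, rtol = config$rtol,
                      atol = config$atol,
                      diffusivity_scale = if (is.infinite(s)) NULL else s,
                      no_diffusion = is.infinite(s))
    for (th in unlist(config$thresholds))
      delays <- rbind(delays, end_to_end_delay(field, th, config$scenario_id, s))
    log_line("scenario=", config$scenario_id, " scale=", s,
             " runtime=", round(proc.time()[3] - t0, 1), "s")
    slug <- paste0(config$scenario_id, "_scale", gsub("Inf", "noD", as.character(s)))
    if (!is.null(outdir)) {
      p <- render_heatmap(field)
      ggplot2::ggsave(file.path(outdir, paste0(slug, "_cleavage.png")), p,
                      width = 6, height = 4, dpi = 120)
    }
    if (keep_fields) fields[[as.character(s)]] <- field
  }
  if (!is.null(outdir)) {
    write_delay_table(delays, file.path(outdir, paste0(config$scenario_id, "_delays.tsv")))
    save_config(config, file.path(outdir, paste0(config$scenario_id, "_config.yaml")))
  }
  list(delays = delays, fields = fields, config = config)
}
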