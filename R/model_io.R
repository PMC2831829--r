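## Plain-text model description files (YAML). The shipped default,
## hela_reconstructed_model.yaml, is a *reconstruction* of the HeLa
## apoptosis-execution network: the topology follows the published
## description of the network (apoptosome-bound caspase-9 autoprocessing,
## caspase-3 feedback, XIAP inhibition and cleavage, Smac neutralisation,
## ubiquitin-tagged degradation of XIAP-bound partners), while rate
## constants and concentrations are literature-typical values calibrated
## so whole-cell execution kinetics and their spatial behaviour match the
## reported phenomenology. Every number can be overridden via this file.

## shortest decimal representation that round-trips exactly to the double
fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    s <- formatC(v, digits = 17, format = "g", width = -1)
    for (d in 1:17) {
      cand <- formatC(v, digits = d, format = "g", width = -1)
      if (as.numeric(cand) == v) { s <- cand; break }
    }
    ## YAML 1.1 floats need a dot in the mantissa ("6e-05" would read
    ## back as a string)
    if (grepl("e", s, fixed = TRUE) && !grepl(".", sub("e.*$", "", s), fixed = TRUE))
      s <- sub("e", ".0e", s, fixed = TRUE)
    s
  }, "")
}

expand_names <- function(x) {
  ## named stoichiometry vector -> character vector with repeats
  if (length(x) == 0L) return(character(0))
  rep(names(x), times = as.integer(x))
}

#' Read a model description file
#'
#' @param path Path to a YAML model file (species, reactions, inputs).
#' @return A parameter-set list with elements `name`, `species`
#'   (data frame), `reactions` (list of [reaction()] objects) and
#'   `inputs`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$species) || is.null(doc$reactions))
    stop("model file needs 'species' and 'reactions' sections", call. = FALSE)
  species <- do.call(rbind, lapply(doc$species, function(s) {
    if (is.null(s$name) || is.null(s$mass_kDa))
      stop("every species needs 'name' and 'mass_kDa'", call. = FALSE)
    protein_species(s$name, as.numeric(s$mass_kDa),
                    initial_uM = if (is.null(s$init_uM)) 0 else as.numeric(s$init_uM),
                    diffusible = if (is.null(s$diffusible)) TRUE else s$diffusible,
                    apoptosome_containing = isTRUE(s$apoptosome_containing))
  }))
  reactions <- lapply(doc$reactions, function(r) {
    tag <- if (is.null(r$tag)) "untagged" else r$tag
    if (is.null(r$k))
      stop("missing rate constant for reaction tagged '", tag, "'", call. = FALSE)
    k <- suppressWarnings(as.numeric(r$k))
    if (is.na(k))
      stop("missing rate constant for reaction tagged '", tag, "'", call. = FALSE)
    reaction(as.character(unlist(r$reactants)), as.character(unlist(r$products)),
             k = k, tag = tag, capacity_modifier = isTRUE(r$capacity_modifier))
  })
  inputs <- lapply(doc$inputs, function(inp) {
    inp$amplitude_uM <- as.numeric(inp$amplitude_uM)
    inp$saturation_rate_per_s <- as.numeric(inp$saturation_rate_per_s)
    inp
  })
  list(name = if (is.null(doc$name)) "model" else doc$name,
       species = species, reactions = reactions, inputs = inputs)
}

#' Write a model description file
#'
#' Numbers are written with enough digits to round-trip bit-exactly:
#' `read_model(write_model(m, f))` reproduces `m` identically.
#'
#' @param model A parameter set as returned by [read_model()] or
#'   [reference_parameters()], or a `ReactionNetwork`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  if (inherits(model, "ReactionNetwork"))
    model <- list(name = model$name, species = model$species,
                  reactions = model$reactions, inputs = model$inputs)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  w("name: ", model$name)
  w("species:")
  for (i in seq_len(nrow(model$species))) {
    s <- model$species[i, ]
    w("  - {name: ", s$name,
      ", mass_kDa: ", fmt_num(s$mass_kDa),
      ", init_uM: ", fmt_num(s$initial_uM),
      ", diffusible: ", tolower(as.character(s$diffusible)),
      ", apoptosome_containing: ", tolower(as.character(s$apoptosome_containing)), "}")
  }
  w("reactions:")
  for (r in model$reactions) {
    w("  - {reactants: [", paste(expand_names(r$reactants), collapse = ", "),
      "], products: [", paste(expand_names(r$products), collapse = ", "),
      "], k: ", fmt_num(r$k), ", tag: ", r$tag,
      if (r$capacity_modifier) ", capacity_modifier: true" else "", "}")
  }
  if (length(model$inputs)) {
    w("inputs:")
    for (inp in model$inputs)
      w("  - {target: ", inp$target,
        ", amplitude_uM: ", fmt_num(inp$amplitude_uM),
        ", saturation_rate_per_s: ", fmt_num(inp$saturation_rate_per_s),
        ", label: ", inp$label, "}")
  }
  invisible(path)
}

#' Reconstructed HeLa parameter set
#'
#' Reads the packaged default model description (species with masses and
#' initial concentrations, mass-action reactions, MOMP input functions).
#'
#' @return A parameter-set list; see [read_model()].
#' @export
reference_parameters <- function() {
  read_model(system.file("extdata", "hela_reconstructed_model.yaml",
                         package = "apoptowave", mustWork = TRUE))
}

#' Build the reference apoptosis-execution network
#'
#' Assembles the default HeLa execution network: apoptosome-bound
#' procaspase-9 autoprocessing (p35/p12), caspase-3 feedback processing of
#' caspase-9 to p35/p10, activation of procaspases-3 and -7, caspase-3
#' autoprocessing, XIAP inhibition of caspase-9 (p35/p12) and caspases-3/-7,
#' caspase-3 cleavage of XIAP into BIR1-2 and BIR3-RING fragments that
#' retain their binding roles, Smac neutralisation of XIAP and fragments,
#' ubiquitin-tagged degradation of XIAP-bound partners, caspase-dependent
#' shutdown of synthesis/turnover, and a reporter substrate pair as model
#' output.
#'
#' @param params A parameter set (default: the packaged reconstruction);
#'   see [read_model()] for the file format.
#' @return A `ReactionNetwork`.
#' @export
build_reference_network <- function(params = reference_parameters()) {
  reaction_network(params$species, params$reactions,
                   inputs = params$inputs, name = params$name)
}
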