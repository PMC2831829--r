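#' Define a protein species
#'
#' A species of the apoptosis-execution network: a protein or protein
#' complex with a molecular mass (which sets its Stokes-Einstein
#' diffusivity, see [stokes_einstein_diffusivity()]), an initial cytosolic
#' concentration, and flags controlling its transport behaviour.
#'
#' @param name Unique species identifier.
#' @param mass_kDa Molecular mass in kDa; must be positive.
#' @param initial_uM Initial concentration in uM; must be non-negative.
#' @param diffusible Logical; immobile species get a diffusivity of zero.
#' @param apoptosome_containing Logical; marks species affected by the
#'   apoptosome-immobilisation variant (the ~700 kDa apoptosome platform
#'   and everything bound to it).
#' @return A one-row data frame.
#' @export
protein_species <- function(name, mass_kDa, initial_uM = 0,
                            diffusible = TRUE, apoptosome_containing = FALSE) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(mass_kDa) || length(mass_kDa) != 1L || mass_kDa <= 0)
    stop("species '", name, "': mass_kDa must be a single positive number", call. = FALSE)
  if (!is.numeric(initial_uM) || length(initial_uM) != 1L || initial_uM < 0)
    stop("species '", name, "': initial_uM must be a single non-negative number", call. = FALSE)
  data.frame(name = name, mass_kDa = as.numeric(mass_kDa),
             initial_uM = as.numeric(initial_uM),
             diffusible = isTRUE(diffusible),
             apoptosome_containing = isTRUE(apoptosome_containing),
             stringsAsFactors = FALSE)
}

#' Define a mass-action reaction
#'
#' Reactants and products are given as character vectors of species names;
#' a name repeated n times means stoichiometry n (e.g. `products =
#' c("c3", "c3")` for autocatalytic doubling). The rate constant has units
#' 1/s for first-order, 1/(uM s) for second-order, and uM/s for
#' zeroth-order (synthesis) reactions.
#'
#' @param reactants,products Character vectors of species names (possibly
#'   empty for synthesis/turnover), or named numeric vectors of
#'   stoichiometries.
#' @param k Non-negative rate constant.
#' @param tag Role label used by scenario variants to find reactions
#'   (e.g. `"c3_feedback_on_c9"`, `"c3_autoprocessing"`, `"xiap_binding"`,
#'   `"ubiquitin_degradation"`, `"synthesis"`, `"turnover"`,
#'   `"substrate_cleavage"`).
#' @param capacity_modifier Logical; if `TRUE` the reaction velocity is
#'   scaled by the uncleaved fraction of the reporter substrate, modelling
#'   effector-caspase-dependent shutdown of protein synthesis and
#'   degradation.
#' @return An object of class `Reaction`.
#' @export
reaction <- function(reactants, products, k, tag, capacity_modifier = FALSE) {
  norm <- function(x, what) {
    if (is.null(x) || length(x) == 0L) return(stats::setNames(numeric(0), character(0)))
    if (is.character(x)) {
      tab <- table(x)
      x <- stats::setNames(as.numeric(tab), names(tab))
    }
    if (is.null(names(x)) || any(names(x) == ""))
      stop("reaction '", tag, "': ", what, " must be species names", call. = FALSE)
    if (any(x <= 0) || any(x != round(x)))
      stop("reaction '", tag, "': stoichiometries must be positive integers", call. = FALSE)
    x
  }
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0)
    stop("reaction '", tag, "': missing or negative rate constant", call. = FALSE)
  stopifnot(is.character(tag), length(tag) == 1L)
  structure(list(reactants = norm(reactants, "reactants"),
                 products = norm(products, "products"),
                 k = as.numeric(k), tag = tag,
                 capacity_modifier = isTRUE(capacity_modifier)),
            class = "Reaction")
}

#' Assemble a reaction network
#'
#' @param species A data frame of species rows (see [protein_species()]),
#'   typically `do.call(rbind, list_of_species)`.
#' @param reactions A list of [reaction()] objects.
#' @param inputs Optional list of input pseudo-reaction descriptors, each a
#'   list with `target`, `amplitude_uM`, `saturation_rate_per_s` and
#'   `label`; consumed by [default_wave_inputs()].
#' @param name Optional model name.
#' @return An object of class `ReactionNetwork`.
#' @export
reaction_network <- function(species, reactions, inputs = NULL, name = "network") {
  stopifnot(is.data.frame(species), is.list(reactions))
  if (anyDuplicated(species$name))
    stop("species names must be unique", call. = FALSE)
  if (any(species$mass_kDa <= 0)) stop("all species masses must be > 0", call. = FALSE)
  if (any(species$initial_uM < 0)) stop("initial concentrations must be >= 0", call. = FALSE)
  for (r in reactions) {
    if (!inherits(r, "Reaction")) stop("reactions must be Reaction objects", call. = FALSE)
    ref <- c(names(r$reactants), names(r$products))
    bad <- setdiff(ref, species$name)
    if (length(bad))
      stop("reaction '", r$tag, "' references unknown species: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  for (inp in inputs) {
    if (is.null(inp$target) || !inp$target %in% species$name)
      stop("input '", inp$label, "' targets unknown species", call. = FALSE)
    if (is.null(inp$amplitude_uM) || is.null(inp$saturation_rate_per_s))
      stop("input '", inp$label, "' needs amplitude_uM and saturation_rate_per_s",
           call. = FALSE)
  }
  structure(list(species = species, reactions = reactions,
                 inputs = inputs, name = name),
            class = "ReactionNetwork")
}

#' @export
print.ReactionNetwork <- function(x, ...) {
  cat("ReactionNetwork '", x$name, "': ", nrow(x$species), " species, ",
      length(x$reactions), " reactions, ", length(x$inputs), " inputs\n", sep = "")
  sc <- attr(x, "diffusivity_scale")
  if (!is.null(sc)) cat("  diffusivity scale: 1/", format(sc), "\n", sep = "")
  invisible(x)
}

#' Net stoichiometry matrix
#'
#' @param network A `ReactionNetwork`.
#' @return A numeric matrix (species x reactions) of net concentration
#'   changes per reaction event.
#' @export
stoichiometry_matrix <- function(network) {
  stopifnot(inherits(network, "ReactionNetwork"))
  sp <- network$species$name
  S <- matrix(0, nrow = length(sp), ncol = length(network$reactions),
              dimnames = list(sp, vapply(network$reactions, `[[`, "", "tag")))
  for (j in seq_along(network$reactions)) {
    r <- network$reactions[[j]]
    for (n in names(r$reactants)) S[n, j] <- S[n, j] - r$reactants[[n]]
    for (n in names(r$products)) S[n, j] <- S[n, j] + r$products[[n]]
  }
  S
}

## flat index structure consumed by the compiled RHS; at most two distinct
## reactant species per reaction (all reactions in the model are at most
## bimolecular)
network_kernel <- function(network) {
  rx <- network$reactions
  sp <- network$species$name
  i1 <- integer(length(rx)); e1 <- numeric(length(rx)); i2 <- integer(length(rx))
  for (j in seq_along(rx)) {
    rr <- rx[[j]]$reactants
    if (length(rr) > 2L)
      stop("reaction '", rx[[j]]$tag, "': more than two reactant species", call. = FALSE)
    i1[j] <- if (length(rr) >= 1L) match(names(rr)[1L], sp) else 0L
    e1[j] <- if (length(rr) >= 1L) rr[[1L]] else 0
    i2[j] <- if (length(rr) >= 2L) match(names(rr)[2L], sp) else 0L
    if (length(rr) == 2L && rr[[2L]] != 1)
      stop("reaction '", rx[[j]]$tag, "': second reactant stoichiometry must be 1",
           call. = FALSE)
  }
  list(S = stoichiometry_matrix(network),
       k = vapply(rx, `[[`, 0, "k"),
       i1 = i1, e1 = e1, i2 = i2,
       capmod = vapply(rx, `[[`, FALSE, "capacity_modifier"),
       isub = match("substrate", sp, nomatch = 1L),
       icle = match("substrate_cleaved", sp, nomatch = 1L))
}

#' Mass-action rates of change at one point
#'
#' Evaluates the reaction part of the model (no diffusion, no inputs):
#' each reaction contributes its mass-action velocity
#' `k * prod(reactant concentrations^stoichiometry)` times its net
#' stoichiometry. Reactions with `capacity_modifier = TRUE` are scaled by
#' the uncleaved substrate fraction.
#'
#' @param network A `ReactionNetwork`.
#' @param concentrations Named numeric vector, one non-negative value per
#'   species (uM).
#' @return Named numeric vector of d(concentration)/dt in uM/s.
#' @export
mass_action_rates <- function(network, concentrations) {
  stopifnot(inherits(network, "ReactionNetwork"))
  sp <- network$species$name
  if (is.null(names(concentrations))) {
    if (length(concentrations) != length(sp))
      stop("need one concentration per species", call. = FALSE)
    names(concentrations) <- sp
  }
  if (!all(sp %in% names(concentrations)))
    stop("concentrations missing for some species", call. = FALSE)
  conc <- concentrations[sp]
  if (any(is.na(conc)) || any(conc < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  ker <- network_kernel(network)
  dy <- rd_network_rhs(0, as.numeric(conc), ker$S, ker$k, ker$i1, ker$e1, ker$i2,
                       ker$capmod, ker$isub, ker$icle,
                       D = numeric(length(sp)), dx = 1, nx = 1L,
                       in_target = integer(0), in_cmax = numeric(0),
                       in_k = numeric(0), t_on = matrix(0, 1, 0), tau = 0)
  stats::setNames(as.numeric(dy), sp)
}

#' Total concentration of a conserved moiety
#'
#' Sums the concentration of every species containing a given moiety,
#' weighted by how many copies each complex carries. Used to check that
#' pure binding/unbinding chemistry conserves totals when synthesis and
#' degradation are disabled.
#'
#' @param concentrations Named numeric vector (or a species x time matrix
#'   with species rownames).
#' @param members Named numeric vector: species name -> copies of the
#'   moiety per molecule.
#' @return Total moiety concentration (scalar or per-time vector).
#' @export
moiety_total <- function(concentrations, members) {
  if (is.matrix(concentrations)) {
    sub <- concentrations[names(members), , drop = FALSE]
    as.numeric(crossprod(members, sub))
  } else {
    sum(concentrations[names(members)] * members)
  }
}

#' Canonical moiety definitions for the reference network
#'
#' @param which One of `"xiap"`, `"caspase3"`, `"caspase7"`, `"caspase9"`,
#'   `"smac"`, `"substrate"`.
#' @return Named numeric vector suitable for [moiety_total()].
#' @export
reference_moiety <- function(which = c("xiap", "caspase3", "caspase7",
                                       "caspase9", "smac", "substrate")) {
  which <- match.arg(which)
  switch(which,
    ## each original XIAP counted once through its BIR1-2 half after cleavage
    xiap = c(xiap = 1, xiap_c3 = 1, xiap_c7 = 1, xiap_apop_c9 = 1, xiap_smac = 1,
             bir12 = 1, bir12_c3 = 1, bir12_c7 = 1, bir12_smac = 1),
    caspase3 = c(pc3 = 1, c3 = 1, xiap_c3 = 1, bir12_c3 = 1),
    caspase7 = c(pc7 = 1, c7 = 1, xiap_c7 = 1, bir12_c7 = 1),
    caspase9 = c(apop_pc9 = 1, apop_c9 = 1, apop_c9_p10 = 1,
                 xiap_apop_c9 = 1, bir3r_apop_c9 = 1),
    smac = c(smac = 1, xiap_smac = 1, bir3r_smac = 1, bir12_smac = 1),
    substrate = c(substrate = 1, substrate_cleaved = 1))
}

#' Apply a scenario variant to a network
#'
#' Pure transformation: the input network is not modified. Available
#' variants:
#' \describe{
#'   \item{`no_c3_to_c9_feedback`}{removes every reaction tagged
#'     `c3_feedback_on_c9` (caspase-3 processing caspase-9 to p35/p10).}
#'   \item{`no_c3_autoprocessing`}{removes every reaction tagged
#'     `c3_autoprocessing`.}
#'   \item{`rate_scale`}{multiplies every rate constant by `value`
#'     (e.g. 10 for the crowding-accelerated kinetics scenario).}
#'   \item{`immobile_apoptosome`}{sets `diffusible = FALSE` for every
#'     apoptosome-containing species, and only those.}
#'   \item{`diffusivity_scale`}{records a fold-reduction `value` for the
#'     transport layer; [simulate()] divides every diffusivity by it.}
#' }
#'
#' @param network A `ReactionNetwork`.
#' @param variant Variant name (single string).
#' @param value Numeric parameter for `rate_scale` / `diffusivity_scale`.
#' @return The transformed `ReactionNetwork`.
#' @seealso [apply_variants()] for combinations.
#' @export
apply_variant <- function(network, variant, value = NULL) {
  stopifnot(inherits(network, "ReactionNetwork"))
  drop_tag <- function(net, tag) {
    keep <- vapply(net$reactions, function(r) r$tag != tag, FALSE)
    net$reactions <- net$reactions[keep]
    net
  }
  out <- switch(variant,
    no_c3_to_c9_feedback = drop_tag(network, "c3_feedback_on_c9"),
    no_c3_autoprocessing = drop_tag(network, "c3_autoprocessing"),
    rate_scale = {
      if (is.null(value) || !is.numeric(value) || value <= 0)
        stop("rate_scale needs a positive numeric value", call. = FALSE)
      network$reactions <- lapply(network$reactions, function(r) {
        r$k <- r$k * value
        r
      })
      network
    },
    immobile_apoptosome = {
      network$species$diffusible <- !network$species$apoptosome_containing &
        network$species$diffusible
      if (!is.null(network$species$diffusivity_um2_s))
        network$species$diffusivity_um2_s[!network$species$diffusible] <- 0
      network
    },
    diffusivity_scale = {
      if (is.null(value) || !is.numeric(value) || value <= 0)
        stop("diffusivity_scale needs a positive value; use no_diffusion = TRUE in simulate() for the diffusion-free case",
             call. = FALSE)
      attr(network, "diffusivity_scale") <- value
      network
    },
    stop("unknown variant '", variant, "'; see ?apply_variant", call. = FALSE))
  out
}

#' Apply several variants in sequence
#'
#' @param network A `ReactionNetwork`.
#' @param variants A list whose elements are variant names or lists
#'   `list(name = , value = )`.
#' @return The transformed network.
#' @export
apply_variants <- function(network, variants) {
  for (v in variants) {
    if (is.character(v)) network <- apply_variant(network, v)
    else network <- apply_variant(network, v$name, v$value)
  }
  network
}
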