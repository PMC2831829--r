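## shared fixtures, built in code; heavier simulation results are cached
## per test session

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

ref_net <- function() cached("ref_net", assign_diffusivities(build_reference_network()))

## toy bimolecular network A + B -> C with one first-order back reaction
toy_binding_network <- function(kon = 2, koff = 0.1) {
  species <- rbind(protein_species("A", 30, initial_uM = 1),
                   protein_species("B", 40, initial_uM = 2),
                   protein_species("C", 70, initial_uM = 0))
  reaction_network(species,
                   list(reaction(c("A", "B"), "C", kon, "bind"),
                        reaction("C", c("A", "B"), koff, "unbind")),
                   name = "toy_binding")
}

## single inert tracer, no reactions: pure diffusion
tracer_network <- function(init = 1, mass = 27) {
  reaction_network(protein_species("tracer", mass, initial_uM = init),
                   list(), name = "tracer")
}

## reference network with synthesis/degradation chemistry disabled
conservative_ref_net <- function() {
  net <- build_reference_network()
  keep <- !vapply(net$reactions, function(r)
    r$tag %in% c("ubiquitin_degradation", "synthesis", "turnover"), FALSE)
  net$reactions <- net$reactions[keep]
  net
}

## independent brute-force mass-action oracle: explicit loop over
## reactions, no shared code with the package internals
oracle_mass_action <- function(net, conc) {
  rates <- stats::setNames(numeric(nrow(net$species)), net$species$name)
  tot <- conc["substrate"] + conc["substrate_cleaved"]
  capacity <- if (!is.na(tot) && tot > 0) conc["substrate"] / tot else 1
  for (r in net$reactions) {
    v <- r$k
    for (nm in names(r$reactants)) v <- v * conc[[nm]]^r$reactants[[nm]]
    if (r$capacity_modifier) v <- v * capacity
    for (nm in names(r$reactants)) rates[nm] <- rates[nm] - r$reactants[[nm]] * v
    for (nm in names(r$products)) rates[nm] <- rates[nm] + r$products[[nm]] * v
  }
  rates
}

## small reference simulation shared across metric/solver tests
ref_field_small <- function() cached("ref_field_small", {
  simulate(ref_net(), spatial_grid(30, 101), t_end = 600)
})

expect_no_na <- function(x) expect_false(anyNA(x))
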