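test_that("reference network contains the documented execution chemistry", {
  net <- build_reference_network()
  tags <- vapply(net$reactions, `[[`, "", "tag")
  expect_true("c9_autoprocessing" %in% tags)
  expect_true("c3_feedback_on_c9" %in% tags)
  expect_true("c3_autoprocessing" %in% tags)
  expect_true("xiap_cleavage" %in% tags)
  expect_true("ubiquitin_degradation" %in% tags)
  expect_true(all(c("synthesis", "turnover") %in% tags))
  needed <- c("apop_pc9", "apop_c9", "apop_c9_p10", "pc3", "c3", "pc7", "c7",
              "xiap", "smac", "bir12", "bir3r", "substrate", "substrate_cleaved")
  expect_true(all(needed %in% net$species$name))
  ## XIAP binds caspase-9 (p35/p12), caspase-3 and caspase-7
  binds <- vapply(net$reactions, function(r)
    r$tag == "xiap_binding" && "xiap" %in% names(r$reactants), FALSE)
  partners <- unlist(lapply(net$reactions[binds], function(r)
    setdiff(names(r$reactants), "xiap")))
  expect_true(all(c("c3", "c7", "apop_c9") %in% partners))
  ## the immobilisation flag covers the apoptosome-containing complexes only
  apo <- net$species$name[net$species$apoptosome_containing]
  expect_setequal(apo, c("apop_pc9", "apop_c9", "apop_c9_p10",
                         "xiap_apop_c9", "bir3r_apop_c9"))
})

test_that("missing rate constants are reported with the reaction tag", {
  tmp <- tempfile(fileext = ".yaml")
  writeLines(c("name: broken",
               "species:",
               "  - {name: A, mass_kDa: 30, init_uM: 1}",
               "reactions:",
               "  - {reactants: [A], products: [], tag: turnover}"), tmp)
  expect_error(read_model(tmp), "turnover")
})

test_that("mass-action rates match the brute-force per-reaction oracle", {
  net <- ref_net()
  sp <- net$species$name
  set.seed(42)
  for (i in 1:5) {
    conc <- stats::setNames(stats::runif(length(sp), 0, 0.5), sp)
    got <- mass_action_rates(net, conc)
    want <- oracle_mass_action(net, conc)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("mass-action rates reproduce textbook A + B -> C kinetics", {
  net <- toy_binding_network(kon = 3, koff = 0)
  r <- mass_action_rates(net, c(A = 1, B = 2, C = 0))
  expect_equal(unname(r["C"]), 2 * 3)
  expect_equal(unname(r["A"]), -6)
  expect_equal(unname(r["B"]), -6)
  ## all-zero state with no zeroth-order synthesis: all rates zero
  expect_equal(unname(mass_action_rates(net, c(A = 0, B = 0, C = 0))),
               c(0, 0, 0))
})

test_that("negative concentrations are a domain error", {
  expect_error(mass_action_rates(toy_binding_network(), c(A = -1, B = 1, C = 0)),
               "non-negative")
})

test_that("knockout variants remove exactly the tagged reactions", {
  net <- ref_net()
  tags <- vapply(net$reactions, `[[`, "", "tag")
  ko <- apply_variant(net, "no_c3_to_c9_feedback")
  expect_equal(length(net$reactions) - length(ko$reactions),
               sum(tags == "c3_feedback_on_c9"))
  expect_false("c3_feedback_on_c9" %in% vapply(ko$reactions, `[[`, "", "tag"))
  ## untouched reactions are identical, and the original is unmodified
  expect_identical(ko$reactions,
                   net$reactions[tags != "c3_feedback_on_c9"])
  expect_equal(length(net$reactions), 37L)
  ## idempotence
  expect_identical(apply_variant(ko, "no_c3_to_c9_feedback"), ko)
})

test_that("rate scaling multiplies every rate constant exactly", {
  net <- ref_net()
  sc <- apply_variant(net, "rate_scale", 10)
  expect_equal(vapply(sc$reactions, `[[`, 0, "k"),
               10 * vapply(net$reactions, `[[`, 0, "k"))
})

test_that("apoptosome immobilisation flags only apoptosome-containing species", {
  net <- ref_net()
  im <- apply_variant(net, "immobile_apoptosome")
  expect_equal(im$species$diffusible, !net$species$apoptosome_containing)
  ## diffusivities of free Smac and caspase-3 unchanged after re-assignment
  im <- assign_diffusivities(im)
  for (s in c("smac", "c3")) {
    expect_equal(im$species$diffusivity_um2_s[im$species$name == s],
                 net$species$diffusivity_um2_s[net$species$name == s])
  }
  expect_equal(im$species$diffusivity_um2_s[im$species$apoptosome_containing],
               rep(0, 5))
})

test_that("unknown variants raise a configuration error", {
  expect_error(apply_variant(ref_net(), "no_such_variant"), "unknown variant")
  expect_error(apply_variant(ref_net(), "diffusivity_scale", 0), "no_diffusion")
})

test_that("binding chemistry conserves moieties when degradation is disabled", {
  net <- conservative_ref_net()
  lo <- simulate_local_ode(net, t_end = 600, save_dt = 5)
  traj <- matrix(lo$values[, 1, ], nrow = length(lo$species_names),
                 dimnames = list(lo$species_names, NULL))
  for (m in c("xiap", "caspase3", "caspase7", "substrate")) {
    tot <- moiety_total(traj, reference_moiety(m))
    expect_lt(max(abs(tot - tot[1])), 1e-6)
  }
})

test_that("zero initial substrate gives identically zero cleavage output", {
  params <- reference_parameters()
  params$species$initial_uM[params$species$name == "substrate"] <- 0
  net <- build_reference_network(params)
  lo <- simulate_local_ode(net, t_end = 400, save_dt = 10)
  cleaved <- lo$values["substrate_cleaved", 1, ]
  expect_equal(max(abs(cleaved)), 0)
})
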