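name: hela_execution_reconstructed
# Reconstructed apoptosis-execution network for a HeLa-like cell.
# Topology: apoptosome/caspase-9/-3/-7/XIAP/Smac execution module with
# XIAP cleavage fragments, ubiquitin-tagged degradation of XIAP-bound
# partners, and caspase-dependent shutdown of synthesis/degradation.
# Rate constants and concentrations are literature-typical values
# ("reconstructed", not measured here); all are overridable.
# Units: uM, s, kDa. Second-order k in 1/(uM s); zeroth-order in uM/s.
species:
  - {name: apop_pc9, mass_kDa: 750, init_uM: 0, diffusible: true, apoptosome_containing: true}
  - {name: apop_c9, mass_kDa: 750, init_uM: 0, diffusible: true, apoptosome_containing: true}
  - {name: apop_c9_p10, mass_kDa: 750, init_uM: 0, diffusible: true, apoptosome_containing: true}
  - {name: pc3, mass_kDa: 32, init_uM: 0.2, diffusible: true, apoptosome_containing: false}
  - {name: c3, mass_kDa: 29, init_uM: 0, diffusible: true, apoptosome_containing: false}
  - {name: pc7, mass_kDa: 35, init_uM: 0.05, diffusible: true, apoptosome_containing: false}
  - {name: c7, mass_kDa: 33, init_uM: 0, diffusible: true, apoptosome_containing: false}
  - {name: xiap, mass_kDa: 57, init_uM: 0.12, diffusible: true, apoptosome_containing: false}
  - {name: xiap_c3, mass_kDa: 86, init_uM: 0, diffusible: true, apoptosome_containing: false}
  - {name: xiap_c7, mass_kDa: 90, init_uM: 0, diffusible: true, apoptosome_containing: false}
  - {name: xiap_apop_c9, mass_kDa: 807, init_uM: 0, diffusible: true, apoptosome_containing: true}
  - {name: smac, mass_kDa: 42, init_uM: 0, diffusible: true, apoptosome_containing: false}
  - {name: xiap_smac, mass_kDa: 99, init_uM: 0, diffusible: true, apoptosome_containing: false}
  - {name: bir12, mass_kDa: 30, init_uM: 0, diffusible: true, apoptosome_containing: false}
  - {name: bir3r, mass_kDa: 27, init_uM: 0, diffusible: true, apoptosome_containing: false}
  - {name: bir12_c3, mass_kDa: 59, init_uM: 0, diffusible: true, apoptosome_containing: false}
  - {name: bir12_c7, mass_kDa: 63, init_uM: 0, diffusible: true, apoptosome_containing: false}
  - {name: bir3r_apop_c9, mass_kDa: 777, init_uM: 0, diffusible: true, apoptosome_containing: true}
  - {name: bir3r_smac, mass_kDa: 69, init_uM: 0, diffusible: true, apoptosome_containing: false}
  - {name: bir12_smac, mass_kDa: 72, init_uM: 0, diffusible: true, apoptosome_containing: false}
  - {name: substrate, mass_kDa: 54, init_uM: 1, diffusible: true, apoptosome_containing: false}
  - {name: substrate_cleaved, mass_kDa: 54, init_uM: 0, diffusible: true, apoptosome_containing: false}
reactions:
  # apoptosome-bound procaspase-9 autoprocessing to p35/p12
  - {reactants: [apop_pc9], products: [apop_c9], k: 0.01, tag: c9_autoprocessing}
  # caspase-3 feedback: processing of caspase-9 to its p35/p10 form
  - {reactants: [apop_pc9, c3], products: [apop_c9_p10, c3], k: 0.5, tag: c3_feedback_on_c9}
  - {reactants: [apop_c9, c3], products: [apop_c9_p10, c3], k: 0.5, tag: c3_feedback_on_c9}
  # effector procaspase activation by apoptosome-bound caspase-9
  - {reactants: [pc3, apop_c9], products: [c3, apop_c9], k: 0.5, tag: effector_activation}
  - {reactants: [pc3, apop_c9_p10], products: [c3, apop_c9_p10], k: 0.5, tag: effector_activation}
  - {reactants: [pc7, apop_c9], products: [c7, apop_c9], k: 0.1, tag: effector_activation}
  - {reactants: [pc7, apop_c9_p10], products: [c7, apop_c9_p10], k: 0.1, tag: effector_activation}
  # caspase-3 autoprocessing and cross-activation of caspase-7
  - {reactants: [pc3, c3], products: [c3, c3], k: 0.05, tag: c3_autoprocessing}
  - {reactants: [pc7, c3], products: [c7, c3], k: 0.3, tag: effector_activation}
  # XIAP inhibition of caspase-3, caspase-7 and caspase-9 (p35/p12)
  - {reactants: [xiap, c3], products: [xiap_c3], k: 5, tag: xiap_binding}
  - {reactants: [xiap_c3], products: [xiap, c3], k: 0.0035, tag: xiap_binding}
  - {reactants: [xiap, c7], products: [xiap_c7], k: 5, tag: xiap_binding}
  - {reactants: [xiap_c7], products: [xiap, c7], k: 0.01, tag: xiap_binding}
  - {reactants: [xiap, apop_c9], products: [xiap_apop_c9], k: 3, tag: xiap_binding}
  - {reactants: [xiap_apop_c9], products: [xiap, apop_c9], k: 0.01, tag: xiap_binding}
  # caspase-3 cleaves XIAP into BIR1-2 and BIR3-RING fragments
  - {reactants: [xiap, c3], products: [bir12, bir3r, c3], k: 0.1, tag: xiap_cleavage}
  # fragments retain their binding roles
  - {reactants: [bir12, c3], products: [bir12_c3], k: 5, tag: xiap_binding}
  - {reactants: [bir12_c3], products: [bir12, c3], k: 0.01, tag: xiap_binding}
  - {reactants: [bir12, c7], products: [bir12_c7], k: 5, tag: xiap_binding}
  - {reactants: [bir12_c7], products: [bir12, c7], k: 0.02, tag: xiap_binding}
  - {reactants: [bir3r, apop_c9], products: [bir3r_apop_c9], k: 3, tag: xiap_binding}
  - {reactants: [bir3r_apop_c9], products: [bir3r, apop_c9], k: 0.02, tag: xiap_binding}
  # Smac neutralisation of XIAP and its fragments
  - {reactants: [smac, xiap], products: [xiap_smac], k: 7, tag: smac_binding}
  - {reactants: [xiap_smac], products: [smac, xiap], k: 0.0005, tag: smac_binding}
  - {reactants: [smac, bir3r], products: [bir3r_smac], k: 7, tag: smac_binding}
  - {reactants: [bir3r_smac], products: [smac, bir3r], k: 0.001, tag: smac_binding}
  - {reactants: [smac, bir12], products: [bir12_smac], k: 7, tag: smac_binding}
  - {reactants: [bir12_smac], products: [smac, bir12], k: 0.001, tag: smac_binding}
  # ubiquitin-tagged proteasomal degradation of XIAP-bound partners
  # (complex degraded as a unit); shut down as the substrate is cleaved
  - {reactants: [xiap_c3], products: [], k: 0.005, tag: ubiquitin_degradation, capacity_modifier: true}
  - {reactants: [xiap_c7], products: [], k: 0.005, tag: ubiquitin_degradation, capacity_modifier: true}
  - {reactants: [xiap_apop_c9], products: [], k: 0.005, tag: ubiquitin_degradation, capacity_modifier: true}
  - {reactants: [bir12_c3], products: [], k: 0.005, tag: ubiquitin_degradation, capacity_modifier: true}
  - {reactants: [bir3r_apop_c9], products: [], k: 0.005, tag: ubiquitin_degradation, capacity_modifier: true}
  # XIAP synthesis/turnover in pre-onset steady state (6e-05 / 0.0005 = 0.12)
  - {reactants: [], products: [xiap], k: 6.0e-05, tag: synthesis, capacity_modifier: true}
  - {reactants: [xiap], products: [], k: 0.0005, tag: turnover, capacity_modifier: true}
  # effector-caspase reporter substrate cleavage (model output)
  - {reactants: [substrate, c3], products: [substrate_cleaved, c3], k: 1, tag: substrate_cleavage}
  - {reactants: [substrate, c7], products: [substrate_cleaved, c7], k: 0.05, tag: substrate_cleavage}
inputs:
  # MOMP-driven pseudo-reactions; Smac release is slower than cyt-c
  # induced apoptosome formation
  - {target: apop_pc9, amplitude_uM: 0.02, saturation_rate_per_s: 0.015, label: apoptosome}
  - {target: smac, amplitude_uM: 0.35, saturation_rate_per_s: 0.007, label: smac}
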