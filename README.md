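# apoptowave

Reaction–diffusion modelling of spatially coordinated apoptosis
execution in a single cell.

During intrinsic apoptosis, mitochondrial outer membrane
permeabilisation (MOMP) can progress across a cell as a slow wave
(~0.1 µm/s), so cytochrome-c and Smac reach the cytosol at one end of
the cell about five minutes before the other. `apoptowave` simulates
what happens downstream: a ~20-species mass-action network (apoptosome,
caspase-9, effector caspases-3/-7, XIAP and its cleavage fragments,
Smac, a reporter substrate) coupled to 1-D Fickian diffusion over a
30 µm model cell,

```
∂c_n/∂t = D_n ∂²c_n/∂x² + R_n(c) + I_n(x, t),   ∂c_n/∂x = 0 at x = 0, L
```

with Stokes–Einstein diffusivities `D_n = 24 (27/M_n)^(1/3) µm²/s`
(anchored at cytosolic GFP, 27 kDa) and travelling-wave MOMP inputs
`I_n` with location-dependent onset times `t_on(x) = x / v_wave`.

The package answers, in silico: does free cytosolic diffusion erase the
MOMP anisotropy before effector caspases act? It provides

* the reconstructed HeLa execution network as a plain-text, fully
  overridable model file, with perturbation variants (caspase-feedback
  knockouts, 10× accelerated kinetics, apoptosome immobilisation,
  diffusivity scaling);
* a stiff method-of-lines solver (`deSolve::lsodes`, compiled RHS) and a
  single-point ODE mode that doubles as the no-diffusion oracle;
* anisotropy metrics: substrate-cleavage fractions, threshold crossing
  times (1 % onset, 50 % half-maximal), end-to-end delays, diffusivity
  sweeps, and delta-to-reference comparisons;
* a slab-versus-sphere dimensionality check with an analytic series
  oracle;
* a deterministic scenario runner (YAML configs, delay tables,
  kymograph figures) and a thin CLI (`inst/cli/apoptowave`).

The intended audience is systems-biology modellers studying
spatiotemporal signalling; everything is deterministic and text-based.

## Worked example

Sweep impaired diffusivity and compare the cell ends:

```r
library(apoptowave)

net <- assign_diffusivities(build_reference_network())
tab <- diffusivity_sweep(net, spatial_grid(30, 150),
                         scales = c(1, 100, Inf),     # Inf = no diffusion
                         thresholds = c(0.01, 0.5), t_end = 1200)
print(tab, row.names = FALSE, digits = 4)
```

```
 scenario_id scale threshold near_time_s far_time_s   delay_s
   reference     1      0.01      179.96      180.4   0.39620
   reference     1      0.50      273.01      273.0  -0.01106
   reference   100      0.01       88.21      280.2 191.94705
   reference   100      0.50      166.92      344.6 177.64051
   reference   Inf      0.01       58.63      357.7 299.02839
   reference   Inf      0.50      120.46      419.3 298.80500
```

Reading the table: the MOMP inputs stagger the two cell ends by 300 s.
At reference diffusivities (`scale 1`) the half-maximal substrate
cleavage delay between the ends is ~0.01 s — diffusion has translated a
strongly anisotropic trigger into a homogeneous execution. Without
diffusion (`Inf`) the full ~300 s stagger survives to the output, and a
100-fold impairment sits in between. `render_heatmap(field)` draws the
corresponding distance × time cleavage map, and

```r
ko  <- apply_variant(net, "no_c3_autoprocessing")
d   <- delta_to_reference(diffusivity_sweep(ko, ...), tab)
```

quantifies how network perturbations shift the anisotropy (negative
`delta_s` = reduced anisotropy).

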