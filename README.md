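# zygoloop

Cohesin-mediated loop extrusion shapes the first chromatin architecture of the
mammalian embryo: in mouse zygotes, removing cohesin (Scc1 deletion) abolishes
chromatin loops and TADs, while blocking cohesin release (Wapl deletion)
enlarges and strengthens them. zygoloop is an R package for modelling and
quantifying this biology from sparse single-nucleus Hi-C (snHi-C) data. It is
written for chromatin biologists and polymer modellers who want to simulate
loop extrusion, measure contact-map features from per-nucleus contact lists,
and infer extrusion parameters from contact-probability curves.

The package has four coupled layers:

1. **1-D loop-extrusion dynamics** (`run_lef_dynamics()`): a fixed number of
   loop-extruding factors (LEFs) on a monomer lattice, with processivity λ
   (mean genomic length extruded before release; per-step release probability
   `2·monomer_bp/λ`), separation `d` (genome length per bound LEF, the
   inverse cohesin density), boundary monomers that stall a leg with
   probability 0.995 per step (a mean delay of 200 steps), and mutual
   blocking, which makes extruded loops nested or disjoint.
2. **A coarse 3-D polymer layer** (`evolve_with_extrusion()`): an overdamped
   Langevin bead–spring chain in a periodic box, with a harmonic bond across
   each extruded loop, contact capture at a 75-nm radius, concave-hull
   surface/volume of the fiber (`hull_metrics()`), and trans-contact
   fractions (`trans_fraction()`).
3. **snHi-C feature statistics**: contact-probability curves P_c(s) with
   smoothed log–log slopes (`compute_pcs()`, `pcs_slope()`), aggregate loops
   and TADs with strength scalars (`average_loops()`, `average_tads()`),
   compartment saddles (`compartment_saddle()`), insulation profiles
   (`insulation_profile()`), in-silico pronucleus sorting
   (`classify_pronucleus()`: maternal chromatin carries a 10–30 Mb contact
   plateau), and bootstrap/permutation statistics for sparse maps
   (`bootstrap_loop_strength_ci()`, `permutation_test_loop_strength()`).
4. **Inference**: the position of the maximum of d log P_c / d log s tracks
   the average extruded loop size, and the depth of the subsequent minimum
   tracks cohesin density (`infer_extruded_loop_size()`);
   `match_simulation_parameters()` matches an experimental curve to a
   simulated processivity–separation sweep.

A synthetic single-nucleus generator (`generate_cell()`, `generate_panel()`)
with analytically calibrated planted loops, TADs, compartments and the
maternal plateau makes every stage testable without external data. See the
methods vignette (`vignettes/zygoloop-methods.Rmd`) for the models, numerical
choices and known limitations.

## Worked example

Simulate the control-zygote parameter set (processivity 120 kb, one cohesin
per 120 kb), measure the extruded loops, and run the slope inference on a
contact-probability curve built from the same loop configurations:

```r
library(zygoloop)

params <- lef_params(30000, processivity_bp = 120e3, separation_bp = 120e3,
                     n_steps = 4000)
stats <- run_lef_dynamics(params, build_boundary_map(30000),
                          record_every = 10, seeds = 1:10)
glance(stats)
#> # A tibble: 1 × 6
#>   mean_loop_bp n_spans n_replicates n_lefs processivity_bp separation_bp
#>          <dbl>   <int>        <int>  <int>           <dbl>         <dbl>
#> 1       76455.  301500           10    150          120000        120000

curve <- pcs_from_loops(stats, pairs_per_bin = 300, capture_radius = 3, seed = 1)
infer_extruded_loop_size(pcs_slope(curve))
#> <extrusion_estimate> loop size 55.2 kb; density signature 1.162 (minimum at 0.76 Mb)
```

The mean extruded loop (76.5 kb here) is well below the 120-kb processivity
because LEFs stall at boundaries and at each other; the slope-derivative
inference recovers that scale (55 kb, within a factor 1.4) from the contact
curve alone, plus a density signature from the dip beyond it.

Synthetic maternal nuclei are recognised by their long-range plateau:

```r
panel <- generate_panel(4, "control", "maternal", n_contacts = 30000, seed = 1)
sort_pronuclei(panel$contacts, panel$genome, phase = "G1")
#> # A tibble: 4 × 2
#>   nucleus label
#>     <int> <chr>
#> 1       1 maternal
#> 2       2 maternal
#> 3       3 maternal
#> 4       4 maternal
```

Each result type has an `autoplot()` method (P_c(s) curves, aggregate loop
and TAD maps, saddles, insulation profiles, loop-size histograms), and
`tidy()`/`glance()` methods return tibbles for downstream work. A YAML-driven
`run_pipeline()` chains sorting, P_c(s), inference and the feature analyses
into one JSON report.

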