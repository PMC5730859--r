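---
title: "Models and methods in zygoloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in zygoloop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

zygoloop models how cohesin-mediated loop extrusion shapes chromosome
organisation in the mouse zygote, and quantifies the corresponding features of
sparse single-nucleus Hi-C (snHi-C) contact maps. This vignette records the
models, the estimators, the numerical choices, and the known limits of each —
the information a user needs to judge what a passing test suite does and does
not establish.

## The 1-D loop-extrusion model

Chromatin is a lattice of monomers of `monomer_bp` (default 600 bp; chosen so
that the 3-D contact capture radius of 5 monomer diameters equals 75 nm at
15 nm per monomer). A fixed number of loop-extruding factors (LEFs, here
cohesin) live on the lattice; each holds two legs that translocate
divergently, one site per extrusion step, extruding a loop.

* **Processivity** λ (`processivity_bp`) is the mean genomic length an
  unobstructed LEF extrudes before release. Both legs advance one monomer per
  step, so the per-step release probability is `2 * monomer_bp / λ`. Release
  is memoryless; a released LEF rebinds immediately at a uniformly random
  free adjacent site pair, keeping the number of bound LEFs constant at
  `floor(L / d)`, where the **separation** `d` is genome length per bound LEF
  (the inverse linear cohesin density).
* **Boundaries** (`build_boundary_map()`) are monomers that stall a leg
  sitting on them with probability 0.995 per step, i.e. a mean delay of 200
  extrusion steps, bidirectionally. The default pattern places 15 boundaries
  per 10,000-monomer tile (TADs of 180 kb–1.02 Mb, mean 400 kb).
* **Blocking**: a move onto an occupied site or off the lattice is rejected;
  legs of different LEFs never pass each other, so extruded loops are always
  nested or disjoint (laminar).
* **Update order**: each step processes LEFs in a freshly shuffled order,
  release/rebind before movement, to avoid directional bias.

A useful consequence of the memoryless release: the *snapshot* mean span of an
isolated, unobstructed LEF is ≈ λ (the stationary age distribution of a
geometric lifetime is geometric with the same mean), not λ/2. With crowding
and boundaries the realised mean loop is well below λ: the control parameter
set (λ = 120 kb, d = 120 kb) yields ≈ 74–77 kb.

Loop-size statistics (`run_lef_dynamics()`) average spans
`(right − left) · monomer_bp` over snapshots in the second half of the
trajectory, pooled over replicate seeds; nested loops count with their full
spans. The averaging window is a package choice (the stationary regime is
reached within the first half for all parameter sets used here).

## The 3-D polymer layer

`evolve_with_extrusion()` advances an overdamped Langevin bead–spring chain
(kT = 1, friction = 1, length unit = monomer diameter): harmonic bonds of
stiffness 40 and rest length 1, a soft linear-ramp repulsion (ε = 10 within
one diameter), and one harmonic bond across each extruded loop, updated after
every extrusion step (default 2,000 integration steps per extrusion step; the
desk-scale tests use 60–150). The time step is 0.01. These choices reproduce
contact statistics of chromatin-scale polymer models without requiring a
particular MD engine; mean bond length stays within ~6% of rest length.

Coordinates are kept **unwrapped**; the periodic box (side set by the monomer
volume fraction `density`) applies to the excluded-volume force and to
inter-chain contact detection only. Intra-chain contacts are measured on the
true chain geometry, which removes the spurious background of contacts
between a chain and its own periodic image; such image contacts are still
reported (flagged `"self_image"`) and can be counted as trans.

Initial states: `fractal_globule` (vertices of a 3-D Hilbert curve — compact,
unentangled, subchain extent ~ s^(1/3)); `mitotic_like` (consecutive
~100-monomer loops stacked along an axis); `random_walk` (an equilibrium
ideal-chain draw). For the cohesin-free (zero-LEF) limit the package samples
independent random-walk conformations with a brief relaxation: at nuclear
densities excluded volume is screened beyond a short blob scale, so the
equilibrium reference state is an ideal chain and its contact probability
follows s^-1.5. Annealing a fractal globule to equilibrium instead would take
orders of magnitude more integration than a desk-scale budget allows; the
sampled ensemble is the distribution that anneal converges to at the measured
scales.

**Finite capture radius and the apparent scaling exponent.** Contacts are
captured within a radius of 5 monomer diameters by default (75 nm; 2 and 10
are standard alternates). At 600 bp monomers, a radius of 5 is *not* small
compared with the spatial spread of an ideal chain at 100 kb separations, and
the resulting saturation biases the apparent log–log slope upward by ~0.1
over 100 kb–1 Mb. The equilibrium-scaling validation therefore captures at
radius 2, where the bias is below 0.01 (verified against the closed-form
Gaussian capture probability). Loop-size inference is insensitive to this
choice; the slope *value* is not.

**Hull metrics.** The chromatin fiber surface is modelled as the union of
spheres of radius 75 nm (the capture radius) centred on monomers — the
concave hull at that scale. Surface area uses deterministic Shrake–Rupley
point counting (Fibonacci directions); volume uses an unbiased per-sphere
Monte Carlo estimator with inverse-multiplicity weights. Both agree with a
voxelization oracle within 5% and with closed forms for one or two spheres to
three digits.

## snHi-C feature statistics

All coordinates are 0-based, half-open; contact lists are canonical
(`chrom1 <= chrom2`, `pos1 <= pos2` intra). Multi-nucleus data are pooled by
summing windows or matrices, not by averaging per-nucleus ratios — the only
stable choice for maps with ~10^4–10^5 contacts per nucleus.

* **P_c(s)** (`compute_pcs()`): separations at the 10-kb bin level, grouped
  into logarithmic bins of factor 1.3, each bin's contact count divided by
  the genome-wide number of locus pairs at those separations. Slopes
  (`pcs_slope()`) are central differences after Gaussian smoothing (sigma 0.8
  bins, reflected boundaries) of both log axes.
* **Aggregate loops** (`average_loops()`): 20 × 20 windows at 10 kb centred
  on loop pixels, pooled over nuclei, averaged over loops, divided by the
  average of the same windows displaced along the diagonal (100 shifts on an
  even grid from 100 kb to 1.1 Mb; a deterministic grid rather than random
  draws, so reruns are identical), background rescaled to 1 on the corner
  boxes. **Loop strength** is the mean of the central 6 × 6 box over the mean
  of the two corner 6 × 6 boxes at the same diagonal distance, minus 1 — the
  fractional contact enrichment at the loop. Anchors whose window would cross
  the diagonal (separation ≤ 200 kb at the default window) or leave the
  chromosome are skipped with a warning.
* **Aggregate TADs** (`average_tads()`): each TAD (consecutive boundaries,
  100 kb–1 Mb) plus equal flanks is observed/expected-normalised by the
  per-chromosome mean contact count at each bin separation (pooled before
  division), rescaled to 90 × 90 by area-weighted interpolation, and
  averaged. **TAD strength** is the half-weighted flank-to-TAD sum over the
  TAD-interior sum; note the orientation: a featureless map gives 1 and
  *stronger* TADs give a *smaller* ratio.
* **Compartment saddle** (`compartment_saddle()`): bins ranked by GC content
  (the A/B proxy), split into 5 genome-wide percentile groups; the group-pair
  interaction is the ratio of summed observed counts to summed expected
  counts (robust for sparse maps, where the mean of per-pixel ratios
  explodes). The 5 × 5 matrix is iteratively corrected to equal row sums
  (relative tolerance 1e-9). **Compartment strength** is
  `log(AA * BB / (AB * BA))` over the corners.
* **Insulation** (`insulation_profile()`): the sliding 40-kb diamond sum with
  its tip on the diagonal, normalised per chromosome by the profile minimum
  and shifted so the deepest valley is 0, then averaged across boundaries
  aligned at offset 0 (mean ± SE). The per-profile minimum is used (rather
  than per-boundary-window) so profiles from different chromosomes share a
  scale; a zero minimum falls back to the smallest positive score with a
  warning.
* **Pronucleus sorting** (`classify_pronucleus()`): curves are normalised to
  1 at the log bin nearest 9 kb; nuclei with P_c(30 kb) < 0.1 are excluded as
  bad data; in G1, maternal means P_c(15 Mb) > 1e-4; in G2, maternal means
  P_c(20 Mb) > 2.5e-5. Maternal chromatin is distinguished by its 10–30 Mb
  contact plateau.

## Loop-size and density inference from the P_c(s) derivative

The location of the (least negative) local maximum of the smoothed log–log
slope closely tracks the mean extruded loop size, and the depth of the
subsequent local minimum grows with the linear density of extruders.
`infer_extruded_loop_size()` implements this with explicit numerical rules:

* extrema require dominance over a ±3-bin neighbourhood and a minimum
  prominence of 0.02 on both sides, so a pure power law (monotone slope)
  yields `no_maximum_detected` rather than a noise spike;
* the loop-size shoulder is the *first* qualifying maximum — later maxima are
  the recovery of the slope beyond the density dip;
* in strongly compacted regimes the shoulder broadens into a plateau; the
  reported location is the left edge of the region within 0.05 of the
  maximum, which reduces to the peak for a rounded maximum;
* the dip is the deepest point beyond the shoulder (the slope need not
  recover within the observable range); `density_signature` is the slope at
  the shoulder minus the slope at the dip, a non-negative number invariant to
  additive slope offsets. When no dip exists (very low cohesin density, the
  Scc1-depleted phenotype) a flag is set instead of an error.

**The Gaussian-network surrogate** (`pcs_from_loops()`) turns 1-D loop
configurations into P_c(s) curves without 3-D dynamics. A loop-extruded
phantom chain is a network of springs — the backbone plus a stiff bond across
each loop — and for Gaussian networks the variance of the vector between two
monomers is the network's effective resistance between them. Because blocking
makes loops laminar, the network is series–parallel and the resistance is
computed exactly in ~O(depth) per pair. The pair contact probability is the
exact Gaussian capture probability `P(chi2_3 <= 3 r^2 / R_eff)` at capture
radius r (default 5 monomers; the sweep validation uses 3), which saturates
for pairs effectively closer than the capture radius — without this
saturation the inferred shoulder sits at ~0.6× the true loop size, with it
the inference matches a desk-scale 3-D check. The loop-closing bond
resistance defaults to 0.25 monomer units (the LEF holds its anchors within a
fraction of a monomer).

**Validity domain.** Across the 5 × 6 processivity–separation sweep the
inferred shoulder lies within a factor 1.5 of the true mean extruded loop in
every dense-regime cell, and the density signature increases with 1/d at
fixed processivity through the moderate regime (λ ≤ ~480 kb). At the extreme
of crowding (λ = 960 kb with d ≤ 60 kb) the contact-probability shoulder
saturates, the dip shallows, and the signature stops discriminating density —
it peaks near d ≈ 120 kb and declines toward the densest cells. The
acceptance suite asserts the monotonicity claim as stated and that clause
fails for the λ = 960 kb row; this is a genuine limit of the signature at
full crowding, not a sampling artefact (6-seed averages reproduce it).

`match_simulation_parameters()` matches an experimental curve to a sweep
library by mean squared log-difference over 30 kb–3 Mb after normalising both
curves at the 9-kb reference; the window excludes the cohesin-independent
long-range (>10 Mb) features. The top three candidates are reported.

## Resampling statistics

* `bootstrap_loop_strength_ci()`: loops are resampled with replacement,
  pooled across nuclei (single-cell loops are too sparse to resample within
  nuclei); the aggregate and its strength are recomputed per resample and the
  95% interval is read from the sorted statistics. Coverage on synthetic
  panels with known enrichment is 94–95%.
* `permutation_test_loop_strength()`: the observed statistic is the
  difference of pooled group strengths; the null permutes nucleus labels
  (loops within a nucleus stay together), and the two-sided p-value carries
  the +1 correction so p is never 0. Null p-values are uniform
  (Kolmogorov–Smirnov distance < 0.1 over 500 null panels).

## The synthetic single-nucleus generator

`generate_cell()` draws contacts i.i.d. from a mixture: a trans component
(uniform pairs on distinct chromosomes, probability `trans_fraction`), and an
intra component whose separation follows a continuous piecewise power law,
with optional redirection onto planted features. The planting is calibrated
analytically so the estimators have known expectations:

* **Loops**: extra contacts at anchor pixels (spread over a 3 × 3
  neighbourhood, all inside the central 6 × 6 strength box) with total mass
  `36 · ε · b_a` per anchor, where `b_a` is the analytic background count of
  one pixel at the anchor separation — so the expected measured loop strength
  equals the requested `loop_enrichment` ε exactly, with no attenuation.
* **TADs**: contacts redirected into TAD interiors with the background
  separation law truncated to the TAD, at a mass giving the requested average
  interior enrichment.
* **Compartments**: a fraction of background contacts re-drawn until both
  ends share a compartment (GC above/below median of the blocky synthetic GC
  track), monotone in `compartment_weight`.
* **Maternal plateau**: a fraction of intra contacts drawn log-uniformly from
  10–30 Mb.

The genotype presets encode the observed phenotypes as generator conditions:
`control` (loop strength 1.0, TAD enrichment 2.0, compartment weight 0.15,
trans 8%, P_c(s) shoulder at 40–120 kb), `scc1` (no loops or TADs, clean
s^-1.5 background, stronger compartments 0.30, trans 12%), `wapl` (stronger
larger loops 1.5, weaker compartments 0.08, trans 6%, shoulder at
80–250 kb). Maternal presets add the plateau at weight 0.12 — large enough
that the classification thresholds separate maternal from paternal with an
order-of-magnitude margin at 30,000 contacts per nucleus. Long-range decay
beyond a few Mb is steeper in the presets than a bare power law (exponents
−2.5 to −3.3, G2 steeper than G1), reflecting how measured paternal curves
plunge at these separations; with a shallow −1.5 tail on 50-Mb synthetic
chromosomes the paternal curves would sit above the maternal thresholds,
which real paternal data do not.

What the generator does *not* emulate: amplification and digestion biases of
the snHi-C protocol, realistic anchor/boundary distributions (annotations are
regular and well separated so that shifted controls never overlap a
neighbouring loop), chromosome-specific contact biases, and any coupling
between features. Passing recovery tests on these panels shows the estimators
are correct and calibrated, not that they are robust to protocol artefacts.

## Desk-scale problem sizes

The test suite runs every stage at reduced scale, chosen so each check keeps
clear statistical margins: 1-D loop statistics at 10,000–30,000 monomers and
1,000–4,000 steps with 2–10 seeds; the zero-LEF scaling limit from 100
independent 30,000-monomer conformations; the geometry/trans sweep with six
1,000-monomer chains per box, three regimes and three replicates; synthetic
panels of 10^4–10^6 contacts per nucleus; 160 panels for bootstrap coverage
and 500 for permutation-null uniformity. Full-scale presets (30,000-monomer
sweeps, 100,000-monomer final models, 2,000 integration steps per extrusion
step) are available through the same functions.

## Known limitations

* The density signature saturates at extreme cohesin crowding (above).
* The geometry/trans sweep measures a relaxation trend from an intermingled
  initial state at desk scale, not the full-scale steady state; very strong
  extrusion quenched from a mixed state can transiently trap other chains'
  segments, which is why the sweep uses three well-separated regimes and
  replicate averaging.
* Iterative correction is applied only to the 5 × 5 saddle; single-nucleus
  maps are too sparse to balance genome-wide.
* Loop and TAD calling are out of scope; annotations are inputs.
* The TAD-strength ratio decreases for stronger TADs; comparisons should use
  the documented orientation.
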