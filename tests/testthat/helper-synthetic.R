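# Shared fixtures: small genomes and quick synthetic cells built in code.

tiny_genome <- function(n_chroms = 2L, size = 20e6) {
  synthetic_genome(n_chroms, size)
}

# a featureless cell: single power-law background, no planted structure
flat_spec <- function(n_contacts = 50000L, exponent = -1.5, seed = 1L,
                      genome = synthetic_genome(), trans_fraction = 0.05) {
  synthetic_spec(
    genome = genome, n_contacts = n_contacts,
    pieces = tibble::tibble(s_lo = 10e3, s_hi = min(genome$size),
                            exponent = exponent),
    trans_fraction = trans_fraction, seed = seed)
}

# a quick loop-only spec on the default genome
loop_spec <- function(enrichment = 1.0, n_contacts = 50000L, seed = 1L,
                      genome = synthetic_genome(),
                      anchors = synthetic_loop_anchors(genome)) {
  synthetic_spec(
    genome = genome, n_contacts = n_contacts,
    loop_anchors = anchors, loop_enrichment = enrichment,
    trans_fraction = 0, seed = seed)
}
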