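Package: chromolin
Title: Single-Cell Lineage Analytics for Bacterial Chromosome Segregation
Version: 0.2.0
Authors@R:
    person("Repo", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Tools for quantifying nonrandom sister-chromosome segregation in
    rod-shaped bacteria from tracked single-cell time-lapse data. Builds
    division forests from tracked-cell tables and propagates cell-pole ages;
    detects anucleate divisions and attributes them to the old or new mother
    pole; computes locus demographs, chromosome-arm distances, opposite-half
    fractions and translational-versus-mirror sister configurations; counts
    debounced chromosome orientation flips and length-resolved flip hazards;
    measures replisome/clamp focus colocalization at the diffraction limit and
    localization-profile widths; and scores ancestral ("immortal") DNA strand
    retention at the older cell pole from pulse-chase label and polar
    chemoreceptor intensities. Ships a seeded generative simulator of
    mother-machine and agarose-pad experiments (strand-level semiconservative
    bookkeeping, orientation flipping, pulse-chase labeling, pole aging) in
    both a mechanistic mode, where the observables emerge from the segregation
    model, and a phenomenological mode, where each observable is governed by a
    direct probability parameter, so that every analysis stage is verifiable
    at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
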