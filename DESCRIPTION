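Package: chromaxent
Title: Maximum-Entropy Inference of Single-Cell Chromosome Conformations
    from Hi-C Contact Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the least-structured (maximum-entropy) distribution of
    single-cell chromosome conformations consistent with a normalized Hi-C
    contact map, for a circular bacterial chromosome modelled as a phantom
    ring polymer on a cubic lattice inside a spherocylindrical cell. Pair
    couplings (Lagrange multipliers) are fitted by inverse Monte Carlo and
    the Hi-C score-to-contact-frequency conversion factor is fixed by the
    entropy-maximization constraint. Includes a Metropolis sampler with an
    exact-enumeration oracle, an exact sequential sampler for the confined
    random-polymer baseline, synthetic ground-truth generators, and the
    downstream ensemble statistics: locus position distributions, axial,
    radial and angular two-point correlations, Super-Domain detection and
    inter-arm overlap, local chromosomal extension, density rendering, and
    per-locus localization information in bits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
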