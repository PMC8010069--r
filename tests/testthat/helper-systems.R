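# Shared fixture builders. Everything is generated in code; no stored data.

# tiny 2x2x2 box + 4-monomer ring (every monomer a region center): the
# exhaustively enumerable reference system
tiny_system <- function() {
  list(conf = lattice_box(2, 2, 2), topo = chain_topology(4, 1))
}

# small spherocylinder matching the synthetic-test density (30 monomers in
# 24 sites ~ paper-scale chain density)
small_system <- function(n_regions = 10, b = 88) {
  list(conf = spherocylinder_confinement(b = b, diameter = 3 * b, cell_length = 7 * b),
       topo = chain_topology(n_regions, 2))
}

# look up 1-based site ids for a matrix of half-integer lattice coordinates
site_ids_for <- function(conf, coords) {
  ids <- chromaxent:::site_id_of(coords[, 1], coords[, 2], coords[, 3],
                                 conf$box_lookup, conf$box_lo, conf$box_dims) + 1L
  stopifnot(all(ids > 0))
  ids
}

# fabricate an ensemble from explicit center coordinates (list of S
# matrices n x 3, half-integer lattice units of conf); chain connectivity
# is irrelevant for the analysis operations under test
toy_ensemble <- function(coord_list, conf, bin_size = 1e4, oriented = TRUE) {
  n <- nrow(coord_list[[1]])
  centers <- t(vapply(coord_list, function(m) site_ids_for(conf, m), integer(n)))
  if (n == 1) centers <- matrix(centers, ncol = 1)
  # hand-made topology: toy fixtures need not satisfy ring-parity rules
  topo <- structure(list(N = n, n_regions = as.integer(n), m = 1L,
                         bin_size = bin_size,
                         region_centers = seq_len(n), circular = TRUE),
                    class = "chain_topology")
  structure(list(center_sites = centers, monomer_sites = NULL,
                 topo = topo,
                 conf = conf, oriented = oriented, acceptance = NA_real_,
                 provenance = list(sampler = "toy", seed = NA)),
            class = "chromo_ensemble")
}

# independent brute-force membership check used against the geometry module
brute_force_sites <- function(b, diameter, cell_length) {
  r <- diameter / 2
  kmax <- ceiling(cell_length / b) + 2
  cand <- expand.grid(x = seq(-kmax, kmax) + 0.5, y = seq(-kmax, kmax) + 0.5,
                      z = seq(-kmax, kmax) + 0.5)
  half_cyl <- cell_length / 2 - r
  dz <- pmax(abs(cand$z * b) - half_cyl, 0)
  keep <- (cand$x * b)^2 + (cand$y * b)^2 + dz^2 <= r^2 + 1e-9
  m <- as.matrix(cand[keep, ])
  m[order(m[, 3], m[, 2], m[, 1]), , drop = FALSE]
}
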