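#' Lattice spherocylinder confinement
#'
#' Enumerates all cubic-lattice sites contained in a spherocylinder (a
#' cylinder of diameter `diameter` along the long z-axis, capped by two
#' hemispheres; total pole-to-pole extent `cell_length`). Lattice sites sit
#' at half-integer multiples of the lattice spacing `b` relative to the cell
#' center, so the site set carries exact x/y/z reflection symmetry and splits
#' exactly into eight octants by coordinate signs. A site is accessible iff
#' its center satisfies the continuous spherocylinder inequality; points
#' exactly on the surface are included.
#'
#' @param b lattice spacing in nm (default 88 nm, the mean spatial distance
#'   between consecutive 10-kb genomic regions).
#' @param diameter cell diameter in nm (default 630 nm, newborn swarmer cell
#'   minus envelope).
#' @param cell_length total pole-to-pole length in nm (default 2200 nm).
#' @return An object of class `confinement`: list with `b`, `diameter`,
#'   `cell_length`, `sites` (M x 3 numeric matrix of coordinates in nm,
#'   columns x, y, z), `M` (site count), plus internal lookup tables used by
#'   the samplers.
#' @examples
#' conf <- spherocylinder_confinement(b = 1, diameter = 2, cell_length = 3)
#' conf$M  # the 2 x 2 x 2 site box
#' @export
spherocylinder_confinement <- function(b = 88, diameter = 630, cell_length = 2200) {
  stopifnot(b > 0)
  if (diameter > cell_length)
    stop("diameter must not exceed cell_length (spherocylinder geometry)")
  if (diameter < 2 * b)
    stop("degenerate geometry: diameter < 2 * b leaves no interior cross-section")
  r <- diameter / 2
  # candidate half-integer coordinates (units of b) covering the bounding box
  half_span <- function(extent) {
    kmax <- ceiling(extent / (2 * b) + 0.5)
    (seq_len(2 * kmax) - kmax - 0.5)
  }
  xs <- half_span(diameter)
  zs <- half_span(cell_length)
  grid <- expand.grid(x = xs, y = xs, z = zs)
  keep <- in_spherocylinder(grid$x * b, grid$y * b, grid$z * b, r, cell_length)
  sites_lat <- as.matrix(grid[keep, , drop = FALSE])
  if (nrow(sites_lat) == 0L) stop("degenerate geometry: no accessible lattice sites")
  # deterministic ordering: z, then y, then x
  ord <- order(sites_lat[, 3], sites_lat[, 2], sites_lat[, 1])
  sites_lat <- sites_lat[ord, , drop = FALSE]
  dimnames(sites_lat) <- list(NULL, c("x", "y", "z"))
  out <- list(
    b = b, diameter = diameter, cell_length = cell_length,
    sites_lat = sites_lat,          # half-integer lattice units
    sites = sites_lat * b,          # nm
    M = nrow(sites_lat)
  )
  out <- c(out, build_site_tables(sites_lat))
  class(out) <- "confinement"
  out
}

#' Point-in-spherocylinder test
#'
#' Continuous membership inequality for the capped cylinder: inside the
#' central section the constraint is radial only; inside the caps the point
#' must lie within the hemispherical ball. Surface points are inside.
#'
#' @param x,y,z coordinates in nm (vectors).
#' @param radius spherocylinder radius in nm.
#' @param cell_length total pole-to-pole extent in nm.
#' @return logical vector.
#' @export
in_spherocylinder <- function(x, y, z, radius, cell_length) {
  half_cyl <- cell_length / 2 - radius  # half-length of the cylindrical section
  dz <- pmax(abs(z) - half_cyl, 0)
  x^2 + y^2 + dz^2 <= radius^2 + 1e-9
}

# Lookup tables: dense box index -> site id, neighbor list, mirror permutation.
build_site_tables <- function(sites_lat) {
  # doubled coordinates are odd integers; shift to positive box indices
  dc <- 2 * sites_lat
  lo <- apply(dc, 2, min)
  dims <- (apply(dc, 2, max) - lo) / 2 + 1
  ijk <- sweep(dc, 2, lo) / 2  # 0-based integer box coordinates
  box_id <- ijk[, 1] + dims[1] * (ijk[, 2] + dims[2] * ijk[, 3])
  lookup <- rep.int(-1L, prod(dims))
  lookup[box_id + 1] <- seq_len(nrow(sites_lat)) - 1L  # 0-based site ids
  # neighbor ids (0-based, -1 = outside), M x 6: -x, +x, -y, +y, -z, +z
  steps <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  nb <- matrix(-1L, nrow(sites_lat), 6)
  for (s in 1:6) {
    nijk <- sweep(ijk, 2, steps[s, ], "+")
    ok <- nijk[, 1] >= 0 & nijk[, 1] < dims[1] &
      nijk[, 2] >= 0 & nijk[, 2] < dims[2] &
      nijk[, 3] >= 0 & nijk[, 3] < dims[3]
    id <- rep.int(-1L, nrow(sites_lat))
    id[ok] <- lookup[nijk[ok, 1] + dims[1] * (nijk[ok, 2] + dims[2] * nijk[ok, 3]) + 1]
    nb[, s] <- id
  }
  # z-mirror permutation (1-based site ids): site -> site with z negated
  mirr <- site_id_of(sites_lat[, 1], sites_lat[, 2], -sites_lat[, 3],
                     lookup, lo, dims) + 1L
  list(box_lo = lo, box_dims = dims, box_lookup = lookup,
       neighbors = nb, z_mirror = mirr)
}

# vectorized lattice-coordinate -> 0-based site id (-1 if not a site)
site_id_of <- function(x, y, z, lookup, lo, dims) {
  i <- (2 * x - lo[1]) / 2
  j <- (2 * y - lo[2]) / 2
  k <- (2 * z - lo[3]) / 2
  out <- rep.int(-1L, length(x))
  ok <- i >= 0 & i < dims[1] & j >= 0 & j < dims[2] & k >= 0 & k < dims[3] &
    i == round(i) & j == round(j) & k == round(k)
  out[ok] <- lookup[i[ok] + dims[1] * (j[ok] + dims[2] * k[ok]) + 1]
  out
}

#' @export
print.confinement <- function(x, ...) {
  cat(sprintf(
    "Lattice spherocylinder confinement: b = %g nm, %g x %g nm, M = %d sites (log2 M = %.2f bits)\n",
    x$b, x$diameter, x$cell_length, x$M, log2(x$M)))
  invisible(x)
}

#' Full rectangular lattice box (testing geometry)
#'
#' A plain nx x ny x nz block of lattice sites, mainly used for exhaustive
#' enumeration oracles where the spherocylinder shape is irrelevant.
#'
#' @param nx,ny,nz site counts along each axis.
#' @param b lattice spacing in nm.
#' @return a `confinement` object.
#' @export
lattice_box <- function(nx, ny, nz, b = 1) {
  stopifnot(nx >= 1, ny >= 1, nz >= 1)
  ax <- function(n) seq_len(n) - (n + 1) / 2
  grid <- expand.grid(x = ax(nx), y = ax(ny), z = ax(nz))
  sites_lat <- as.matrix(grid)[order(grid$z, grid$y, grid$x), , drop = FALSE]
  dimnames(sites_lat) <- list(NULL, c("x", "y", "z"))
  out <- list(b = b, diameter = NA_real_, cell_length = NA_real_,
              sites_lat = sites_lat, sites = sites_lat * b, M = nrow(sites_lat))
  out <- c(out, build_site_tables(sites_lat))
  class(out) <- "confinement"
  out
}

#' Chain topology of the coarse-grained circular chromosome
#'
#' The chromosome is a circular phantom chain of `N = monomers_per_region *
#' n_regions` monomers on the lattice; every `monomers_per_region`-th monomer
#' is the center of one genomic region (one Hi-C bin). Region `k` covers the
#' half-open genomic interval `[(k-1) * bin_size, k * bin_size)`.
#'
#' `monomers_per_region` must be even in any fitting application: the cubic
#' lattice is bipartite, so monomers an odd number of bonds apart can never
#' co-occupy a site, and an odd spacing would make every odd-genomic-distance
#' contact constraint unsatisfiable. Odd values are allowed (for tiny oracle
#' systems) but flagged with a warning when above 1.
#'
#' @param n_regions number of genomic regions (Hi-C bins).
#' @param monomers_per_region monomers per region, m (default 2, the even
#'   spacing closest to the measured inter-bin distance; see
#'   [calibrate_monomers_per_region()]).
#' @param bin_size Hi-C bin size in bp (default 10 kb).
#' @return object of class `chain_topology` with fields `N`, `n_regions`,
#'   `m`, `bin_size`, `region_centers` (monomer indices, 1-based).
#' @export
chain_topology <- function(n_regions, monomers_per_region = 2, bin_size = 1e4) {
  stopifnot(n_regions >= 3, monomers_per_region >= 1)
  N <- n_regions * monomers_per_region
  if (N %% 2 != 0)
    stop("N = n_regions * monomers_per_region must be even: a closed walk on the cubic lattice has even length")
  if (monomers_per_region > 1 && monomers_per_region %% 2 != 0)
    warning("odd monomers_per_region: odd-genomic-distance region pairs can never co-occupy a site (lattice parity)")
  out <- list(N = N, n_regions = as.integer(n_regions),
              m = as.integer(monomers_per_region), bin_size = bin_size,
              region_centers = as.integer(seq(1L, N, by = monomers_per_region)),
              circular = TRUE)
  class(out) <- "chain_topology"
  out
}

#' @export
print.chain_topology <- function(x, ...) {
  cat(sprintf("Circular chain: N = %d monomers, %d regions x m = %d, bin = %g bp\n",
              x$N, x$n_regions, x$m, x$bin_size))
  invisible(x)
}

#' Single chromosome configuration
#'
#' A microstate: one lattice position per monomer. Consecutive monomers
#' (including the ring-closing pair) occupy nearest-neighbor sites; the chain
#' is phantom, so non-adjacent monomers may coincide.
#'
#' @param site_ids integer vector of length N, 1-based site ids into
#'   `conf$sites`.
#' @param topo a [chain_topology()].
#' @param conf a [spherocylinder_confinement()].
#' @param oriented logical; TRUE once [orient_configuration()] has been
#'   applied.
#' @param validate check ring connectivity and confinement membership.
#' @return object of class `chromo_config`.
#' @export
chromo_config <- function(site_ids, topo, conf, oriented = FALSE, validate = TRUE) {
  site_ids <- as.integer(site_ids)
  stopifnot(length(site_ids) == topo$N)
  if (validate) {
    if (any(site_ids < 1L | site_ids > conf$M))
      stop("configuration contains sites outside the confinement")
    steplen <- ring_step_lengths(site_ids, conf)
    if (any(abs(steplen - 1) > 1e-9))
      stop("broken ring: consecutive monomers must occupy nearest-neighbor sites")
  }
  structure(list(site_ids = site_ids, topo = topo, conf = conf,
                 oriented = isTRUE(oriented)),
            class = "chromo_config")
}

ring_step_lengths <- function(site_ids, conf) {
  p <- conf$sites_lat[site_ids, , drop = FALSE]
  q <- p[c(2:nrow(p), 1), , drop = FALSE]
  sqrt(rowSums((p - q)^2))
}

#' Scaled long-axis position of a region center
#'
#' Maps a region center's z-coordinate to the fraction of the confinement's
#' axial site extent, 0 at the ori-proximal pole (after orientation) and 1 at
#' the opposite pole.
#'
#' @param config a [chromo_config()].
#' @param region region index (1-based).
#' @return value in `[0, 1]`.
#' @export
scaled_axial_position <- function(config, region) {
  stopifnot(region >= 1, region <= config$topo$n_regions)
  conf <- config$conf
  zr <- range(conf$sites_lat[, 3])
  z <- conf$sites_lat[config$site_ids[config$topo$region_centers[region]], 3]
  unname((z - zr[1]) / (zr[2] - zr[1]))
}

#' Orient a configuration by the ori cell half
#'
#' Cells are oriented by putting the ori pole in the cell half that contains
#' ori: if ori's z-coordinate lies in the upper half (scaled position > 0.5)
#' the whole configuration is mirrored through z -> -z, otherwise it is
#' returned unchanged. With half-integer lattice offsets no site sits exactly
#' at z = 0; should a custom geometry produce scaled position exactly 0.5,
#' the configuration is kept unmirrored. Idempotent, and an isometry (all
#' inter-monomer distances are preserved).
#'
#' @param config a [chromo_config()].
#' @param ori_region region index of ori (default 1).
#' @return the oriented `chromo_config` (field `oriented` set to TRUE).
#' @export
orient_configuration <- function(config, ori_region = 1L) {
  s <- scaled_axial_position(config, ori_region)
  ids <- config$site_ids
  if (s > 0.5) ids <- config$conf$z_mirror[ids]
  config$site_ids <- ids
  config$oriented <- TRUE
  config
}

#' Calibrate monomers-per-region against a measured inter-bin distance
#'
#' Chooses the number of chain monomers per genomic region, m, such that the
#' forward-simulated mean spatial distance between consecutive region centers
#' of the non-interacting confined ring matches a measured value (129 nm
#' between loci 10 kb apart at b = 88 nm).
#'
#' @param conf confinement.
#' @param n_regions number of regions for the calibration chain.
#' @param target_nm measured mean consecutive-bin distance (nm).
#' @param m_candidates candidate m values (even by default — lattice
#'   parity — and those yielding even N are kept).
#' @param n_samples configurations per candidate.
#' @param seed RNG seed.
#' @return list with `m` (selected), and a data.frame `table` of candidate m
#'   vs simulated mean distance.
#' @export
calibrate_monomers_per_region <- function(conf, n_regions = 50, target_nm = 129,
                                          m_candidates = c(2, 4, 6), n_samples = 400,
                                          seed = 1) {
  m_candidates <- m_candidates[(m_candidates * n_regions) %% 2 == 0]
  res <- vapply(seq_along(m_candidates), function(k) {
    m <- m_candidates[k]
    topo <- chain_topology(n_regions, m)
    ens <- random_polymer_baseline(topo, conf, n_samples = n_samples,
                                   seed = derive_seed(seed, k))
    d <- consecutive_center_distances(ens)
    mean(d)
  }, numeric(1))
  tab <- data.frame(m = m_candidates, mean_distance_nm = res)
  list(m = m_candidates[which.min(abs(res - target_nm))], table = tab)
}

# mean over snapshots and regions of the distance between consecutive centers
consecutive_center_distances <- function(ens) {
  n <- ens$topo$n_regions
  S <- nrow(ens$center_sites)
  nxt <- c(2:n, 1)
  ax <- function(a) matrix(ens$conf$sites[ens$center_sites, a], nrow = S)
  x <- ax(1); y <- ax(2); z <- ax(3)
  d <- sqrt((x - x[, nxt, drop = FALSE])^2 + (y - y[, nxt, drop = FALSE])^2 +
            (z - z[, nxt, drop = FALSE])^2)
  matrix(d, nrow = S)
}

# deterministic sub-seed derivation (single root seed, named substreams)
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(k)) %% 2147483647)
}
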