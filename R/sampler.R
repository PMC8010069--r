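#' Symmetric pair-coupling matrix
#'
#' Effective couplings between genomic region centers: two region centers
#' occupying the same lattice site contribute `eps[i, j]` to the
#' dimensionless Hamiltonian `H = 1/2 * sum_ij eps_ij delta(r_i, r_j)`.
#' Forbidden contacts (couplings diverging to +Inf) are carried as a
#' hard-core exclusion mask rather than a large float.
#'
#' @param eps symmetric numeric n x n matrix, zero diagonal.
#' @param infinite_mask symmetric logical n x n matrix of forbidden pairs
#'   (default none).
#' @return object of class `interaction_matrix` with fields `eps`,
#'   `infinite_mask`, `n_regions`.
#' @export
interaction_matrix <- function(eps, infinite_mask = NULL) {
  eps <- as.matrix(eps)
  n <- nrow(eps)
  stopifnot(ncol(eps) == n)
  if (max(abs(eps - t(eps))) > 1e-8) stop("eps must be symmetric")
  eps <- (eps + t(eps)) / 2
  diag(eps) <- 0
  if (is.null(infinite_mask)) infinite_mask <- matrix(FALSE, n, n)
  infinite_mask <- infinite_mask | t(infinite_mask)
  diag(infinite_mask) <- FALSE
  structure(list(eps = eps, infinite_mask = infinite_mask, n_regions = n),
            class = "interaction_matrix")
}

as_interaction_matrix <- function(x, n_regions = NULL) {
  if (inherits(x, "interaction_matrix")) return(x)
  if (is.matrix(x)) return(interaction_matrix(x))
  if (is.null(x)) {
    stopifnot(!is.null(n_regions))
    return(interaction_matrix(matrix(0, n_regions, n_regions)))
  }
  stop("cannot interpret couplings")
}

#' Total energy of a configuration
#'
#' Dimensionless Hamiltonian `H = 1/2 sum_ij eps_ij delta(r_i, r_j)` over
#' region centers; `+Inf` if a forbidden (hard-core) pair co-occupies a site.
#'
#' @param config a [chromo_config()].
#' @param eps an [interaction_matrix()] (or plain symmetric matrix).
#' @return numeric scalar (possibly `Inf`).
#' @export
total_energy <- function(config, eps) {
  eps <- as_interaction_matrix(eps, config$topo$n_regions)
  if (eps$n_regions != config$topo$n_regions) stop("dimension mismatch")
  sites <- config$site_ids[config$topo$region_centers]
  same <- outer(sites, sites, "==")
  diag(same) <- FALSE
  if (any(eps$infinite_mask & same)) return(Inf)
  sum(eps$eps[same]) / 2
}

# deterministic legal start: ring alternating between two adjacent sites
# ("dimer" fold). `anchor_monomer`/`anchor_sites`: force that monomer onto
# one of the given sites (tethering).
initial_ring <- function(topo, conf, anchor_monomer = NULL, anchor_sites = NULL) {
  if (is.null(anchor_sites)) {
    d2 <- rowSums(conf$sites_lat^2)
    s0 <- which.min(d2)  # most central site, deterministic tie-break by order
  } else {
    s0 <- anchor_sites[which.min(rowSums(conf$sites_lat[anchor_sites, , drop = FALSE]^2))]
  }
  nbs <- conf$neighbors[s0, ]
  s1 <- nbs[nbs >= 0][1] + 1L
  if (is.na(s1)) stop("initialization error: start site has no accessible neighbor")
  anchor <- if (is.null(anchor_monomer)) 1L else anchor_monomer
  parity <- (seq_len(topo$N) - anchor) %% 2L
  ifelse(parity == 0L, s0, s1)
}

#' Sample an ensemble of chromosome configurations by Metropolis Monte Carlo
#'
#' Samples the Boltzmann-form maximum-entropy distribution
#' `P(config) = exp(-H)/Z` of the confined phantom ring with couplings `eps`,
#' using single-monomer kink moves, bonded-pair translations, and rigid
#' whole-ring translations (a symmetric, confinement-respecting proposal
#' set; its correctness is certified against [enumerate_ring_ensemble()]).
#' Rejected moves retain the previous configuration, which is counted in
#' all averages.
#'
#' @param eps couplings ([interaction_matrix()] or matrix); `NULL` for the
#'   non-interacting chain.
#' @param topo a [chain_topology()].
#' @param conf a [spherocylinder_confinement()] or [lattice_box()].
#' @param n_samples number of snapshots to record.
#' @param thin_sweeps sweeps between snapshots (1 sweep = N attempted
#'   moves); default `N/2`, check with [snapshot_autocorrelation()].
#' @param burn_in sweeps discarded before the first snapshot (default 50 N).
#' @param seed integer seed (all randomness is drawn from R's RNG).
#' @param keep_monomers record all N monomer positions per snapshot (needed
#'   for [render_density()]), not just the region centers.
#' @param tether optional integer vector of site ids to which the ori region
#'   center is confined (see [pole_tether_sites()]).
#' @param ori_region region whose center the tether applies to.
#' @param p_translate,p_pair proposal mix for rigid translations and pair
#'   moves (remainder: kink moves).
#' @param init optional initial site-id vector (length N legal ring).
#' @return object of class `chromo_ensemble`: `center_sites` (S x n_regions
#'   1-based site ids), optional `monomer_sites`, `topo`, `conf`,
#'   `oriented`, `acceptance`, `provenance`.
#' @export
sample_ensemble <- function(eps, topo, conf, n_samples,
                            thin_sweeps = NULL, burn_in = NULL, seed = 1,
                            keep_monomers = FALSE, tether = NULL,
                            ori_region = 1L,
                            p_translate = 0.02, p_pair = 0.2, init = NULL) {
  stopifnot(n_samples >= 1)
  eps <- as_interaction_matrix(eps, topo$n_regions)
  if (eps$n_regions != topo$n_regions) stop("eps dimension does not match topology")
  if (is.null(thin_sweeps)) thin_sweeps <- max(1L, topo$N %/% 2L)
  if (is.null(burn_in)) burn_in <- 50L * topo$N
  monomer_reg <- rep.int(-1L, topo$N)
  monomer_reg[topo$region_centers] <- seq_len(topo$n_regions) - 1L

  tether_mono <- -1L
  tether_ok <- rep(FALSE, conf$M)
  if (!is.null(tether)) {
    if (length(tether) == 0) stop("empty tether site set")
    tether_mono <- topo$region_centers[ori_region] - 1L
    tether_ok[tether] <- TRUE
  }

  set.seed(seed)
  if (is.null(init)) {
    init <- initial_ring(topo, conf,
                         anchor_monomer = if (tether_mono >= 0) tether_mono + 1L else NULL,
                         anchor_sites = tether)
  }
  # hard-core pairs cannot start co-occupying: pre-thermalize with the
  # exclusions softened to a strong finite repulsion, then verify
  if (any(eps$infinite_mask)) {
    soft <- eps$eps
    soft[eps$infinite_mask] <- 8
    for (attempt in 1:20) {
      pre <- mc_sample_cpp(conf$neighbors, init - 1L, monomer_reg,
                           topo$region_centers - 1L, soft,
                           matrix(FALSE, topo$n_regions, topo$n_regions),
                           burn_sweeps = 20L * topo$N, n_samples = 1L,
                           thin_sweeps = 1L, keep_monomers = TRUE,
                           p_translate = p_translate, p_pair = p_pair,
                           tether_ok = tether_ok, tether_mono = tether_mono)
      init <- pre$monomers[1, ] + 1L
      cs <- pre$centers[1, ] + 1L
      bad <- outer(cs, cs, "==") & eps$infinite_mask
      if (!any(bad)) break
      if (attempt == 20) stop("initialization error: could not reach a configuration clearing all hard-core exclusions")
    }
  }

  res <- mc_sample_cpp(conf$neighbors, init - 1L, monomer_reg,
                       topo$region_centers - 1L, eps$eps, eps$infinite_mask,
                       burn_sweeps = as.integer(burn_in),
                       n_samples = as.integer(n_samples),
                       thin_sweeps = as.integer(thin_sweeps),
                       keep_monomers = keep_monomers,
                       p_translate = p_translate, p_pair = p_pair,
                       tether_ok = tether_ok, tether_mono = tether_mono)
  structure(list(
    center_sites = res$centers + 1L,
    monomer_sites = if (keep_monomers) res$monomers + 1L else NULL,
    topo = topo, conf = conf, oriented = FALSE,
    acceptance = res$acceptance,
    provenance = list(sampler = "metropolis", seed = seed,
                      burn_in = burn_in, thin_sweeps = thin_sweeps,
                      eps_checksum = signif(sum(eps$eps^2), 10),
                      tether = !is.null(tether))
  ), class = "chromo_ensemble")
}

#' @export
print.chromo_ensemble <- function(x, ...) {
  cat(sprintf("Chromosome ensemble: %d snapshots x %d regions (%s sampler, %s)\n",
              nrow(x$center_sites), x$topo$n_regions,
              x$provenance$sampler,
              if (x$oriented) "oriented" else "unoriented"))
  invisible(x)
}

#' Orient every snapshot of an ensemble
#'
#' Applies the ori-pole convention snapshot-wise: configurations whose ori
#' center lies in the upper z cell half are mirrored through z -> -z.
#'
#' @param ens a `chromo_ensemble`.
#' @param ori_region region index of ori (default 1).
#' @return the oriented ensemble.
#' @export
orient_ensemble <- function(ens, ori_region = 1L) {
  z_ori <- ens$conf$sites_lat[ens$center_sites[, ori_region], 3]
  flip <- z_ori > 0
  if (any(flip)) {
    mirr <- ens$conf$z_mirror
    ens$center_sites[flip, ] <- matrix(mirr[ens$center_sites[flip, , drop = FALSE]],
                                       nrow = sum(flip))
    if (!is.null(ens$monomer_sites))
      ens$monomer_sites[flip, ] <- matrix(mirr[ens$monomer_sites[flip, , drop = FALSE]],
                                          nrow = sum(flip))
  }
  ens$oriented <- TRUE
  ens
}

#' Model contact frequencies from an ensemble
#'
#' Two genomic regions are in contact with probability `gamma` when their
#' centers occupy the same lattice site: `f_ij = gamma * P(r_i == r_j)`,
#' estimated as the co-occupancy fraction across snapshots.
#'
#' @param ens a `chromo_ensemble`.
#' @param gamma contact probability factor in (0, 1].
#' @return a [contact_map()] of kind `"model_frequency"`.
#' @export
estimate_contact_frequencies <- function(ens, gamma = 1) {
  stopifnot(gamma > 0, gamma <= 1)
  if (nrow(ens$center_sites) == 0) stop("empty ensemble")
  f <- gamma * cooccupancy_cpp(ens$center_sites)
  contact_map(f, kind = "model_frequency")
}

#' Lag autocorrelation of a snapshot observable
#'
#' Autocorrelation (at the given snapshot lags) of the ori-center axial
#' position, the slowest simple observable; used to verify that
#' `thin_sweeps` exceeds the correlation time.
#'
#' @param ens a `chromo_ensemble`.
#' @param lags integer snapshot lags.
#' @param region region whose axial position is tracked.
#' @return data.frame with `lag` and `acf`.
#' @export
snapshot_autocorrelation <- function(ens, lags = 1:5, region = 1L) {
  z <- ens$conf$sites_lat[ens$center_sites[, region], 3]
  a <- stats::acf(z, lag.max = max(lags), plot = FALSE, demean = TRUE)
  data.frame(lag = lags, acf = a$acf[lags + 1])
}

#' Pole-proximal tether site set
#'
#' Sites whose scaled axial position is below `frac` — the target set used
#' to tether ori near a cell pole in the tethered random-polymer baseline.
#'
#' @param conf confinement.
#' @param frac fraction of the axial extent (default 0.2).
#' @return integer vector of site ids.
#' @export
pole_tether_sites <- function(conf, frac = 0.2) {
  zr <- range(conf$sites_lat[, 3])
  scal <- (conf$sites_lat[, 3] - zr[1]) / (zr[2] - zr[1])
  which(scal < frac)
}
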