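# Synthetic ground truth: coupling matrices with the motifs seen in
# bacterial Hi-C (near-diagonal attraction from domain compaction, a
# secondary anti-diagonal from SMC-mediated arm juxtaposition, sparse
# random couplings), the contact maps they imply, and random-polymer
# baselines. Used for the coupling-recovery validation of the inverse
# algorithm, which closes the loop with zero external inputs.

#' Generate a ground-truth coupling matrix from motif blocks
#'
#' Motifs are superposed additively onto a zero matrix. Supported motif
#' types:
#' \describe{
#'   \item{`near_diagonal`}{`strength` on pairs at circular genomic
#'     distance 2..`width+1` (the distance-0/1 band belongs to chain
#'     connectivity and is left untouched).}
#'   \item{`secondary_diagonal`}{`strength` on inter-arm pairs `(i, j)`
#'     with `(i + j - 2) mod n` within `width` of 0 — the juxtaposed-arm
#'     anti-diagonal through ori.}
#'   \item{`random_sparse`}{independent pairs switched on with probability
#'     `density`, coupling `strength` (negative = attraction).}
#' }
#'
#' @param n_regions matrix dimension.
#' @param motifs list of motif lists, each with `type`, `strength` and the
#'   fields above.
#' @param seed RNG seed (used by `random_sparse`).
#' @return an [interaction_matrix()].
#' @examples
#' eps <- generate_ground_truth(10, list(
#'   list(type = "near_diagonal", strength = -0.8, width = 2),
#'   list(type = "secondary_diagonal", strength = -1.2, width = 1)), seed = 7)
#' @export
generate_ground_truth <- function(n_regions, motifs = list(), seed = 1) {
  n <- n_regions
  e <- matrix(0, n, n)
  idx <- seq_len(n)
  set.seed(seed)
  for (m in motifs) {
    type <- m$type
    if (type == "near_diagonal") {
      width <- if (is.null(m$width)) 1 else m$width
      dmat <- circular_distance(outer(idx, idx, function(a, b) a),
                                outer(idx, idx, function(a, b) b), n)
      sel <- dmat >= 2 & dmat <= width + 1
      e[sel] <- e[sel] + m$strength
    } else if (type == "secondary_diagonal") {
      width <- if (is.null(m$width)) 0 else m$width
      smat <- (outer(idx, idx, "+") - 2) %% n
      sel <- pmin(smat, n - smat) <= width
      dmat <- circular_distance(outer(idx, idx, function(a, b) a),
                                outer(idx, idx, function(a, b) b), n)
      sel <- sel & dmat >= 2
      e[sel] <- e[sel] + m$strength
    } else if (type == "random_sparse") {
      density <- if (is.null(m$density)) 0.1 else m$density
      up <- which(upper.tri(e) &
                  circular_distance(outer(idx, idx, function(a, b) a),
                                    outer(idx, idx, function(a, b) b), n) >= 2)
      on <- up[stats::runif(length(up)) < density]
      add <- matrix(0, n, n)
      add[on] <- m$strength
      e <- e + add + t(add)
      next
    } else stop("unknown motif type: ", type)
  }
  interaction_matrix(e)
}

#' Simulate a normalized Hi-C map from known couplings
#'
#' Long forward Monte Carlo run under `eps_star`; co-occupancy frequencies
#' are divided by `c_true` (so the fitter must also recover the conversion
#' factor) and optionally corrupted with multiplicative log-normal score
#' noise (symmetrized after noising).
#'
#' @param eps_star ground-truth [interaction_matrix()].
#' @param topo,conf system geometry.
#' @param n_samples forward snapshots.
#' @param c_true true conversion factor.
#' @param noise log-normal sigma of the multiplicative score noise (0 =
#'   none).
#' @param seed RNG seed.
#' @param ... passed to [sample_ensemble()].
#' @return a [contact_map()] of kind `normalized_experimental`.
#' @export
simulate_hic_map <- function(eps_star, topo, conf, n_samples = 20000,
                             c_true = 1, noise = 0, seed = 1, ...) {
  stopifnot(c_true > 0, noise >= 0)
  ens <- sample_ensemble(eps_star, topo, conf, n_samples = n_samples,
                         seed = derive_seed(seed, 1), ...)
  f <- estimate_contact_frequencies(ens, gamma = 1)$scores / c_true
  if (noise > 0) {
    set.seed(derive_seed(seed, 2))
    fac <- matrix(exp(stats::rnorm(length(f), sd = noise)), nrow(f))
    f <- f * fac
    f <- (f + t(f)) / 2
  }
  contact_map(f, kind = "normalized_experimental")
}

#' Confined random-polymer baseline ensemble
#'
#' The non-interacting (couplings identically zero) confined ring: the
#' paper-style null against which Hi-C-constrained organization is judged.
#' Sampled *exactly* — every legal ring configuration has equal weight, so
#' i.i.d. configurations are drawn by sequential conditioning on closed-walk
#' counts (powers of the confinement adjacency operator) rather than by
#' Markov-chain relaxation. Optionally the ori region center is tethered to
#' a pole-proximal site set.
#'
#' @param topo,conf system geometry.
#' @param tether `"none"` or `"ori_pole"` (ori constrained to sites with
#'   scaled axial position < `tether_frac`).
#' @param n_samples configurations to draw.
#' @param seed RNG seed.
#' @param ori_region region index of ori.
#' @param tether_frac axial fraction defining the pole set.
#' @param keep_monomers store all monomer positions.
#' @return an unoriented `chromo_ensemble` (apply [orient_ensemble()]
#'   before positional statistics).
#' @export
random_polymer_baseline <- function(topo, conf, tether = c("none", "ori_pole"),
                                    n_samples = 2000, seed = 1,
                                    ori_region = 1L, tether_frac = 0.2,
                                    keep_monomers = FALSE) {
  tether <- match.arg(tether)
  allowed <- if (tether == "ori_pole") pole_tether_sites(conf, tether_frac)
             else seq_len(conf$M)
  if (length(allowed) == 0) stop("empty tether site set")

  # closed-walk counts per start site; reflection symmetries of the site
  # set make counts equal within |x|,|y|,|z| orbits, so only orbit
  # representatives are evaluated
  key_all <- apply(abs(conf$sites_lat), 1, paste, collapse = ",")
  key <- key_all[allowed]
  reps <- !duplicated(key)
  logD_rep <- ring_logcounts_cpp(conf$neighbors, topo$N,
                                 as.integer(allowed[reps] - 1L))
  logD <- logD_rep[match(key, key[reps])]
  if (!any(is.finite(logD)))
    stop("initialization error: no closed chain of this length fits the confinement")
  w <- exp(logD - max(logD, na.rm = TRUE))
  w[!is.finite(w)] <- 0

  set.seed(seed)
  starts <- allowed[sample.int(length(allowed), n_samples, replace = TRUE, prob = w)]
  walks <- ring_exact_sample_cpp(conf$neighbors, topo$N, as.integer(starts - 1L)) + 1L

  # walk element k is monomer (start_monomer + k - 1); re-index so column
  # j holds monomer j, with the start monomer at the (tethered) ori center
  start_mono <- topo$region_centers[ori_region]
  col_of_monomer <- ((seq_len(topo$N) - start_mono) %% topo$N) + 1L
  monomers <- walks[, col_of_monomer, drop = FALSE]
  structure(list(
    center_sites = monomers[, topo$region_centers, drop = FALSE],
    monomer_sites = if (keep_monomers) monomers else NULL,
    topo = topo, conf = conf, oriented = FALSE,
    acceptance = NA_real_,
    provenance = list(sampler = "exact-sequential", seed = seed,
                      tether = tether, tether_frac = tether_frac)
  ), class = "chromo_ensemble")
}
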