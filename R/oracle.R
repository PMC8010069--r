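#' Exhaustive enumeration of ring configurations (test oracle)
#'
#' Enumerates every confinement-legal labeled ring configuration of N
#' monomers, together with exact Boltzmann probabilities `exp(-H)/Z` and the
#' exact contact map. Intended as an independent oracle for the Monte Carlo
#' sampler on tiny systems; the state count is bounded a priori through the
#' trace of the N-th power of the confinement adjacency matrix, and the
#' function refuses (rather than truncates) when it exceeds `max_states`.
#'
#' @param eps couplings ([interaction_matrix()] or matrix or NULL).
#' @param topo a [chain_topology()].
#' @param conf confinement.
#' @param max_states hard cap on the legal state count.
#' @return list with `states` (n_states x N matrix of 1-based site ids),
#'   `energies`, `probabilities` (summing to 1; hard-core states removed),
#'   `contact_map` (exact co-occupancy probabilities, gamma = 1),
#'   `occupancy` (n_regions x M matrix of exact site-occupancy marginals).
#' @export
enumerate_ring_ensemble <- function(eps, topo, conf, max_states = 1e7) {
  eps <- as_interaction_matrix(eps, topo$n_regions)
  N <- topo$N
  M <- conf$M
  A <- matrix(0, M, M)
  for (d in 1:6) {
    j <- conf$neighbors[, d]
    ok <- j >= 0
    A[cbind(which(ok), j[ok] + 1L)] <- 1
  }
  n_closed <- sum(diag(matrix_power(A, N)))
  if (n_closed > max_states)
    stop(sprintf("state-space overflow: %.3g legal states exceeds cap %g", n_closed, max_states))

  # breadth-wise walk growth: partial walks as a matrix, one column per step
  walks <- matrix(seq_len(M), ncol = 1)
  for (step in 2:N) {
    pieces <- vector("list", 6)
    for (d in 1:6) {
      nxt <- conf$neighbors[walks[, step - 1], d] + 1L
      keep <- nxt > 0
      pieces[[d]] <- cbind(walks[keep, , drop = FALSE], nxt[keep])
    }
    walks <- do.call(rbind, pieces)
  }
  # ring closure: last monomer adjacent to the first
  adj_first <- A[cbind(walks[, N], walks[, 1])] > 0
  states <- walks[adj_first, , drop = FALSE]
  stopifnot(nrow(states) == n_closed)

  centers <- states[, topo$region_centers, drop = FALSE]
  n <- topo$n_regions
  H <- numeric(nrow(states))
  hard <- logical(nrow(states))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    co <- centers[, i] == centers[, j]
    if (eps$infinite_mask[i, j]) hard <- hard | co else H <- H + eps$eps[i, j] * co
  }
  states <- states[!hard, , drop = FALSE]
  centers <- centers[!hard, , drop = FALSE]
  H <- H[!hard]
  wt <- exp(-(H - min(H)))
  p <- wt / sum(wt)

  f <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    f[i, j] <- sum(p[centers[, i] == centers[, j]])
    f[j, i] <- f[i, j]
  }
  occ <- matrix(0, n, M)
  for (i in seq_len(n))
    occ[i, ] <- vapply(seq_len(M), function(s) sum(p[centers[, i] == s]), numeric(1))

  list(states = states, energies = H, probabilities = p,
       contact_map = contact_map(f, kind = "model_frequency"),
       occupancy = occ, n_states = nrow(states))
}

matrix_power <- function(A, n) {
  out <- diag(nrow(A))
  P <- A
  while (n > 0) {
    if (n %% 2 == 1) out <- out %*% P
    P <- P %*% P
    n <- n %/% 2
  }
  out
}

#' Map ensemble snapshots to enumerated state ids
#'
#' Utility for comparing Monte Carlo samples against
#' [enumerate_ring_ensemble()]: every snapshot (all N monomers) is matched
#' to its row in the oracle's state list.
#'
#' @param ens a `chromo_ensemble` sampled with `keep_monomers = TRUE`.
#' @param oracle result of [enumerate_ring_ensemble()].
#' @return integer vector of state indices (NA if unmatched).
#' @export
match_states <- function(ens, oracle) {
  if (is.null(ens$monomer_sites)) stop("ensemble was sampled without keep_monomers")
  key <- function(m) apply(m, 1, paste, collapse = ",")
  match(key(ens$monomer_sites), key(oracle$states))
}
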