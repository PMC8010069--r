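#' Contact map container
#'
#' A symmetric non-negative matrix of either normalized experimental Hi-C
#' scores or model contact frequencies, with a logical mask of pairs that
#' are excluded from fitting (mask TRUE = excluded). The diagonal is always
#' masked.
#'
#' @param scores symmetric non-negative numeric matrix.
#' @param kind `"normalized_experimental"` or `"model_frequency"`.
#' @param mask logical matrix of excluded pairs (default: diagonal only).
#' @param infinite_pairs logical matrix of pairs mapped to forbidden
#'   contacts (couplings -> +Inf), see [mask_zero_scores()].
#' @param sym_tol largest tolerated relative asymmetry before an error.
#' @return object of class `contact_map`.
#' @export
contact_map <- function(scores,
                        kind = c("normalized_experimental", "model_frequency"),
                        mask = NULL, infinite_pairs = NULL, sym_tol = 1e-8) {
  kind <- match.arg(kind)
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (ncol(scores) != n) stop("contact map must be square")
  if (any(scores < 0, na.rm = TRUE)) stop("negative contact scores")
  asym <- max(abs(scores - t(scores)), na.rm = TRUE)
  if (asym > sym_tol * max(1, max(abs(scores), na.rm = TRUE)))
    stop("contact map is not symmetric")
  scores <- (scores + t(scores)) / 2
  if (is.null(mask)) mask <- matrix(FALSE, n, n)
  mask <- mask | t(mask)
  mask[is.na(scores)] <- TRUE
  scores[is.na(scores)] <- 0
  diag(mask) <- TRUE
  if (is.null(infinite_pairs)) infinite_pairs <- matrix(FALSE, n, n)
  structure(list(scores = scores, kind = kind, mask = mask,
                 infinite_pairs = infinite_pairs, n_regions = n),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("Contact map (%s): %d x %d, %d unmasked pairs\n", x$kind,
              x$n_regions, x$n_regions, sum(!x$mask[upper.tri(x$mask)])))
  invisible(x)
}

# circular genomic distance between region indices
circular_distance <- function(i, j, n) pmin(abs(i - j), n - abs(i - j))

band_mask <- function(n, band) {
  idx <- seq_len(n)
  circular_distance(outer(idx, idx, function(a, b) a), outer(idx, idx, function(a, b) b), n) <= band
}

#' Handle zero Hi-C scores and the diagonal band
#'
#' Pairs with score at or below `floor` are either removed from the fitted
#' constraint set (`policy = "exclude"`) or declared forbidden contacts
#' (`policy = "infinite"`, the reading of white regions in a coupling map as
#' diverging couplings). Pairs within `mask_band` circular bins of the
#' diagonal are always excluded: their contacts are dominated by chain
#' connectivity, not couplings. All-zero rows are masked entirely and
#' reported via a message.
#'
#' @param hic a [contact_map()] of kind `normalized_experimental`.
#' @param policy `"exclude"` or `"infinite"`.
#' @param floor score at or below which a pair counts as zero.
#' @param mask_band circular diagonal half-width to exclude (default 1 =
#'   self plus nearest neighbors).
#' @return the updated `contact_map`.
#' @export
mask_zero_scores <- function(hic, policy = c("exclude", "infinite"),
                             floor = 0, mask_band = 1) {
  policy <- match.arg(policy)
  n <- hic$n_regions
  zero <- hic$scores <= floor
  diag(zero) <- FALSE
  band <- band_mask(n, mask_band)
  hic$mask <- hic$mask | band
  if (policy == "exclude") {
    hic$mask <- hic$mask | zero
  } else {
    hic$infinite_pairs <- hic$infinite_pairs | (zero & !band)
    hic$mask <- hic$mask | zero
  }
  dead_rows <- which(vapply(seq_len(n), function(i) all(zero[i, -i]), logical(1)))
  if (length(dead_rows)) {
    hic$mask[dead_rows, ] <- TRUE
    hic$mask[, dead_rows] <- TRUE
    message(sprintf("mask_zero_scores: %d all-zero row(s) fully masked: %s",
                    length(dead_rows), paste(dead_rows, collapse = ", ")))
  }
  hic
}

#' Fit-quality diagnostics
#'
#' Mean pairwise deviation as a percentage of the mean target score, and
#' the Pearson correlation, both over unmasked pairs.
#'
#' @param f_model,f_target [contact_map()]s (or plain matrices) of matching
#'   size.
#' @param mask optional logical exclusion matrix; defaults to the union of
#'   the two maps' masks.
#' @return list with `deviation_pct` and `pearson`.
#' @export
fit_diagnostics <- function(f_model, f_target, mask = NULL) {
  m <- if (inherits(f_model, "contact_map")) f_model$scores else as.matrix(f_model)
  t_ <- if (inherits(f_target, "contact_map")) f_target$scores else as.matrix(f_target)
  if (!all(dim(m) == dim(t_))) stop("dimension mismatch")
  if (is.null(mask)) {
    mask <- matrix(FALSE, nrow(m), ncol(m))
    if (inherits(f_model, "contact_map")) mask <- mask | f_model$mask
    if (inherits(f_target, "contact_map")) mask <- mask | f_target$mask
    diag(mask) <- TRUE
  }
  u <- upper.tri(m) & !mask
  if (!any(u)) stop("no unmasked pairs")
  mv <- m[u]; tv <- t_[u]
  if (stats::sd(mv) == 0 || stats::sd(tv) == 0)
    stop("Pearson undefined: zero variance in one of the maps")
  list(deviation_pct = mean(abs(mv - tv)) / mean(tv) * 100,
       pearson = stats::cor(mv, tv))
}

#' Entropy-maximization residual of the conversion-factor constraint
#'
#' At the entropy-maximizing conversion factor the couplings satisfy
#' `sum_ij eps_ij f~_ij = 0` over the fitted pairs. Returns the raw residual
#' and the relative residual `|sum eps f~| / sum |eps| f~`.
#'
#' @param eps [interaction_matrix()] (or matrix).
#' @param f_tilde normalized experimental map ([contact_map()] or matrix).
#' @param mask logical exclusion matrix (defaults to the map's mask).
#' @return list with `residual`, `relative`, `denominator`.
#' @export
conversion_residual <- function(eps, f_tilde, mask = NULL) {
  eps <- as_interaction_matrix(eps)
  ft <- if (inherits(f_tilde, "contact_map")) f_tilde$scores else as.matrix(f_tilde)
  if (is.null(mask) && inherits(f_tilde, "contact_map")) mask <- f_tilde$mask
  if (is.null(mask)) mask <- diag(TRUE, nrow(ft))
  if (all(ft[!mask] == 0)) stop("all-zero normalized scores: constraint undefined")
  u <- upper.tri(ft) & !mask
  num <- sum(eps$eps[u] * ft[u])
  den <- sum(abs(eps$eps[u]) * ft[u])
  list(residual = num, relative = if (den > 0) abs(num) / den else NA_real_,
       denominator = den)
}

#' One multiplicative update of the conversion factor
#'
#' Moves `c_tilde` so as to shrink the entropy-maximization residual: a net
#' positive `sum eps f~` (contacts over-penalized) raises the target
#' frequencies, which lowers the couplings on the next iteration, and vice
#' versa. Used inside [fit_maxent()]; exposed for scalar root-find studies.
#'
#' @param eps [interaction_matrix()].
#' @param f_tilde normalized map.
#' @param c_tilde current conversion factor.
#' @param kappa damping of the log-step.
#' @param mask exclusion matrix.
#' @return list with the updated `c_tilde` and the residual diagnostics.
#' @export
solve_conversion_factor <- function(eps, f_tilde, c_tilde, kappa = 0.5, mask = NULL) {
  r <- conversion_residual(eps, f_tilde, mask)
  if (is.finite(r$relative) && r$denominator > 0)
    c_tilde <- c_tilde * exp(kappa * r$residual / r$denominator)
  list(c_tilde = c_tilde, residual = r$residual, relative = r$relative)
}

#' Log-ratio coupling update
#'
#' Per-pair update `eps_ij <- eps_ij + step * log((f_model_ij + eta) /
#' (f_target_ij + eta))`: pairs whose model contact frequency exceeds the
#' target get penalized (coupling raised). Masked pairs are untouched;
#' symmetry is preserved.
#'
#' @param eps [interaction_matrix()].
#' @param f_model,f_target matrices (or [contact_map()]s) on the same
#'   frequency scale.
#' @param step positive step size.
#' @param eta ratio regularizer (half a count, `1/(2 n_samples)`, by
#'   default in [fit_maxent()]).
#' @param mask logical exclusion matrix.
#' @param clamp largest per-pair coupling change per update; poorly
#'   resolved pairs (model or target frequency near zero) otherwise take
#'   runaway steps from the log ratio.
#' @return updated [interaction_matrix()].
#' @export
update_interactions <- function(eps, f_model, f_target, step, eta = 1e-4,
                                mask = NULL, clamp = 0.5) {
  if (step <= 0) stop("step must be positive")
  eps <- as_interaction_matrix(eps)
  m <- if (inherits(f_model, "contact_map")) f_model$scores else as.matrix(f_model)
  t_ <- if (inherits(f_target, "contact_map")) f_target$scores else as.matrix(f_target)
  if (!all(dim(m) == dim(t_)) || !all(dim(m) == dim(eps$eps)))
    stop("dimension mismatch")
  upd <- pmin(pmax(step * log((m + eta) / (t_ + eta)), -clamp), clamp)
  if (!is.null(mask)) upd[mask] <- 0
  diag(upd) <- 0
  e <- eps$eps + (upd + t(upd)) / 2
  interaction_matrix(e, eps$infinite_mask)
}

#' Infer maximum-entropy couplings from a normalized Hi-C map
#'
#' Inverse Monte Carlo: iterates (sample ensemble under current couplings ->
#' estimate model contact frequencies -> update couplings by log-ratio
#' matching -> adjust the conversion factor toward the entropy-maximization
#' constraint) until the model map reproduces the target within the
#' configured deviation/correlation/residual tolerances, or the iteration
#' budget is exhausted (then `converged = FALSE`, never an error).
#'
#' @param hic [contact_map()] of kind `normalized_experimental`.
#' @param topo [chain_topology()] with `n_regions` matching the map.
#' @param conf confinement.
#' @param max_iter iteration budget.
#' @param n_samples Monte Carlo snapshots per iteration (grows linearly to
#'   `n_samples_final` over the budget).
#' @param n_samples_final snapshots in the last iterations and in the
#'   returned model map.
#' @param step0 initial coupling step size; decays as `step0 / (1 + k/20)`.
#' @param kappa_c damping of the conversion-factor updates.
#' @param fit_c_tilde infer the conversion factor through the
#'   entropy-maximization constraint (default). With `FALSE` the factor is
#'   frozen at `c_tilde0` — the mode for inverting maps whose absolute
#'   contact-frequency scale is already known (e.g. model-generated
#'   frequency maps), where the couplings are then identified without the
#'   entropy-gauge freedom.
#' @param c_tilde0 initial (or, if frozen, final) conversion factor;
#'   `NULL` = match the mean unmasked score to the non-interacting model's
#'   mean contact frequency.
#' @param gamma contact probability factor (absorbed into the conversion
#'   factor; only `c_tilde = c/gamma` is identifiable).
#' @param tol_deviation_pct,tol_pearson,tol_residual convergence tolerances
#'   on the map deviation (%), Pearson correlation, and relative
#'   entropy-maximization residual.
#' @param zero_policy passed to [mask_zero_scores()].
#' @param mask_band diagonal band excluded from fitting.
#' @param thin_sweeps,burn_in sampler schedule per iteration (defaults:
#'   `N/2` and `20 N` after a warm start).
#' @param seed root seed; per-iteration sampler seeds are derived from it.
#' @param verbose print per-iteration diagnostics.
#' @return object of class `maxent_fit`: `eps` ([interaction_matrix()]),
#'   `c_tilde`, `converged`, `history` (per-iteration data.frame),
#'   `f_model` (model [contact_map()] from the final long run), `mask`,
#'   `seed`.
#' @export
fit_maxent <- function(hic, topo, conf,
                       max_iter = 80, n_samples = 2000, n_samples_final = 8000,
                       step0 = 0.6, kappa_c = 0.5, gamma = 1,
                       fit_c_tilde = TRUE, c_tilde0 = NULL,
                       tol_deviation_pct = 6.0, tol_pearson = 0.998,
                       tol_residual = 1e-2,
                       zero_policy = "exclude", mask_band = 1,
                       thin_sweeps = NULL, burn_in = NULL,
                       seed = 1, verbose = FALSE) {
  stopifnot(inherits(hic, "contact_map"))
  if (hic$kind != "normalized_experimental")
    stop("fit_maxent expects a normalized experimental map")
  if (hic$n_regions != topo$n_regions)
    stop("Hi-C matrix size does not match the chain topology")
  hic <- mask_zero_scores(hic, policy = zero_policy, mask_band = mask_band)
  n <- topo$n_regions
  ft <- hic$scores
  mask <- hic$mask
  u <- upper.tri(ft) & !mask
  if (!any(u)) stop("no unmasked pairs to fit")

  inf_mask <- hic$infinite_pairs
  eps <- interaction_matrix(matrix(0, n, n), inf_mask)
  if (is.null(thin_sweeps)) thin_sweeps <- max(1L, topo$N %/% 2L)
  if (is.null(burn_in)) burn_in <- 20L * topo$N

  # reference non-interacting ensemble fixes the initial conversion factor
  ens <- sample_ensemble(eps, topo, conf, n_samples = n_samples,
                         thin_sweeps = thin_sweeps, burn_in = 50L * topo$N,
                         seed = derive_seed(seed, 0), keep_monomers = TRUE)
  f0 <- estimate_contact_frequencies(ens, gamma = 1)$scores
  c_tilde <- if (!is.null(c_tilde0)) c_tilde0 else mean(f0[u]) / mean(ft[u])

  hist_rows <- vector("list", max_iter)
  converged <- FALSE
  warm <- ens$monomer_sites[nrow(ens$monomer_sites), ]
  f_model <- f0
  for (k in seq_len(max_iter)) {
    if (c_tilde * max(ft[u]) > 1)
      stop("infeasible constraints: target contact probability exceeds 1 (score above achievable maximum)")
    target <- c_tilde * ft  # co-occupancy probabilities implied by the map
    step <- step0 / (1 + (k - 1) / 20)
    eta <- 1 / (2 * nrow(ens$center_sites))
    # NA-safe diagnostics: a degenerate (e.g. constant) target never raises
    # here — the fit simply cannot converge and says so
    mv <- f_model[u]; tv <- target[u]
    d <- list(deviation_pct = mean(abs(mv - tv)) / mean(tv) * 100,
              pearson = if (stats::sd(mv) > 0 && stats::sd(tv) > 0)
                stats::cor(mv, tv) else NA_real_)
    cr <- conversion_residual(eps, ft, mask = mask)
    hist_rows[[k]] <- data.frame(
      iter = k, step = step, c_tilde = c_tilde,
      deviation_pct = d$deviation_pct, pearson = d$pearson,
      residual_rel = cr$relative, acceptance = ens$acceptance)
    if (verbose)
      message(sprintf("iter %3d: dev %6.2f%%  r %.5f  |resid| %8.2e  c~ %.4g",
                      k, d$deviation_pct, d$pearson,
                      ifelse(is.na(cr$relative), 0, cr$relative), c_tilde))
    if (k > 3 && d$deviation_pct <= tol_deviation_pct &&
        !is.na(d$pearson) && d$pearson >= tol_pearson &&
        (!fit_c_tilde || is.na(cr$relative) || cr$relative <= tol_residual)) {
      converged <- TRUE
      break
    }
    eps <- update_interactions(eps, f_model, target, step = step, eta = eta,
                               mask = mask)
    if (fit_c_tilde)
      c_tilde <- solve_conversion_factor(eps, ft, c_tilde, kappa = kappa_c,
                                         mask = mask)$c_tilde
    S_k <- round(n_samples + (n_samples_final - n_samples) * (k / max_iter))
    ens <- sample_ensemble(eps, topo, conf, n_samples = S_k,
                           thin_sweeps = thin_sweeps, burn_in = burn_in,
                           seed = derive_seed(seed, k), keep_monomers = TRUE,
                           init = warm)
    warm <- ens$monomer_sites[nrow(ens$monomer_sites), ]
    f_model <- estimate_contact_frequencies(ens, gamma = 1)$scores
  }

  history <- do.call(rbind, hist_rows[!vapply(hist_rows, is.null, logical(1))])
  structure(list(eps = eps, c_tilde = c_tilde, converged = converged,
                 history = history,
                 f_model = contact_map(f_model, kind = "model_frequency",
                                       mask = mask),
                 target = hic, mask = mask, gamma = gamma, seed = seed),
            class = "maxent_fit")
}

#' @export
print.maxent_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf(paste0(
    "MaxEnt fit: %d regions, %s after %d iterations\n",
    "  deviation %.2f%% of mean score, Pearson r = %.4f, ",
    "relative entropy-constraint residual = %.2e, c~ = %.4g\n"),
    x$eps$n_regions, if (x$converged) "converged" else "NOT converged",
    nrow(x$history), last$deviation_pct, last$pearson,
    ifelse(is.na(last$residual_rel), 0, last$residual_rel), x$c_tilde))
  invisible(x)
}
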