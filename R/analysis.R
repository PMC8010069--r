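# Ensemble statistics: position distributions, two-point correlations,
# Super-Domain (SuD) detection, local extension, density rendering,
# localization information, and the extension-peak / gene overlap test.

# S x n matrices of center coordinates (lattice units unless nm = TRUE)
center_coords <- function(ens, axis, nm = FALSE) {
  src <- if (nm) ens$conf$sites else ens$conf$sites_lat
  matrix(src[ens$center_sites, axis], nrow = nrow(ens$center_sites))
}

require_oriented <- function(ens) {
  if (!isTRUE(ens$oriented))
    stop("ensemble must be oriented first (orient_ensemble)")
}

#' Distribution of scaled long-axis positions of one region
#'
#' Normalized histogram (probabilities summing to 1) of the region center's
#' scaled axial position across snapshots; the bin count is configurable so
#' model histograms can be binned like a comparison dataset.
#'
#' @param ens oriented `chromo_ensemble`.
#' @param region region index.
#' @param bins number of equal bins on `[0, 1]`.
#' @return data.frame with `mid` (bin midpoint) and `prob`.
#' @export
axial_distribution <- function(ens, region, bins = 25) {
  require_oriented(ens)
  zl <- ens$conf$sites_lat[, 3]
  zr <- range(zl)
  z <- (ens$conf$sites_lat[ens$center_sites[, region], 3] - zr[1]) / (zr[2] - zr[1])
  breaks <- seq(0, 1, length.out = bins + 1)
  cnt <- tabulate(pmin(findInterval(z, breaks, rightmost.closed = TRUE), bins),
                  nbins = bins)
  data.frame(mid = (breaks[-1] + breaks[-(bins + 1)]) / 2, prob = cnt / sum(cnt))
}

# shared Pearson machinery: correlation matrix of an S x n observable,
# zero-variance regions flagged NA (reported via attribute, never zeroed)
pearson_matrix <- function(x, coordinate) {
  sdv <- apply(x, 2, stats::sd)
  undef <- which(sdv == 0)
  C <- suppressWarnings(stats::cor(x))
  if (length(undef)) {
    C[undef, ] <- NA_real_
    C[, undef] <- NA_real_
  }
  ok <- setdiff(seq_len(ncol(x)), undef)
  C[cbind(ok, ok)] <- 1
  structure(C, coordinate = coordinate, undefined_regions = undef,
            class = c("correlation_matrix", "matrix"))
}

#' Two-point axial correlations
#'
#' Pearson correlation of the long-axis positions `z_i`, `z_j` of every
#' region pair across snapshots of an oriented ensemble.
#'
#' @param ens oriented `chromo_ensemble`.
#' @return n x n `correlation_matrix` (attribute `undefined_regions` lists
#'   zero-variance regions, whose rows/columns are NA).
#' @export
axial_correlations <- function(ens) {
  require_oriented(ens)
  pearson_matrix(center_coords(ens, 3), "axial")
}

#' Two-point radial correlations
#'
#' Pearson correlation of the radial positions `r_i = sqrt(x^2 + y^2)`.
#'
#' @inheritParams axial_correlations
#' @return n x n `correlation_matrix`.
#' @export
radial_correlations <- function(ens) {
  r <- sqrt(center_coords(ens, 1)^2 + center_coords(ens, 2)^2)
  pearson_matrix(r, "radial")
}

#' Two-point angular correlations
#'
#' Each chromosome segment (a run of `segment_length` consecutive region
#' centers) gets a transverse orientation unit vector `u = (x, y)/|(x, y)|`
#' of its centroid; the correlation is `C_ij = <u_i . u_j>` across
#' snapshots. Snapshots whose segment centroid falls on the long axis are
#' excluded for that segment (the count is reported via attribute
#' `n_excluded`).
#'
#' @param ens oriented `chromo_ensemble`.
#' @param segment_length region centers per segment (default 1).
#' @return n_segments x n_segments `correlation_matrix`-like matrix of
#'   `<u_i . u_j>` values (diagonal 1).
#' @export
angular_correlations <- function(ens, segment_length = 1) {
  require_oriented(ens)
  x <- center_coords(ens, 1)
  y <- center_coords(ens, 2)
  n <- ncol(x)
  nseg <- n %/% segment_length
  if (segment_length > 1) {
    grp <- rep(seq_len(nseg), each = segment_length)[seq_len(n)]
    x <- t(apply(x, 1, function(v) tapply(v, grp, mean)))[, seq_len(nseg), drop = FALSE]
    y <- t(apply(y, 1, function(v) tapply(v, grp, mean)))[, seq_len(nseg), drop = FALSE]
  }
  rr <- sqrt(x^2 + y^2)
  on_axis <- rr == 0
  ux <- ifelse(on_axis, NA_real_, x / rr)
  uy <- ifelse(on_axis, NA_real_, y / rr)
  C <- matrix(NA_real_, nseg, nseg)
  for (i in seq_len(nseg)) for (j in i:nseg) {
    dot <- ux[, i] * ux[, j] + uy[, i] * uy[, j]
    C[i, j] <- mean(dot, na.rm = TRUE)
    C[j, i] <- C[i, j]
  }
  structure(C, coordinate = "angular", n_excluded = sum(on_axis),
            class = c("correlation_matrix", "matrix"))
}

# ---- Super Domains -----------------------------------------------------

# single-linkage clustering of one snapshot's center coordinates (lattice
# units) at the given radius, split into genomically contiguous circular
# runs, short runs dropped. Returns a list of integer vectors.
sud_members_one <- function(coords, radius = 2, min_size = 5) {
  n <- nrow(coords)
  d2 <- as.matrix(stats::dist(coords))^2
  adj <- d2 <= radius^2
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  runs <- list()
  for (k in seq_len(cid)) {
    mem <- which(comp == k)
    if (length(mem) < min_size) next
    # split into circular runs of consecutive region indices
    inset <- logical(n)
    inset[mem] <- TRUE
    brk <- which(inset & !inset[c(n, seq_len(n - 1))])  # run starts
    if (length(brk) == 0) {  # full circle
      runs[[length(runs) + 1]] <- seq_len(n)
      next
    }
    for (b in brk) {
      run <- b
      i <- b %% n + 1L
      while (inset[i] && length(run) < n) {
        run <- c(run, i)
        i <- i %% n + 1L
      }
      if (length(run) >= min_size) runs[[length(runs) + 1]] <- run
    }
  }
  runs
}

#' Identify Super Domains in one configuration
#'
#' High-density clusters of genomically consecutive regions: region centers
#' are clustered by spatial proximity (single linkage at `radius` lattice
#' units), clusters are split into genomically contiguous circular runs, and
#' runs shorter than `min_size` regions are discarded. Each SuD is labeled
#' by chromosomal arm (right arm = first genome half, ori to ter; left arm
#' = second half) by majority membership, and by its axial extent.
#'
#' @param config a [chromo_config()], or a `chromo_ensemble` plus
#'   `snapshot`.
#' @param snapshot snapshot index when `config` is an ensemble.
#' @param radius clustering radius in lattice units (default 2).
#' @param min_size minimum regions per SuD (default 5).
#' @return data.frame with one row per SuD: `sud`, `arm`, `n_regions`,
#'   `first_region`, `last_region`, `z_lo`, `z_hi` (nm), plus attribute
#'   `members` (list of region index vectors).
#' @export
identify_suds <- function(config, snapshot = NULL, radius = 2, min_size = 5) {
  if (inherits(config, "chromo_ensemble")) {
    stopifnot(!is.null(snapshot))
    coords <- matrix(config$conf$sites_lat[config$center_sites[snapshot, ], ],
                     ncol = 3)
    zs <- config$conf$sites[config$center_sites[snapshot, ], 3]
    n <- config$topo$n_regions
  } else {
    ids <- config$site_ids[config$topo$region_centers]
    coords <- matrix(config$conf$sites_lat[ids, ], ncol = 3)
    zs <- config$conf$sites[ids, 3]
    n <- config$topo$n_regions
  }
  runs <- sud_members_one(coords, radius, min_size)
  arm_of <- function(mem) if (mean(mem <= n / 2) >= 0.5) "right" else "left"
  if (!length(runs)) {
    out <- data.frame(sud = integer(0), arm = character(0),
                      n_regions = integer(0), first_region = integer(0),
                      last_region = integer(0), z_lo = numeric(0),
                      z_hi = numeric(0))
    attr(out, "members") <- list()
    return(out)
  }
  out <- data.frame(
    sud = seq_along(runs),
    arm = vapply(runs, arm_of, character(1)),
    n_regions = lengths(runs),
    first_region = vapply(runs, function(r) r[1], integer(1)),
    last_region = vapply(runs, function(r) r[length(r)], integer(1)),
    z_lo = vapply(runs, function(r) min(zs[r]), numeric(1)),
    z_hi = vapply(runs, function(r) max(zs[r]), numeric(1)))
  attr(out, "members") <- runs
  out
}

#' Ensemble SuD statistics
#'
#' Means (with standard errors across snapshots) of the fraction of regions
#' inside a SuD, SuDs per chromosomal arm, and regions per SuD.
#'
#' @param ens `chromo_ensemble`.
#' @param radius,min_size clustering parameters, see [identify_suds()].
#' @return list with `fraction_in_suds`, `suds_per_arm`,
#'   `regions_per_sud` (each `c(mean, se)`), and the per-snapshot table.
#' @export
sud_statistics <- function(ens, radius = 2, min_size = 5) {
  S <- nrow(ens$center_sites)
  if (S == 0) stop("empty ensemble")
  n <- ens$topo$n_regions
  per <- lapply(seq_len(S), function(s) {
    su <- identify_suds(ens, snapshot = s, radius = radius, min_size = min_size)
    mem <- attr(su, "members")
    data.frame(snapshot = s,
               fraction = if (length(mem)) length(unique(unlist(mem))) / n else 0,
               n_suds = nrow(su),
               suds_per_arm = nrow(su) / 2,
               mean_size = if (nrow(su)) mean(su$n_regions) else NA_real_)
  })
  per <- do.call(rbind, per)
  mse <- function(x) {
    x <- x[is.finite(x)]
    c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)))
  }
  list(fraction_in_suds = mse(per$fraction),
       suds_per_arm = mse(per$suds_per_arm),
       regions_per_sud = mse(per$mean_size),
       per_snapshot = per)
}

# interval-union helpers (matrices with columns lo, hi)
merge_intervals <- function(iv) {
  if (nrow(iv) == 0) return(iv)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (k in seq_len(nrow(iv))[-1]) {
    if (iv[k, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], iv[k, 2])
    } else out <- rbind(out, iv[k, ])
  }
  out
}
union_length <- function(iv) { iv <- merge_intervals(iv); sum(iv[, 2] - iv[, 1]) }
intersect_length <- function(a, b) {
  a <- merge_intervals(a); b <- merge_intervals(b)
  tot <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    lo <- max(a[i, 1], b[j, 1]); hi <- min(a[i, 2], b[j, 2])
    if (hi > lo) tot <- tot + (hi - lo)
  }
  tot
}

# axial-interval unions of left/right-arm SuDs for every snapshot
sud_arm_intervals <- function(ens, radius, min_size) {
  lapply(seq_len(nrow(ens$center_sites)), function(s) {
    su <- identify_suds(ens, snapshot = s, radius = radius, min_size = min_size)
    list(left = as.matrix(su[su$arm == "left", c("z_lo", "z_hi"), drop = FALSE]),
         right = as.matrix(su[su$arm == "right", c("z_lo", "z_hi"), drop = FALSE]))
  })
}

arm_overlap_fraction <- function(left, right) {
  if (nrow(left) == 0 || nrow(right) == 0) return(NA_real_)
  both <- rbind(left, right)
  intersect_length(left, right) / union_length(both)
}

#' Reduction of inter-arm SuD axial overlap versus randomly paired arms
#'
#' Within each configuration, the overlap is the fraction of axial extent
#' shared by the left-arm and right-arm SuD interval unions (intersection
#' over union). The baseline recomputes the same statistic with each
#' configuration's right-arm intervals replaced by those of a different,
#' randomly chosen configuration. Returns the percent reduction
#' `(baseline - observed)/baseline * 100`; configurations lacking SuDs on
#' both arms are excluded (and counted).
#'
#' @param ens `chromo_ensemble` with at least 2 snapshots.
#' @param n_shuffles random arm re-pairings for the baseline.
#' @param seed RNG seed.
#' @param radius,min_size clustering parameters.
#' @return list with `reduction_pct`, `observed`, `baseline`,
#'   `n_excluded`.
#' @export
sud_overlap_reduction <- function(ens, n_shuffles = 20, seed = 1,
                                  radius = 2, min_size = 5) {
  S <- nrow(ens$center_sites)
  stopifnot(S >= 2)
  iv <- sud_arm_intervals(ens, radius, min_size)
  obs <- vapply(iv, function(v) arm_overlap_fraction(v$left, v$right), numeric(1))
  usable <- which(is.finite(obs))
  if (length(usable) < 2) stop("fewer than 2 configurations with SuDs on both arms")
  set.seed(seed)
  base <- numeric(0)
  for (t in seq_len(n_shuffles)) {
    partner <- vapply(usable, function(s) {
      pool <- setdiff(usable, s)
      pool[sample.int(length(pool), 1)]
    }, integer(1))
    base <- c(base, mapply(function(s, p)
      arm_overlap_fraction(iv[[s]]$left, iv[[p]]$right), usable, partner))
  }
  observed <- mean(obs[usable])
  baseline <- mean(base, na.rm = TRUE)
  list(reduction_pct = (baseline - observed) / baseline * 100,
       observed = observed, baseline = baseline,
       n_excluded = S - length(usable))
}

# ---- local structure ---------------------------------------------------

#' Local chromosomal extension profile
#'
#' `delta_i`: the spatial distance between the two genomic neighbors of
#' region i — computed as the symmetric mean of the distances to both
#' neighboring region centers (circular indexing), averaged over snapshots,
#' in nm. A one-sided variant (distance to the next center only) is
#' available via `side = "next"`.
#'
#' @param ens `chromo_ensemble`.
#' @param side `"symmetric"` (default) or `"next"`.
#' @param condition optional label stored with the profile.
#' @return data.frame of class `extension_profile` with `region` and
#'   `delta_nm`; attributes `bin_size`, `condition`.
#' @export
local_extension <- function(ens, side = c("symmetric", "next"), condition = NA) {
  side <- match.arg(side)
  d <- consecutive_center_distances(ens)  # S x n, col i = d(center i, center i+1)
  n <- ncol(d)
  delta <- if (side == "next") colMeans(d)
           else colMeans((d + d[, c(n, seq_len(n - 1)), drop = FALSE]) / 2)
  structure(data.frame(region = seq_len(n), delta_nm = delta),
            bin_size = ens$topo$bin_size, condition = condition,
            class = c("extension_profile", "data.frame"))
}

#' Mean pairwise spatial distance map
#'
#' @param ens `chromo_ensemble`.
#' @return symmetric n x n matrix of mean Euclidean center distances (nm),
#'   zero diagonal.
#' @export
mean_distance_map <- function(ens) {
  x <- center_coords(ens, 1, nm = TRUE)
  y <- center_coords(ens, 2, nm = TRUE)
  z <- center_coords(ens, 3, nm = TRUE)
  n <- ncol(x)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    dx <- x[, (i + 1):n, drop = FALSE] - x[, i]
    dy <- y[, (i + 1):n, drop = FALSE] - y[, i]
    dz <- z[, (i + 1):n, drop = FALSE] - z[, i]
    D[i, (i + 1):n] <- colMeans(sqrt(dx^2 + dy^2 + dz^2))
  }
  D + t(D)
}

#' Render a blurred chromosome density grid
#'
#' Histogram of all monomer positions of one configuration on a voxel grid,
#' convolved with an anisotropic Gaussian whose standard deviations match
#' the stated imaging resolutions, and rescaled to maximum 1.
#'
#' @param config [chromo_config()] (all monomers).
#' @param blur_xyz Gaussian sigma per axis in nm (default 120, 120, 300).
#' @param voxel voxel edge in nm (default: the lattice spacing).
#' @return list of class `density_grid`: `density` (max-normalized 3D
#'   array), `raw` (unblurred counts), `blurred` (unnormalized), `voxel`,
#'   `sigma_vox`, `axes` (voxel center coordinates).
#' @export
render_density <- function(config, blur_xyz = c(120, 120, 300), voxel = NULL) {
  conf <- config$conf
  if (is.null(voxel)) voxel <- conf$b
  ext <- apply(conf$sites, 2, range)
  if (voxel > min(ext[2, ] - ext[1, ] + conf$b))
    stop("voxel larger than the cell")
  axes <- lapply(1:3, function(a)
    seq(ext[1, a] - conf$b / 2 + voxel / 2, ext[2, a] + conf$b / 2, by = voxel))
  dims <- vapply(axes, length, integer(1))
  pos <- conf$sites[config$site_ids, , drop = FALSE]
  idx <- vapply(1:3, function(a)
    pmin(pmax(1L, findInterval(pos[, a], axes[[a]] - voxel / 2)), dims[a]),
    integer(nrow(pos)))
  raw <- array(0, dims)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]; l <- idx[k, 3]
    raw[i, j, l] <- raw[i, j, l] + 1
  }
  blurred <- gaussian_blur3d(raw, blur_xyz / voxel)
  structure(list(density = blurred / max(blurred), raw = raw, blurred = blurred,
                 voxel = voxel, sigma_vox = blur_xyz / voxel, axes = axes),
            class = "density_grid")
}

# separable 3D Gaussian convolution, zero-padded, mass-preserving away from
# boundaries (kernel normalized to sum 1)
gaussian_blur3d <- function(arr, sigma_vox) {
  for (a in 1:3) {
    s <- sigma_vox[a]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(-r:r, sd = s)
    k <- k / sum(k)
    arr <- convolve_axis(arr, k, a)
  }
  arr
}

convolve_axis <- function(arr, k, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  x <- aperm(arr, perm)
  dd <- dim(x)
  m <- matrix(x, nrow = dd[1])
  r <- (length(k) - 1) / 2
  pad <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
  out <- matrix(0, dd[1], ncol(m))
  for (t in seq_along(k))
    out <- out + k[t] * pad[t:(t + dd[1] - 1), , drop = FALSE]
  aperm(array(out, dd), order(perm))
}

# ---- localization information ------------------------------------------

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Localization information of an explicit site distribution
#'
#' `log2(M) - H(p)` in bits: the reduction in positional uncertainty of a
#' distribution `p` over the M accessible confinement sites relative to the
#' uniform distribution (a Kullback-Leibler divergence from uniform).
#'
#' @param p probability vector over the confinement sites (length M).
#' @param conf confinement (or the site count M).
#' @return information in bits.
#' @export
distribution_information <- function(p, conf) {
  M <- if (inherits(conf, "confinement")) conf$M else conf
  stopifnot(length(p) == M, abs(sum(p) - 1) < 1e-9)
  log2(M) - entropy_bits(p)
}

#' Per-region localization information profile
#'
#' For every region the Shannon entropy of its estimated occupancy
#' distribution over the M accessible sites is subtracted from the maximum
#' `log2(M)`. The plug-in entropy is biased low at finite sample size
#' (inflating information); the Miller-Madow correction
#' `+(K_observed - 1)/(2 S)` nats is applied by default. Estimates are
#' clamped to the valid `[0, log2(M)]` band.
#'
#' @param ens oriented `chromo_ensemble`.
#' @param bias_correction `"miller_madow"` or `"none"`.
#' @param coordinate `"3d"` (occupancy over sites, default) or `"axial"`
#'   (occupancy over z-planes, reference `log2(n_planes)`).
#' @return data.frame of class `information_profile` with `region` and
#'   `info_bits`; attribute `reference_bits` = `log2(M)`.
#' @export
localization_information <- function(ens,
                                     bias_correction = c("miller_madow", "none"),
                                     coordinate = c("3d", "axial")) {
  require_oriented(ens)
  bias_correction <- match.arg(bias_correction)
  coordinate <- match.arg(coordinate)
  S <- nrow(ens$center_sites)
  if (S == 0) stop("empty ensemble")
  if (coordinate == "3d") {
    lev <- ens$conf$M
    obs <- ens$center_sites
  } else {
    zvals <- sort(unique(ens$conf$sites_lat[, 3]))
    lev <- length(zvals)
    obs <- matrix(match(ens$conf$sites_lat[ens$center_sites, 3], zvals),
                  nrow = S)
  }
  ref <- log2(lev)
  info <- vapply(seq_len(ncol(obs)), function(i) {
    cnt <- tabulate(obs[, i], nbins = lev)
    p <- cnt / S
    H <- entropy_bits(p)
    if (bias_correction == "miller_madow")
      H <- H + (sum(cnt > 0) - 1) / (2 * S * log(2))
    min(max(ref - H, 0), ref)
  }, numeric(1))
  structure(data.frame(region = seq_len(ncol(obs)), info_bits = info),
            reference_bits = ref, coordinate = coordinate,
            class = c("information_profile", "data.frame"))
}

# ---- extension peaks vs highly transcribed genes -----------------------

#' Call peaks on a local-extension profile
#'
#' Circular local maxima whose height exceeds the profile median by
#' `prominence_mad` median-absolute-deviations.
#'
#' @param profile an `extension_profile` (see [local_extension()]).
#' @param prominence_mad prominence threshold in MADs.
#' @return integer vector of peak region indices.
#' @export
extension_peaks <- function(profile, prominence_mad = 1) {
  d <- profile$delta_nm
  n <- length(d)
  prv <- d[c(n, seq_len(n - 1))]
  nxt <- d[c(2:n, 1)]
  thr <- stats::median(d) + prominence_mad * stats::mad(d)
  which(d > prv & d >= nxt & d >= thr)
}

#' Overlap of extension peaks with gene positions (permutation test)
#'
#' Counts extension peaks falling within `window` regions (circular) of a
#' gene, and compares against a null in which the same number of peak
#' positions is redrawn uniformly along the genome (optionally restricted
#' to a stratum such as one arm). One-sided permutation p-value with +1
#' correction.
#'
#' @param profile `extension_profile`.
#' @param genes data.frame with columns `start`, `end` (bp, half-open) and
#'   optionally `strand`; e.g. the most highly transcribed genes.
#' @param n_permutations null draws.
#' @param seed RNG seed.
#' @param window circular tolerance in regions (default 1).
#' @param prominence_mad peak threshold, see [extension_peaks()].
#' @param restrict_regions optional region subset (stratum) to which both
#'   peaks and null draws are restricted.
#' @return list with `observed_overlap`, `n_peaks`, `p_value`,
#'   `peak_regions`, `gene_regions`.
#' @export
extension_peak_gene_overlap <- function(profile, genes, n_permutations = 1000,
                                        seed = 1, window = 1,
                                        prominence_mad = 1,
                                        restrict_regions = NULL) {
  bin <- attr(profile, "bin_size")
  n <- nrow(profile)
  if (is.null(genes) || nrow(genes) == 0) stop("empty gene list")
  gene_regions <- unique(((genes$start + genes$end) / 2) %/% bin + 1)
  gene_regions <- gene_regions[gene_regions >= 1 & gene_regions <= n]
  peaks <- extension_peaks(profile, prominence_mad)
  if (!is.null(restrict_regions)) {
    peaks <- intersect(peaks, restrict_regions)
    gene_regions <- intersect(gene_regions, restrict_regions)
  }
  if (length(peaks) == 0) stop("no peaks callable from the profile")
  if (length(gene_regions) == 0) stop("no genes in the evaluated stratum")
  count_overlap <- function(pk) {
    sum(vapply(pk, function(p)
      any(circular_distance(p, gene_regions, n) <= window), logical(1)))
  }
  obs <- count_overlap(peaks)
  pool <- if (is.null(restrict_regions)) seq_len(n) else restrict_regions
  set.seed(seed)
  null_ge <- 0L
  for (t in seq_len(n_permutations)) {
    pk <- sample(pool, length(peaks), replace = FALSE)
    if (count_overlap(pk) >= obs) null_ge <- null_ge + 1L
  }
  list(observed_overlap = obs, n_peaks = length(peaks),
       p_value = (1 + null_ge) / (n_permutations + 1),
       peak_regions = peaks, gene_regions = gene_regions)
}
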