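# most fixtures here are hand-built toy ensembles with construction-known
# answers (see helper-systems.R); larger statistical checks use the exact
# random-polymer sampler

box6 <- function() lattice_box(6, 6, 6)

test_that("axial distributions are normalized and localize a pinned region", {
  conf <- box6()
  still <- toy_ensemble(rep(list(matrix(c(0.5, 0.5, -2.5), 1)), 10), conf)
  h <- axial_distribution(still, 1, bins = 5)
  expect_equal(sum(h$prob), 1, tolerance = 1e-12)
  expect_equal(h$prob[1], 1)  # all mass in the pole-most bin
  moving <- toy_ensemble(list(matrix(c(0.5, 0.5, -2.5), 1),
                              matrix(c(0.5, 0.5, 2.5), 1)), conf)
  h2 <- axial_distribution(moving, 1, bins = 5)
  expect_equal(sum(h2$prob), 1, tolerance = 1e-12)
  expect_equal(h2$prob[c(1, 5)], c(0.5, 0.5))
  un <- still; un$oriented <- FALSE
  expect_error(axial_distribution(un, 1), "oriented")
})

test_that("tethered random polymer concentrates ori near the pole", {
  sys <- small_system()
  te <- orient_ensemble(random_polymer_baseline(sys$topo, sys$conf,
                                                tether = "ori_pole",
                                                n_samples = 400, seed = 9))
  h <- axial_distribution(te, 1, bins = 5)
  expect_equal(h$prob[1], 1)  # tether set is the pole-most axial slab
})

test_that("axial/radial correlations match hand-computed Pearson on a toy ensemble", {
  conf <- box6()
  # 3 snapshots, 3 regions; z-columns: a = (-2.5,-0.5,1.5), b = (-1.5,0.5,0.5),
  # c rigidly follows a one lattice step above
  mk <- function(za, zb, zc) rbind(c(0.5, 0.5, za), c(1.5, 0.5, zb), c(0.5, 1.5, zc))
  ens <- toy_ensemble(list(mk(-2.5, -1.5, -1.5), mk(-0.5, 0.5, 0.5),
                           mk(1.5, 0.5, 2.5)), conf)
  C <- axial_correlations(ens)
  expect_equal(diag(C), rep(1, 3))
  expect_equal(C[1, 2], cor(c(-2.5, -0.5, 1.5), c(-1.5, 0.5, 0.5)))
  expect_equal(C[1, 3], 1)  # rigid co-motion
  expect_true(all(C[!is.na(C)] >= -1 & C[!is.na(C)] <= 1))
})

test_that("radial correlations flag zero-variance regions and track co-motion", {
  conf <- box6()
  # region 1 radius varies; region 2 fixed radius (undefined); region 3
  # shares region 1's transverse position (correlation 1)
  at <- function(xy1, xy2) rbind(c(xy1, 0.5), c(xy2, 0.5), c(xy1, 1.5))
  ens <- toy_ensemble(list(at(c(0.5, 0.5), c(1.5, 0.5)),
                           at(c(2.5, 0.5), c(0.5, 1.5)),
                           at(c(1.5, 1.5), c(1.5, 0.5))), conf)
  R <- radial_correlations(ens)
  expect_equal(attr(R, "undefined_regions"), 2L)
  expect_true(all(is.na(R[2, ])))
  expect_equal(R[1, 1], 1)
  expect_equal(R[1, 3], 1)
})

test_that("angular correlations: identity, anti-alignment, isotropic decay", {
  conf <- box6()
  # region 2 always diametrically opposite region 1
  snaps <- lapply(list(c(0.5, 0.5), c(-1.5, 0.5), c(0.5, -2.5)), function(xy)
    rbind(c(xy, 0.5), c(-xy, 0.5)))
  ens <- toy_ensemble(snaps, conf)
  C <- angular_correlations(ens)
  expect_equal(diag(C), rep(1, 2))
  expect_equal(C[1, 2], -1)
  # independent uniform angles decorrelate
  set.seed(4)
  angs <- lapply(1:500, function(s) {
    xy <- matrix(sample(c(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5), 4, TRUE), 2)
    cbind(xy, c(0.5, 0.5))
  })
  iso <- toy_ensemble(angs, conf)
  Ci <- angular_correlations(iso)
  expect_lt(abs(Ci[1, 2]), 3 / sqrt(500))
})

test_that("SuD calls: collapse, two blobs, declustered, contiguity", {
  conf <- lattice_box(14, 14, 14)
  n <- 12
  collapsed <- matrix(rep(c(0.5, 0.5, 0.5), each = n), n)
  ens1 <- toy_ensemble(list(collapsed), conf, bin_size = 1e4)
  su1 <- identify_suds(ens1, snapshot = 1, radius = 2, min_size = 5)
  expect_equal(nrow(su1), 1)
  expect_equal(su1$n_regions, n)
  # two compact blobs joined by a stretched linker: regions 1-5 at one
  # corner, 7-11 far away, 6 and 12 isolated in between
  blob <- function(cx) rbind(c(cx, 0.5, 0.5), c(cx + 1, 0.5, 0.5),
                             c(cx, 1.5, 0.5), c(cx, 0.5, 1.5), c(cx + 1, 1.5, 0.5))
  two <- rbind(blob(-5.5), c(-0.5, 0.5, 5.5), blob(3.5), c(-0.5, 0.5, -5.5))
  # reorder rows to genomic order: 1-5 blob A, 6 linker, 7-11 blob B, 12 linker
  two <- two[c(1:5, 6, 7:11, 12), ]
  ens2 <- toy_ensemble(list(two), conf)
  su2 <- identify_suds(ens2, snapshot = 1, radius = 2, min_size = 5)
  expect_equal(nrow(su2), 2)
  expect_equal(sort(su2$n_regions), c(5, 5))
  mem <- attr(su2, "members")
  for (m in mem) expect_true(all(diff(m) == 1))  # genomic contiguity
  # widely spread grid: no SuDs
  spread <- cbind(seq(-5.5, 5.5, length.out = n), 0.5, rep(c(-5.5, 5.5), 6))
  spread <- spread[, c(1, 2, 3)]
  ens3 <- toy_ensemble(list(matrix(spread, n)), conf)
  expect_equal(nrow(identify_suds(ens3, snapshot = 1, radius = 1, min_size = 5)), 0)
})

test_that("SuD statistics do fixture bookkeeping exactly", {
  conf <- lattice_box(14, 14, 14)
  n <- 12
  collapsed <- matrix(rep(c(0.5, 0.5, 0.5), each = n), n)
  ens <- toy_ensemble(list(collapsed, collapsed), conf)
  st <- sud_statistics(ens)
  expect_equal(unname(st$fraction_in_suds["mean"]), 1)
  expect_equal(unname(st$regions_per_sud["mean"]), n)
  spread <- matrix(cbind(seq(-5.5, 5.5, length.out = n), 0.5,
                         rep(c(-5.5, 5.5), 6)), n)
  none <- toy_ensemble(list(spread), conf)
  st0 <- sud_statistics(none, radius = 1)
  expect_equal(unname(st0$fraction_in_suds["mean"]), 0)
})

test_that("inter-arm overlap reduction matches interval arithmetic on fixtures", {
  conf <- lattice_box(14, 14, 22)
  n <- 12  # regions 1-6 right arm, 7-12 left arm
  # configuration A: right-arm SuD occupies z in [-7.5,-2.5], left in [2.5,7.5]
  slab <- function(z0, x0 = 0.5) t(vapply(0:5, function(k)
    c(x0, 0.5, z0 + k), numeric(3)))
  confA <- rbind(slab(-7.5), slab(2.5, x0 = 3.5))
  # configuration B: arms swapped in z, so self-overlap is still 0 but
  # cross-pairing (right of A with left of B) overlaps fully
  confB <- rbind(slab(2.5), slab(-7.5, x0 = 3.5))
  ens <- toy_ensemble(list(confA, confB), conf)
  ov <- sud_overlap_reduction(ens, n_shuffles = 4, seed = 1,
                              radius = 1.2, min_size = 5)
  expect_equal(ov$observed, 0)
  expect_equal(ov$baseline, 1)  # swapped pairing: identical interval unions
  expect_equal(ov$reduction_pct, 100)
  # pairing a configuration with itself gives zero reduction by definition
  iv <- chromaxent:::sud_arm_intervals(ens, radius = 1.2, min_size = 5)
  self_base <- chromaxent:::arm_overlap_fraction(iv[[1]]$left, iv[[1]]$right)
  expect_equal(self_base, ov$observed)
})

test_that("local extension reproduces hand-computed toy values and bounds", {
  conf <- lattice_box(10, 10, 10)
  b <- conf$b
  # straight stretch: centers 3 lattice units apart along z
  n <- 4
  line <- cbind(0.5, 0.5, c(-4.5, -1.5, 1.5, 4.5))
  # make it a ring-consistent toy: circular neighbor of region 1 is region 4
  ens <- toy_ensemble(list(line), conf)
  d <- local_extension(ens)
  # d(4,1) = 9, others 3: delta_1 = (9+3)/2, delta_2 = 3, delta_4 = (3+9)/2
  expect_equal(d$delta_nm, c(6, 3, 3, 6) * b)
  one <- local_extension(ens, side = "next")
  expect_equal(one$delta_nm, c(3, 3, 3, 9) * b)
  collapsed <- toy_ensemble(list(matrix(rep(c(0.5, 0.5, 0.5), each = 6), 6)), conf)
  expect_equal(local_extension(collapsed)$delta_nm, rep(0, 6))
  # two-snapshot mean
  two <- toy_ensemble(list(line, cbind(0.5, 0.5, c(-1.5, -0.5, 0.5, 1.5))), conf)
  d2 <- local_extension(two)
  expect_equal(d2$delta_nm[2], mean(c(3, (1 + 1) / 2)) * b)
})

test_that("mean distance map: zero diagonal, symmetry, hand value", {
  conf <- box6()
  a <- rbind(c(0.5, 0.5, 0.5), c(0.5, 0.5, 2.5))
  b2 <- rbind(c(0.5, 0.5, 0.5), c(2.5, 0.5, 0.5))
  ens <- toy_ensemble(list(a, b2), conf)
  D <- mean_distance_map(ens)
  expect_equal(diag(D), rep(0, 2))
  expect_equal(D, t(D))
  expect_equal(D[1, 2], 2 * conf$b)
})

test_that("density rendering: single voxel, max normalization, mass conservation", {
  conf <- lattice_box(12, 12, 12)
  topo <- chain_topology(4, 4)
  ids <- chromaxent:::initial_ring(topo, conf)  # dimer fold at the center
  cfg <- chromo_config(ids, topo, conf)
  d0 <- render_density(cfg, blur_xyz = c(0, 0, 0), voxel = 1)
  expect_equal(max(d0$density), 1)
  expect_equal(sum(d0$raw), topo$N)
  expect_equal(sum(d0$raw > 0), 2)  # dimer start occupies two sites
  # blur well inside the grid conserves integrated density
  mid <- render_density(cfg, blur_xyz = c(0.8, 0.8, 0.8), voxel = 1)
  expect_lt(abs(sum(mid$blurred) - sum(mid$raw)) / sum(mid$raw), 1e-6)
  expect_equal(max(mid$density), 1)
  expect_error(render_density(cfg, voxel = 1e5), "voxel larger")
})

test_that("localization information: delta, uniform, octant, bounds", {
  conf <- spherocylinder_confinement(1, 3, 7)
  M <- conf$M
  expect_equal(distribution_information(rep(1 / M, M), conf), 0)
  p <- rep(0, M); p[5] <- 1
  expect_equal(distribution_information(p, conf), log2(M))
  oct <- conf$sites_lat[, 1] > 0 & conf$sites_lat[, 2] > 0 & conf$sites_lat[, 3] > 0
  po <- ifelse(oct, 1 / sum(oct), 0)
  expect_equal(distribution_information(po, conf), 3)
  # ensemble profile obeys the information bounds
  sys <- small_system()
  ens <- orient_ensemble(random_polymer_baseline(sys$topo, sys$conf,
                                                 n_samples = 600, seed = 12))
  prof <- localization_information(ens)
  expect_true(all(prof$info_bits >= 0 & prof$info_bits <= log2(sys$conf$M)))
  still <- toy_ensemble(rep(list(matrix(c(0.5, 0.5, 0.5), 1)), 50), box6())
  expect_equal(localization_information(still)$info_bits, log2(box6()$M))
})

test_that("sampled ori information converges to the exact transfer-matrix value", {
  sys <- small_system()
  conf <- sys$conf
  # exact marked-monomer marginal from closed-walk counts
  key <- apply(abs(conf$sites_lat), 1, paste, collapse = ",")
  reps <- which(!duplicated(key))
  logD <- chromaxent:::ring_logcounts_cpp(conf$neighbors, sys$topo$N,
                                          as.integer(reps - 1L))[match(key, key[reps])]
  p <- exp(logD - max(logD)); p <- p / sum(p)
  lower <- conf$sites_lat[, 3] < 0
  pf <- p[lower] + p[conf$z_mirror[lower]]
  exact_info <- log2(conf$M) + sum(pf * log2(pf))
  ens <- orient_ensemble(random_polymer_baseline(sys$topo, conf,
                                                 n_samples = 8000, seed = 19))
  est <- localization_information(ens)$info_bits[1]
  expect_lt(abs(est - exact_info), 0.1)
})

test_that("axial statistics are invariant under rotation about the long axis", {
  sys <- small_system()
  ens <- orient_ensemble(random_polymer_baseline(sys$topo, sys$conf,
                                                 n_samples = 500, seed = 23))
  # site permutation for the quarter-turn (x, y) -> (-y, x)
  rot <- site_ids_for(sys$conf, cbind(-sys$conf$sites_lat[, 2],
                                      sys$conf$sites_lat[, 1],
                                      sys$conf$sites_lat[, 3]))
  rens <- ens
  rens$center_sites <- matrix(rot[ens$center_sites], nrow(ens$center_sites))
  expect_equal(axial_correlations(rens), axial_correlations(ens))
  expect_equal(local_extension(rens)$delta_nm, local_extension(ens)$delta_nm)
  expect_equal(localization_information(rens)$info_bits,
               localization_information(ens)$info_bits)
  expect_equal(sud_statistics(rens)$fraction_in_suds,
               sud_statistics(ens)$fraction_in_suds)
})

test_that("extension peaks vs genes: extremes and null calibration", {
  conf <- box6()
  n <- 20
  set.seed(31)
  snaps <- lapply(1:3, function(s)
    cbind(sample(c(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5), n, TRUE),
          sample(c(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5), n, TRUE),
          sample(c(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5), n, TRUE)))
  ens <- toy_ensemble(snaps, conf)
  prof <- local_extension(ens)
  # force a known peak structure
  prof$delta_nm <- rep(1, n)
  prof$delta_nm[c(5, 14)] <- 10
  pk <- extension_peaks(prof)
  expect_equal(pk, c(5, 14))
  genes_hit <- data.frame(start = (pk - 1) * 1e4, end = pk * 1e4)
  res <- extension_peak_gene_overlap(prof, genes_hit, n_permutations = 200,
                                     seed = 1, window = 0)
  expect_equal(res$observed_overlap, length(pk))
  expect_lte(res$p_value, 0.06)
  genes_miss <- data.frame(start = 8 * 1e4, end = 9 * 1e4)  # region 9, no peak
  res0 <- extension_peak_gene_overlap(prof, genes_miss, n_permutations = 50,
                                      seed = 1, window = 0)
  expect_equal(res0$observed_overlap, 0)
  expect_equal(res0$p_value, 1)
  expect_error(extension_peak_gene_overlap(prof, genes_hit[0, ]), "empty gene")
  # null calibration: with genes placed independently of the peaks, the
  # permutation p-value is valid (super-uniform up to Monte Carlo error;
  # exact uniformity is unattainable for a discrete statistic)
  set.seed(7)
  pvals <- replicate(150, {
    g <- data.frame(start = (sample(n, 3) - 1) * 1e4)
    g$end <- g$start + 1e4
    extension_peak_gene_overlap(prof, g, n_permutations = 60,
                                seed = sample.int(1e6, 1), window = 1)$p_value
  })
  for (alpha in c(0.1, 0.25, 0.5)) {
    se <- sqrt(alpha * (1 - alpha) / 150)
    expect_lte(mean(pvals <= alpha), alpha + 3 * se)
  }
})
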