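test_that("ground-truth generation is deterministic and motif-faithful", {
  expect_equal(generate_ground_truth(8, list())$eps, matrix(0, 8, 8))
  m <- list(list(type = "random_sparse", strength = 0.5, density = 0.3))
  a <- generate_ground_truth(12, m, seed = 5)
  b <- generate_ground_truth(12, m, seed = 5)
  expect_identical(a$eps, b$eps)
  expect_identical(a$eps, t(a$eps))
  # secondary diagonal: anti-diagonal partner pairs carry the strength
  n <- 10
  sd_ <- generate_ground_truth(n, list(list(type = "secondary_diagonal",
                                            strength = -1.5, width = 0)))
  for (i in 3:(n - 1)) {
    j <- ((n - i + 1) %% n) + 1
    if (chromaxent:::circular_distance(i, j, n) >= 2)
      expect_equal(sd_$eps[i, j], -1.5)
  }
  nd <- generate_ground_truth(n, list(list(type = "near_diagonal",
                                           strength = -0.4, width = 2)))
  expect_equal(nd$eps[1, 3], -0.4)
  expect_equal(nd$eps[1, 4], -0.4)
  expect_equal(nd$eps[1, 5], 0)
  expect_equal(nd$eps[1, 2], 0)  # connectivity band untouched
  expect_error(generate_ground_truth(8, list(list(type = "nope", strength = 1))),
               "unknown motif")
})

test_that("simulated maps scale with the conversion factor and stay symmetric", {
  sys <- small_system(n_regions = 6)
  eps <- generate_ground_truth(6, list(list(type = "near_diagonal",
                                            strength = -0.6, width = 1)))
  m1 <- simulate_hic_map(eps, sys$topo, sys$conf, n_samples = 2000, seed = 3)
  m2 <- simulate_hic_map(eps, sys$topo, sys$conf, n_samples = 2000, seed = 3,
                         c_true = 2)
  expect_equal(m2$scores, m1$scores / 2)
  expect_equal(m1$kind, "normalized_experimental")
  mn <- simulate_hic_map(eps, sys$topo, sys$conf, n_samples = 2000, seed = 3,
                         noise = 0.2)
  expect_identical(mn$scores, t(mn$scores))
  expect_false(identical(mn$scores, m1$scores))
})

test_that("tiny simulated map matches enumeration frequencies within noise", {
  sys <- tiny_system()
  e <- matrix(0, 4, 4); e[1, 3] <- e[3, 1] <- -0.9
  orc <- enumerate_ring_ensemble(e, sys$topo, sys$conf)
  m <- simulate_hic_map(interaction_matrix(e), sys$topo, sys$conf,
                        n_samples = 3e4, c_true = 2, seed = 9,
                        thin_sweeps = 8, burn_in = 400)
  fex <- orc$contact_map$scores / 2
  se <- sqrt(orc$contact_map$scores * (1 - orc$contact_map$scores) / 3e4) / 2
  off <- upper.tri(fex)
  expect_true(all(abs(m$scores[off] - fex[off]) <= 4 * pmax(se[off], 1e-12)))
})

test_that("contact maps round-trip through dense and triplet text formats", {
  tmp <- withr::local_tempdir()
  m <- matrix(c(0, 0.123456789012345, 2e-7, 0.123456789012345, 0, 3,
                2e-7, 3, 0), 3)
  cm <- contact_map(m)
  dense <- file.path(tmp, "m.tsv")
  write_contact_map(cm, dense)
  back <- read_contact_map(dense)
  expect_equal(back$scores, cm$scores, tolerance = 1e-15)
  # triplet, upper triangle only, mirrored on load
  trip <- file.path(tmp, "m3.txt")
  writeLines(c("1 2 0.5", "1 3 0.25", "2 3 1.5"), trip)
  tm <- read_contact_map(trip, dialect = "triplet")
  expect_equal(tm$scores[2, 1], 0.5)
  expect_equal(tm$scores[3, 1], 0.25)
  # malformed inputs
  writeLines(c("1 2 3 4", "5 6 7 8"), file.path(tmp, "bad.tsv"))
  expect_error(read_contact_map(file.path(tmp, "bad.tsv")), "square")
  asym <- file.path(tmp, "asym.tsv")
  writeLines(c("0\t1\t2", "9\t0\t3", "2\t3\t0"), asym)
  expect_error(read_contact_map(asym), "symmetric")
  neg <- file.path(tmp, "neg.tsv")
  writeLines(c("0\t-1", "-1\t0"), neg)
  expect_error(read_contact_map(neg), "negative")
  expect_error(read_contact_map(file.path(tmp, "missing.tsv")), "not found")
})

test_that("fit results and configurations round-trip losslessly", {
  tmp <- withr::local_tempdir()
  n <- 5
  e <- matrix(0, n, n); e[1, 3] <- e[3, 1] <- -0.25
  mask <- matrix(FALSE, n, n); mask[2, 5] <- mask[5, 2] <- TRUE
  fit <- structure(list(eps = interaction_matrix(e, mask), c_tilde = 1.25,
                        converged = TRUE, gamma = 1, seed = 42,
                        history = data.frame(iter = 1, step = 0.5,
                                             c_tilde = 1.25, deviation_pct = 2,
                                             pearson = 0.999,
                                             residual_rel = 1e-3,
                                             acceptance = 0.7)),
                   class = "maxent_fit")
  stem <- file.path(tmp, "fit")
  write_fit_result(fit, stem)
  back <- read_interaction_matrix(paste0(stem, "_eps.tsv"))
  expect_equal(back$eps, fit$eps$eps, tolerance = 1e-15)
  expect_equal(back$infinite_mask, fit$eps$infinite_mask)
  side <- jsonlite::read_json(paste0(stem, ".json"))
  expect_equal(side$c_tilde, 1.25)
  cfg <- read_run_config(NULL)
  cfg$seed <- 17
  y <- file.path(tmp, "c.yaml")
  write_run_config(cfg, y)
  expect_equal(read_run_config(y)$seed, 17)
  expect_equal(read_run_config(y)$geometry$lattice_spacing_nm, 88)
  j <- file.path(tmp, "c.json")
  write_run_config(cfg, j)
  expect_equal(read_run_config(j)$fit$tol_pearson, 0.998)
})

test_that("BED6 gene tables parse with strand information", {
  tmp <- withr::local_tempdir()
  bed <- file.path(tmp, "genes.bed")
  writeLines(c("chr\t1000\t2500\tgeneA\t900\t+",
               "chr\t52000\t53000\tgeneB\t880\t-"), bed)
  g <- read_bed_genes(bed)
  expect_equal(g$start, c(1000, 52000))
  expect_equal(g$strand, c("+", "-"))
})

test_that("ensemble export writes coordinates with provenance ordering", {
  sys <- tiny_system()
  ens <- random_polymer_baseline(sys$topo, sys$conf, n_samples = 3, seed = 2)
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "ens.tsv")
  write_ensemble(ens, f, xyz = file.path(tmp, "ens.xyz"))
  tab <- read.table(f, header = TRUE)
  expect_equal(nrow(tab), 3 * 4)
  expect_equal(tab$x[1:4], sys$conf$sites[ens$center_sites[1, ], 1])
  expect_equal(readLines(file.path(tmp, "ens.xyz"))[1], "4")
})

test_that("CLI closes the loop: synth -> fit -> recovery, and fails cleanly", {
  tmp <- withr::local_tempdir()
  out <- file.path(tmp, "run")
  code <- chromaxent_cli(c("recover-test", "--n-regions", "10",
                           "--seed", "3", "--out", out))
  expect_equal(code, 0L)
  rep <- jsonlite::read_json(paste0(out, "_recovery.json"))
  expect_lt(rep$rmse, 0.15)
  expect_gt(rep$pearson, 0.95)
  # malformed (non-square) matrix: nonzero exit, no fit output
  bad <- file.path(tmp, "bad")
  writeLines(c("0\t0.5\t0.2", "0.5\t0\t0.4"), file.path(tmp, "bad_hic.tsv"))
  code2 <- chromaxent_cli(c("fit", "--hic", file.path(tmp, "bad_hic.tsv"),
                            "--out", bad))
  expect_equal(code2, 1L)
  expect_false(file.exists(paste0(bad, "_eps.tsv")))
  expect_equal(chromaxent_cli(c("frobnicate")), 1L)
})

test_that("CLI synth runs are byte-identical under a fixed seed", {
  tmp <- withr::local_tempdir()
  a <- file.path(tmp, "a"); b <- file.path(tmp, "b")
  expect_equal(chromaxent_cli(c("synth", "--n-regions", "8", "--seed", "5",
                                "--out", a)), 0L)
  expect_equal(chromaxent_cli(c("synth", "--n-regions", "8", "--seed", "5",
                                "--out", b)), 0L)
  expect_identical(readLines(paste0(a, "_hic.tsv")),
                   readLines(paste0(b, "_hic.tsv")))
  expect_identical(readLines(paste0(a, "_eps_true.tsv")),
                   readLines(paste0(b, "_eps_true.tsv")))
})
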