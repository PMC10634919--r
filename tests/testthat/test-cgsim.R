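test_that("single-chain builder counts beads, bonds and charges", {
  cfg <- simulation_config(box = c(10, 10, 10), seed = 2)
  sys <- build_single_chain(protein_sequence(strrep("A", 10)), cfg)
  expect_equal(nrow(sys$topology$beads), 10L)
  expect_equal(nrow(sys$topology$bonds), 9L)
  # initial bond lengths all at r0
  b <- sys$topology$bonds
  d <- sqrt(rowSums((sys$coords[b[, 1], ] - sys$coords[b[, 2], ])^2))
  expect_equal(d, rep(0.38, 9), tolerance = 1e-9)

  kkee <- build_single_chain(protein_sequence("KKEE"), cfg)
  expect_equal(sum(kkee$topology$beads$charge), 0)
  expect_error(build_single_chain(protein_sequence(strrep("G", 100)),
                                  simulation_config(box = c(1, 1, 1))),
               "too small")
})

test_that("slab builder packs chains in the central z-third", {
  cfg <- simulation_config(box = c(8, 8, 36), seed = 5)
  seq20 <- protein_sequence(strrep("GS", 10))
  sys <- build_slab(seq20, 10, cfg)
  expect_equal(nrow(sys$topology$beads), 200L)
  expect_equal(nrow(sys$topology$bonds), 190L)
  expect_true(all(sys$coords[, 3] >= 36 / 2 - 36 / 6 &
                    sys$coords[, 3] <= 36 / 2 + 36 / 6))
  # no two beads overlap
  dmin <- min(dist(sys$coords))
  expect_gt(dmin, 0.3)
  # identical seed, identical coordinates
  sys2 <- build_slab(seq20, 10, cfg)
  expect_identical(sys$coords, sys2$coords)
})

test_that("pair potential has the documented shape and signs", {
  cfg <- simulation_config()
  # far beyond every cutoff
  expect_equal(pair_potential("G", "S", 5, cfg), 0)
  # electrostatic sign symmetry at equal distance
  e_pp <- pair_potential("K", "K", 1, cfg)
  e_pm <- pair_potential("K", "E", 1, cfg)
  e_gg <- pair_potential("G", "G", 1, cfg)
  expect_gt(e_pp - e_gg, 0)
  expect_lt(e_pm - e_gg, 0)
  # continuity across the hydropathy split at 2^(1/6) sigma
  sig <- mean(hps_parameters()$sigma[hps_parameters()$aa %in% "Y"])
  rs <- 2^(1 / 6) * sig + c(-1e-9, 1e-9)
  ee <- pair_potential("Y", "Y", rs, cfg)
  expect_lt(abs(diff(ee)), 1e-6)
  expect_error(pair_potential("B", "G", 1, cfg), "unknown residue")
})

test_that("a zero-hydropathy pair reduces to pure repulsion", {
  # glutamate pairs carry lambda = 0: compare with the attractive branch
  cfg <- simulation_config(ionic_strength_mM = 1e9)  # kill electrostatics
  r <- seq(0.3, 1.99, by = 0.005)
  ee <- pair_potential("E", "E", r, cfg)
  expect_true(all(ee >= -1e-12))
  # a high-lambda pair does attract
  expect_lt(min(pair_potential("Y", "Y", r, cfg)), -0.5)
})

test_that("R-level pair potential agrees with the compiled energy", {
  cfg <- simulation_config(box = c(50, 50, 50), seed = 3)
  seqx <- protein_sequence("KYEGSAQTPV")
  sys <- build_single_chain(seqx, cfg)
  e_cpp <- cg_potential_energy(sys$topology, sys$coords, cfg,
                               periodic = FALSE)
  chars <- strsplit(seqx$residues, "")[[1]]
  e_r <- 0
  for (i in 1:9) {
    # bond energy
    d <- sqrt(sum((sys$coords[i, ] - sys$coords[i + 1, ])^2))
    e_r <- e_r + 0.5 * 8368 * (d - 0.38)^2
  }
  for (i in 1:9) {
    for (j in (i + 1):10) {
      if (j == i + 1) next
      d <- sqrt(sum((sys$coords[i, ] - sys$coords[j, ])^2))
      e_r <- e_r + pair_potential(chars[i], chars[j], d, cfg)
    }
  }
  expect_equal(e_cpp, e_r, tolerance = 1e-9)
})

test_that("dynamics are deterministic and hold the target temperature", {
  seq50 <- protein_sequence(strrep("GS", 25))
  cfg <- simulation_config(box = c(20, 20, 20), n_steps = 150000,
                           save_every = 150, seed = 7, t_damp_ps = 1)
  sys <- build_single_chain(seq50, cfg)
  tr <- run_langevin(sys$topology, sys$coords, cfg, nonbonded = FALSE,
                     periodic = FALSE)
  tr2 <- run_langevin(sys$topology, sys$coords, cfg, nonbonded = FALSE,
                      periodic = FALSE)
  expect_identical(tr$coords, tr2$coords)
  expect_equal(n_frames(tr), 1000L)
  expect_true(all(diff(tr$time) > 0))

  # equipartition: mean kinetic temperature within 2% of the target
  kt <- attr(tr, "kinetic_temperature")
  expect_lt(abs(mean(kt) - 300) / 300, 0.02)

  # center-of-mass motion stays within the diffusive envelope
  m <- sys$topology$beads$mass
  com <- apply(tr$coords, c(1, 3), function(x) sum(x * m) / sum(m))
  disp2 <- rowSums((com - matrix(com[1, ], nrow(com), 3, byrow = TRUE))^2)
  d_com <- 0.0083144621 * 300 * cfg$t_damp_ps / sum(m)  # nm^2/ps
  expect_lt(max(disp2), 25 * 6 * d_com * max(tr$time))
})

test_that("bond lengths follow the harmonic Boltzmann distribution", {
  seq20 <- protein_sequence(strrep("A", 20))
  cfg <- simulation_config(box = c(20, 20, 20), n_steps = 120000,
                           save_every = 300, seed = 13, t_damp_ps = 1)
  sys <- build_single_chain(seq20, cfg)
  tr <- run_langevin(sys$topology, sys$coords, cfg, nonbonded = FALSE,
                     periodic = FALSE)
  b <- sys$topology$bonds
  obs <- as.vector(sqrt((tr$coords[, b[, 1], 1] - tr$coords[, b[, 2], 1])^2 +
                          (tr$coords[, b[, 1], 2] - tr$coords[, b[, 2], 2])^2 +
                          (tr$coords[, b[, 1], 3] - tr$coords[, b[, 2], 3])^2))
  obs <- obs[seq(1, length(obs), by = 8)]
  # oracle: direct sampling from p(r) ~ r^2 exp(-k (r - r0)^2 / (2 kT))
  set.seed(99)
  kT <- 0.0083144621 * 300
  sd_b <- sqrt(kT / 8368)
  cand <- rnorm(40000, 0.38, sd_b)
  keep <- runif(40000) < (cand / (0.38 + 4 * sd_b))^2
  oracle <- cand[keep]
  ks <- suppressWarnings(stats::ks.test(obs, oracle))
  expect_gt(ks$p.value, 1e-3)
})

test_that("bonds-only chains reproduce ideal-chain statistics", {
  n <- 50
  seq50 <- protein_sequence(strrep("GS", 25))
  cfg <- simulation_config(box = c(20, 20, 20), n_steps = 200000,
                           save_every = 200, seed = 17, t_damp_ps = 1)
  sys <- build_single_chain(seq50, cfg)
  tr <- run_langevin(sys$topology, sys$coords, cfg, nonbonded = FALSE,
                     periodic = FALSE)
  rg2 <- mean(radius_of_gyration(tr)$rg^2)
  ideal <- 0.38^2 * (n^2 - 1) / (6 * n)
  expect_equal(rg2, ideal, tolerance = 0.1)
})

test_that("unstable integration aborts with a diagnostic", {
  seq5 <- protein_sequence("GGGGG")
  cfg <- simulation_config(box = c(5, 5, 5), n_steps = 50000,
                           save_every = 100, timestep_fs = 3e4, seed = 1)
  sys <- build_single_chain(seq5, cfg)
  expect_error(run_langevin(sys$topology, sys$coords, cfg,
                            minimize_steps = 0, thermalize_ps = 0),
               "blow-up")
})

test_that("sticky chains condense while repulsive chains stay uniform", {
  sticky <- protein_sequence(strrep("YGY", 5))  # 15-mer, strongly attractive
  cfg <- simulation_config(box = c(5, 5, 25), n_steps = 100000,
                           save_every = 500, seed = 23)
  sys <- build_slab(sticky, 6, cfg)
  tr <- run_langevin(sys$topology, sys$coords, cfg)
  prof <- density_profile(center_slab(tr), bin_nm = 1.25,
                          equilibration_ps = 0.4 * max(tr$time))
  expect_gt(max(prof$conc_mg_ml) / max(min(prof$conc_mg_ml), 1e-9), 5)

  # purely repulsive interactions: the (uncentered) profile is flat within
  # noise; centering a uniform system on its own fluctuations would bias the
  # central bins, so flatness is judged on the raw frames
  trr <- run_langevin(sys$topology, sys$coords, cfg, lambda_scale = 0)
  pr <- density_profile(trr, bin_nm = 2.5,
                        equilibration_ps = 0.5 * max(trr$time), n_blocks = 8)
  sem <- apply(pr$blocks, 2, sd) / sqrt(nrow(pr$blocks))
  dev <- abs(pr$conc_mg_ml - mean(pr$conc_mg_ml))
  expect_true(mean(dev <= 3 * pmax(sem, 1e-9)) >= 0.8)
  prc <- density_profile(center_slab(trr), bin_nm = 1.25,
                         equilibration_ps = 0.5 * max(trr$time), n_blocks = 8)
  expect_true(coexistence_densities(prc)$single_phase)
})
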