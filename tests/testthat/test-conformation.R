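test_that("contact counting respects the cutoff threshold", {
  close_pair <- toy_trajectory(list(rbind(c(0, 0, 0), c(0.59, 0, 0))),
                               resid = c(1L, 3L))
  far_pair <- toy_trajectory(list(rbind(c(0, 0, 0), c(0.61, 0, 0))),
                             resid = c(1L, 3L))
  expect_equal(sum(contact_map(close_pair, 0.6)$counts), 2)  # symmetric
  expect_equal(sum(contact_map(far_pair, 0.6)$counts), 0)
  expect_error(contact_map(close_pair, -1), "positive")
})

test_that("contact maps are symmetric and match brute force", {
  set.seed(5)
  n_at <- 120
  frames <- lapply(1:4, function(f) matrix(runif(n_at * 3, 0, 3), ncol = 3))
  resid <- rep(1:30, each = 4)
  chain <- rep(1:2, each = 60)
  element <- sample(c("C", "N", "O", "H"), n_at, replace = TRUE)
  tr <- toy_trajectory(frames, resid = resid, chain = chain,
                       element = element, box = c(3, 3, 3))

  for (mode in c("intramolecular", "intermolecular")) {
    cm <- contact_map(tr, 0.6, mode = mode)
    expect_identical(cm$counts, t(cm$counts))
    bf <- matrix(0, 30, 30)
    for (f in 1:4) {
      bf <- bf + brute_force_contacts(frames[[f]], resid, chain,
                                      element != "H", 0.6, mode = mode,
                                      exclude = 1L, box = c(3, 3, 3))
    }
    expect_equal(cm$counts, bf)
  }

  # intramolecular mode excludes bonded neighbours
  lin <- toy_trajectory(list(cbind(seq(0, 1.5, length.out = 6), 0, 0)))
  cm <- contact_map(lin, 0.7, mode = "intramolecular", exclude = 1L)
  expect_equal(cm$counts[1, 2], 0)
  expect_equal(cm$counts[1, 3], 1)
})

test_that("residue-type aggregation conserves the grand total", {
  tr <- toy_trajectory(list(rbind(c(0, 0, 0), c(0.3, 0, 0), c(0.45, 0, 0))),
                       resid = 1:3)
  cm <- contact_map(tr, 0.6, exclude = 0L)
  seq3 <- protein_sequence("YYG")
  tt <- residue_type_contacts(cm, seq3)
  expect_equal(sum(tt), sum(cm$counts))
  expect_equal(tt["Y", "Y"], 2)  # the (1,2) contact counted from both ends
  expect_equal(tt["Y", "G"] + tt["G", "Y"], 4)
  expect_error(residue_type_contacts(cm, protein_sequence("YY")),
               "numbering")
})

test_that("per-residue profile conserves totals and finds sticky patches", {
  set.seed(6)
  frames <- lapply(1:3, function(f) matrix(runif(60, 0, 2.5), ncol = 3))
  tr <- toy_trajectory(frames, resid = 1:20)
  cm <- contact_map(tr, 0.6)
  prof <- per_residue_contacts(cm)
  expect_equal(sum(prof$contacts_total), sum(cm$counts))

  zero <- per_residue_contacts(contact_map(tr, 1e-6))
  expect_true(all(zero$contacts_total == 0))

  # chain with one clustered patch: profile peaks at the patch residues
  x <- seq(0, 19) * 0.8
  x[9:12] <- 7.0 + c(0, 0.3, 0.15, 0.45)  # residues 9-12 piled together
  patch <- toy_trajectory(list(cbind(x, 0, 0)))
  pp <- per_residue_contacts(contact_map(patch, 0.6))
  expect_true(min(pp$contacts_total[9:12]) > max(pp$contacts_total[-(9:12)]))
})

test_that("distance-proxy PRE profile matches hand-computed geometry", {
  # rigid linear 5-bead chain, 1 nm spacing, label at bead 1
  tr <- toy_trajectory(list(cbind(0:4, 0, 0)), resid = 1:5)
  prof <- pre_proxy(tr, label_residue = 1, cutoff = 3.5)
  raw <- c(1, 2, 3)^-6  # bead 5 at 4 nm is beyond the cutoff
  expect_equal(prof$value, c(raw / max(raw), 0))
  expect_equal(prof$value[1], 1)  # normalising residue exactly 1
  expect_error(pre_proxy(tr, label_residue = 99), "no heavy atoms")
})

test_that("PRE proxy is scale covariant and replica-averaged", {
  set.seed(7)
  frames <- lapply(1:5, function(f) matrix(rnorm(30, sd = 0.8), ncol = 3))
  tr <- toy_trajectory(frames, resid = 1:10)
  p1 <- pre_proxy(tr, 3, cutoff = 2)
  dilated <- toy_trajectory(lapply(frames, function(m) 1.7 * m),
                            resid = 1:10)
  p2 <- pre_proxy(dilated, 3, cutoff = 2 * 1.7)
  expect_equal(p1$value, p2$value, tolerance = 1e-12)

  reps <- pre_proxy(list(tr, dilated), 3, cutoff = 2)
  expect_true(all(is.finite(reps$sem)))
})

test_that("radius of gyration matches closed forms", {
  coincident <- toy_trajectory(list(matrix(0, 5, 3)))
  expect_equal(radius_of_gyration(coincident)$rg, 0)

  # collinear rod: Rg^2 = b^2 (N^2 - 1) / 12
  n <- 11
  b <- 0.38
  rod <- toy_trajectory(list(cbind(b * (0:(n - 1)), 0, 0)),
                        mass = rep(1, n))
  expect_equal(radius_of_gyration(rod)$rg^2, b^2 * (n^2 - 1) / 12,
               tolerance = 1e-12)

  # freely-jointed ensemble: <Rg^2> = b^2 (N^2 - 1) / (6 N)
  nb <- 40
  tr <- toy_trajectory(ideal_chain_frames(nb, 800, b = b, seed = 3),
                       resid = 1:nb, mass = rep(1, nb))
  expect_equal(mean(radius_of_gyration(tr)$rg^2),
               b^2 * (nb^2 - 1) / (6 * nb), tolerance = 0.05)

  # wrapped chains are rejected with advice
  wrapped <- toy_trajectory(list(rbind(c(0.1, 0, 0), c(2.9, 0, 0))),
                            box = c(3, 3, 3))
  expect_error(radius_of_gyration(wrapped), "unwrap")
  expect_equal(radius_of_gyration(unwrap_chains(wrapped))$rg,
               0.1, tolerance = 1e-12)
})

test_that("whole-chain Rg obeys the parallel-axis decomposition", {
  set.seed(9)
  x <- matrix(rnorm(60), ncol = 3)
  m <- runif(20, 50, 150)
  tr <- toy_trajectory(list(x), resid = 1:20, mass = m)
  segs <- list(1:7, 8:13, 14:20)
  whole <- radius_of_gyration(tr)$rg^2
  com <- colSums(x * m) / sum(m)
  acc <- 0
  for (s in segs) {
    ms <- sum(m[s])
    cs <- colSums(x[s, , drop = FALSE] * m[s]) / ms
    rg2s <- sum(m[s] * rowSums((x[s, ] - matrix(cs, length(s), 3,
                                                byrow = TRUE))^2)) / ms
    acc <- acc + ms / sum(m) * (rg2s + sum((cs - com)^2))
  }
  expect_equal(whole, acc, tolerance = 1e-12)
})

test_that("Rg correlation time recovers the AR(1) constant", {
  set.seed(10)
  phi <- exp(-1 / 20)  # tau = 20 frames
  n <- 20000
  x <- numeric(n)
  for (i in 2:n) x[i] <- phi * x[i - 1] + rnorm(1)
  expect_equal(rg_correlation_time(2 + 0.1 * x, dt_ps = 1), 20,
               tolerance = 0.1)

  white <- rnorm(5000)
  expect_lt(rg_correlation_time(white, dt_ps = 1), 1)
  expect_error(rg_correlation_time(rep(1, 100)), "constant")
})

test_that("distance scaling separates rod, ideal and zero-separation", {
  n <- 30
  rod <- toy_trajectory(list(cbind(0.38 * (0:(n - 1)), 0, 0)), resid = 1:n)
  ds <- distance_scaling(rod)
  expect_equal(ds$exponent, 1, tolerance = 1e-9)
  expect_equal(ds$curve$mean_distance[ds$curve$separation == 0], 0)

  tr <- toy_trajectory(ideal_chain_frames(40, 600, seed = 4), resid = 1:40)
  di <- distance_scaling(tr, window = c(3, 20))
  expect_equal(di$exponent, 0.5, tolerance = 0.05)
})

test_that("segment compaction ranks collapsed regions", {
  # homogeneous ideal chain: equal-length segments indistinguishable
  tr <- toy_trajectory(ideal_chain_frames(60, 400, seed = 8), resid = 1:60)
  sc <- segment_compaction(tr, list(c(1, 20), c(21, 40), c(41, 60)))
  ks <- suppressWarnings(
    stats::ks.test(sc$distributions[[1]]$rg, sc$distributions[[3]]$rg))
  expect_gt(ks$p.value, 0.001)

  # one collapsed block: that segment has the smallest mean Rg
  frames <- ideal_chain_frames(60, 200, seed = 12)
  frames <- lapply(frames, function(m) {
    mid <- colMeans(m[21:40, ])
    m[21:40, ] <- matrix(mid, 20, 3, byrow = TRUE) +
      0.15 * (m[21:40, ] - matrix(mid, 20, 3, byrow = TRUE))
    m
  })
  trc <- toy_trajectory(frames, resid = 1:60)
  scc <- segment_compaction(trc, list(c(1, 20), c(21, 40), c(41, 60)))
  expect_equal(which.min(scc$summary$mean_rg), 2L)

  single <- segment_compaction(tr, list(c(5, 5)), strict = FALSE)
  expect_true(all(single$distributions[[1]]$rg == 0))
  expect_error(segment_compaction(tr, list(c(1, 30), c(25, 60))), "overlap")
  expect_error(segment_compaction(tr, list(c(0, 10))), "out of range")
})
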