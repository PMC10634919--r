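static_nh_trajectory <- function(u, n_frames, n_residues = 1, dt = 1,
                                 invert_alternate = FALSE) {
  frames <- lapply(seq_len(n_frames), function(f) {
    sgn <- if (invert_alternate && f %% 2 == 0) -1 else 1
    do.call(rbind, lapply(seq_len(n_residues), function(r) {
      n <- c(2 * r, 0, 0)
      rbind(n, n + 0.102 * sgn * u)
    }))
  })
  toy_trajectory(frames,
                 resid = rep(seq_len(n_residues), each = 2),
                 atom = rep(c("N", "H"), n_residues),
                 element = rep(c("N", "H"), n_residues),
                 mass = rep(c(14, 1), n_residues), dt = dt)
}

test_that("P2 autocorrelation is 1 for static and inversion-flipped vectors", {
  u <- c(1, 2, 2) / 3
  tr <- static_nh_trajectory(u, n_frames = 64)
  acfs <- nh_autocorrelation(tr, block_ps = 32)
  expect_equal(as.vector(acfs$acf), rep(1, length(acfs$lag_ps)),
               tolerance = 1e-10)
  expect_equal(acfs$n_blocks, 2L)

  # P2 is inversion symmetric: a vector flipped every frame decorrelates not
  tr2 <- static_nh_trajectory(u, n_frames = 64, invert_alternate = TRUE)
  acfs2 <- nh_autocorrelation(tr2, block_ps = 32)
  expect_equal(as.vector(acfs2$acf), rep(1, length(acfs2$lag_ps)),
               tolerance = 1e-10)
})

test_that("amide-free residues are absent and block length is validated", {
  u <- c(0, 0, 1)
  tr <- static_nh_trajectory(u, n_frames = 32, n_residues = 3)
  tr$topology$atom[2] <- "CA"  # residue 1 loses its H
  acfs <- nh_autocorrelation(tr, block_ps = 16)
  expect_equal(acfs$residues, c(2L, 3L))
  expect_error(nh_autocorrelation(tr, block_ps = 1e6), "exceeds")
})

test_that("diffusive rotor ACF matches the analytic exponential", {
  d_r <- 2e-3  # rad^2/ps -> tau = 1/(6 d_r) ~ 83 ps
  tr <- make_rotor_trajectory(n_residues = 12, n_frames_ = 6000, dt_ps = 1,
                              d_r = d_r, seed = 4)
  acfs <- nh_autocorrelation(tr, block_ps = 1500, max_lag_fraction = 0.2)
  mean_acf <- colMeans(acfs$acf)
  expected <- exp(-6 * d_r * acfs$lag_ps)
  expect_lt(max(abs(mean_acf - expected)), 0.05)
})

test_that("bi-exponential fits round-trip and tolerate degeneracy", {
  lag <- seq(0, 5000, by = 10)  # ps
  clean <- list(lag_ps = lag,
                acf = rbind(0.6 * exp(-lag / 100) + 0.4 * exp(-lag / 5000),
                            exp(-lag / 800)),
                residues = 1:2)
  fit <- fit_biexponential(clean)
  expect_true(all(fit$converged))
  # parameters recovered for the genuinely bi-exponential residue
  expect_equal(fit$a1[1], 0.6, tolerance = 1e-6)
  expect_equal(fit$tau1_ps[1], 100, tolerance = 1e-4)
  expect_equal(fit$a2[1], 0.4, tolerance = 1e-6)
  expect_equal(fit$tau2_ps[1], 5000, tolerance = 1e-3)
  # degenerate single exponential: the fitted curve reproduces the input
  curve2 <- fit$a1[2] * exp(-lag / fit$tau1_ps[2]) +
    fit$a2[2] * exp(-lag / fit$tau2_ps[2])
  expect_lt(max(abs(curve2 - clean$acf[2, ])), 1e-6)
  expect_error(fit_biexponential(list(lag_ps = 1:5, acf = matrix(1, 1, 5),
                                      residues = 1)), "lag points")
})

test_that("tau2 is recovered within 5% on average from 1% noise", {
  set.seed(31)
  lag <- seq(0, 4000, by = 20)
  truth <- 0.5 * exp(-lag / 80) + 0.5 * exp(-lag / 2000)
  reps <- 100
  tau2 <- numeric(reps)
  for (r in seq_len(reps)) {
    noisy <- truth + rnorm(length(lag), sd = 0.01)
    fit <- fit_biexponential(list(lag_ps = lag, acf = rbind(noisy),
                                  residues = 1))
    tau2[r] <- fit$tau2_ps
  }
  expect_lt(abs(mean(tau2) - 2000) / 2000, 0.05)
})

test_that("spectral density matches closed form and quadrature", {
  a <- c(0.3, 0.7)
  tau <- c(50, 3000)  # ps
  expect_equal(spectral_density(a, tau, 0), sum(a * tau * 1e-12),
               tolerance = 1e-12)
  w <- 10^seq(6, 10, length.out = 20)
  J <- spectral_density(a, tau, w)
  expect_true(all(diff(J) < 0))
  expect_lt(spectral_density(a, tau, 1e15), 1e-20)
  expect_true(all(spectral_density(a, tau, c(-w, w)) >= 0))

  # numeric cosine transform of the bi-exponential as oracle
  for (wk in c(1e7, 5e8, 4e9)) {
    quad <- integrate(function(t) {
      (a[1] * exp(-t / (tau[1] * 1e-12)) + a[2] * exp(-t / (tau[2] * 1e-12))) *
        cos(wk * t)
    }, 0, Inf, rel.tol = 1e-10, subdivisions = 1000L)
    expect_equal(spectral_density(a, tau, wk), quad$value,
                 tolerance = 1e-6)
  }
})

test_that("relaxation rates reproduce the analytic limits", {
  # extreme narrowing with CSA off: R1 = R2
  cst <- spin_system_constants(csa_ppm = 0)
  p <- data.frame(residue = 1L, a1 = 1, tau1_ps = 1e-3, a2 = 0,
                  tau2_ps = 1e-3, converged = TRUE)
  rr <- relaxation_rates(p, cst)
  expect_equal(rr$r1, rr$r2, tolerance = 1e-9)
  # extreme narrowing dipolar NOE -> 1 + gammaH / (2 gammaN)
  expect_equal(rr$noe, 1 + cst$gamma_h / (2 * cst$gamma_n), tolerance = 1e-9)
})

test_that("rates match an independently coded textbook oracle", {
  cst <- spin_system_constants()
  for (tau_ns in c(0.01, 0.1, 1, 5, 20, 100)) {
    p <- data.frame(residue = 1L, a1 = 1, tau1_ps = tau_ns * 1e3, a2 = 0,
                    tau2_ps = tau_ns * 1e3, converged = TRUE)
    rr <- relaxation_rates(p, cst)
    or <- oracle_rates(a = c(1, 0), tau_s = c(tau_ns * 1e-9, 1e-12))
    expect_equal(rr$r1, unname(or["r1"]), tolerance = 1e-9)
    expect_equal(rr$r2, unname(or["r2"]), tolerance = 1e-9)
    expect_equal(rr$noe, unname(or["noe"]), tolerance = 1e-9)
  }
  # mixed two-component case
  p2 <- data.frame(residue = 1L, a1 = 0.4, tau1_ps = 60, a2 = 0.5,
                   tau2_ps = 4000, converged = TRUE)
  rr2 <- relaxation_rates(p2, cst)
  or2 <- oracle_rates(a = c(0.4, 0.5), tau_s = c(60e-12, 4e-9))
  expect_equal(rr2$r2, unname(or2["r2"]), tolerance = 1e-9)
})

test_that("R2 grows with correlation time and with slower ACF decay", {
  cst <- spin_system_constants()
  taus <- 10^seq(1, 5, length.out = 12)  # ps
  r2 <- vapply(taus, function(tv) {
    relaxation_rates(data.frame(residue = 1, a1 = 1, tau1_ps = tv, a2 = 0,
                                tau2_ps = tv, converged = TRUE), cst)$r2
  }, numeric(1))
  expect_true(all(diff(r2) > 0))
  expect_true(all(r2 > 0))

  # two trajectories of the same chain where one has strictly slower ACF
  # decay at every residue (the same bond-vector path on a 4x dilated clock):
  # computed R2 is elementwise larger (dense-phase contract)
  dr <- seq(2e-3, 6e-3, length.out = 6)
  fast <- make_rotor_trajectory(6, 4000, dt_ps = 1, d_r = dr, seed = 8)
  slow <- make_rotor_trajectory(6, 4000, dt_ps = 4, d_r = dr / 4, seed = 8)
  expect_identical(slow$coords, fast$coords)  # same path, slower clock
  rf <- trajectory_relaxation(fast, cst, block_ps = 1000)
  rs <- trajectory_relaxation(slow, cst, block_ps = 4000)
  expect_true(all(rs$r2 > rf$r2))
})

test_that("trajectory pipeline: flat profiles, block consistency, mobile tail", {
  cst <- spin_system_constants()
  # rigid rotating frame: every residue shares the same bond-vector motion
  one <- make_rotor_trajectory(1, 4000, 1, d_r = 1.5e-3, seed = 12)
  n_res <- 5
  coords <- array(NA_real_, dim = c(4000, 2 * n_res, 3))
  for (r in seq_len(n_res)) {
    coords[, 2 * r - 1, ] <- one$coords[, 1, ] + 3 * r
    coords[, 2 * r, ] <- one$coords[, 2, ] + 3 * r
  }
  rigid <- trajectory(coords, data.frame(
    atom = rep(c("N", "H"), n_res), resid = rep(1:n_res, each = 2),
    resname = "G", chain = 1L, mass = rep(c(14, 1), n_res),
    element = rep(c("N", "H"), n_res)), time = one$time)
  prof <- trajectory_relaxation(rigid, cst, block_ps = 1000)
  expect_lt(diff(range(prof$r2)) / mean(prof$r2), 1e-6)

  # two block lengths that divide the duration agree within sampling error
  p1 <- trajectory_relaxation(one, cst, block_ps = 1000)
  p2 <- trajectory_relaxation(one, cst, block_ps = 2000)
  expect_equal(p1$r2, p2$r2, tolerance = 0.25)

  # known mobility gradient: fast ends relax slower (lower R2)
  grad <- make_rotor_trajectory(7, 4000, 1,
                                d_r = c(8e-3, 4e-3, 1e-3, 5e-4, 1e-3, 4e-3,
                                        8e-3), seed = 13)
  pg <- trajectory_relaxation(grad, cst, block_ps = 1000)
  expect_lt(pg$r2[1], pg$r2[4])
  expect_lt(pg$r2[7], pg$r2[4])
})
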