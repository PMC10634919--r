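# Coarse-grained simulator: topology building (single chain and slab),
# the hydropathy-scaled pair potential, and the Langevin driver around the
# compiled BAOAB core.

with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

bead_params <- function(seq) {
  chars <- seq_chars(seq)
  idx <- match(chars, HPS_URRY_TABLE$aa)
  data.frame(aa = chars,
             resid = seq$start_index + seq_along(chars) - 1L,
             mass = HPS_URRY_TABLE$mass[idx],
             charge = HPS_URRY_TABLE$charge[idx],
             sigma = HPS_URRY_TABLE$sigma[idx],
             lambda = HPS_URRY_TABLE$lambda[idx],
             stringsAsFactors = FALSE)
}

new_cg_topology <- function(beads, bonds, r0 = HPS_BOND_R0, k = HPS_BOND_K) {
  structure(list(beads = beads, bonds = bonds, bond_r0 = r0, bond_k = k),
            class = "cg_topology")
}

#' @export
print.cg_topology <- function(x, ...) {
  cat(sprintf("cg_topology: %d beads, %d bonds, %d chains, net charge %+g e\n",
              nrow(x$beads), nrow(x$bonds), length(unique(x$beads$chain)),
              sum(x$beads$charge)))
  invisible(x)
}

# grow one chain as a self-avoiding random walk with fixed bond length,
# confined to [lo, hi] per dimension; uses the current RNG stream
grow_chain <- function(n, r0, lo, hi, existing = NULL, min_dist = 0.35,
                       max_retry = 2000L) {
  coords <- matrix(NA_real_, n, 3)
  coords[1, ] <- lo + runif(3) * (hi - lo)
  for (i in seq_len(n)[-1]) {
    placed <- FALSE
    for (try in seq_len(max_retry)) {
      u <- rnorm(3)
      cand <- coords[i - 1, ] + r0 * u / sqrt(sum(u^2))
      if (any(cand < lo | cand > hi)) next
      prev <- coords[seq_len(i - 1), , drop = FALSE]
      d2 <- rowSums((prev - matrix(cand, nrow(prev), 3, byrow = TRUE))^2)
      d2 <- d2[-length(d2)]                     # bonded neighbour may be close
      if (length(d2) > 0 && min(d2) < min_dist^2) next
      if (!is.null(existing) && nrow(existing) > 0) {
        de <- rowSums((existing - matrix(cand, nrow(existing), 3,
                                         byrow = TRUE))^2)
        if (min(de) < min_dist^2) next
      }
      coords[i, ] <- cand
      placed <- TRUE
      break
    }
    if (!placed) return(NULL)
  }
  coords
}

#' Build a single-chain coarse-grained system
#'
#' One bead per residue with masses, charges, diameters and hydropathies from
#' [hps_parameters()]; consecutive beads bonded at the model bond length. The
#' initial conformation is a self-avoiding random walk inside the box,
#' deterministic under the config seed.
#'
#' @param seq a [protein_sequence()].
#' @param cfg a [simulation_config()].
#' @return list with elements `topology` (a `cg_topology`) and `coords`
#'   (n x 3 matrix, nm).
#' @export
build_single_chain <- function(seq, cfg) {
  stopifnot(inherits(seq, "protein_sequence"), inherits(cfg, "sim_config"))
  beads <- bead_params(seq)
  beads$chain <- 1L
  n <- nrow(beads)
  # volume feasibility: beads at close packing must fit with headroom
  if (n * (4 / 3) * pi * 0.3^3 > 0.3 * prod(cfg$box)) {
    stop("box too small for chain")
  }
  bonds <- cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)
  coords <- with_local_seed(cfg$seed, {
    margin <- 0.5
    lo <- rep(margin, 3)
    hi <- cfg$box - margin
    out <- NULL
    for (attempt in 1:50) {
      out <- grow_chain(n, HPS_BOND_R0, lo, hi)
      if (!is.null(out)) break
    }
    if (is.null(out)) stop("could not place chain in box (box too small?)")
    out
  })
  list(topology = new_cg_topology(beads, bonds), coords = coords)
}

#' Build a slab-coexistence coarse-grained system
#'
#' `n_chains` copies of the sequence packed into the central third of an
#' elongated box (slab axis = z), each chain a self-avoiding random walk and
#' no two beads of different chains closer than an overlap tolerance. Starting
#' from a condensed slab is the standard direct-coexistence protocol: the
#' dense layer either persists (coexistence) or evaporates (single phase).
#'
#' @param seq a [protein_sequence()].
#' @param n_chains number of chains (>= 2).
#' @param cfg a [simulation_config()]; `cfg$box` should be elongated in z.
#' @return list with `topology` and `coords` as in [build_single_chain()].
#' @export
build_slab <- function(seq, n_chains, cfg) {
  stopifnot(inherits(seq, "protein_sequence"), n_chains >= 2,
            inherits(cfg, "sim_config"))
  one <- bead_params(seq)
  n <- nrow(one)
  beads <- do.call(rbind, lapply(seq_len(n_chains), function(ch) {
    b <- one
    b$chain <- as.integer(ch)
    b
  }))
  rownames(beads) <- NULL
  bonds <- do.call(rbind, lapply(seq_len(n_chains), function(ch) {
    off <- (ch - 1L) * n
    cbind(off + seq_len(n - 1L), off + seq_len(n - 1L) + 1L)
  }))
  coords <- with_local_seed(cfg$seed, {
    margin <- 0.3
    zc <- cfg$box[3] / 2
    lo <- c(margin, margin, zc - cfg$box[3] / 6)
    hi <- c(cfg$box[1] - margin, cfg$box[2] - margin, zc + cfg$box[3] / 6)
    placed <- matrix(numeric(0), 0, 3)
    chains <- vector("list", n_chains)
    for (ch in seq_len(n_chains)) {
      out <- NULL
      for (attempt in 1:100) {
        out <- grow_chain(n, HPS_BOND_R0, lo, hi, existing = placed)
        if (!is.null(out)) break
      }
      if (is.null(out)) stop("packing failure: could not place chain ", ch,
                             " after bounded retries")
      chains[[ch]] <- out
      placed <- rbind(placed, out)
    }
    do.call(rbind, chains)
  })
  list(topology = new_cg_topology(beads, bonds), coords = coords)
}

#' Nonbonded pair potential of the coarse-grained model
#'
#' Energy (kJ/mol) of two beads at a given separation: the hydropathy-scaled
#' Ashbaugh-Hatch short-range term (Lorentz combination of diameters,
#' arithmetic mean of hydropathies) plus Debye-Hueckel screened electrostatics
#' with the screening length set by the config's ionic strength. Both terms
#' are truncated at their cutoffs.
#'
#' @param aa_i,aa_j one-letter residue codes.
#' @param r separation in nm (> 0); vectorised.
#' @param cfg a [simulation_config()] (supplies temperature and ionic
#'   strength).
#' @param eps short-range interaction depth, kJ/mol.
#' @return numeric energy, kJ/mol.
#' @export
pair_potential <- function(aa_i, aa_j, r, cfg = simulation_config(),
                           eps = HPS_EPSILON) {
  stopifnot(all(r > 0))
  i <- match(toupper(aa_i), HPS_URRY_TABLE$aa)
  j <- match(toupper(aa_j), HPS_URRY_TABLE$aa)
  if (is.na(i) || is.na(j)) stop("unknown residue code")
  sigma <- (HPS_URRY_TABLE$sigma[i] + HPS_URRY_TABLE$sigma[j]) / 2
  lambda <- (HPS_URRY_TABLE$lambda[i] + HPS_URRY_TABLE$lambda[j]) / 2
  qq <- HPS_URRY_TABLE$charge[i] * HPS_URRY_TABLE$charge[j]
  lj <- 4 * eps * ((sigma / r)^12 - (sigma / r)^6)
  rmin <- 2^(1 / 6) * sigma
  e_vdw <- ifelse(r <= rmin, lj + (1 - lambda) * eps, lambda * lj)
  e_vdw[r >= HPS_CUTOFF_VDW] <- 0
  ld <- debye_length(cfg$ionic_strength_mM, cfg$temperature)
  screen <- if (is.infinite(ld)) 1 else exp(-r / ld)
  e_el <- (COULOMB_KJ / HPS_DIELECTRIC) * qq / r * screen
  e_el[r >= HPS_CUTOFF_ELEC] <- 0
  e_vdw + e_el
}

#' Run coarse-grained Langevin dynamics
#'
#' BAOAB Langevin integration of a coarse-grained system at the configured
#' temperature, with per-bead friction `gamma_i = m_i / t_damp`, periodic
#' boundaries (minimum image) and deterministic output under the config seed.
#' Coordinates are propagated unwrapped; analyses that need wrapped positions
#' (e.g. z-density profiles) wrap them on the fly.
#'
#' @param topology a `cg_topology` from [build_single_chain()] or
#'   [build_slab()].
#' @param coords n x 3 starting coordinates (nm).
#' @param cfg a [simulation_config()].
#' @param nonbonded logical; FALSE disables all nonbonded interactions (ideal
#'   chain with bonds only).
#' @param periodic logical; FALSE runs without periodic boundaries.
#' @param lambda_scale multiplier applied to all bead hydropathies (attraction
#'   strength dial for synthetic-system construction); 0 gives the purely
#'   repulsive branch plus electrostatics.
#' @param minimize_steps capped-displacement steepest-descent iterations run
#'   before the dynamics to relax packing overlaps (0 disables).
#' @param thermalize_ps length of a strongly-coupled (1 ps damping)
#'   thermalization phase run before production so the system starts at the
#'   target temperature; frames are not saved (0 disables).
#' @return a [trajectory()] with attributes `potential`, `kinetic` and
#'   `kinetic_temperature` (per saved frame).
#' @export
run_langevin <- function(topology, coords, cfg, nonbonded = TRUE,
                         periodic = TRUE, lambda_scale = 1,
                         minimize_steps = 500L, thermalize_ps = 50) {
  stopifnot(inherits(topology, "cg_topology"), inherits(cfg, "sim_config"),
            nrow(coords) == nrow(topology$beads))
  if (!all(is.finite(coords))) stop("non-finite starting coordinates")
  b <- topology$beads
  res <- .run_langevin_cpp(
    as.matrix(coords), b$mass, b$charge, pmin(1, b$lambda * lambda_scale),
    b$sigma, topology$bonds - 1L, topology$bond_r0, topology$bond_k,
    cfg$box, periodic, cfg$temperature, cfg$timestep_fs * 1e-3, cfg$t_damp_ps,
    cfg$n_steps, cfg$save_every, cfg$seed, HPS_EPSILON,
    as.integer(minimize_steps),
    as.integer(round(thermalize_ps / (cfg$timestep_fs * 1e-3))),
    HPS_CUTOFF_VDW,
    HPS_CUTOFF_ELEC, COULOMB_KJ / HPS_DIELECTRIC,
    debye_length(cfg$ionic_strength_mM, cfg$temperature),
    as.integer(nonbonded))
  n <- nrow(b)
  coords_arr <- aperm(array(res$coords, dim = c(3, n, res$n_saved)),
                      c(3, 2, 1))
  top_df <- data.frame(atom = "CA", resid = b$resid, resname = b$aa,
                       chain = b$chain, mass = b$mass, element = "C",
                       stringsAsFactors = FALSE)
  traj <- trajectory(coords_arr, top_df, box = cfg$box, time = res$time,
                     bonds = topology$bonds)
  attr(traj, "potential") <- res$potential
  attr(traj, "kinetic") <- res$kinetic
  attr(traj, "kinetic_temperature") <- 2 * res$kinetic / (3 * n * KB_KJ)
  traj
}

#' Total potential energy of a configuration
#'
#' Brute-force all-pairs evaluation of the model energy (bonds + nonbonded)
#' for one frame; used as an independent cross-check of the dynamics core.
#'
#' @inheritParams run_langevin
#' @return energy in kJ/mol.
#' @export
cg_potential_energy <- function(topology, coords, cfg, nonbonded = TRUE,
                                periodic = TRUE, lambda_scale = 1) {
  b <- topology$beads
  .cg_energy_cpp(as.matrix(coords), b$charge, pmin(1, b$lambda * lambda_scale),
                 b$sigma, topology$bonds - 1L, topology$bond_r0,
                 topology$bond_k, cfg$box, periodic, HPS_EPSILON,
                 HPS_CUTOFF_VDW, HPS_CUTOFF_ELEC,
                 COULOMB_KJ / HPS_DIELECTRIC,
                 debye_length(cfg$ionic_strength_mM, cfg$temperature),
                 as.integer(nonbonded))
}
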