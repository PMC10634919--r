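# Shared fixture builders: small deterministic trajectories and sequences
# constructed in code.

# trajectory with explicit coordinates: coords_list is a list of n_atoms x 3
# matrices (one per frame)
toy_trajectory <- function(coords_list, resid = NULL, chain = NULL,
                           element = NULL, atom = NULL, mass = NULL,
                           resname = NULL, box = NULL, dt = 1) {
  n_at <- nrow(coords_list[[1]])
  coords <- array(NA_real_, dim = c(length(coords_list), n_at, 3))
  for (f in seq_along(coords_list)) coords[f, , ] <- coords_list[[f]]
  if (is.null(resid)) resid <- seq_len(n_at)
  if (is.null(chain)) chain <- rep(1L, n_at)
  if (is.null(element)) element <- rep("C", n_at)
  if (is.null(atom)) atom <- rep("CA", n_at)
  if (is.null(mass)) mass <- rep(100, n_at)
  if (is.null(resname)) resname <- rep("G", n_at)
  trajectory(coords,
             data.frame(atom = atom, resid = resid, resname = resname,
                        chain = chain, mass = mass, element = element,
                        stringsAsFactors = FALSE),
             box = box, time = (seq_along(coords_list) - 1) * dt)
}

# freely-jointed chain ensemble (ideal-chain statistics), one chain per frame
ideal_chain_frames <- function(n_beads, n_frames, b = 0.38, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_frames), function(f) {
    steps <- matrix(rnorm(3 * (n_beads - 1)), ncol = 3)
    steps <- b * steps / sqrt(rowSums(steps^2))
    rbind(c(0, 0, 0), apply(steps, 2, cumsum))
  })
}

# random amino-acid sequence
random_sequence <- function(n, seed = 1) {
  set.seed(seed)
  protein_sequence(paste(sample(c("A", "G", "S", "Y", "Q", "T", "P", "K",
                                  "E"), n, replace = TRUE), collapse = ""))
}

# brute-force tyrosine-motif scanner: double loop over all position pairs
brute_force_motifs <- function(seq) {
  chars <- strsplit(seq$residues, "")[[1]]
  ypos <- which(chars == "Y")
  yxy <- 0L
  yxxy <- 0L
  for (i in ypos) {
    for (j in ypos) {
      if (j - i == 2L) yxy <- yxy + 1L
      if (j - i == 3L) yxxy <- yxxy + 1L
    }
  }
  list(yxy = yxy, yxxy = yxxy)
}

# brute-force O(N^2) contact map in plain R
brute_force_contacts <- function(coords, resid, chain, heavy, cutoff,
                                 mode = "intramolecular", exclude = 1L,
                                 box = NULL) {
  residues <- sort(unique(resid))
  out <- matrix(0, length(residues), length(residues))
  n <- nrow(coords)
  for (i in seq_len(n - 1)) {
    if (!heavy[i]) next
    for (j in (i + 1):n) {
      if (!heavy[j]) next
      if (mode == "intramolecular") {
        if (chain[i] != chain[j]) next
        if (abs(resid[i] - resid[j]) <= exclude) next
      } else {
        if (chain[i] == chain[j]) next
      }
      d <- coords[i, ] - coords[j, ]
      if (!is.null(box) && mode == "intermolecular") {
        d <- d - box * round(d / box)
      }
      if (sum(d^2) < cutoff^2) {
        ri <- match(resid[i], residues)
        rj <- match(resid[j], residues)
        out[ri, rj] <- out[ri, rj] + 1
        if (ri != rj) out[rj, ri] <- out[rj, ri] + 1
      }
    }
  }
  out
}

# independently coded textbook relaxation expressions (Abragam forms with
# J(w) = sum a_i tau_i / (1 + w^2 tau_i^2)); second implementation used as
# the oracle for relaxation_rates()
oracle_rates <- function(a, tau_s, field_mhz = 700.15, r_nh = 1.02e-10,
                         csa = -163e-6) {
  gh <- 2.6752218744e8
  gn <- -2.71261804e7
  hbar <- 1.054571817e-34
  wh <- 2 * pi * field_mhz * 1e6
  wn <- wh * abs(gn) / gh
  J <- function(w) sum(a * tau_s / (1 + (w * tau_s)^2))
  d2 <- (1e-7 * gh * gn * hbar / r_nh^3)^2
  c2 <- (wn * csa)^2
  r1 <- d2 / 10 * (J(wh - wn) + 3 * J(wn) + 6 * J(wh + wn)) +
    (2 / 15) * c2 * J(wn)
  r2 <- d2 / 20 * (4 * J(0) + J(wh - wn) + 3 * J(wn) + 6 * J(wh) +
                     6 * J(wh + wn)) +
    (1 / 45) * c2 * (4 * J(0) + 3 * J(wn))
  noe <- 1 + d2 / 10 * (gh / gn) * (6 * J(wh + wn) - J(wh - wn)) / r1
  c(r1 = r1, r2 = r2, noe = noe)
}
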