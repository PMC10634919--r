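# Contact-map, PRE-proxy and chain-compaction analysis of single-chain and
# multi-chain trajectories. "Heavy atom" means any non-hydrogen atom; for
# coarse-grained beads every bead is heavy.

#' Residue-residue heavy-atom contact map
#'
#' Counts, per residue pair, the heavy-atom pairs closer than `cutoff`
#' (default 0.6 nm), accumulated over frames: summing over all atom pairs of a
#' residue pair means longer sidechains contribute more contacts.
#' Intramolecular mode restricts to pairs on the same chain separated by more
#' than `exclude` residues (nonbonded contacts) and uses plain distances, so
#' chains must be whole ([unwrap_chains()] first if needed); intermolecular
#' mode counts only pairs on different chains with minimum-image distances. Residue numbers repeat across chains, so the map
#' is position-by-position, aggregated over chains.
#'
#' @param traj a [trajectory()].
#' @param cutoff contact distance in nm (> 0).
#' @param mode "intramolecular" or "intermolecular".
#' @param exclude intramolecular sequence-neighbour exclusion width (|i-j| <=
#'   exclude skipped; default 1).
#' @return object of class `contact_map`: list with `counts` (cumulative,
#'   symmetric), `per_frame` (counts / n_frames), `residues`, `mode`,
#'   `n_frames`.
#' @export
contact_map <- function(traj, cutoff = 0.6,
                        mode = c("intramolecular", "intermolecular"),
                        exclude = 1L) {
  mode <- match.arg(mode)
  if (cutoff <= 0) stop("cutoff must be positive")
  top <- traj$topology
  residues <- sort(unique(top$resid))
  ridx <- match(top$resid, residues)
  heavy <- top$element != "H"
  box <- if (is.null(traj$box)) c(1, 1, 1) else traj$box
  counts <- matrix(0, length(residues), length(residues))
  for (f in seq_len(n_frames(traj))) {
    counts <- counts + .contact_counts_cpp(
      traj$coords[f, , ], as.integer(top$resid), ridx,
      as.integer(top$chain), heavy, cutoff, length(residues),
      if (mode == "intramolecular") 0L else 1L,
      as.integer(exclude), box, !is.null(traj$box))
  }
  structure(list(counts = counts, per_frame = counts / n_frames(traj),
                 residues = residues, mode = mode,
                 n_frames = n_frames(traj)),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map (%s): %d residues, %d frames, %g total contacts\n",
              x$mode, length(x$residues), x$n_frames, sum(x$counts) / 2))
  invisible(x)
}

#' Aggregate a contact map by residue-type pair
#'
#' Sums the contacts of all residue pairs of each amino-acid type pair into a
#' 20 x 20 table; the grand total is conserved between the two views.
#'
#' @param map a [contact_map()].
#' @param seq the [protein_sequence()] the map positions refer to.
#' @return 20 x 20 symmetric numeric matrix with amino-acid dimnames.
#' @export
residue_type_contacts <- function(map, seq) {
  stopifnot(inherits(map, "contact_map"), inherits(seq, "protein_sequence"))
  chars <- seq_chars(seq)
  pos <- seq$start_index + seq_along(chars) - 1L
  if (!all(map$residues %in% pos)) {
    stop("contact-map residues do not match the sequence numbering")
  }
  types <- chars[match(map$residues, pos)]
  out <- matrix(0, 20, 20, dimnames = list(AA_CODES, AA_CODES))
  ti <- match(types, AA_CODES)
  for (a in seq_along(types)) {
    for (b in seq_along(types)) {
      out[ti[a], ti[b]] <- out[ti[a], ti[b]] + map$counts[a, b]
    }
  }
  out
}

#' Per-residue contact profile
#'
#' Row sums of the contact map (self excluded), reported per frame; the
#' profile total is twice the map total because each contact is counted from
#' both ends.
#'
#' @param map a [contact_map()].
#' @return data.frame with `residue`, `contacts_per_frame`, `contacts_total`.
#' @export
per_residue_contacts <- function(map) {
  stopifnot(inherits(map, "contact_map"))
  m <- map$counts
  diag(m) <- 0
  tot <- rowSums(m)
  data.frame(residue = map$residues, contacts_per_frame = tot / map$n_frames,
             contacts_total = tot)
}

residue_atoms <- function(traj, heavy_only = TRUE) {
  top <- traj$topology
  keep <- if (heavy_only) top$element != "H" else rep(TRUE, nrow(top))
  split(which(keep), paste(top$chain[keep], top$resid[keep]))
}

#' Distance-proxy PRE profile
#'
#' For a spin label placed at `label_residue`, computes the ensemble average
#' of r^-6 over all heavy-atom pairs between the label residue and each target
#' residue, with pairs beyond `cutoff` contributing zero, then normalises the
#' profile by its maximum: the <r^-6>/<r^-6>max proxy for PRE rates when no
#' rotamer library is available for the label. Multiple trajectories are
#' treated as replicas, averaged with the standard error of the mean.
#'
#' @param trajs a [trajectory()] or list of replica trajectories
#'   (single-chain; unwrapped automatically).
#' @param label_residue residue number carrying the label.
#' @param cutoff distance cutoff in nm (default 3.5).
#' @return data.frame of class `pre_proxy_profile`: `residue`, `value`
#'   (normalised to max 1), `sem` (NA for a single replica).
#' @export
pre_proxy <- function(trajs, label_residue, cutoff = 3.5) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  per_replica <- lapply(trajs, function(traj) {
    traj <- unwrap_chains(traj)
    top <- traj$topology
    heavy <- top$element != "H"
    lab <- which(top$resid == label_residue & heavy)
    if (length(lab) == 0L) stop("label residue has no heavy atoms")
    residues <- sort(setdiff(unique(top$resid), label_residue))
    raw <- vapply(residues, function(rr) {
      tgt <- which(top$resid == rr & heavy)
      acc <- 0
      for (f in seq_len(n_frames(traj))) {
        la <- matrix(traj$coords[f, lab, ], nrow = length(lab))
        ta <- matrix(traj$coords[f, tgt, ], nrow = length(tgt))
        d2 <- outer(rowSums(la^2), rowSums(ta^2), "+") - 2 * la %*% t(ta)
        d2 <- pmax(d2, 1e-12)
        contrib <- ifelse(d2 <= cutoff^2, d2^(-3), 0)
        acc <- acc + mean(contrib)
      }
      acc / n_frames(traj)
    }, numeric(1))
    list(residues = residues, raw = raw)
  })
  residues <- per_replica[[1]]$residues
  mat <- do.call(rbind, lapply(per_replica, function(x) x$raw))
  mean_raw <- colMeans(mat)
  norm <- max(mean_raw)
  value <- if (norm > 0) mean_raw / norm else mean_raw
  sem <- if (nrow(mat) > 1) {
    apply(mat / norm, 2, sd) / sqrt(nrow(mat))
  } else rep(NA_real_, length(residues))
  out <- data.frame(residue = residues, value = value, sem = sem)
  class(out) <- c("pre_proxy_profile", "data.frame")
  out
}

select_atoms <- function(traj, residues = NULL, chain = NULL,
                         heavy_only = FALSE) {
  top <- traj$topology
  keep <- rep(TRUE, nrow(top))
  if (!is.null(residues)) keep <- keep & top$resid %in% residues
  if (!is.null(chain)) keep <- keep & top$chain %in% chain
  if (heavy_only) keep <- keep & top$element != "H"
  which(keep)
}

#' Mass-weighted radius of gyration
#'
#' Rg per frame and per chain over a residue selection. Chains must be whole:
#' a bond longer than half the box raises an error demanding
#' [unwrap_chains()] first, because Rg of a wrapped chain is meaningless.
#'
#' @param traj a [trajectory()].
#' @param residues optional residue numbers to restrict to.
#' @param chains optional chain ids to restrict to.
#' @return data.frame with `frame`, `chain`, `rg` (nm); mean Rg in attribute
#'   `mean_rg`.
#' @export
radius_of_gyration <- function(traj, residues = NULL, chains = NULL) {
  if (has_wrapped_chains(traj)) {
    stop("trajectory contains chains wrapped across the box; ",
         "call unwrap_chains() first")
  }
  top <- traj$topology
  sel <- select_atoms(traj, residues = residues, chain = chains)
  if (length(sel) == 0L) stop("empty selection")
  chain_ids <- sort(unique(top$chain[sel]))
  rows <- list()
  for (ch in chain_ids) {
    idx <- sel[top$chain[sel] == ch]
    m <- top$mass[idx]
    w <- m / sum(m)
    for (f in seq_len(n_frames(traj))) {
      x <- traj$coords[f, idx, , drop = TRUE]
      if (is.null(dim(x))) x <- matrix(x, nrow = 1)
      com <- colSums(x * w)
      rg2 <- sum(w * rowSums((x - matrix(com, nrow(x), 3, byrow = TRUE))^2))
      rows[[length(rows) + 1L]] <- data.frame(frame = f, chain = ch,
                                              rg = sqrt(rg2))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "mean_rg") <- mean(out$rg)
  out
}

#' Correlation time of a radius-of-gyration series
#'
#' Normalised fluctuation autocorrelation of the Rg time series; the
#' correlation time is the first crossing of 1/e, located by linear
#' interpolation. Warns when the series is shorter than ten correlation
#' times; a constant series (zero variance) is an error.
#'
#' @param rg numeric Rg series (equally spaced frames).
#' @param dt_ps frame spacing in ps.
#' @return correlation time in ps.
#' @export
rg_correlation_time <- function(rg, dt_ps = 1) {
  if (length(rg) < 10L) stop("series too short")
  x <- rg - mean(rg)
  if (var(x) == 0) stop("constant series: correlation time undefined")
  n <- length(x)
  ac <- fft_acf(matrix(x, ncol = 1), n_lags = n)[, 1]
  ac <- ac / ac[1]
  below <- which(ac < exp(-1))
  if (length(below) == 0L) {
    warning("ACF never decays to 1/e within the series")
    return(NA_real_)
  }
  k <- below[1]
  if (k == 1L) return(0)
  frac <- (ac[k - 1] - exp(-1)) / (ac[k - 1] - ac[k])
  tau <- (k - 2 + frac) * dt_ps
  if (length(rg) * dt_ps < 10 * tau) {
    warning("series shorter than 10 correlation times; estimate is noisy")
  }
  tau
}

residue_centers <- function(traj, chain) {
  top <- traj$topology
  heavy <- top$element != "H" & top$chain == chain
  residues <- sort(unique(top$resid[heavy]))
  centers <- array(NA_real_, dim = c(n_frames(traj), length(residues), 3))
  for (r in seq_along(residues)) {
    idx <- which(heavy & top$resid == residues[r])
    m <- top$mass[idx]
    w <- m / sum(m)
    for (k in 1:3) {
      m3 <- matrix(traj$coords[, idx, k], ncol = length(idx))
      centers[, r, k] <- as.vector(m3 %*% w)
    }
  }
  list(residues = residues, centers = centers)
}

#' Inter-residue distance scaling
#'
#' Mean inter-residue distance <r_ij> (residue mass centers, heavy atoms) as a
#' function of sequence separation s = |i-j|, averaged over all pairs at each
#' separation, frames and selected chains, with a power-law fit
#' r(s) = b * s^nu over a separation window. The exponent nu distinguishes
#' collapsed (< 0.5), ideal (0.5) and extended (> 0.5, rod = 1) statistics.
#'
#' @param traj a [trajectory()] (unwrapped automatically).
#' @param chains chain ids to include (default all).
#' @param window integer length-2: separation range used in the fit (default
#'   from 2 to half the maximum separation).
#' @return list with `curve` (data.frame `separation`, `mean_distance`),
#'   `exponent`, `prefactor`, `window`.
#' @export
distance_scaling <- function(traj, chains = NULL, window = NULL) {
  traj <- unwrap_chains(traj)
  if (is.null(chains)) chains <- sort(unique(traj$topology$chain))
  sums <- NULL
  counts <- NULL
  for (ch in chains) {
    rc <- residue_centers(traj, ch)
    L <- length(rc$residues)
    if (L < 3L) stop("chain shorter than the fitting window")
    smax <- L - 1L
    if (is.null(sums)) {
      sums <- numeric(smax)
      counts <- numeric(smax)
    }
    for (s in seq_len(min(smax, length(sums)))) {
      i <- seq_len(L - s)
      d <- sqrt((rc$centers[, i + s, 1] - rc$centers[, i, 1])^2 +
                  (rc$centers[, i + s, 2] - rc$centers[, i, 2])^2 +
                  (rc$centers[, i + s, 3] - rc$centers[, i, 3])^2)
      sums[s] <- sums[s] + sum(d)
      counts[s] <- counts[s] + length(d)
    }
  }
  keep <- counts > 0
  curve <- data.frame(separation = c(0L, which(keep)),
                      mean_distance = c(0, (sums / counts)[keep]))
  if (is.null(window)) window <- c(2L, max(2L, floor(max(which(keep)) / 2)))
  fitsel <- curve$separation >= window[1] & curve$separation <= window[2] &
    curve$separation > 0
  fit <- lm(log(mean_distance) ~ log(separation), data = curve[fitsel, ])
  list(curve = curve, exponent = unname(coef(fit)[2]),
       prefactor = exp(unname(coef(fit)[1])), window = window)
}

#' Per-segment radius-of-gyration distributions
#'
#' Rg distribution for each residue segment (e.g. the three equal-length
#' segments used to quantify N-terminal, linker and C-terminal compaction),
#' with segments ranked by mean Rg.
#'
#' @param traj a [trajectory()] (must be unwrapped, see
#'   [radius_of_gyration()]).
#' @param segments list of integer length-2 vectors `c(first, last)` in
#'   residue numbers.
#' @param chains optional chain restriction.
#' @param strict reject overlapping or out-of-range segments (default TRUE).
#' @return list with `distributions` (named list of Rg data.frames), `summary`
#'   (data.frame `segment`, `mean_rg`, `rank`).
#' @export
segment_compaction <- function(traj, segments, chains = NULL, strict = TRUE) {
  all_res <- range(traj$topology$resid)
  labs <- vapply(segments, function(s) paste0(s[1], "-", s[2]), character(1))
  if (strict) {
    for (s in segments) {
      if (s[1] < all_res[1] || s[2] > all_res[2] || s[1] > s[2]) {
        stop("segment out of range: ", s[1], "-", s[2])
      }
    }
    cov <- unlist(lapply(segments, function(s) s[1]:s[2]))
    if (anyDuplicated(cov)) stop("segments overlap")
  }
  dists <- lapply(segments, function(s) {
    radius_of_gyration(traj, residues = s[1]:s[2], chains = chains)
  })
  names(dists) <- labs
  means <- vapply(dists, function(d) mean(d$rg), numeric(1))
  summary <- data.frame(segment = labs, mean_rg = unname(means),
                        rank = rank(means))
  list(distributions = dists, summary = summary)
}
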