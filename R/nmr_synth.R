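# Synthetic peak-table generators with known ground truth. Each generator's
# noiseless output is exactly invertible by the corresponding fit, which gives
# the round-trip identities the test suite leans on.

#' Generate synthetic relaxation peak tables
#'
#' Forward models of the relaxation experiments: exponential decays over the
#' given delays for T1/T1rho, the two-point pair for proton T2, and the
#' saturated/unsaturated pair for heteronuclear NOE. Noise is multiplicative
#' Gaussian at fraction `noise` (I -> I * (1 + noise * xi)), deterministic
#' under `seed`. At `noise = 0` the corresponding fit recovers the truth
#' exactly.
#'
#' @param truth data.frame with column `residue` plus, depending on `kind`,
#'   `rate` (s^-1, for "T1"/"T1rho"/"two_point_T2") or `noe` (for
#'   "hetNOE_pair").
#' @param kind experiment kind, see [peak_table()].
#' @param delays delay grid in seconds (defaults: the documented protocol
#'   delays for each kind; ignored for "hetNOE_pair").
#' @param noise multiplicative noise fraction (e.g. 0.02 for 2%).
#' @param i0 reference intensity.
#' @param seed RNG seed.
#' @return a [peak_table()] whose `noise` field carries `noise * i0`.
#' @export
generate_peak_table <- function(truth,
                                kind = c("T1", "T1rho", "two_point_T2",
                                         "hetNOE_pair"),
                                delays = NULL, noise = 0, i0 = 1000,
                                seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(delays)) {
    delays <- switch(kind, T1 = T1_DELAYS_S, T1rho = T1RHO_DELAYS_S,
                     two_point_T2 = TWO_POINT_DELAYS_S,
                     hetNOE_pair = c("saturated", "unsaturated"))
  }
  n <- nrow(truth)
  if (kind == "hetNOE_pair") {
    stopifnot("noe" %in% names(truth))
    clean <- cbind(saturated = i0 * truth$noe,
                   unsaturated = rep(i0, n))
  } else {
    stopifnot("rate" %in% names(truth), all(truth$rate >= 0))
    tt <- as.numeric(delays)
    clean <- i0 * exp(-outer(truth$rate, tt))
  }
  noisy <- with_local_seed(seed, {
    clean * (1 + noise * matrix(rnorm(length(clean)), nrow(clean)))
  })
  peak_table(kind = kind, residues = truth$residue, delays = delays,
             intensities = noisy,
             noise = if (noise > 0) noise * i0 else NULL)
}

#' Generate paired paramagnetic/diamagnetic two-point tables
#'
#' Builds the two `two_point_T2` tables of a PRE experiment from a ground-truth
#' Gamma2 profile and a diamagnetic base rate, so that
#' `gamma2(fit(para), fit(dia))` recovers the truth. Residues flagged
#' broadened-out in the truth get a non-positive paramagnetic intensity at the
#' long delay (peak lost in the noise).
#'
#' @param truth data.frame with `residue`, `gamma2` and optionally a logical
#'   `broadened_out` column.
#' @param r2_dia diamagnetic transverse rate (s^-1), recycled per residue.
#' @param noise,i0,seed see [generate_peak_table()].
#' @return list with elements `para` and `dia`, each a [peak_table()].
#' @export
generate_pre_tables <- function(truth, r2_dia = 5, noise = 0, i0 = 1000,
                                seed = 1L) {
  n <- nrow(truth)
  rd <- rep_len(r2_dia, n)
  broad <- if ("broadened_out" %in% names(truth)) truth$broadened_out else
    rep(FALSE, n)
  rp <- rd + truth$gamma2
  dia <- generate_peak_table(data.frame(residue = truth$residue, rate = rd),
                             kind = "two_point_T2", noise = noise, i0 = i0,
                             seed = seed)
  para <- generate_peak_table(data.frame(residue = truth$residue,
                                         rate = ifelse(broad, 0, rp)),
                              kind = "two_point_T2", noise = noise, i0 = i0,
                              seed = seed + 1L)
  para$intensities[broad, 2] <- 0   # peak broadened beyond detection
  list(para = para, dia = dia)
}

#' Extract a PRE profile from paired two-point tables
#'
#' The composition used on real data: two-point rates for the paramagnetic and
#' diamagnetic samples, then their difference as Gamma2.
#'
#' @param para,dia `two_point_T2` [peak_table()]s.
#' @return a `pre_profile`, see [gamma2()].
#' @export
pre_from_two_point <- function(para, dia) {
  fp <- fit_two_point(para)
  fd <- fit_two_point(dia)
  rp <- data.frame(residue = fp$residue,
                   rate = ifelse(fp$broadened_out, NA_real_, fp$rate))
  rd <- data.frame(residue = fd$residue, rate = fd$rate)
  gamma2(rp, rd)
}
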