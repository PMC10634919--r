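# Experimental-side NMR analysis: exponential T1/T1rho fits, the
# rotating-frame R2 relation, heteronuclear NOE ratios, two-time-point proton
# transverse rates, PRE Gamma2 differences, and synthetic peak-table
# generators with known ground truth.

#' Default relaxation delay sets
#'
#' The interleaved relaxation delays of the T1 and T1rho experiments (in
#' seconds) and the two-point proton-T2 delay pair used for PRE measurements.
#'
#' @name nmr_delays
#' @export
T1_DELAYS_S <- c(0.040, 0.080, 0.120, 0.200, 0.280, 0.400, 0.600, 0.800)

#' @rdname nmr_delays
#' @export
T1RHO_DELAYS_S <- c(0.001, 0.021, 0.031, 0.041, 0.061, 0.081, 0.121, 0.201)

#' @rdname nmr_delays
#' @export
TWO_POINT_DELAYS_S <- c(1e-6, 6.01e-4)  # Ta, Tb with delta-T = 0.6 ms

#' Construct a peak-intensity table
#'
#' Per-residue NMR peak intensities across relaxation delays (or across the
#' saturated/unsaturated pair for heteronuclear NOE), the common input of all
#' rate-extraction fits.
#'
#' @param kind one of "T1", "T1rho", "two_point_T2", "hetNOE_pair".
#' @param residues integer residue numbers (rows).
#' @param delays delay times in seconds (columns); for "hetNOE_pair" use the
#'   labels `c("saturated", "unsaturated")`.
#' @param intensities numeric matrix, residues x delays.
#' @param noise optional per-table intensity noise estimate (spectral noise
#'   floor, same units as intensities).
#' @return object of class `peak_table`.
#' @export
peak_table <- function(kind = c("T1", "T1rho", "two_point_T2", "hetNOE_pair"),
                       residues, delays, intensities, noise = NULL) {
  kind <- match.arg(kind)
  intensities <- as.matrix(intensities)
  stopifnot(length(residues) == nrow(intensities),
            length(delays) == ncol(intensities))
  if (kind == "two_point_T2" && length(delays) != 2L) {
    stop("two_point_T2 tables carry exactly 2 time points")
  }
  if (kind == "hetNOE_pair") {
    if (!identical(sort(as.character(delays)),
                   c("saturated", "unsaturated"))) {
      stop("hetNOE_pair tables need the columns 'saturated'/'unsaturated'")
    }
  } else {
    delays <- as.numeric(delays)
    stopifnot(all(delays >= 0))
  }
  if (any(!is.finite(intensities))) stop("intensities must be finite")
  structure(list(kind = kind, residues = as.integer(residues),
                 delays = delays, intensities = intensities, noise = noise),
            class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("peak_table (%s): %d residues x %d points\n", x$kind,
              length(x$residues), length(x$delays)))
  invisible(x)
}

#' Fit per-residue monoexponential decays
#'
#' Least-squares fit of I(t) = I0 * exp(-R t) to each residue of a T1 or
#' T1rho peak table. Starting values come from a log-linear regression on the
#' positive intensities; the nonlinear fit is by Levenberg-Marquardt. Rate
#' uncertainties are taken from the fit covariance; residues whose fit fails
#' are flagged rather than dropped.
#'
#' @param table a [peak_table()] of kind "T1" or "T1rho".
#' @return data.frame with columns `residue`, `rate` (s^-1), `rate_err`,
#'   `i0`, `converged`.
#' @export
fit_monoexponential <- function(table) {
  stopifnot(inherits(table, "peak_table"))
  if (!table$kind %in% c("T1", "T1rho")) {
    stop("monoexponential fits apply to T1/T1rho tables")
  }
  t <- as.numeric(table$delays)
  if (length(t) < 3L) stop("need at least 3 delays")
  out <- lapply(seq_along(table$residues), function(i) {
    y <- table$intensities[i, ]
    ok <- is.finite(y)
    if (sum(ok) < 3L) {
      return(data.frame(residue = table$residues[i], rate = NA_real_,
                        rate_err = NA_real_, i0 = NA_real_,
                        converged = FALSE))
    }
    pos <- ok & y > 0
    if (sum(pos) >= 2L) {
      lf <- lm(log(y[pos]) ~ t[pos])
      start <- list(i0 = exp(coef(lf)[1]), r = max(-coef(lf)[2], 0))
    } else {
      start <- list(i0 = max(abs(y[ok])), r = 1)
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ i0 * exp(-r * tt),
                        data = list(y = y[ok], tt = t[ok]),
                        start = start, control = list(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) {
      # degenerate cases (e.g. exactly constant intensities) have a singular
      # nonlinear gradient; the log-linear fit is exact there
      if (sum(pos) >= 3L) {
        lf <- lm(log(y[pos]) ~ t[pos])
        se <- tryCatch(
          suppressWarnings(summary(lf)$coefficients[2, 2]),
          error = function(e) NA_real_)
        return(data.frame(residue = table$residues[i],
                          rate = unname(-coef(lf)[2]), rate_err = se,
                          i0 = exp(unname(coef(lf)[1])), converged = TRUE))
      }
      return(data.frame(residue = table$residues[i], rate = NA_real_,
                        rate_err = NA_real_, i0 = NA_real_,
                        converged = FALSE))
    }
    cf <- coef(fit)
    se <- tryCatch(sqrt(diag(vcov(fit)))["r"], error = function(e) NA_real_)
    data.frame(residue = table$residues[i], rate = unname(cf["r"]),
               rate_err = unname(se), i0 = unname(cf["i0"]),
               converged = TRUE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Transverse rate from the rotating-frame relation
#'
#' Inverts R1rho = R1 cos^2(theta) + R2 sin^2(theta) with
#' theta = arctan(omega1 / Omega): the measured rotating-frame rate is a
#' tilt-weighted mix of longitudinal and transverse relaxation, and
#' on-resonance (Omega = 0, theta = 90 deg) R1rho equals R2. Entries whose
#' effective sin^2(theta) falls below `min_sin2` (offset far exceeding the
#' spin-lock field) are flagged unreliable and returned as NA.
#'
#' @param r1rho rotating-frame rate(s), s^-1.
#' @param r1 longitudinal rate(s), s^-1.
#' @param omega1 spin-lock field strength, rad/s (> 0).
#' @param offset resonance offset Omega from the spin-lock carrier, rad/s.
#' @param min_sin2 reliability floor on sin^2(theta).
#' @return data.frame with columns `r2` and `flagged`.
#' @export
r2_from_r1rho <- function(r1rho, r1, omega1, offset = 0, min_sin2 = 0.05) {
  stopifnot(all(omega1 > 0))
  theta <- atan2(omega1, offset)
  s2 <- sin(theta)^2
  c2 <- cos(theta)^2
  flagged <- s2 < min_sin2
  r2 <- (r1rho - r1 * c2) / s2
  r2[flagged] <- NA_real_
  data.frame(r2 = r2, flagged = flagged)
}

#' Heteronuclear NOE from a saturated/unsaturated pair
#'
#' NOE = I_saturated / I_unsaturated per residue, with first-order error
#' propagation from the table's intensity noise estimate. Negative NOEs are
#' legal (highly flexible residues); a non-positive unsaturated (reference)
#' intensity is an error.
#'
#' @param table a [peak_table()] of kind "hetNOE_pair".
#' @return data.frame with columns `residue`, `noe`, `noe_err`.
#' @export
hetnoe <- function(table) {
  stopifnot(inherits(table, "peak_table"), table$kind == "hetNOE_pair")
  isat <- table$intensities[, match("saturated", table$delays)]
  iun <- table$intensities[, match("unsaturated", table$delays)]
  if (any(iun <= 0)) stop("non-positive unsaturated (reference) intensity")
  noe <- isat / iun
  sig <- if (is.null(table$noise)) NA_real_ else table$noise
  err <- abs(noe) * sqrt((sig / isat)^2 + (sig / iun)^2)
  data.frame(residue = table$residues, noe = noe, noe_err = err)
}

#' Two-time-point transverse relaxation rate
#'
#' R = ln(I_Ta / I_Tb) / (Tb - Ta): the two-delay estimate of the proton
#' transverse rate used for PRE measurements. Residues with a non-positive
#' intensity are flagged broadened-out (no rate); negative rates (second point
#' brighter than the first) are retained but flagged noise-dominated, since
#' downstream comparisons need the noise floor.
#'
#' @param i_ta intensities at the short delay Ta.
#' @param i_tb intensities at the long delay Tb.
#' @param delta_t Tb - Ta in seconds (default 0.6 ms, the documented
#'   protocol).
#' @param residues optional residue numbers.
#' @return data.frame with `residue`, `rate` (s^-1), `broadened_out`,
#'   `noise_dominated`.
#' @export
two_point_r2 <- function(i_ta, i_tb, delta_t = diff(TWO_POINT_DELAYS_S),
                         residues = seq_along(i_ta)) {
  stopifnot(length(i_ta) == length(i_tb), delta_t > 0)
  broad <- !(i_ta > 0 & i_tb > 0)
  rate <- rep(NA_real_, length(i_ta))
  rate[!broad] <- log(i_ta[!broad] / i_tb[!broad]) / delta_t
  data.frame(residue = residues, rate = rate, broadened_out = broad,
             noise_dominated = !broad & rate < 0)
}

#' Extract rates from a two-point peak table
#'
#' Convenience wrapper applying [two_point_r2()] to a `two_point_T2`
#' [peak_table()].
#'
#' @param table a [peak_table()] of kind "two_point_T2".
#' @return see [two_point_r2()].
#' @export
fit_two_point <- function(table) {
  stopifnot(inherits(table, "peak_table"), table$kind == "two_point_T2")
  ord <- order(as.numeric(table$delays))
  two_point_r2(table$intensities[, ord[1]], table$intensities[, ord[2]],
               delta_t = diff(as.numeric(table$delays)[ord]),
               residues = table$residues)
}

#' PRE rates from paramagnetic and diamagnetic transverse rates
#'
#' Gamma2 = R2,paramagnetic - R2,diamagnetic per residue on the intersection
#' of the two residue sets; uncertainties add in quadrature. Residues present
#' in the diamagnetic set whose paramagnetic rate is missing (peak broadened
#' beyond detection by the spin label) are flagged broadened-out and carry no
#' number.
#'
#' @param r_para data.frame with columns `residue`, `rate` and optionally
#'   `rate_err` (paramagnetic sample).
#' @param r_dia same layout for the diamagnetic (quenched) sample.
#' @return data.frame of class `pre_profile`: `residue`, `gamma2`,
#'   `gamma2_err`, `broadened_out`.
#' @export
gamma2 <- function(r_para, r_dia) {
  common <- intersect(r_dia$residue, r_para$residue)
  residues <- sort(unique(r_dia$residue))
  if (length(common) == 0L) stop("no residues shared between the two sets")
  ip <- match(residues, r_para$residue)
  id <- match(residues, r_dia$residue)
  rp <- r_para$rate[ip]
  rd <- r_dia$rate[id]
  ep <- if ("rate_err" %in% names(r_para)) r_para$rate_err[ip] else 0
  ed <- if ("rate_err" %in% names(r_dia)) r_dia$rate_err[id] else 0
  broad <- is.na(rp)
  g <- rp - rd
  err <- sqrt(ifelse(is.na(ep), 0, ep)^2 + ifelse(is.na(ed), 0, ed)^2)
  g[broad] <- NA_real_
  err[broad] <- NA_real_
  out <- data.frame(residue = residues, gamma2 = g, gamma2_err = err,
                    broadened_out = broad)
  class(out) <- c("pre_profile", "data.frame")
  out
}

#' Summary statistics of a solvent-PRE profile
#'
#' Mean and dispersion of a Gamma2 profile plus a flatness test: the slope of
#' a linear trend of Gamma2 on residue number, with flatness accepted when the
#' slope is statistically indistinguishable from zero. A flat solvent profile
#' indicates the PREs arise from specific protein-protein contacts rather
#' than from label-solvent encounters.
#'
#' @param profile a `pre_profile` from [gamma2()] (>= 10 unflagged residues).
#' @param alpha significance level of the trend test.
#' @return list with `mean`, `sd`, `slope`, `slope_p`, `flat`.
#' @export
solvent_baseline <- function(profile, alpha = 0.05) {
  ok <- !profile$broadened_out & is.finite(profile$gamma2)
  if (sum(ok) < 10L) stop("need at least 10 residues with Gamma2 values")
  g <- profile$gamma2[ok]
  r <- profile$residue[ok]
  if (sd(g) == 0) {
    return(list(mean = mean(g), sd = 0, slope = 0, slope_p = 1, flat = TRUE))
  }
  fit <- lm(g ~ r)
  p <- suppressWarnings(summary(fit)$coefficients[2, 4])
  list(mean = mean(g), sd = sd(g), slope = unname(coef(fit)[2]),
       slope_p = p, flat = p > alpha)
}
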