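#!/usr/bin/env Rscript
# Back-calculation of R1/R2/hetNOE from bond-vector dynamics: a synthetic
# chain with a known mobility gradient (rigid core, mobile tails) is analysed
# with the block autocorrelation -> bi-exponential fit -> spectral density
# pipeline at 700.15 MHz.

suppressPackageStartupMessages(library(ewsphase))
dir.create("results", showWarnings = FALSE)

# rotational diffusion coefficients per residue (rad^2/ps): tails an order of
# magnitude more mobile than the core
n_res <- 24
d_r <- 2e-4 + 3e-3 * exp(-pmin(seq_len(n_res) - 1, n_res - seq_len(n_res)) / 3)
tr <- make_rotor_trajectory(n_res, n_frames_ = 8000, dt_ps = 1, d_r = d_r,
                            seed = 31)

cst <- spin_system_constants()  # 700.15 MHz, r_NH 1.02 A, CSA -163 ppm
prof <- trajectory_relaxation(tr, cst, block_ps = 2000)
prof$d_r <- d_r[prof$residue]
write_analysis_table(prof, "results/04_backcalculated_rates.csv")

cat("Back-calculated relaxation profile (terminal vs core):\n")
show <- prof[prof$residue %in% c(1, 2, 12, 13, 23, 24), ]
print(show[, c("residue", "r1", "r2", "noe")], row.names = FALSE)
cat(sprintf("\nCore R2 / tail R2 = %.1f (the rigid core relaxes faster transversely than the mobile tails)\n",
            prof$r2[12] / prof$r2[1]))

acfs <- nh_autocorrelation(tr, block_ps = 2000)
params <- attr(prof, "params")
write_analysis_table(params, "results/04_biexponential_fits.csv")
cat(sprintf("Bi-exponential fits converged for %d/%d residues\n",
            sum(params$converged), nrow(params)))
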