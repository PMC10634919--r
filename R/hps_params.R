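# One-bead-per-residue coarse-grained parameter table (HPS-Urry flavour):
# average residue masses (amu), net charges at neutral pH (e), van der Waals
# diameters sigma (nm) and Urry-scale hydropathies lambda (dimensionless,
# scaled into [0, 1]). All interaction constants live here so the model is
# editable in one place.

HPS_URRY_TABLE <- data.frame(
  aa = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
  mass = c(71.08, 156.19, 114.10, 115.09, 103.14, 128.13, 129.12, 57.05,
           137.14, 113.16, 113.16, 128.17, 131.19, 147.18, 97.12, 87.08,
           101.10, 186.21, 163.18, 99.07),
  charge = c(0, 1, 0, -1, 0, 0, -1, 0, 0, 0,
             0, 1, 0, 0, 0, 0, 0, 0, 0, 0),
  sigma = c(0.504, 0.656, 0.568, 0.558, 0.548, 0.602, 0.592, 0.450,
            0.608, 0.618, 0.618, 0.636, 0.618, 0.636, 0.556, 0.518,
            0.562, 0.678, 0.646, 0.586),
  lambda = c(0.602942, 0.558824, 0.588236, 0.294119, 0.647059, 0.558824,
             0.000000, 0.573530, 0.764707, 0.705883, 0.720589, 0.382354,
             0.676471, 0.823530, 0.758824, 0.588236, 0.588236, 1.000000,
             0.897059, 0.664707),
  stringsAsFactors = FALSE
)

# Physical constants in the simulator's units (kJ/mol, nm, amu, ps, K, e)
KB_KJ <- 0.0083144621            # Boltzmann constant, kJ/mol/K
COULOMB_KJ <- 138.935458         # e^2/(4 pi eps0), kJ/mol * nm / e^2

# Model constants (editable defaults)
HPS_EPSILON <- 0.8368            # short-range interaction depth, kJ/mol
HPS_BOND_R0 <- 0.38              # bond length, nm
HPS_BOND_K <- 8368               # bond spring constant, kJ/mol/nm^2
HPS_CUTOFF_VDW <- 2.0            # short-range cutoff, nm
HPS_CUTOFF_ELEC <- 3.5           # electrostatic cutoff, nm
HPS_DIELECTRIC <- 80             # relative permittivity of water

#' Coarse-grained residue parameters
#'
#' The per-residue parameter table of the hydropathy-scale coarse-grained
#' model: average residue mass (amu), net charge (e), bead diameter sigma
#' (nm), and hydropathy lambda on the Urry scale. Returned as a copy so
#' callers can modify parameters before building a topology.
#'
#' @return data.frame with columns `aa`, `mass`, `charge`, `sigma`, `lambda`.
#' @export
hps_parameters <- function() HPS_URRY_TABLE

#' Debye screening length of a 1:1 salt solution
#'
#' @param ionic_strength_mM ionic strength in mM.
#' @param temperature temperature in K.
#' @param dielectric relative permittivity (default 80).
#' @return screening length in nm (Inf at zero ionic strength).
#' @export
debye_length <- function(ionic_strength_mM, temperature = 300,
                         dielectric = HPS_DIELECTRIC) {
  if (ionic_strength_mM <= 0) return(Inf)
  lb <- COULOMB_KJ / (dielectric * KB_KJ * temperature)  # Bjerrum length, nm
  n <- ionic_strength_mM * 1e-3 * 0.602214076            # ions/nm^3 per species
  1 / sqrt(8 * pi * lb * n)
}

#' Simulation configuration
#'
#' Physical and run-length settings for the coarse-grained Langevin simulator.
#' Defaults follow the published slab protocol (10 fs timestep, 1000 ps
#' Langevin damping time, 300 K) at desk scale.
#'
#' @param temperature K.
#' @param timestep_fs integration timestep, fs.
#' @param t_damp_ps Langevin damping time; per-bead friction is
#'   `gamma_i = m_i / t_damp`.
#' @param box numeric length-3, box edge lengths in nm.
#' @param n_steps total integration steps.
#' @param save_every save a frame every this many steps.
#' @param seed RNG seed for initial placement, velocities and thermostat noise.
#' @param ionic_strength_mM 1:1 salt ionic strength, mM (sets the Debye
#'   screening length).
#' @return object of class `sim_config` (a validated list).
#' @export
simulation_config <- function(temperature = 300, timestep_fs = 10,
                              t_damp_ps = 1000, box = c(15, 15, 15),
                              n_steps = 10000L, save_every = 100L,
                              seed = 1L, ionic_strength_mM = 100) {
  stopifnot(temperature > 0, timestep_fs > 0, t_damp_ps > 0,
            length(box) == 3, all(box > 0), n_steps >= 1, save_every >= 1,
            ionic_strength_mM >= 0)
  structure(list(temperature = temperature, timestep_fs = timestep_fs,
                 t_damp_ps = t_damp_ps, box = as.numeric(box),
                 n_steps = as.integer(n_steps),
                 save_every = as.integer(save_every), seed = as.integer(seed),
                 ionic_strength_mM = ionic_strength_mM),
            class = "sim_config")
}
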