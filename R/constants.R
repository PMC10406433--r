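# Physical constants (CODATA) and unit conversion factors.
# Internal units: length nm, mass kDa, time ns (MSD) / ps (pressure),
# concentration mM, viscosity mPa.s, diffusion um^2/s.

.kB <- 1.380649e-23          # J/K
.NA <- 6.02214076e23         # 1/mol
.xi_cubic <- 2.837297        # self-interaction term of a cubic lattice

# molar concentration (mM) of n entities in V nm^3:
# n / (NA * V) mol/nm^3 = n * 1e27 / (NA * V) mmol/L
.conc_mM_per_inv_nm3 <- 1e27 / .NA

# Green-Kubo prefactor: eta[mPa.s] = .gk_factor / T[K] * V[nm^3] * I[bar^2 ps]
# 1 bar^2 nm^3 ps = 1e10 Pa^2 * 1e-27 m^3 * 1e-12 s = 1e-29 Pa^2 m^3 s
# eta[Pa.s] = V I / (kB T); mPa.s = 1e3 Pa.s
.gk_factor <- 1e-29 / .kB * 1e3

# finite-size diffusion correction, um^2/s:
# kB T xi / (6 pi eta L), eta in mPa.s (1e-3 Pa.s), L in nm (1e-9 m),
# result m^2/s -> 1e12 um^2/s
.yeh_hummer_factor <- .kB * .xi_cubic / (6 * pi * 1e-3 * 1e-9) * 1e12

# MSD slope nm^2/ns -> D um^2/s : (1e-18 m^2 / 1e-9 s) = 1e-9 m^2/s = 1e3 um^2/s
.msd_slope_to_um2s <- 1e3 / 6

# Bondi van der Waals radii, nm
.vdw_radii <- c(H = 0.120, C = 0.170, N = 0.155, O = 0.152, S = 0.180,
                P = 0.180, F = 0.147, CL = 0.175, BR = 0.185, I = 0.198)

# atomic masses, Da
.atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                    P = 30.974, F = 18.998, CL = 35.45, BR = 79.904, I = 126.9)

# empirical coil scaling for disordered chains: Rg = 0.254 * N^0.522 (nm)
.coil_R0 <- 0.254
.coil_nu <- 0.522

# specific van der Waals volume of protein matter, nm^3 per kDa
# (protein mass density ~1.35 g/cm^3 -> ~1.21 A^3/Da)
.vdw_nm3_per_kda <- 1.21

.lookup_element <- function(elements, table, what) {
  key <- toupper(trimws(elements))
  out <- unname(table[key])
  if (anyNA(out)) {
    stop("no ", what, " for element(s): ",
         paste(unique(key[is.na(out)]), collapse = ", "))
  }
  out
}

#' Van der Waals radii for elements
#'
#' Bondi radii in nm for the elements commonly found in proteins.
#'
#' @param elements character vector of element symbols.
#' @return numeric vector of radii (nm).
#' @export
vdw_radius <- function(elements) .lookup_element(elements, .vdw_radii, "vdW radius")

#' Atomic masses for elements
#'
#' @param elements character vector of element symbols.
#' @return numeric vector of masses (Da).
#' @export
atomic_mass <- function(elements) .lookup_element(elements, .atomic_masses, "mass")
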