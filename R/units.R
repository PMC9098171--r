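# Conversions between reduced DPD units and physical units. The water-bead
# mapping fixes the length scale: N_A r_c^3 = rho r_c^3 * N_m * V_m, so with
# N_m = 2 water molecules per bead, V_m = 18e-6 m^3/mol and reduced density
# rho r_c^3 = 3 one mole of DPD volume elements is ~0.108 L and
# r_c = 5.64 Angstrom.

.AVOGADRO <- 6.02214076e23          # 1/mol
.ECHARGE  <- 1.602176634e-19        # C
.KBOLTZ   <- 1.380649e-23           # J/K
.EPS0     <- 8.8541878128e-12       # F/m

#' DPD mapping context
#'
#' Bundles the water-bead mapping parameters and the derived quantities
#' used throughout the unit conversions.
#'
#' @param N_m water molecules per bead (mapping number).
#' @param V_m molar volume of water in m^3/mol.
#' @param reduced_density reduced bead density rho r_c^3.
#' @return a list of class `dpd_mapping` with elements `N_m`, `V_m`,
#'   `reduced_density`, `rc_m` (metres), `rc_A` (Angstrom) and
#'   `molar_volume_L` (N_A r_c^3 in litres).
#' @export
dpd_mapping <- function(N_m = 2, V_m = 18e-6, reduced_density = 3) {
  stopifnot(N_m > 0, V_m > 0, reduced_density > 0)
  vol <- reduced_density * N_m * V_m        # N_A rc^3 in m^3/mol
  rc <- (vol / .AVOGADRO)^(1 / 3)
  structure(list(N_m = N_m, V_m = V_m, reduced_density = reduced_density,
                 rc_m = rc, rc_A = rc * 1e10, molar_volume_L = vol * 1e3),
            class = "dpd_mapping")
}

#' @export
print.dpd_mapping <- function(x, ...) {
  cat(sprintf(
    "DPD mapping: N_m = %g, V_m = %g m^3/mol, rho rc^3 = %g\n  rc = %.3f A, N_A rc^3 = %.4f L/mol\n",
    x$N_m, x$V_m, x$reduced_density, x$rc_A, x$molar_volume_L))
  invisible(x)
}

#' DPD length unit from the water-bead mapping
#'
#' r_c = (rho r_c^3 * N_m * V_m / N_A)^(1/3), reported in Angstrom.
#' The defaults give 5.64 A.
#'
#' @inheritParams dpd_mapping
#' @return r_c in Angstrom.
#' @export
rc_from_mapping <- function(N_m = 2, V_m = 18e-6, reduced_density = 3) {
  dpd_mapping(N_m, V_m, reduced_density)$rc_A
}

#' Dimensionless electrostatic coupling
#'
#' Gamma = e^2 / (kB T eps0 eps_r r_c): the ratio of the Coulomb energy of
#' two unit charges at separation r_c (up to the 4*pi of the SI Coulomb
#' law, which is carried by the potential) to the thermal energy. The
#' defaults (298 K, eps_r = 78.3, r_c = 5.64 A) give 15.94.
#'
#' @param temperature in K.
#' @param eps_r relative dielectric permittivity.
#' @param rc_m the DPD length unit in metres.
#' @return Gamma (dimensionless).
#' @export
coupling_gamma <- function(temperature = 298, eps_r = 78.3,
                           rc_m = dpd_mapping()$rc_m) {
  stopifnot(temperature > 0, eps_r > 0, rc_m > 0)
  .ECHARGE^2 / (.KBOLTZ * temperature * .EPS0 * eps_r * rc_m)
}

#' Salt bead pairs for a molar concentration
#'
#' Converts a salt molarity to the integer number of cation/anion bead
#' pairs (formula units) in a cubic box of side `L` (in r_c), via
#' N_salt = C_salt * (L/r_c)^3 * N_A r_c^3. One "salt" is one cation bead
#' plus one anion bead, inserted by replacing water beads so the reduced
#' density is preserved.
#'
#' @param C_salt salt concentration in mol/L.
#' @param L box side in r_c.
#' @param ctx a [dpd_mapping()] context.
#' @return integer number of ion pairs.
#' @export
salt_pairs_for_concentration <- function(C_salt, L, ctx = dpd_mapping()) {
  if (any(C_salt < 0)) stop("salt concentration must be >= 0")
  stopifnot(L > 0)
  as.integer(round(C_salt * L^3 * ctx$molar_volume_L))
}

#' Molar concentration for a salt bead-pair count
#'
#' Inverse of [salt_pairs_for_concentration()].
#'
#' @param n_pairs number of cation/anion bead pairs.
#' @param L box side in r_c.
#' @param ctx a [dpd_mapping()] context.
#' @return concentration in mol/L.
#' @export
concentration_from_salt_pairs <- function(n_pairs, L, ctx = dpd_mapping()) {
  if (any(n_pairs < 0)) stop("pair count must be >= 0")
  stopifnot(L > 0)
  n_pairs / (L^3 * ctx$molar_volume_L)
}

#' Surfactant molecule count for a weight percentage
#'
#' Converts a surfactant loading in wt% to a molecule count for a box of
#' side `L` r_c, using the topology's molar mass and treating the solution
#' density as that of water (adequate at the few-percent loadings used
#' here).
#'
#' @param wt_percent surfactant weight percent.
#' @param topo a `dpd_topology` carrying `molar_mass` in g/mol.
#' @param L box side in r_c.
#' @param ctx a [dpd_mapping()] context.
#' @return integer molecule count.
#' @export
molecules_for_wt_percent <- function(wt_percent, topo, L,
                                     ctx = dpd_mapping()) {
  stopifnot(wt_percent >= 0, L > 0)
  if (is.null(topo$molar_mass)) {
    stop("topology '", topo$name, "' has no molar_mass; wt% conversion ",
         "requires one")
  }
  box_L <- L^3 * ctx$molar_volume_L / .AVOGADRO          # litres
  grams <- wt_percent / 100 * box_L * 1000               # ~1 kg/L solvent
  as.integer(round(grams / topo$molar_mass * .AVOGADRO))
}
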