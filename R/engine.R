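# DPD engine: system construction, integration, and observables. The force
# loops live in src/dpd.cpp; this file owns validation, unit bookkeeping
# and the trajectory container.

#' Simulation settings
#'
#' @param dt timestep in DPD time units.
#' @param n_steps number of integration steps.
#' @param gamma thermostat friction (the random-force amplitude follows
#'   from sigma^2 = 2 gamma kT).
#' @param kT target temperature in reduced units.
#' @param ensemble "NVT" or "NPT".
#' @param target_pressure NPT target in reduced units (23.7 is the pure
#'   DPD water reference).
#' @param barostat_tau Berendsen box-rescaling time constant (DPD time).
#' @param sample_every trajectory/observable sampling interval in steps.
#' @param equilibration_steps steps discarded by analysis; defaults to
#'   1/8 of the run (the production protocol discards 5e5 of 4e6 steps,
#'   and short desk runs discard the same fraction).
#' @param seed RNG seed (controls initial velocities and random forces).
#' @param bond_constant harmonic bond constant k_b in kBT/r_c^2.
#' @param angle_constant harmonic angle constant k_a in kBT/rad^2.
#' @param electrostatics `NULL` (off) or an [electrostatic_settings()].
#' @param max_step_displacement instability guard in r_c per step.
#' @return a list of class `dpd_settings`.
#' @export
simulation_settings <- function(dt = 0.01, n_steps = 10000, gamma = 4.5,
                                kT = 1, ensemble = c("NVT", "NPT"),
                                target_pressure = 23.7, barostat_tau = 1.0,
                                sample_every = 1000,
                                equilibration_steps = NULL, seed = 1,
                                bond_constant = 150, angle_constant = 5,
                                electrostatics = NULL,
                                max_step_displacement = 0.5) {
  ensemble <- match.arg(ensemble)
  stopifnot(dt > 0, n_steps >= 1, sample_every >= 1, gamma >= 0, kT > 0,
            bond_constant > 0, angle_constant >= 0)
  if (is.null(equilibration_steps)) {
    equilibration_steps <- floor(n_steps / 8)
  }
  structure(list(dt = dt, n_steps = as.integer(n_steps), gamma = gamma,
                 kT = kT, ensemble = ensemble,
                 target_pressure = target_pressure,
                 barostat_tau = barostat_tau,
                 sample_every = as.integer(sample_every),
                 equilibration_steps = as.integer(equilibration_steps),
                 seed = as.integer(seed), bond_constant = bond_constant,
                 angle_constant = angle_constant,
                 electrostatics = electrostatics,
                 max_step_displacement = max_step_displacement),
            class = "dpd_settings")
}

# Build per-type interaction matrices for the bead types present, failing
# fast on any unresolvable pair.
.build_type_matrices <- function(ff, type_names) {
  nt <- length(type_names)
  aM <- matrix(0, nt, nt)
  RM <- matrix(0, nt, nt)
  for (i in seq_len(nt)) {
    for (j in i:nt) {
      p <- pair_lookup(ff, type_names[i], type_names[j])
      aM[i, j] <- aM[j, i] <- p$a
      RM[i, j] <- RM[j, i] <- p$R
    }
  }
  list(a = aM, R = RM)
}

#' Build a DPD system
#'
#' Assembles a random initial configuration: surfactant molecules grown as
#' random walks with their bonded geometry, salt ion pairs and water beads
#' placed uniformly, Maxwell velocities with the net momentum zeroed. The
#' total bead count must match the reduced density (default 3) unless
#' explicitly overridden, and charged systems must be electroneutral.
#'
#' @param ff a `dpd_forcefield`.
#' @param L cubic box side in r_c.
#' @param molecules list of `list(topology =, count =)` entries.
#' @param salt `NULL` or `list(cation =, anion =, n_cation =, n_anion =)`
#'   (equal counts may be given as `pairs =`).
#' @param water number of water beads, or `"fill"` to complete the density.
#' @param density target reduced density rho r_c^3.
#' @param allow_density_mismatch permit a total bead count that does not
#'   match `density`.
#' @param seed RNG seed for the initial configuration.
#' @return a list of class `dpd_system`.
#' @export
build_system <- function(ff, L, molecules = list(), salt = NULL,
                         water = "fill", density = 3,
                         allow_density_mismatch = FALSE, seed = 1) {
  stopifnot(inherits(ff, "dpd_forcefield"), L > 0)
  n_target <- round(density * L^3)

  mol_beads <- 0L
  for (m in molecules) {
    stopifnot(inherits(m$topology, "dpd_topology"), m$count >= 0)
    mol_beads <- mol_beads + m$count * length(m$topology$beads)
  }
  n_cat <- n_an <- 0L
  if (!is.null(salt)) {
    if (!is.null(salt$pairs)) {
      n_cat <- n_an <- as.integer(salt$pairs)
    } else {
      n_cat <- as.integer(salt$n_cation %||% 0L)
      n_an <- as.integer(salt$n_anion %||% 0L)
    }
    qc <- bead_charge(ff, salt$cation)
    qa <- bead_charge(ff, salt$anion)
    if (qc <= 0 || qa >= 0) stop("salt cation/anion roles are inverted")
    if (n_cat * qc + n_an * qa != 0) {
      stop("charged system is not electroneutral: ", n_cat, " x ",
           salt$cation, " and ", n_an, " x ", salt$anion)
    }
  }
  if (identical(water, "fill")) {
    water <- n_target - mol_beads - n_cat - n_an
    if (water < 0) {
      stop("composition exceeds the bead budget for density ", density,
           " in an L = ", L, " box")
    }
  }
  n_total <- mol_beads + n_cat + n_an + water
  if (n_total != n_target && !allow_density_mismatch) {
    stop("total bead count ", n_total, " does not give reduced density ",
         density, " (expected ", n_target, " beads); pass ",
         "allow_density_mismatch = TRUE to override")
  }

  set.seed(seed)
  bead_names <- character(n_total)
  molecule_id <- rep(NA_integer_, n_total)
  molecule_name <- rep(NA_character_, n_total)
  pos <- matrix(0, n_total, 3)
  bonds <- list(); angles <- list()
  idx <- 0L; mol <- 0L
  for (m in molecules) {
    topo <- m$topology
    validate_topology(topo, ff)
    nb <- length(topo$beads)
    for (cnt in seq_len(m$count)) {
      mol <- mol + 1L
      base <- idx
      bead_names[base + seq_len(nb)] <- topo$beads
      molecule_id[base + seq_len(nb)] <- mol
      molecule_name[base + seq_len(nb)] <- topo$name
      # random-walk growth along the bond list
      pos[base + 1L, ] <- runif(3, 0, L)
      placed <- c(1L)
      for (b in seq_len(nrow(topo$bonds))) {
        i <- topo$bonds$i[b]; j <- topo$bonds$j[b]; r0 <- topo$bonds$r0[b]
        if (i %in% placed && !(j %in% placed)) {
          from <- i; to <- j
        } else if (j %in% placed && !(i %in% placed)) {
          from <- j; to <- i
        } else next
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        pos[base + to, ] <- (pos[base + from, ] + r0 * u) %% L
        placed <- c(placed, to)
      }
      if (nrow(topo$bonds)) {
        bonds[[length(bonds) + 1L]] <- cbind(base + topo$bonds$i,
                                             base + topo$bonds$j,
                                             topo$bonds$r0)
      }
      if (nrow(topo$angles)) {
        angles[[length(angles) + 1L]] <- cbind(base + topo$angles$i,
                                               base + topo$angles$j,
                                               base + topo$angles$k,
                                               topo$angles$theta0)
      }
      idx <- idx + nb
    }
  }
  if (n_cat > 0L) {
    bead_names[idx + seq_len(n_cat)] <- salt$cation
    pos[idx + seq_len(n_cat), ] <- matrix(runif(3 * n_cat, 0, L), ncol = 3)
    idx <- idx + n_cat
  }
  if (n_an > 0L) {
    bead_names[idx + seq_len(n_an)] <- salt$anion
    pos[idx + seq_len(n_an), ] <- matrix(runif(3 * n_an, 0, L), ncol = 3)
    idx <- idx + n_an
  }
  if (water > 0L) {
    bead_names[idx + seq_len(water)] <- "W"
    pos[idx + seq_len(water), ] <- matrix(runif(3 * water, 0, L), ncol = 3)
    idx <- idx + water
  }

  type_names <- unique(bead_names)
  mats <- .build_type_matrices(ff, type_names)
  type_id <- match(bead_names, type_names) - 1L
  charge <- as.numeric(bead_charge(ff, bead_names))
  if (abs(sum(charge)) > 1e-9) stop("system carries net charge ", sum(charge))

  bonds <- if (length(bonds)) do.call(rbind, bonds) else
    matrix(0, 0, 3)
  angles <- if (length(angles)) do.call(rbind, angles) else
    matrix(0, 0, 4)

  vel <- cpp_maxwell_velocities(n_total, 1, seed)

  structure(list(positions = pos, velocities = vel,
                 bead_names = bead_names, type_names = type_names,
                 type_id = type_id, charge = charge,
                 molecule_id = molecule_id, molecule_name = molecule_name,
                 bonds = bonds, angles = angles,
                 aMat = mats$a, RMat = mats$R, L = L,
                 topologies = molecules, seed = seed),
            class = "dpd_system")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dpd_system <- function(x, ...) {
  cat("DPD system: ", nrow(x$positions), " beads in L = ", x$L,
      " r_c box (rho = ", round(nrow(x$positions) / x$L^3, 3), ")\n", sep = "")
  cat("  types:", paste(x$type_names, collapse = ", "), "\n")
  nmol <- length(unique(stats::na.omit(x$molecule_id)))
  if (nmol) cat("  molecules:", nmol, "\n")
  invisible(x)
}

#' Run a DPD simulation
#'
#' Integrates the system with velocity Verlet and the pairwise
#' dissipative/random thermostat, sampling frames and observables at the
#' settings' interval. Deterministic for a given seed. Errors out if any
#' bead moves more than the instability guard in one step.
#'
#' @param system a `dpd_system` from [build_system()].
#' @param settings a [simulation_settings()].
#' @return an object of class `dpd_trajectory` with frames, per-sample
#'   temperature/pressure/energy series and the final state.
#' @export
run_simulation <- function(system, settings = simulation_settings()) {
  stopifnot(inherits(system, "dpd_system"), inherits(settings, "dpd_settings"))
  es <- settings$electrostatics
  elec_on <- !is.null(es) && any(system$charge != 0)
  if (elec_on && system$L < 2 * es$rcut_real) {
    stop("box side ", system$L, " r_c is smaller than twice the Ewald ",
         "real-space cutoff ", es$rcut_real)
  }
  if (is.null(es)) es <- electrostatic_settings()
  res <- cpp_run_dpd(
    system$positions, system$velocities, system$type_id, system$charge,
    system$L, system$aMat, system$RMat,
    as.integer(system$bonds[, 1] - 1L), as.integer(system$bonds[, 2] - 1L),
    as.numeric(system$bonds[, 3]), settings$bond_constant,
    as.integer(system$angles[, 1] - 1L), as.integer(system$angles[, 2] - 1L),
    as.integer(system$angles[, 3] - 1L), as.numeric(system$angles[, 4]),
    settings$angle_constant,
    elec_on, es$gamma, es$beta_star, es$alpha, es$rcut_real, es$kcut,
    es$rcut_corr,
    settings$dt, settings$n_steps, settings$gamma, settings$kT,
    settings$seed, settings$sample_every,
    identical(settings$ensemble, "NPT"), settings$target_pressure,
    settings$barostat_tau, settings$max_step_displacement)
  structure(list(frames = res$frames, steps = res$steps, L = res$L,
                 temperature = res$temperature, pressure = res$pressure,
                 potential = res$potential, kinetic = res$kinetic,
                 bead_names = system$bead_names,
                 molecule_id = system$molecule_id,
                 molecule_name = system$molecule_name,
                 final = list(positions = res$positions,
                              velocities = res$velocities, L = res$box),
                 settings = settings, system_seed = system$seed),
            class = "dpd_trajectory")
}

#' @export
print.dpd_trajectory <- function(x, ...) {
  cat("DPD trajectory:", length(x$frames), "frames,",
      length(x$bead_names), "beads, final L =",
      round(x$final$L, 4), "r_c\n")
  if (length(x$temperature)) {
    cat(sprintf("  <T> = %.4f  <P> = %.3f (all samples)\n",
                mean(x$temperature), mean(x$pressure)))
  }
  invisible(x)
}

#' Conservative soft-repulsion forces
#'
#' Evaluates the linear DPD repulsion F = a_ij (1 - r/R_ij) r-hat for all
#' pairs within their cutoffs, returning per-bead forces, the scalar
#' virial (sum of r_ij . F_ij) and the potential energy. Coincident beads
#' get zero force for that pair (the soft potential is finite at r = 0)
#' and are reported via a warning.
#'
#' @param positions N x 3 matrix in r_c.
#' @param bead_names length-N bead type labels.
#' @param ff a `dpd_forcefield`.
#' @param L box side in r_c.
#' @param method "cell" (linked cells, the default) or "allpairs"
#'   (O(N^2) reference).
#' @return list with `forces`, `virial`, `energy`.
#' @export
conservative_forces <- function(positions, bead_names, ff, L,
                                method = c("cell", "allpairs")) {
  method <- match.arg(method)
  type_names <- unique(bead_names)
  mats <- .build_type_matrices(ff, type_names)
  res <- cpp_conservative_forces(positions,
                                 match(bead_names, type_names) - 1L, L,
                                 mats$a, mats$R,
                                 identical(method, "allpairs"))
  if (res$overlaps > 0) {
    warning(res$overlaps, " coincident bead pair(s): force direction ",
            "undefined, zero force applied")
  }
  res[c("forces", "virial", "energy")]
}

#' Bonded (bond + angle) forces
#'
#' Harmonic bond energy 0.5 k_b (r - r0)^2 and angle energy
#' 0.5 k_a (theta - theta0)^2 with forces as exact negative gradients;
#' bond vectors use the minimum image and collinear angles take a
#' stabilized small-sine branch.
#'
#' @param positions N x 3 matrix in r_c.
#' @param bonds matrix with columns (i, j, r0), 1-based indices.
#' @param angles matrix with columns (i, j, k, theta0), theta0 in radians.
#' @param L box side in r_c.
#' @param bond_constant,angle_constant k_b and k_a.
#' @return list with `forces`, `energy`, `virial`.
#' @export
bonded_forces <- function(positions, bonds, angles, L,
                          bond_constant = 150, angle_constant = 5) {
  if (is.null(bonds)) bonds <- matrix(0, 0, 3)
  if (is.null(angles)) angles <- matrix(0, 0, 4)
  cpp_bonded_forces(positions, L,
                    as.integer(bonds[, 1] - 1L), as.integer(bonds[, 2] - 1L),
                    as.numeric(bonds[, 3]), bond_constant,
                    as.integer(angles[, 1] - 1L),
                    as.integer(angles[, 2] - 1L),
                    as.integer(angles[, 3] - 1L),
                    as.numeric(angles[, 4]), angle_constant)
}

#' Average observables over a trajectory window
#'
#' Temperature is 2 KE / (3N - 3) and pressure (N kT + virial/3)/V per
#' sample, both in reduced units, averaged over samples after the
#' equilibration discard.
#'
#' @param traj a `dpd_trajectory`.
#' @param discard_steps samples at steps <= this are excluded; defaults to
#'   the settings' equilibration.
#' @return list with `temperature`, `pressure`, `n_samples`.
#' @export
measure_observables <- function(traj, discard_steps = NULL) {
  stopifnot(inherits(traj, "dpd_trajectory"))
  if (is.null(discard_steps)) discard_steps <- traj$settings$equilibration_steps
  keep <- traj$steps > discard_steps
  if (!any(keep)) stop("no samples after the equilibration discard")
  list(temperature = mean(traj$temperature[keep]),
       pressure = mean(traj$pressure[keep]),
       n_samples = sum(keep))
}
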