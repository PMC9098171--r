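# Deterministic synthetic-input generators. These are geometric /
# statistical constructions for exercising the analysis stages without
# long simulations: planted-micelle trajectories for the clustering and
# P(N) machinery, and planted-parameter Setschenow datasets for the
# fitting machinery.

#' Generate a trajectory with planted micelles
#'
#' Places `n_micelles` micelles (sizes drawn uniformly from `size_range`)
#' and `n_monomers` free molecules of the given topology in a cubic box.
#' Tail beads of one micelle are packed inside a ball of radius
#' `core_radius` (default 0.45 r_c, so any two tail beads are within
#' 2 x 0.45 < 1 r_c: single-linkage connectivity at the standard cutoff is
#' guaranteed by construction); head beads point radially outward. Micelle
#' centers are kept >= `center_sep` apart and monomers >= 3 r_c from every
#' micelle center and >= `monomer_sep` from each other, so the planted
#' partition is exactly recoverable. Each frame re-jitters all placements.
#' Purely geometric: these fixtures test analysis code, not physics.
#'
#' @param L box side in r_c.
#' @param n_micelles number of planted micelles.
#' @param size_range integer range (N_lo, N_hi) of micelle sizes.
#' @param n_monomers number of free molecules.
#' @param topology a `dpd_topology` (default: the packaged 4-bead model
#'   amphiphile).
#' @param n_frames frames to emit.
#' @param core_radius tail-packing ball radius in r_c.
#' @param center_sep minimum micelle-center separation in r_c.
#' @param monomer_sep minimum monomer-monomer separation in r_c.
#' @param seed RNG seed; equal specs and seeds give identical output.
#' @return list with `trajectory` (a `dpd_trajectory`) and `labels`
#'   (per-molecule ground-truth aggregate ids; each monomer carries its
#'   own singleton label).
#' @export
generate_micelle_trajectory <- function(L, n_micelles, size_range,
                                        n_monomers, topology = NULL,
                                        n_frames = 5, core_radius = 0.45,
                                        center_sep = 4.0, monomer_sep = 2.5,
                                        seed = 1) {
  if (is.null(topology)) topology <- load_topology("AMPH4")
  stopifnot(inherits(topology, "dpd_topology"), L > 0, n_frames >= 1)
  set.seed(seed)
  sizes <- if (n_micelles > 0) {
    rng <- size_range[1]:size_range[2]
    if (length(rng) == 1L) rep(rng, n_micelles)
    else sample(rng, n_micelles, replace = TRUE)
  } else integer()

  place_points <- function(n, min_sep, avoid = NULL, avoid_sep = 0) {
    pts <- matrix(0, 0, 3)
    tries <- 0L
    while (nrow(pts) < n) {
      cand <- runif(3, 0, L)
      ok <- TRUE
      if (nrow(pts)) {
        d <- sweep(pts, 2, cand)
        d <- d - L * round(d / L)
        if (min(sqrt(rowSums(d^2))) < min_sep) ok <- FALSE
      }
      if (ok && !is.null(avoid) && nrow(avoid)) {
        d <- sweep(avoid, 2, cand)
        d <- d - L * round(d / L)
        if (min(sqrt(rowSums(d^2))) < avoid_sep) ok <- FALSE
      }
      if (ok) pts <- rbind(pts, cand)
      tries <- tries + 1L
      if (tries > 20000L) {
        stop("infeasible packing: cannot place ", n, " points at ",
             "separation ", min_sep, " in an L = ", L, " box")
      }
    }
    pts
  }

  centers <- if (n_micelles > 0) {
    place_points(n_micelles, center_sep)
  } else matrix(0, 0, 3)
  mono_pos <- if (n_monomers > 0) {
    place_points(n_monomers, monomer_sep, avoid = centers, avoid_sep = 3.0)
  } else matrix(0, 0, 3)

  nb <- length(topology$beads)
  tailset <- topology$tail_beads
  is_tail <- topology$beads %in% tailset
  n_mol <- sum(sizes) + n_monomers
  n_beads <- n_mol * nb
  bead_names <- rep(topology$beads, n_mol)
  molecule_id <- rep(seq_len(n_mol), each = nb)
  molecule_name <- rep(topology$name, n_beads)

  labels <- integer(n_mol)
  mol <- 0L
  for (m in seq_along(sizes)) {
    labels[mol + seq_len(sizes[m])] <- m
    mol <- mol + sizes[m]
  }
  if (n_monomers > 0) {
    labels[mol + seq_len(n_monomers)] <- n_micelles + seq_len(n_monomers)
  }

  make_frame <- function() {
    pos <- matrix(0, n_beads, 3)
    mol <- 0L
    for (m in seq_along(sizes)) {
      for (s in seq_len(sizes[m])) {
        mol <- mol + 1L
        u <- rnorm(3); u <- u / sqrt(sum(u^2))   # outward axis
        base <- (mol - 1L) * nb
        for (b in seq_len(nb)) {
          if (is_tail[b]) {
            # inside the core ball
            v <- rnorm(3); v <- v / sqrt(sum(v^2))
            rad <- core_radius * runif(1)^(1 / 3)
            pos[base + b, ] <- (centers[m, ] + rad * v) %% L
          } else {
            pos[base + b, ] <- (centers[m, ] +
                                  (core_radius + 0.5) * u) %% L
          }
        }
      }
    }
    for (s in seq_len(n_monomers)) {
      mol <- mol + 1L
      base <- (mol - 1L) * nb
      for (b in seq_len(nb)) {
        pos[base + b, ] <- (mono_pos[s, ] + 0.2 * rnorm(3)) %% L
      }
    }
    pos
  }
  frames <- lapply(seq_len(n_frames), function(f) make_frame())
  traj <- structure(list(frames = frames,
                         steps = seq_len(n_frames) * 1000L,
                         L = rep(L, n_frames),
                         temperature = numeric(), pressure = numeric(),
                         potential = numeric(), kinetic = numeric(),
                         bead_names = bead_names,
                         molecule_id = molecule_id,
                         molecule_name = molecule_name,
                         final = list(positions = frames[[n_frames]],
                                      velocities = NULL, L = L),
                         settings = NULL, system_seed = seed),
                    class = "dpd_trajectory")
  list(trajectory = traj, labels = labels, sizes = sizes)
}

#' Generate a synthetic Setschenow dataset with planted parameters
#'
#' Draws k_s from a planted separable model and emits (i) a k_s table in
#' the experimental-data format and (ii) per-(surfactant, salt) CMC series
#' following ln(CMC/CMC0) = -k_s C with optional lognormal noise on the
#' CMCs. With zero noise, [fit_ks()], [fit_surfactant_AB()] and
#' [fit_ion_amplitudes()] recover the planted parameters exactly.
#'
#' @param surfactant_params planted A/B table (`surfactant`, `A`, `B`).
#' @param ion_params planted amplitudes (`ion`, `amplitude`, optional
#'   `charge`).
#' @param salts data.frame with columns `cation`, `anion`; default: all
#'   cation/anion combinations.
#' @param concentrations salt concentration grid in mol/L (must include 0).
#' @param cmc0 zero-salt CMC in mol/L used for every series.
#' @param sigma lognormal noise sd on the CMCs (0 = exact).
#' @param seed RNG seed.
#' @param dir optional output directory; when given, writes
#'   `ks_table.csv` and one `cmc_<surfactant>_<cation><anion>.csv` per
#'   series in the formats read by the fitting functions.
#' @return list with `ks_table`, `cmc_series` (named list of data.frames
#'   with `csalt`, `cmc`), and the planted `model`.
#' @export
generate_ks_dataset <- function(surfactant_params, ion_params,
                                salts = NULL,
                                concentrations = c(0, 0.5, 1, 1.5, 2),
                                cmc0 = 0.01, sigma = 0, seed = 1,
                                dir = NULL) {
  stopifnot(sigma >= 0, 0 %in% concentrations)
  model <- separable_ks_model(surfactant_params, ion_params)
  if (is.null(salts)) {
    cats <- ion_params$ion[grepl("\\+$", ion_params$ion)]
    ans <- ion_params$ion[grepl("-$", ion_params$ion)]
    salts <- expand.grid(cation = cats, anion = ans,
                         stringsAsFactors = FALSE)
  }
  set.seed(seed)
  rows <- expand.grid(surfactant = surfactant_params$surfactant,
                      idx = seq_len(nrow(salts)),
                      stringsAsFactors = FALSE)
  rows$cation <- salts$cation[rows$idx]
  rows$anion <- salts$anion[rows$idx]
  rows$idx <- NULL
  rows$ks_true <- predict_ks(model, rows$surfactant, rows$cation, rows$anion)

  series <- list()
  ks_fit <- numeric(nrow(rows))
  for (r in seq_len(nrow(rows))) {
    cmc <- cmc0 * exp(-rows$ks_true[r] * concentrations)
    if (sigma > 0) cmc <- cmc * rlnorm(length(cmc), 0, sigma)
    s <- data.frame(csalt = concentrations, cmc = cmc)
    nm <- paste0(rows$surfactant[r], "_", rows$cation[r], rows$anion[r])
    series[[nm]] <- s
    ks_fit[r] <- fit_ks(s, cmc0 = if (sigma > 0) NULL else cmc0)$ks
  }
  ks_table <- data.frame(surfactant = rows$surfactant,
                         cation = rows$cation, anion = rows$anion,
                         ks = ks_fit, source_flag = "monovalent",
                         stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(ks_table, file.path(dir, "ks_table.csv"), row.names = FALSE)
    for (nm in names(series)) {
      write.csv(series[[nm]],
                file.path(dir, paste0("cmc_", gsub("[+]", "p",
                          gsub("-", "m", nm)), ".csv")),
                row.names = FALSE)
    }
  }
  list(ks_table = ks_table, cmc_series = series, model = model)
}
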