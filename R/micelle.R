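# Micelle identification and CMC extraction. Aggregates are defined by
# single-linkage tail-bead contact: two surfactant molecules belong to the
# same aggregate iff some pair of their tail beads is within the contact
# cutoff (minimum image), closed transitively. The aggregation-number
# distribution P(N) then separates free surfactant (N < N_cut) from
# micelles at its interior minimum, and the CMC is the mean free-surfactant
# concentration.

#' Partition the surfactant molecules of one frame into aggregates
#'
#' Single-linkage clustering on tail-bead contacts under the minimum
#' image. Beads without a molecule id (water, ions) are ignored.
#'
#' @param positions N x 3 matrix in r_c.
#' @param L box side in r_c.
#' @param molecule_id length-N integer molecule ids (NA for non-surfactant
#'   beads).
#' @param bead_names length-N bead labels.
#' @param tail_beads character set of tail bead names defining the
#'   micelle core.
#' @param cutoff contact cutoff in r_c.
#' @return integer vector: aggregate id per molecule (named by molecule
#'   id, sorted).
#' @export
cluster_frame <- function(positions, L, molecule_id, bead_names,
                          tail_beads = c("T", "T2", "C2"), cutoff = 1.0) {
  stopifnot(cutoff > 0)
  mols <- sort(unique(molecule_id[!is.na(molecule_id)]))
  if (!length(mols)) stop("frame contains no surfactant molecules")
  sel <- which(!is.na(molecule_id) & bead_names %in% tail_beads)
  if (!length(sel)) stop("no tail beads found for bead set: ",
                         paste(tail_beads, collapse = ", "))
  p <- positions[sel, , drop = FALSE]
  mid <- match(molecule_id[sel], mols)
  nt <- length(sel)

  # pairwise min-image distances between tail beads (vectorized)
  dx <- outer(p[, 1], p[, 1], "-"); dx <- dx - L * round(dx / L)
  dy <- outer(p[, 2], p[, 2], "-"); dy <- dy - L * round(dy / L)
  dz <- outer(p[, 3], p[, 3], "-"); dz <- dz - L * round(dz / L)
  close_ <- (dx * dx + dy * dy + dz * dz) < cutoff^2
  edge <- which(close_ & upper.tri(close_), arr.ind = TRUE)

  parent <- seq_along(mols)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  if (nrow(edge)) {
    for (e in seq_len(nrow(edge))) {
      a <- mid[edge[e, 1]]; b <- mid[edge[e, 2]]
      if (a != b) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  roots <- vapply(seq_along(mols), find, integer(1))
  out <- match(roots, unique(roots))
  names(out) <- mols
  out
}

#' Aggregation-number distribution
#'
#' Pools per-frame aggregate sizes over the post-equilibration window and
#' histograms them. The default weighting is molecule-weighted (the count
#' at N is the number of molecules residing in size-N aggregates);
#' aggregate weighting counts aggregates instead. A moving-average
#' smoothing of P(N) (default window 3) is stored for minimum-finding.
#'
#' @param traj a `dpd_trajectory` with a molecule map.
#' @param cutoff tail-contact cutoff in r_c.
#' @param tail_beads tail bead name set.
#' @param discard_steps frames at steps <= this are dropped; defaults to
#'   the trajectory settings' equilibration (1/8 of the run when built by
#'   this package).
#' @param window moving-average smoothing window (odd integer).
#' @param weighting "molecule" or "aggregate".
#' @return an object of class `aggregate_distribution` with fields `N`,
#'   `count`, `P`, `P_smooth`, `n_frames`, `window`, `weighting`, `flags`.
#' @export
aggregation_distribution <- function(traj, cutoff = 1.0,
                                     tail_beads = c("T", "T2", "C2"),
                                     discard_steps = NULL, window = 3,
                                     weighting = c("molecule", "aggregate")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(traj, "dpd_trajectory"))
  if (is.null(discard_steps)) {
    discard_steps <- if (!is.null(traj$settings))
      traj$settings$equilibration_steps else 0L
  }
  keep <- which(traj$steps > discard_steps)
  if (!length(keep)) stop("equilibration discard leaves no frames")
  flags <- character()
  if (length(keep) < 10L) {
    warning("only ", length(keep), " usable frames; P(N) may be noisy")
    flags <- c(flags, "few_frames")
  }
  nmol <- length(unique(stats::na.omit(traj$molecule_id)))
  sizes <- integer()
  free_per_frame <- NULL
  for (f in keep) {
    part <- cluster_frame(traj$frames[[f]], traj$L[f], traj$molecule_id,
                          traj$bead_names, tail_beads, cutoff)
    stopifnot(sum(tabulate(part)) == nmol)
    sizes <- c(sizes, tabulate(part))
  }
  sizes <- sizes[sizes > 0L]
  Nmax <- max(sizes)
  cnt <- tabulate(sizes, nbins = Nmax)
  if (weighting == "molecule") cnt <- cnt * seq_len(Nmax)
  P <- cnt / sum(cnt)
  structure(list(N = seq_len(Nmax), count = cnt, P = P,
                 P_smooth = .moving_average(P, window),
                 n_frames = length(keep), window = window,
                 weighting = weighting, flags = flags,
                 n_molecules = nmol),
            class = "aggregate_distribution")
}

.moving_average <- function(x, window) {
  if (window <= 1L || length(x) < window) return(x)
  half <- (window - 1L) %/% 2L
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    out[i] <- mean(x[lo:hi])
  }
  out
}

#' @export
print.aggregate_distribution <- function(x, ...) {
  cat("Aggregation-number distribution over", x$n_frames, "frames (",
      x$weighting, "-weighted ), N up to", max(x$N), "\n")
  occ <- x$N[x$count > 0]
  cat("  occupied sizes:", paste(utils::head(occ, 15), collapse = " "),
      if (length(occ) > 15) "...", "\n")
  invisible(x)
}

#' Select N_cut at the interior minimum of P(N)
#'
#' Finds the minimum of the smoothed P(N) strictly between the monomer
#' mode (the first local maximum) and the largest micellar mode (the last
#' local maximum). When the minimum is attained on a contiguous run of
#' equally depleted sizes -- the common case when the depleted region is
#' entirely empty -- the run's midpoint is returned; otherwise ties break
#' toward the smaller N. A distribution with no interior minimum (monotone
#' P) falls back to the configured default with a warning.
#'
#' @param dist an `aggregate_distribution`.
#' @param default N_cut used on the fallback path.
#' @return integer N_cut (>= 2).
#' @export
find_ncut <- function(dist, default = 10L) {
  stopifnot(inherits(dist, "aggregate_distribution"))
  P <- dist$P_smooth
  n <- length(P)
  if (n < 3L) {
    warning("distribution support too narrow for an interior minimum; ",
            "falling back to N_cut = ", default)
    return(as.integer(default))
  }
  is_max <- vapply(seq_len(n), function(i) {
    left <- if (i > 1L) P[i] > P[i - 1L] else P[i] > 0
    right <- if (i < n) P[i] >= P[i + 1L] else TRUE
    left && right && P[i] > 0
  }, logical(1))
  # the monomer mode: treat index 1 as a mode when P is locally decreasing
  if (P[1] >= P[2] && P[1] > 0) is_max[1] <- TRUE
  modes <- which(is_max)
  if (length(modes) < 2L) {
    warning("P(N) has no interior minimum (monotone distribution); ",
            "falling back to N_cut = ", default)
    return(as.integer(default))
  }
  lo <- modes[1]; hi <- modes[length(modes)]
  interior <- (lo + 1L):(hi - 1L)
  if (!length(interior)) {
    warning("modes are adjacent; falling back to N_cut = ", default)
    return(as.integer(default))
  }
  m <- min(P[interior])
  cand <- interior[P[interior] <= m + 1e-12]
  ncut <- if (length(cand) > 1L && all(diff(cand) == 1L)) {
    cand[ceiling(length(cand) / 2)]
  } else {
    cand[1]
  }
  max(as.integer(ncut), 2L)
}

#' CMC from the free-surfactant concentration
#'
#' Per frame, the free count is the number of molecules in aggregates
#' smaller than N_cut (monomers and submicellar aggregates alike); the CMC
#' is the mean free count converted to mol/L through the box volume and
#' the DPD volume mapping.
#'
#' @param traj a `dpd_trajectory`.
#' @param n_cut aggregation-number separator (from [find_ncut()] or user
#'   supplied).
#' @param ctx a [dpd_mapping()] context.
#' @param cutoff,tail_beads,discard_steps clustering parameters, as in
#'   [aggregation_distribution()].
#' @return an object of class `cmc_estimate`: `cmc_molL`, `mean_free`
#'   (molecules per box), `free_per_frame`, `n_cut`, `flags`.
#' @export
cmc_from_trajectory <- function(traj, n_cut, ctx = dpd_mapping(),
                                cutoff = 1.0,
                                tail_beads = c("T", "T2", "C2"),
                                discard_steps = NULL) {
  stopifnot(inherits(traj, "dpd_trajectory"), n_cut >= 2)
  if (is.null(discard_steps)) {
    discard_steps <- if (!is.null(traj$settings))
      traj$settings$equilibration_steps else 0L
  }
  keep <- which(traj$steps > discard_steps)
  if (!length(keep)) stop("equilibration discard leaves no frames")
  flags <- character()
  free <- numeric(length(keep))
  max_seen <- 0L
  for (ii in seq_along(keep)) {
    f <- keep[ii]
    part <- cluster_frame(traj$frames[[f]], traj$L[f], traj$molecule_id,
                          traj$bead_names, tail_beads, cutoff)
    sz <- tabulate(part)
    max_seen <- max(max_seen, max(sz))
    free[ii] <- sum(sz[sz < n_cut])
  }
  if (n_cut > max_seen) {
    flags <- c(flags, "ncut_exceeds_largest_aggregate")
  }
  if (all(free == 0)) flags <- c(flags, "no_free_surfactant")
  L <- mean(traj$L[keep])
  cmc <- mean(free) / (L^3 * ctx$molar_volume_L)
  structure(list(cmc_molL = cmc, mean_free = mean(free),
                 free_per_frame = free, n_cut = as.integer(n_cut),
                 L = L, flags = flags),
            class = "cmc_estimate")
}

#' @export
print.cmc_estimate <- function(x, ...) {
  cat(sprintf("CMC estimate: %.4g mol/L (mean %.1f free molecules, N_cut = %d)\n",
              x$cmc_molL, x$mean_free, x$n_cut))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Average CMC across runs at different surfactant loadings
#'
#' Applies [cmc_from_trajectory()] to each run (typically 4, 5 and 6 wt%)
#' and reports the per-run values and their mean.
#'
#' @param trajs list of `dpd_trajectory` objects.
#' @param n_cut shared aggregation-number separator.
#' @param ... passed to [cmc_from_trajectory()].
#' @return list with `per_run` (numeric vector of CMCs in mol/L), `mean`,
#'   and the individual `cmc_estimate` objects.
#' @export
cmc_from_runs <- function(trajs, n_cut, ...) {
  ests <- lapply(trajs, cmc_from_trajectory, n_cut = n_cut, ...)
  per <- vapply(ests, function(e) e$cmc_molL, numeric(1))
  list(per_run = per, mean = mean(per), estimates = ests)
}
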