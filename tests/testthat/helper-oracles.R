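# Independent oracles used across the test files. These deliberately take
# the slow, obvious route (all-pairs loops in R, direct lattice sums) so
# they share no code with the implementation they check.

min_image_vec <- function(d, L) d - L * round(d / L)

# O(N^2) soft-repulsion reference in plain R
brute_conservative <- function(pos, nm, ff, L) {
  n <- nrow(pos)
  F <- matrix(0, n, 3)
  vir <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- min_image_vec(pos[i, ] - pos[j, ], L)
      r <- sqrt(sum(d^2))
      p <- pair_lookup(ff, nm[i], nm[j])
      if (r < p$R && r > 0) {
        fm <- p$a * (1 - r / p$R)
        f <- fm * d / r
        F[i, ] <- F[i, ] + f
        F[j, ] <- F[j, ] - f
        vir <- vir + fm * r
      }
    }
  }
  list(forces = F, virial = vir)
}

# O(M^2) union-find clustering reference over molecules
brute_cluster <- function(pos, L, molecule_id, bead_names, tail_beads,
                          cutoff) {
  mols <- sort(unique(molecule_id[!is.na(molecule_id)]))
  parent <- seq_along(mols)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  sel <- which(!is.na(molecule_id) & bead_names %in% tail_beads)
  for (ii in seq_along(sel)) {
    for (jj in seq_along(sel)) {
      if (jj <= ii) next
      i <- sel[ii]; j <- sel[jj]
      mi <- match(molecule_id[i], mols); mj <- match(molecule_id[j], mols)
      if (mi == mj) next
      d <- min_image_vec(pos[i, ] - pos[j, ], L)
      if (sum(d^2) < cutoff^2) {
        ri <- find(mi); rj <- find(mj)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_along(mols), find, integer(1))
  match(roots, unique(roots))
}

# direct lattice sum of the smeared pair potential over image shells
brute_slater_lattice <- function(pos, q, L, nimg,
                                 settings = electrostatic_settings()) {
  E <- 0
  sh <- -nimg:nimg
  for (i in seq_len(nrow(pos))) {
    for (j in i:nrow(pos)) {
      if (q[i] * q[j] == 0) next
      d0 <- pos[i, ] - pos[j, ]
      for (mx in sh) for (my in sh) for (mz in sh) {
        if (i == j && mx == 0 && my == 0 && mz == 0) next
        r <- sqrt(sum((d0 + c(mx, my, mz) * L)^2))
        w <- if (i == j) 0.5 else 1
        E <- E + w * slater_pair_energy(r, q[i], q[j], settings)
      }
    }
  }
  E
}

# same-partition predicate (labels up to renaming)
same_partition <- function(a, b) {
  all(outer(a, a, "==") == outer(b, b, "=="))
}

# a rock-salt cube of 8 unit charges: neutral with zero cell dipole, so
# the direct lattice sum converges quickly
rocksalt_cube <- function(L = 6) {
  g <- expand.grid(x = c(L / 4, 3 * L / 4), y = c(L / 4, 3 * L / 4),
                   z = c(L / 4, 3 * L / 4))
  list(pos = as.matrix(g),
       q = ifelse(((g$x > L / 2) + (g$y > L / 2) + (g$z > L / 2)) %% 2 == 0,
                  1, -1))
}
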