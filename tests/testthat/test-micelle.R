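test_that("tail-contact clustering follows the single-linkage rule", {
  # two 1-bead-tail molecules: same aggregate iff tails within the cutoff
  mk <- function(d) {
    list(pos = matrix(c(1, 1, 1, 1 + d, 1, 1), 2, 3, byrow = TRUE),
         mid = c(1L, 2L), nm = c("T", "T"))
  }
  x <- mk(0.9)
  p <- cluster_frame(x$pos, 10, x$mid, x$nm, tail_beads = "T", cutoff = 1)
  expect_equal(unname(p[1]), unname(p[2]))
  y <- mk(1.1)
  p2 <- cluster_frame(y$pos, 10, y$mid, y$nm, tail_beads = "T", cutoff = 1)
  expect_false(p2[1] == p2[2])
  # minimum image: contact across the boundary
  z <- list(pos = matrix(c(0.2, 1, 1, 9.8, 1, 1), 2, 3, byrow = TRUE),
            mid = c(1L, 2L), nm = c("T", "T"))
  p3 <- cluster_frame(z$pos, 10, z$mid, z$nm, tail_beads = "T", cutoff = 1)
  expect_equal(unname(p3[1]), unname(p3[2]))
  expect_error(cluster_frame(x$pos, 10, c(NA_integer_, NA_integer_), x$nm),
               "no surfactant molecules")
})

test_that("clustering matches the O(M^2) union-find oracle", {
  set.seed(21)
  topo <- load_topology("AMPH4")
  for (rep in 1:3) {
    L <- 12
    nmol <- 50
    nb <- length(topo$beads)
    pos <- matrix(0, nmol * nb, 3)
    for (m in seq_len(nmol)) {
      base <- runif(3, 0, L)
      pos[(m - 1) * nb + seq_len(nb), ] <-
        (matrix(rep(base, each = nb), nb, 3) +
           0.3 * matrix(rnorm(3 * nb), nb, 3)) %% L
    }
    mid <- rep(seq_len(nmol), each = nb)
    nms <- rep(topo$beads, nmol)
    got <- cluster_frame(pos, L, mid, nms, tail_beads = "T", cutoff = 1)
    want <- brute_cluster(pos, L, mid, nms, tail_beads = "T", cutoff = 1)
    expect_true(same_partition(unname(got), want))
  }
})

test_that("clustering is invariant to molecule order and rigid translation", {
  fx <- generate_micelle_trajectory(L = 18, n_micelles = 3,
                                    size_range = c(8, 14), n_monomers = 8,
                                    seed = 31)
  tr <- fx$trajectory
  pos <- tr$frames[[1]]
  base <- cluster_frame(pos, tr$L[1], tr$molecule_id, tr$bead_names,
                        tail_beads = "T")
  # permute beads
  set.seed(1)
  perm <- sample(nrow(pos))
  permuted <- cluster_frame(pos[perm, ], tr$L[1], tr$molecule_id[perm],
                            tr$bead_names[perm], tail_beads = "T")
  expect_true(same_partition(unname(base), unname(permuted)))
  # rigid translation with periodic wrap
  shifted <- cluster_frame((pos + 7.3) %% tr$L[1], tr$L[1], tr$molecule_id,
                           tr$bead_names, tail_beads = "T")
  expect_true(same_partition(unname(base), unname(shifted)))
})

test_that("P(N) pools frames and respects the molecule budget", {
  fx <- generate_micelle_trajectory(L = 20, n_micelles = 1,
                                    size_range = c(20, 20), n_monomers = 5,
                                    n_frames = 12, seed = 2)
  d <- aggregation_distribution(fx$trajectory, tail_beads = "T",
                                discard_steps = 0)
  expect_s3_class(d, "aggregate_distribution")
  occupied <- d$N[d$count > 0]
  expect_setequal(occupied, c(1, 20))
  expect_true(all(d$P >= 0))
  expect_equal(sum(d$P), 1)
  # molecule-weighted: 20 molecules in the micelle vs 5 monomers
  expect_equal(d$P[20] / d$P[1], 20 / 5)
  # aggregate weighting counts aggregates instead
  da <- aggregation_distribution(fx$trajectory, tail_beads = "T",
                                 discard_steps = 0,
                                 weighting = "aggregate")
  expect_equal(da$P[20] / da$P[1], 1 / 5)
  expect_error(aggregation_distribution(fx$trajectory, tail_beads = "T",
                                        discard_steps = 1e6),
               "no frames")
  expect_warning(aggregation_distribution(fx$trajectory, tail_beads = "T",
                                          discard_steps = 11000),
                 "usable frames")
})

test_that("N_cut lands in the depleted region between the modes", {
  # constructed bimodal distribution: monomer mode, depleted middle with a
  # weakly occupied size, micellar modes
  counts <- c(100, 30, 5, 0, 0, 0, 0, 0, 0, 0.5,
              rep(0, 14), 40, 0, 0, 0, 0, 35)
  d <- structure(list(N = seq_along(counts), count = counts,
                      P = counts / sum(counts),
                      P_smooth = setsolv:::.moving_average(
                        counts / sum(counts), 3),
                      n_frames = 100, window = 3,
                      weighting = "molecule", flags = character()),
                 class = "aggregate_distribution")
  nc <- find_ncut(d)
  expect_gt(nc, 3)
  expect_lt(nc, 25)

  # strictly decreasing distribution falls back with a warning
  d2 <- d
  d2$count <- rev(sort(runif(20, 1, 100)))
  d2$P <- d2$count / sum(d2$count)
  d2$P_smooth <- setsolv:::.moving_average(d2$P, 3)
  expect_warning(nc2 <- find_ncut(d2), "falling back")
  expect_equal(nc2, 10L)

  # planted gap: N_cut recovered inside the gap across seeds
  for (seed in 1:20) {
    fx <- generate_micelle_trajectory(L = 25, n_micelles = 4,
                                      size_range = c(16, 30),
                                      n_monomers = 15, n_frames = 10,
                                      seed = seed)
    d3 <- aggregation_distribution(fx$trajectory, tail_beads = "T",
                                   discard_steps = 0)
    nc3 <- find_ncut(d3)
    expect_gte(nc3, 2)
    expect_lte(nc3, 15)
  }
})

test_that("CMC converts mean free counts through the volume mapping", {
  fx <- generate_micelle_trajectory(L = 30, n_micelles = 1,
                                    size_range = c(20, 20),
                                    n_monomers = 12, n_frames = 4, seed = 1)
  est <- cmc_from_trajectory(fx$trajectory, n_cut = 10, tail_beads = "T",
                             discard_steps = 0)
  expect_equal(est$mean_free, 12)
  expect_equal(est$cmc_molL, 12 / (27000 * dpd_mapping()$molar_volume_L))
  expect_equal(round(est$cmc_molL * 1000, 1), 4.1)  # ~4.1 mM

  # no free surfactant: zero CMC, flagged
  fx0 <- generate_micelle_trajectory(L = 20, n_micelles = 2,
                                     size_range = c(15, 15),
                                     n_monomers = 0, n_frames = 3, seed = 2)
  est0 <- cmc_from_trajectory(fx0$trajectory, n_cut = 10, tail_beads = "T",
                              discard_steps = 0)
  expect_equal(est0$cmc_molL, 0)
  expect_true("no_free_surfactant" %in% est0$flags)

  # N_cut above every observed aggregate: everything counted free, flagged
  estall <- cmc_from_trajectory(fx0$trajectory, n_cut = 40,
                                tail_beads = "T", discard_steps = 0)
  expect_true("ncut_exceeds_largest_aggregate" %in% estall$flags)
  expect_equal(estall$mean_free, 30)
})

test_that("multi-run CMC averaging returns per-run values and their mean", {
  planted <- c(10, 12, 14)
  trajs <- lapply(seq_along(planted), function(i) {
    generate_micelle_trajectory(L = 30, n_micelles = 1,
                                size_range = c(20, 20),
                                n_monomers = planted[i], n_frames = 3,
                                seed = i)$trajectory
  })
  res <- cmc_from_runs(trajs, n_cut = 10, tail_beads = "T",
                       discard_steps = 0)
  conv <- planted / (27000 * dpd_mapping()$molar_volume_L)
  expect_equal(res$per_run, conv)
  expect_equal(res$mean, mean(conv))
})
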