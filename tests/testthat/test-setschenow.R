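ip <- load_ion_params()
sp <- load_surfactant_params()

test_that("fit_ks inverts exact log-linear series and flags bad input", {
  s <- data.frame(csalt = c(0, 0.5, 1, 2), cmc = 0.01 * exp(-0.5 * c(0, 0.5, 1, 2)))
  f <- fit_ks(s)
  expect_equal(f$ks, 0.5, tolerance = 1e-12)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  # constant CMC: no salt effect
  expect_equal(fit_ks(data.frame(csalt = c(0, 1, 2), cmc = rep(0.02, 3)))$ks,
               0, tolerance = 1e-12)
  # sign convention: decreasing CMC means positive ks (salting out)
  expect_gt(fit_ks(data.frame(csalt = c(0, 1), cmc = c(0.02, 0.01)))$ks, 0)
  expect_error(fit_ks(data.frame(csalt = c(0, 1), cmc = c(0.02, -1))),
               "positive")
  expect_error(fit_ks(data.frame(csalt = c(0, 0), cmc = c(0.02, 0.02))),
               "two distinct")
  expect_error(fit_ks(data.frame(csalt = c(1, 2), cmc = c(0.02, 0.01))),
               "zero-salt")
})

test_that("fit_ks recovers a planted coefficient under lognormal noise", {
  set.seed(99)
  ks_hat <- replicate(200, {
    cs <- c(0, 0.4, 0.8, 1.2, 1.6, 2)
    cmc <- 0.01 * exp(-0.8 * cs) * rlnorm(6, 0, 0.05)
    fit_ks(data.frame(csalt = cs, cmc = cmc), cmc0 = 0.01)$ks
  })
  expect_lt(abs(mean(ks_hat) - 0.8), 0.02)
})

test_that("separable model reproduces the published coefficient table", {
  m <- separable_ks_model(sp, ip)
  expect_equal(round(predict_ks(m, "GLUCO8", "Na+", "Cl-"), 2), 0.58)
  expect_equal(round(predict_ks(m, "MEGA8", "Cs+", "Cl-"), 2), 0.39)
  expect_equal(round(predict_ks(m, "MEGA9", "Li+", "Cl-"), 2), 0.41)
  expect_equal(round(predict_ks(m, "C12E6", "K+", "Br-"), 2), 0.48)
  # A = 0 collapses the prediction to B
  m0 <- separable_ks_model(data.frame(surfactant = "X", A = 0, B = 0.7), ip)
  expect_equal(predict_ks(m0, "X", "Li+", "I-"), 0.7)
  expect_error(predict_ks(m, "NOPE", "Na+", "Cl-"), "NOPE")
  expect_error(predict_ks(m, "MEGA8", "Na+", "F-"), "F-")
})

test_that("prediction is monotone and additive in the ion amplitudes", {
  m <- separable_ks_model(sp, ip)
  # A < 0: weaker ion-tail repulsion gives smaller ks
  amp <- seq(40, 140, by = 10)
  for (s in sp$surfactant) {
    ks <- vapply(amp, function(a) {
      mi <- separable_ks_model(sp, data.frame(ion = c("X+", "Cl-"),
                                              amplitude = c(a, 94)))
      predict_ks(mi, s, "X+", "Cl-")
    }, numeric(1))
    expect_true(all(diff(ks) > 0))
  }
  # swapping the anion shifts predictions by A * (1/a1 - 1/a2) for every
  # surfactant: the ion contributions separate additively
  for (s in sp$surfactant) {
    d_br_cl <- predict_ks(m, s, "Na+", "Br-") - predict_ks(m, s, "Na+", "Cl-")
    A <- sp$A[sp$surfactant == s]
    expect_equal(d_br_cl, A * (1 / 66 - 1 / 94), tolerance = 1e-12)
    d2 <- predict_ks(m, s, "K+", "Br-") - predict_ks(m, s, "K+", "Cl-")
    expect_equal(d2, d_br_cl)
  }
})

test_that("surfactant constants are recovered from noiseless predictions", {
  rows <- expand.grid(cation = c("Li+", "Na+", "K+"),
                      anion = c("Cl-", "Br-", "I-"),
                      stringsAsFactors = FALSE)
  truth <- separable_ks_model(data.frame(surfactant = "X", A = -50, B = 2),
                              ip)
  rows$ks <- predict_ks(truth, rep("X", nrow(rows)), rows$cation, rows$anion)
  fit <- fit_surfactant_AB(rows, ip)
  expect_equal(fit$A, -50, tolerance = 1e-8)
  expect_equal(fit$B, 2, tolerance = 1e-8)
  expect_lt(fit$ssr, 1e-16)
  expect_error(fit_surfactant_AB(rows[1, ], ip), "two salts")
  same_x <- data.frame(cation = c("Na+", "Na+"), anion = c("Cl-", "Cl-"),
                       ks = c(0.5, 0.6))
  expect_error(fit_surfactant_AB(same_x, ip), "rank-deficient")
})

test_that("experimental data reproduce the published surfactant constants", {
  exp_ks <- load_experimental_ks(monovalent_only = TRUE)
  m8 <- exp_ks[exp_ks$surfactant == "MEGA8", ]
  fit <- fit_surfactant_AB(m8, ip)
  expect_lt(abs(fit$A - (-29.42)) / 29.42, 0.05)
  expect_lt(abs(fit$B - 1.24) / 1.24, 0.05)
  # predictions from the refit constants stay within the printed rounding
  m_fit <- separable_ks_model(data.frame(surfactant = "MEGA8", A = fit$A,
                                         B = fit$B), ip)
  m_pub <- separable_ks_model(sp, ip)
  for (r in seq_len(nrow(m8))) {
    expect_lt(abs(predict_ks(m_fit, "MEGA8", m8$cation[r], m8$anion[r]) -
                    predict_ks(m_pub, "MEGA8", m8$cation[r], m8$anion[r])),
              0.02 + 1e-9)
  }
})

test_that("ion amplitudes are recovered exactly from noiseless data", {
  exp_ks <- load_experimental_ks(monovalent_only = TRUE)
  truth <- separable_ks_model(sp, ip)
  exp_ks$ks <- predict_ks(truth, exp_ks$surfactant, exp_ks$cation,
                          exp_ks$anion)
  fit <- fit_ion_amplitudes(exp_ks, sp)
  expect_lt(max(abs(fit$amplitudes[ip$ion] - ip$amplitude)), 0.5)
  expect_lt(fit$ssr, 1e-12)
})

test_that("per-ion bounds pin amplitudes at active constraints", {
  exp_ks <- load_experimental_ks(monovalent_only = TRUE)
  ions <- unique(c(exp_ks$cation, exp_ks$anion))
  b <- matrix(rep(c(35, 150), length(ions)), 2,
              dimnames = list(NULL, ions))
  b[, "Na+"] <- c(60, 60)
  fit <- fit_ion_amplitudes(exp_ks, sp, bounds = b)
  expect_equal(unname(fit$amplitudes["Na+"]), 60)
})

test_that("fitting the experimental table reproduces the published ions", {
  exp_ks <- load_experimental_ks(monovalent_only = TRUE)
  fit <- fit_ion_amplitudes(exp_ks, sp)   # chloride-anchored gauge
  a <- fit$amplitudes
  expect_lt(abs(a[["Na+"]] - 72), 5)
  # Hofmeister-like cation ordering of the tail repulsions
  expect_true(a[["Na+"]] > a[["K+"]])
  expect_true(a[["K+"]] > a[["Cs+"]])
  expect_true(a[["Cs+"]] > a[["Li+"]])
  expect_identical(fit$anchored, "Cl-")
  # the free fit carries the gauge warning instead
  expect_warning(fit_ion_amplitudes(exp_ks, sp, anchor = NULL),
                 "gauge")
})

test_that("exclusive ion couples are reported as weakly identified", {
  tab <- data.frame(surfactant = c("MEGA8", "MEGA8", "MEGA8", "MEGA9"),
                    cation = c("Na+", "Na+", "Rb+", "Rb+"),
                    anion = c("Cl-", "Br-", "ClO4-", "ClO4-"),
                    ks = c(0.5, 0.45, 0.4, 0.45))
  fit <- fit_ion_amplitudes(tab, sp)
  expect_setequal(fit$weakly_identified, c("Rb+", "ClO4-"))
})

test_that("R^2 follows the standard definition", {
  expect_equal(r_squared(c(0.3, 0.5, 0.7), c(0.3, 0.5, 0.7)), 1)
  # hand-computable small case: SS_res = 1, SS_tot about mean 0.5 = 0.5
  expect_equal(r_squared(c(0, 1), c(1, 0)), -3)
  expect_error(r_squared(c(0.5, 0.5), c(0.4, 0.6)), "zero variance")
  expect_error(r_squared(0.5, 0.5), "two pairs")
})

test_that("round-trip: fitting model output returns the model parameters", {
  # full-pipeline consistency on noiseless synthetic data
  gen <- generate_ks_dataset(sp, ip, sigma = 0, seed = 4)
  tab <- gen$ks_table
  for (s in sp$surfactant) {
    fit <- fit_surfactant_AB(tab[tab$surfactant == s, ], ip)
    expect_equal(fit$A, sp$A[sp$surfactant == s], tolerance = 1e-6)
    expect_equal(fit$B, sp$B[sp$surfactant == s], tolerance = 1e-6)
  }
  fit_i <- fit_ion_amplitudes(tab, sp)
  expect_lt(max(abs(fit_i$amplitudes[ip$ion] - ip$amplitude)), 1e-3)
})
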