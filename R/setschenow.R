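# Setschenow-coefficient fitting and the separable ion/surfactant model.
# The salting-out relation ln(CMC/CMC0) = -k_s C_salt defines k_s; the
# separable model k_s = A (1/a+ + 1/a-) + B links it to the cation-tail
# and anion-tail repulsion amplitudes, with surfactant-specific constants
# A (M^-1 kBT) and B (M^-1). Weaker ion-tail repulsion means smaller k_s
# (A < 0 for all fitted surfactants), and a salt is the sum of the
# independent effects of its two ions.

#' Fit a Setschenow coefficient from a CMC-salt series
#'
#' Ordinary least squares of ln(CMC/CMC0) against salt concentration, with
#' a free (reported) intercept; k_s is minus the slope, so positive k_s
#' means the CMC decreases with added salt (salting out).
#'
#' @param series data.frame with columns `csalt` (mol/L) and `cmc`
#'   (mol/L); the zero-salt row supplies CMC0 unless `cmc0` is given.
#' @param cmc0 optional explicit zero-salt CMC.
#' @return an object of class `setschenow_fit`: `ks` (M^-1), `intercept`,
#'   `se` (standard error of the slope), `n`.
#' @export
fit_ks <- function(series, cmc0 = NULL) {
  stopifnot(all(c("csalt", "cmc") %in% names(series)))
  if (any(series$cmc <= 0)) stop("all CMC values must be positive")
  if (any(series$csalt < 0)) stop("salt concentrations must be >= 0")
  if (is.null(cmc0)) {
    z <- which(series$csalt == 0)
    if (!length(z)) {
      stop("series has no zero-salt point; supply cmc0 explicitly")
    }
    cmc0 <- mean(series$cmc[z])
  }
  if (length(unique(series$csalt)) < 2L) {
    stop("at least two distinct salt concentrations are required")
  }
  y <- log(series$cmc / cmc0)
  fit <- lm(y ~ csalt, data = series)
  sm <- suppressWarnings(summary(fit))   # exact series trip a perfect-fit note
  structure(list(ks = -unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 se = sm$coefficients[2, 2],
                 n = nrow(series), cmc0 = cmc0),
            class = "setschenow_fit")
}

#' @export
print.setschenow_fit <- function(x, ...) {
  cat(sprintf("Setschenow fit: k_s = %.4f M^-1 (se %.4f, n = %d, CMC0 = %.4g M)\n",
              x$ks, x$se, x$n, x$cmc0))
  invisible(x)
}

#' Separable Setschenow model
#'
#' Bundles per-surfactant constants (A, B) with per-ion tail repulsion
#' amplitudes into a model object for [predict_ks()]. With no arguments,
#' loads the packaged published parameter sets.
#'
#' @param surfactant_params data.frame with columns `surfactant`, `A`, `B`.
#' @param ion_params data.frame with columns `ion`, `amplitude` (kBT);
#'   a `charge` column is optional metadata.
#' @return an object of class `eq_separable_model`.
#' @export
separable_ks_model <- function(surfactant_params = load_surfactant_params(),
                               ion_params = load_ion_params()) {
  stopifnot(all(c("surfactant", "A", "B") %in% names(surfactant_params)),
            all(c("ion", "amplitude") %in% names(ion_params)))
  if (any(ion_params$amplitude <= 0)) stop("ion amplitudes must be > 0")
  structure(list(surfactants = surfactant_params, ions = ion_params),
            class = "eq_separable_model")
}

#' @export
print.eq_separable_model <- function(x, ...) {
  cat("Separable k_s model:", nrow(x$surfactants), "surfactants,",
      nrow(x$ions), "ions\n")
  invisible(x)
}

#' Predict a Setschenow coefficient from the separable model
#'
#' k_s = A (1/a+ + 1/a-) + B. Vectorized over equal-length surfactant /
#' cation / anion vectors; missing parameters raise an error naming the
#' absent entry.
#'
#' @param model an [separable_ks_model()].
#' @param surfactant,cation,anion names to look up.
#' @return predicted k_s in M^-1.
#' @export
predict_ks <- function(model, surfactant, cation, anion) {
  stopifnot(inherits(model, "eq_separable_model"))
  si <- match(surfactant, model$surfactants$surfactant)
  if (anyNA(si)) stop("no A/B constants for surfactant '",
                      surfactant[which(is.na(si))[1]], "'")
  ci <- match(cation, model$ions$ion)
  if (anyNA(ci)) stop("no amplitude for ion '",
                      cation[which(is.na(ci))[1]], "'")
  ai <- match(anion, model$ions$ion)
  if (anyNA(ai)) stop("no amplitude for ion '",
                      anion[which(is.na(ai))[1]], "'")
  A <- model$surfactants$A[si]
  B <- model$surfactants$B[si]
  ap <- model$ions$amplitude[ci]
  am <- model$ions$amplitude[ai]
  A * (1 / ap + 1 / am) + B
}

#' Fit surfactant constants A and B with ion amplitudes fixed
#'
#' Least squares of experimental k_s against x = 1/a+ + 1/a- over the
#' salts measured for one surfactant: k_s = A x + B is linear in (A, B),
#' so this is an ordinary regression. Errors out when fewer than two salts
#' are available or when all salts share the same x (rank-deficient
#' design).
#'
#' @param ks_table data.frame with columns `cation`, `anion`, `ks` for one
#'   surfactant.
#' @param ion_params data.frame with columns `ion`, `amplitude`.
#' @return list with `A`, `B`, `ssr` (sum of squared residuals), `n`.
#' @export
fit_surfactant_AB <- function(ks_table, ion_params) {
  stopifnot(all(c("cation", "anion", "ks") %in% names(ks_table)))
  if (nrow(ks_table) < 2L) {
    stop("at least two salts are required to fit A and B")
  }
  amp <- setNames(ion_params$amplitude, ion_params$ion)
  miss <- setdiff(unique(c(ks_table$cation, ks_table$anion)), names(amp))
  if (length(miss)) stop("no amplitude for ion(s): ",
                         paste(miss, collapse = ", "))
  x <- 1 / amp[ks_table$cation] + 1 / amp[ks_table$anion]
  if (diff(range(x)) < 1e-12) {
    stop("rank-deficient design: all salts share the same 1/a+ + 1/a-")
  }
  fit <- lm(ks_table$ks ~ x)
  list(A = unname(coef(fit)[2]), B = unname(coef(fit)[1]),
       ssr = sum(fit$residuals^2), n = nrow(ks_table))
}

#' Fit ion-tail amplitudes with surfactant constants fixed
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}) over all (surfactant, salt) rows jointly, minimizing
#' the squared misfit of k_s = A_s (1/a+ + 1/a-) + B_s. Amplitudes are
#' bounded to the screened range 35-150 kBT by default; per-ion bounds
#' may be supplied.
#'
#' Because only the sum 1/a+ + 1/a- enters the model, the joint fit has
#' an exact one-parameter gauge freedom: shifting every cation reciprocal
#' amplitude by +delta and every anion reciprocal by -delta leaves all
#' predictions unchanged. The gauge is pinned by `anchor`, a named vector
#' of amplitudes held fixed during the fit; the default anchors chloride
#' (the counter-ion common to most salts) at its published tail
#' repulsion. Pass `anchor = NULL` to fit all ions free, in which case
#' the reported amplitudes are one representative of the gauge family
#' (the solver returns the stationary point nearest its start) and a
#' warning is attached. Ion pairs that only ever occur together -- so
#' even their reciprocal sum is shared -- are additionally reported as
#' weakly identified rather than silently fitted.
#'
#' @param ks_table data.frame with columns `surfactant`, `cation`,
#'   `anion`, `ks`.
#' @param surfactant_params data.frame with `surfactant`, `A`, `B`.
#' @param bounds length-2 numeric (shared) or a 2-row matrix with one
#'   column per ion (dimnames give the ion names).
#' @param start optional named start values; defaults to the bound
#'   midpoint.
#' @param anchor named numeric of amplitudes to hold fixed (gauge pin);
#'   `NULL` fits all ions free. Anchored ions absent from `ks_table` are
#'   ignored.
#' @return list with `amplitudes` (named vector, kBT, including anchored
#'   ions), `residuals` table, `ssr`, `weakly_identified`, `anchored`.
#' @export
fit_ion_amplitudes <- function(ks_table, surfactant_params,
                               bounds = c(35, 150), start = NULL,
                               anchor = c("Cl-" = 94)) {
  stopifnot(all(c("surfactant", "cation", "anion", "ks") %in%
                  names(ks_table)))
  ions <- unique(c(ks_table$cation, ks_table$anion))
  si <- match(ks_table$surfactant, surfactant_params$surfactant)
  if (anyNA(si)) stop("no A/B constants for surfactant '",
                      ks_table$surfactant[which(is.na(si))[1]], "'")
  A <- surfactant_params$A[si]
  B <- surfactant_params$B[si]

  anchor <- anchor[names(anchor) %in% ions]
  free <- setdiff(ions, names(anchor))
  if (!length(free)) stop("no free ions left to fit")

  if (is.matrix(bounds)) {
    lower <- bounds[1, free]; upper <- bounds[2, free]
    if (anyNA(lower) || anyNA(upper)) stop("bounds matrix must cover all ions")
  } else {
    lower <- rep(bounds[1], length(free))
    upper <- rep(bounds[2], length(free))
  }
  names(lower) <- names(upper) <- free
  # degenerate bounds pin an ion outright; treat it like an anchor so the
  # optimizer never sees a zero-width box
  pinned <- free[lower == upper]
  if (length(pinned)) {
    anchor <- c(anchor, setNames(lower[pinned], pinned))
    free <- setdiff(free, pinned)
    lower <- lower[free]; upper <- upper[free]
    if (!length(free)) stop("no free ions left to fit")
  }
  if (is.null(start)) start <- (lower + upper) / 2
  else start <- start[free]
  start <- pmin(pmax(start, lower), upper)

  # weak identification: an exclusive cation/anion couple constrains only
  # the sum of its reciprocal amplitudes
  weakly <- character()
  for (cat_ in unique(ks_table$cation)) {
    partners <- unique(ks_table$anion[ks_table$cation == cat_])
    if (length(partners) == 1L) {
      co <- unique(ks_table$cation[ks_table$anion == partners])
      if (identical(co, cat_)) weakly <- c(weakly, cat_, partners)
    }
  }
  weakly <- unique(weakly)

  all_amp <- setNames(numeric(length(ions)), ions)
  all_amp[names(anchor)] <- anchor
  ic <- match(ks_table$cation, ions)
  ia <- match(ks_table$anion, ions)
  fidx <- match(free, ions)
  resid_fn <- function(par) {
    all_amp[fidx] <- par
    A * (1 / all_amp[ic] + 1 / all_amp[ia]) + B - ks_table$ks
  }
  fit <- minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  all_amp[fidx] <- fit$par
  res <- resid_fn(fit$par)
  if (!length(anchor) && length(unique(ks_table$cation)) > 0 &&
      length(unique(ks_table$anion)) > 0) {
    warning("no gauge anchor: amplitudes are identified only up to a ",
            "shared shift of reciprocal cation vs anion amplitudes")
  }
  list(amplitudes = all_amp,
       residuals = data.frame(ks_table[, c("surfactant", "cation", "anion")],
                              ks = ks_table$ks,
                              ks_fit = ks_table$ks + res,
                              residual = res),
       ssr = sum(res^2),
       weakly_identified = weakly,
       anchored = names(anchor))
}

#' Coefficient of determination between experimental and calculated k_s
#'
#' R^2 = 1 - SS_res/SS_tot with SS_tot taken about the mean of the
#' experimental values.
#'
#' @param ks_exp,ks_calc equal-length numeric vectors.
#' @return R^2.
#' @export
r_squared <- function(ks_exp, ks_calc) {
  stopifnot(length(ks_exp) == length(ks_calc))
  if (length(ks_exp) < 2L) stop("at least two pairs are required")
  sst <- sum((ks_exp - mean(ks_exp))^2)
  if (sst == 0) stop("experimental values have zero variance")
  1 - sum((ks_exp - ks_calc)^2) / sst
}

# --------------------------------------------------------------------------
# Packaged parameter tables

#' Load the packaged experimental Setschenow coefficients
#'
#' Experimental k_s (per mole of salt) for MEGA8, MEGA9, GLUCO8 and C12E6
#' in a long format with one row per (surfactant, salt). `source_flag`
#' marks rows as `monovalent` (used for fitting), `divalent` (retained for
#' completeness, out of the monovalent scope) or `excluded` (fluoride,
#' whose tail amplitude cannot be resolved by this route).
#'
#' @param path CSV path; default is the packaged table.
#' @param monovalent_only drop divalent and excluded rows.
#' @return data.frame with columns `surfactant`, `cation`, `anion`, `ks`,
#'   `source_flag`.
#' @export
load_experimental_ks <- function(path = NULL, monovalent_only = FALSE) {
  if (is.null(path)) {
    path <- system.file("extdata", "experimental_ks.csv", package = "setsolv")
  }
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (monovalent_only) d <- d[d$source_flag == "monovalent", ]
  d
}

#' Load the packaged surfactant constants (A, B)
#' @param path CSV path; default is the packaged table.
#' @return data.frame with columns `surfactant`, `A`, `B`.
#' @export
load_surfactant_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "surfactant_constants.csv",
                        package = "setsolv")
  }
  read.csv(path, stringsAsFactors = FALSE)
}

#' Load the packaged ion-tail repulsion amplitudes
#' @param path CSV path; default is the packaged table.
#' @return data.frame with columns `ion`, `charge`, `amplitude`.
#' @export
load_ion_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ion_tail_amplitudes.csv",
                        package = "setsolv")
  }
  read.csv(path, stringsAsFactors = FALSE)
}
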