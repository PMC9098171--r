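# Reporting and pipeline orchestration: the experimental-vs-calculated
# k_s comparison table and a small stage runner with a reproducibility
# manifest.

#' Experimental vs calculated Setschenow coefficients
#'
#' Joins the experimental k_s table with predictions from the separable
#' model, rounding calculated values to 2 decimal places (the precision
#' the parameter tables carry) and reporting error = exp - calc. Rows
#' whose parameters are missing are flagged, never silently dropped. The
#' coefficient of determination over the unflagged rows is attached as
#' attribute `r_squared`.
#'
#' @param surfactant_params data.frame `surfactant`, `A`, `B`.
#' @param ion_params data.frame `ion`, `amplitude`.
#' @param experimental_ks data.frame `surfactant`, `cation`, `anion`,
#'   `ks` (+ optional `source_flag`).
#' @param monovalent_only keep only rows flagged `monovalent` (default).
#' @param digits rounding for the calculated column.
#' @return data.frame with columns `surfactant`, `cation`, `anion`,
#'   `ks_exp`, `ks_calc`, `error`, `note`; attribute `r_squared`.
#' @export
ks_comparison_table <- function(surfactant_params = load_surfactant_params(),
                                ion_params = load_ion_params(),
                                experimental_ks = load_experimental_ks(),
                                monovalent_only = TRUE, digits = 2) {
  d <- experimental_ks
  if (monovalent_only && "source_flag" %in% names(d)) {
    d <- d[d$source_flag == "monovalent", , drop = FALSE]
  }
  if (!nrow(d)) {
    out <- data.frame(surfactant = character(), cation = character(),
                      anion = character(), ks_exp = numeric(),
                      ks_calc = numeric(), error = numeric(),
                      note = character())
    attr(out, "r_squared") <- NA_real_
    return(out)
  }
  model <- separable_ks_model(surfactant_params, ion_params)
  calc <- rep(NA_real_, nrow(d))
  note <- rep("", nrow(d))
  for (r in seq_len(nrow(d))) {
    calc[r] <- tryCatch(
      predict_ks(model, d$surfactant[r], d$cation[r], d$anion[r]),
      error = function(e) {
        note[r] <<- conditionMessage(e)
        NA_real_
      })
  }
  out <- data.frame(surfactant = d$surfactant, cation = d$cation,
                    anion = d$anion, ks_exp = d$ks,
                    ks_calc = round(calc, digits),
                    error = round(d$ks - round(calc, digits), digits),
                    note = note, stringsAsFactors = FALSE)
  ok <- !is.na(out$ks_calc)
  attr(out, "r_squared") <- if (sum(ok) >= 2)
    r_squared(out$ks_exp[ok], out$ks_calc[ok]) else NA_real_
  rownames(out) <- NULL
  out
}

#' Run a configured pipeline of stages
#'
#' Executes the requested stages in order -- `fit` (refit surfactant A/B
#' and ion amplitudes from an experimental table), `report` (the
#' comparison table), `simulate` + `analyze` (a DPD run followed by P(N),
#' N_cut and CMC extraction) -- fanning one master seed out per stage, and
#' writes a manifest (config snapshot, seeds, package version, output
#' digests, timing) alongside the outputs. Re-running with the same config
#' and seed reproduces identical analysis outputs.
#'
#' @param config nested list; see the packaged CLI for the file format.
#'   Recognized top-level keys: `stages` (character vector), `fit`,
#'   `simulate`, `analyze` sections.
#' @param out_dir output directory.
#' @param seed master seed.
#' @return list of stage results, invisibly; artifacts land in `out_dir`.
#' @export
pipeline_run <- function(config, out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  stages <- config$stages %||% "report"
  results <- list()
  manifest <- list(config = config, master_seed = seed,
                   package_version = as.character(utils::packageVersion("setsolv")),
                   stages = stages, outputs = list(), status = "running")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              force = TRUE),
             file.path(out_dir, "manifest.json"))
  stage_seed <- function(k) (seed * 97L + k * 131L) %% .Machine$integer.max

  for (k in seq_along(stages)) {
    st <- stages[k]
    res <- tryCatch({
      switch(st,
        fit = {
          exp_ks <- if (!is.null(config$fit$experimental_ks)) {
            read.csv(config$fit$experimental_ks, stringsAsFactors = FALSE)
          } else load_experimental_ks()
          mono <- exp_ks[exp_ks$source_flag %in% "monovalent", ]
          sp <- load_surfactant_params()
          ions <- fit_ion_amplitudes(mono, sp)
          out <- data.frame(ion = names(ions$amplitudes),
                            amplitude = unname(ions$amplitudes))
          write.csv(out, file.path(out_dir, "fitted_ion_amplitudes.csv"),
                    row.names = FALSE)
          list(ions = ions)
        },
        report = {
          tab <- ks_comparison_table()
          write.csv(tab, file.path(out_dir, "ks_comparison.csv"),
                    row.names = FALSE)
          writeLines(sprintf("R_squared %.4f", attr(tab, "r_squared")),
                     file.path(out_dir, "ks_comparison_r2.txt"))
          tab
        },
        simulate = {
          sc <- config$simulate
          ff <- load_default_forcefield()
          topo <- load_topology(sc$topology %||% "AMPH4")
          sys <- build_system(ff, L = sc$L %||% 8,
                              molecules = list(list(topology = topo,
                                                    count = sc$n_molecules %||% 40)),
                              seed = stage_seed(k))
          setts <- simulation_settings(n_steps = sc$n_steps %||% 20000,
                                       sample_every = sc$sample_every %||% 500,
                                       seed = stage_seed(k))
          traj <- run_simulation(sys, setts)
          write_trajectory_xyz(traj, file.path(out_dir, "trajectory.xyz"),
                               file.path(out_dir, "molecule_map.csv"))
          traj
        },
        analyze = {
          traj <- results[["simulate"]]
          if (is.null(traj)) {
            traj <- read_trajectory_xyz(file.path(out_dir, "trajectory.xyz"),
                                        file.path(out_dir, "molecule_map.csv"))
          }
          dist <- aggregation_distribution(traj)
          ncut <- find_ncut(dist)
          est <- cmc_from_trajectory(traj, ncut)
          write.csv(data.frame(N = dist$N, count = dist$count, P = dist$P),
                    file.path(out_dir, "aggregation_distribution.csv"),
                    row.names = FALSE)
          summ <- list(n_cut = ncut, cmc_molL = est$cmc_molL,
                       mean_free = est$mean_free, flags = est$flags)
          writeLines(jsonlite::toJSON(summ, auto_unbox = TRUE, pretty = TRUE),
                     file.path(out_dir, "cmc_summary.json"))
          summ
        },
        stop("unknown stage '", st, "'"))
    }, error = function(e) {
      manifest$status <<- paste0("failed at stage '", st, "': ",
                                 conditionMessage(e))
      NULL
    })
    if (!is.null(res)) results[[st]] <- res
    if (!identical(manifest$status, "running")) break
  }
  if (identical(manifest$status, "running")) manifest$status <- "ok"
  outs <- setdiff(list.files(out_dir, full.names = TRUE),
                  file.path(out_dir, "manifest.json"))
  manifest$outputs <- as.list(tools::md5sum(outs))
  manifest$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              force = TRUE),
             file.path(out_dir, "manifest.json"))
  if (!identical(manifest$status, "ok")) {
    warning("pipeline ", manifest$status, "; partial outputs retained in ",
            out_dir)
  }
  invisible(results)
}
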