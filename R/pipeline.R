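#' Configuration for an end-to-end synthetic pipeline run
#'
#' Collects every stage's settings behind one object with a single
#' master seed. Stage seeds are derived by fixed documented offsets:
#' tau cohort `seed + 1`, volume cohort `seed + 2`, phantom `seed + 3`,
#' tau fit `seed + 10`, volume fit `seed + 20` (each chain adds
#' `1000 * chain`), associations `seed + 30`.
#'
#' @param out_dir Run directory (created by [run_pipeline()]).
#' @param seed Master seed.
#' @param profile MCMC profile, `"desk"` or `"paper"`.
#' @param n_roi Number of ROIs (84 reproduces the study layout).
#' @param sim_tau,sim_volume [simulation_params()] for the two
#'   modalities (defaults built from `seed` and `n_roi`).
#' @param n_permutations Permutations for the maxT correction.
#' @param scca_penalty Lasso penalty for both SCCA datasets.
#' @param n_components SCCA components retained.
#' @param stages Character vector of stages to run, in order, among
#'   `"simulate"`, `"quantify"`, `"fit"`, `"lobes"`, `"associate"`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            profile = c("desk", "paper"),
                            n_roi = 84L,
                            sim_tau = NULL, sim_volume = NULL,
                            n_permutations = 1000L,
                            scca_penalty = 0.2, n_components = 2L,
                            stages = c("simulate", "quantify", "fit",
                                       "lobes", "associate")) {
  profile <- match.arg(profile)
  lobe_map <- if (n_roi == 84L) default_lobe_map()
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed), profile = profile,
    n_roi = as.integer(n_roi),
    sim_tau = sim_tau %||% simulation_params(
      "tau", n_roi = n_roi, lobe_map = lobe_map, seed = seed + 1L),
    sim_volume = sim_volume %||% simulation_params(
      "volume", n_roi = n_roi, lobe_map = lobe_map, seed = seed + 2L),
    n_permutations = as.integer(n_permutations),
    scca_penalty = scca_penalty,
    n_components = as.integer(n_components),
    stages = match.arg(stages, several.ok = TRUE)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields of [pipeline_config()] can be set from a plain YAML
#' mapping; unknown keys are rejected.
#'
#' @param path YAML file.
#' @param out_dir Run directory (overrides any `out_dir` in the file).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  raw <- yaml::read_yaml(path)
  known <- c("out_dir", "seed", "profile", "n_roi", "n_permutations",
             "scca_penalty", "n_components", "stages")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  raw$out_dir <- out_dir %||% raw$out_dir
  if (is.null(raw$out_dir)) stop("out_dir is required", call. = FALSE)
  do.call(pipeline_config, raw)
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes simulate -> quantify -> fit -> lobe-compare -> associate on a
#' synthetic cohort, writing `cohort/`, `posterior/`, `lobes/`,
#' `associations/`, `log.txt` and `provenance.json` under the run
#' directory. Reruns with the same configuration are draw-identical:
#' every stage draws its randomness from a seed derived from the master
#' seed by the offsets documented in [pipeline_config()].
#'
#' @param config A `pipeline_config`.
#' @return The run directory, invisibly; stage outputs on disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("cohort", "posterior", "lobes", "associations"))
    dir.create(file.path(config$out_dir, d), showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "log.txt")
  cat("", file = log_path)
  logi <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   sprintf(...))
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  fail <- function(stage, e) {
    jsonlite::write_json(
      list(stage = stage, error = conditionMessage(e)),
      file.path(config$out_dir, "error.json"), auto_unbox = TRUE)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  run_stage <- function(stage, fun) {
    if (!stage %in% config$stages) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) fail(stage, e))
    logi("stage %s done in %.1fs", stage,
         proc.time()[["elapsed"]] - t0)
    res
  }

  state <- new.env(parent = emptyenv())

  run_stage("simulate", function() {
    state$tau <- generate_cohort(config$sim_tau)
    state$vol <- generate_cohort(config$sim_volume,
                                 subjects = state$tau$subjects)
    write_cohort_csv(state$tau,
                     file.path(config$out_dir, "cohort", "tau.csv"))
    write_cohort_csv(state$vol,
                     file.path(config$out_dir, "cohort", "volume.csv"))
    logi("simulated %d subjects x %d ROIs (tau + volume)",
         nrow(state$tau$subjects), config$n_roi)
  })

  run_stage("quantify", function() {
    ph <- generate_phantom(config$n_roi, reference_median = 2,
                           seed = config$seed + 3L)
    write_phantom_nifti(ph$baseline,
                        file.path(config$out_dir, "cohort"),
                        "phantom_baseline")
    med <- phantom_roi_medians(ph$baseline,
                               reference_id = ph$reference_id)
    suvr <- compute_suvr(med$roi_medians, med$reference_median,
                         subject_id = "phantom")
    utils::write.csv(suvr,
                     file.path(config$out_dir, "cohort",
                               "phantom_suvr.csv"),
                     row.names = FALSE)
    state$changes_tau <- compute_annualized_changes(state$tau)
    state$changes_vol <- compute_annualized_changes(state$vol)
    for (m in c("tau", "vol")) {
      utils::write.csv(
        state[[paste0("changes_", m)]],
        file.path(config$out_dir, "cohort",
                  paste0("annualized_changes_", m, ".csv")),
        row.names = FALSE)
    }
    logi("quantified phantom (%d ROIs) and annualized changes",
         config$n_roi)
  })

  run_stage("fit", function() {
    for (m in c("tau", "vol")) {
      coh <- state[[if (m == "tau") "tau" else "vol"]]
      spec <- hier_spec(config$profile,
                        seed = config$seed +
                          if (m == "tau") 10L else 20L)
      design <- build_model_input(coh, state[[paste0("changes_", m)]])
      draws <- fit_mcmc(spec, design)
      state[[paste0("fit_", m)]] <- draws
      pooled <- pooled_atypical_effect(
        draws, sum(coh$subjects$group == "LPA"),
        sum(coh$subjects$group == "PCA"))
      contr <- relative_to_controls(pooled, draws)
      decade <- relative_to_controls(
        pooled_atypical_effect(draws,
                               sum(coh$subjects$group == "LPA"),
                               sum(coh$subjects$group == "PCA"),
                               parameter = "beta"),
        draws, parameter = "beta")
      state[[paste0("contrast_", m)]] <- contr
      summ <- summarize_regions(contr, roi_ids = coh$roi_ids)
      dsum <- summarize_regions(decade, roi_ids = coh$roi_ids)
      names(dsum)[-1] <- paste0("decade_", names(dsum)[-1])
      utils::write.csv(cbind(summ, dsum[-1]),
                       file.path(config$out_dir, "posterior",
                                 paste0("summary_", m, ".csv")),
                       row.names = FALSE)
      rhat <- gelman_rubin(draws)
      utils::write.csv(data.frame(parameter = names(rhat), rhat = rhat),
                       file.path(config$out_dir, "posterior",
                                 paste0("rhat_", m, ".csv")),
                       row.names = FALSE)
      logi("fitted %s model: %d retained draws, max hyper R-hat %.3f",
           m, retained_draws(spec), max(rhat))
    }
  })

  run_stage("lobes", function() {
    map <- config$sim_tau$lobe_map %||% default_lobe_map()
    for (m in c("tau", "vol")) {
      lob <- lobe_average(state[[paste0("contrast_", m)]], map)
      cmp <- comparison_matrix(lob)
      write_comparison_csv(cmp, file.path(config$out_dir, "lobes",
                                          paste0("comparison_", m,
                                                 ".csv")))
      write_comparison_csv(cmp, file.path(config$out_dir, "lobes",
                                          paste0("comparison_", m,
                                                 "_display.csv")),
                           formatted = TRUE)
    }
    logi("lobe comparison matrices written")
  })

  run_stage("associate", function() {
    pat <- state$tau$subjects$group %in% c("LPA", "PCA")
    age <- cbind(age = state$tau$subjects$age_baseline[pat])
    tau_base <- state$tau$baseline[pat, , drop = FALSE]
    vol_base <- state$vol$baseline[pat, , drop = FALSE]
    tau_chg <- attr(state$changes_tau, "change_matrix")[pat, ,
                                                        drop = FALSE]
    vol_chg <- attr(state$changes_vol, "change_matrix")[pat, ,
                                                        drop = FALSE]
    pairs <- list(
      tau_base_vs_tau_change = list(tau_base, tau_chg),
      vol_base_vs_jacobian = list(vol_base, vol_chg),
      tau_base_vs_jacobian = list(tau_base, vol_chg),
      tau_change_vs_jacobian = list(tau_chg, vol_chg))
    for (nm in names(pairs)) {
      Xm <- pairs[[nm]][[1]]; Ym <- pairs[[nm]][[2]]
      res <- permutation_fwe(Xm, Ym, covariates = age,
                             n_permutations = config$n_permutations,
                             seed = config$seed + 30L)
      utils::write.csv(res$r,
                       file.path(config$out_dir, "associations",
                                 paste0(nm, "_r.csv")))
      utils::write.csv(res$p_adjusted,
                       file.path(config$out_dir, "associations",
                                 paste0(nm, "_p_adjusted.csv")))
      sc <- scca(Xm, Ym, penalty_x = config$scca_penalty,
                 penalty_y = config$scca_penalty,
                 n_components = config$n_components,
                 seed = config$seed + 30L)
      utils::write.csv(canonical_weight_table(sc),
                       file.path(config$out_dir, "associations",
                                 paste0(nm, "_scca_weights.csv")),
                       row.names = FALSE)
      logi("association %s: max |r| %.3f, min adj p %.4f, scca r1 %.3f",
           nm, max(abs(res$r)), min(res$p_adjusted),
           sc[[1]]$correlation)
    }
  })

  cfg_json <- jsonlite::toJSON(
    config[setdiff(names(config), c("sim_tau", "sim_volume"))],
    auto_unbox = TRUE)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  provenance <- list(
    package = "taulong",
    version = as.character(utils::packageVersion("taulong")),
    seed = config$seed,
    profile = config$profile,
    stages = config$stages,
    config_hash = unname(tools::md5sum(tmp)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  unlink(tmp)
  jsonlite::write_json(provenance,
                       file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logi("pipeline complete: %s", config$out_dir)
  invisible(config$out_dir)
}
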