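# End-to-end pipeline: simulate (or load) -> marker QC -> kernels ->
# spatial BLUEs -> model fits -> cross-validation -> report. Driven by a
# YAML configuration with a versioned schema; one global seed fans out to
# fixed per-stage offsets so each stage is independently reproducible.

STAGE_SEED_OFFSETS <- c(simulate = 0L, qc = 101L, kernels = 202L,
                        blues = 303L, fit = 404L, cv = 505L)

#' Load and validate a run configuration
#'
#' YAML schema (version 1): \code{schema_version}, \code{seed},
#' \code{trait}, \code{output_dir}, plus optional blocks \code{simulate}
#' (arguments of \code{\link{sim_config}}), \code{inputs} (paths:
#' genotypes, phenotypes, ecs), \code{qc} (thresholds), \code{mcmc}
#' (arguments of \code{\link{mcmc_config}}), \code{models} (character
#' vector), \code{cv} (schemes, n_reps, frac_test). Unknown keys are
#' errors.
#'
#' @param path YAML file, or a list already parsed.
#' @return validated config list of class \code{run_config}.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  known <- c("schema_version", "seed", "trait", "output_dir", "simulate",
             "inputs", "qc", "mcmc", "models", "cv")
  unknown <- setdiff(names(cfg), known)
  stop_if(length(unknown),
          "unknown config keys: ", paste(unknown, collapse = ", "))
  stop_if(is.null(cfg$schema_version) || cfg$schema_version != 1,
          "config schema_version must be 1")
  stop_if(is.null(cfg$trait), "config must name the trait")
  stop_if(is.null(cfg$seed), "config must set a seed")
  cfg$output_dir <- cfg$output_dir %||% "menvgp_run"
  cfg$models <- cfg$models %||% c("gblup", "mtm1")
  ok_models <- c("gblup", "gxc", "mxe", "mtm1", "mtm2")
  stop_if(!all(cfg$models %in% ok_models),
          "models must be among: ", paste(ok_models, collapse = ", "))
  cfg$cv <- modifyList(list(schemes = "cv2", n_reps = 10, frac_test = 0.2),
                       cfg$cv %||% list())
  cfg$qc <- modifyList(list(maf_max_removed = 0.05, miss_max = 0.10,
                            corr_max = 0.99), cfg$qc %||% list())
  for (p in unlist(cfg$inputs))
    stop_if(!file.exists(p), "input path does not exist: ", p)
  class(cfg) <- "run_config"
  cfg
}

log_stage <- function(log_path, stage, seed, t0, inputs = character(0)) {
  hashes <- if (length(inputs)) {
    paste(names(tools::md5sum(inputs)), tools::md5sum(inputs),
          sep = "=", collapse = ";")
  } else ""
  line <- sprintf("%s\tstage=%s\tseed=%d\twall_s=%.2f\tinputs=%s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage, seed,
                  as.numeric(Sys.time()) - t0, hashes)
  cat(line, "\n", file = log_path, append = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, QC, kernel construction, per-environment spatial
#' adjustment, model fitting and cross-validation according to the config,
#' writing every intermediate artifact (TSV/CSV) plus a structured log to
#' the output directory. Re-running an identical config reproduces
#' identical files.
#'
#' @param cfg a \code{run_config} (or path to its YAML).
#' @return (invisibly) the output directory; side effect: artifacts
#'   qc_report.tsv, grm.csv, ec_kernel.csv, blues.csv, fit summaries,
#'   cv_results.tsv, pipeline.log.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- read_run_config(cfg)
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out, "pipeline.log")
  cat(sprintf("# menvgp %s | R %s\n",
              as.character(utils::packageVersion("menvgp")),
              paste(R.version$major, R.version$minor, sep = ".")),
      file = log_path)
  seed <- as.integer(cfg$seed)
  mcmc <- do.call(mcmc_config, modifyList(
    list(n_iter = 2000, burn_in = 500, thin = 5, seed = seed +
           STAGE_SEED_OFFSETS[["fit"]]), cfg$mcmc %||% list()))
  # --- stage: simulate or load ---------------------------------------------
  t0 <- as.numeric(Sys.time())
  if (!is.null(cfg$simulate)) {
    sc <- do.call(sim_config, modifyList(
      cfg$simulate, list(seed = seed + STAGE_SEED_OFFSETS[["simulate"]])))
    G <- simulate_genotypes(sc)
    ecs <- simulate_env_covariates(sc)
    # truth-generating GRM: markers monomorphic in this draw carry no
    # information and would break standardization, so use the polymorphic
    # ones (the analysis GRM below is built from the QC'd markers anyway)
    poly <- apply(G, 2, var) > 0
    W0 <- center_standardize(G[, poly, drop = FALSE])
    K0 <- grm_vanraden(W0)
    U <- simulate_breeding_values(K0, sc$env_cov_matrix,
                                  seed = sc$seed + 10L)
    trial <- simulate_field_trial(sc, U)
    plots <- trial$plots
    names(plots)[names(plots) == "y"] <- cfg$trait
    write_genotypes(G, file.path(out, "genotypes.tsv"))
    write.table(plots, file.path(out, "plots.csv"), sep = ",",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(env = rownames(ecs), ecs),
                file.path(out, "ecs.csv"), sep = ",", quote = FALSE,
                row.names = FALSE)
    write.table(data.frame(genotype = rownames(trial$truth$true_u),
                           trial$truth$true_u),
                file.path(out, "truth_breeding_values.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    log_stage(log_path, "simulate", sc$seed, t0)
  } else {
    stop_if(is.null(cfg$inputs), "config needs either simulate or inputs")
    G <- read_genotypes(cfg$inputs$genotypes)
    plots <- read_phenotypes(cfg$inputs$phenotypes, trait = cfg$trait)
    ecs <- read_ecs(cfg$inputs$ecs)
    log_stage(log_path, "load", seed, t0, unlist(cfg$inputs))
  }
  # --- stage: qc ------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  qc <- qc_markers(G, cfg$qc$maf_max_removed, cfg$qc$miss_max,
                   cfg$qc$corr_max)
  rep_df <- data.frame(rule = c("input", "maf", "missing", "correlation",
                                "retained"),
                       n = c(qc$report$n_input, qc$report$n_removed_maf,
                             qc$report$n_removed_missing,
                             qc$report$n_removed_corr,
                             length(qc$report$retained_marker_ids)))
  write.table(rep_df, file.path(out, "qc_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  log_stage(log_path, "qc", seed + STAGE_SEED_OFFSETS[["qc"]], t0)
  # --- stage: kernels -------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  W <- center_standardize(qc$genotypes)
  K <- grm_vanraden(W)
  Omega <- ec_kernel(ecs)
  write_kernel(K, file.path(out, "grm.csv"))
  write_kernel(Omega, file.path(out, "ec_kernel.csv"))
  log_stage(log_path, "kernels", seed + STAGE_SEED_OFFSETS[["kernels"]], t0)
  # --- stage: spatial blues -------------------------------------------------
  t0 <- as.numeric(Sys.time())
  fits <- lapply(split(plots, plots$env), fit_spatial_model,
                 trait = cfg$trait)
  bl <- extract_blues(fits, K = K)
  write.table(data.frame(genotype = rownames(bl$blues), bl$blues),
              file.path(out, "blues.csv"), sep = ",", quote = FALSE,
              row.names = FALSE)
  vc_df <- do.call(rbind, lapply(names(fits), function(e)
    data.frame(env = e, component = names(fits[[e]]$var_comp),
               variance = unname(fits[[e]]$var_comp),
               lambda = unname(fits[[e]]$lambda[
                 names(fits[[e]]$var_comp)]),
               converged = fits[[e]]$converged)))
  write.table(vc_df, file.path(out, "spatial_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  log_stage(log_path, "blues", seed + STAGE_SEED_OFFSETS[["blues"]], t0)
  # --- stage: fit -----------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  B <- bl$blues
  Kb <- K[rownames(B), rownames(B)]
  fit_rows <- list()
  for (m in cfg$models) {
    fit <- if (m == "gblup") {
      fit_gblup_single_env(B[, 1], Kb, mcmc)
    } else fit_and_predict(B, m, Kb, Omega, mcmc)
    vc <- if (inherits(fit, "menvgp_mtm")) {
      c(setNames(diag(fit$E_mean), paste0("genetic_", fit$envs)),
        residual = unname(fit$var_comp["residual"] %||%
                            mean(fit$var_samples[, "residual"])))
    } else fit$var_comp
    fit_rows[[m]] <- data.frame(model = m, component = names(vc),
                                posterior_mean = unname(vc))
  }
  write.table(do.call(rbind, fit_rows), file.path(out, "fit_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage(log_path, "fit", mcmc$seed, t0)
  # --- stage: cv ------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  cv_seed <- seed + STAGE_SEED_OFFSETS[["cv"]]
  cv_rows <- list()
  for (sch in cfg$cv$schemes) {
    plans <- make_cv_plans(rownames(B), colnames(B), sch,
                           n_reps = cfg$cv$n_reps,
                           frac_test = cfg$cv$frac_test, seed = cv_seed)
    for (m in cfg$models) {
      if (m == "gblup" && sch != "single_env") next
      if (m != "gblup" && sch == "single_env") next
      cv_rows[[paste(sch, m)]] <-
        run_cv(B, Kb, m, plans, mcmc, Omega = Omega)
    }
  }
  if (length(cv_rows)) {
    cv_all <- do.call(rbind, cv_rows)
    write.table(cv_all, file.path(out, "cv_results.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(summarize_cv(cv_all), file.path(out, "cv_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  log_stage(log_path, "cv", cv_seed, t0)
  invisible(out)
}
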