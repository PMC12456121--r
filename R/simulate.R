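# Synthetic multi-environment trial generator. Emulates a diversity panel of
# fully inbred lines phenotyped in a row-column layout over several
# environments, with known breeding values, spatial surfaces and
# heritabilities so that downstream estimators can be checked against truth.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic data generator. Defaults describe the
#' kind of trial the package targets: a few hundred inbred (homozygous)
#' lines, thousands of independent biallelic SNPs, four environments with two
#' replicates each in a row-column field, moderate heritability and high but
#' imperfect between-environment genetic correlation, and unbalanced
#' line-by-environment coverage.
#'
#' @param n_lines number of inbred lines.
#' @param n_markers number of biallelic SNPs.
#' @param maf_range length-2 numeric in (0, 0.5]; per-marker allele
#'   frequencies are drawn uniformly from this interval.
#' @param n_envs number of environments J.
#' @param env_cov_matrix J x J positive-definite covariance of breeding
#'   values across environments (trait units squared). Default: unit
#'   variances with pairwise correlation 0.8.
#' @param env_means J environment intercepts (trait units).
#' @param h2_per_env J heritabilities in (0,1), defined at the level of
#'   line means over replicates within an environment.
#' @param n_reps replicates per environment (complete blocks).
#' @param field_rows,field_cols field layout; must hold
#'   \code{n_lines * n_reps} plots.
#' @param spatial_amplitude standard deviation (trait units) of the smooth
#'   spatial surface added to each plot; 0 disables it.
#' @param rep_sd standard deviation of the i.i.d. replicate (block) effect.
#' @param missing_cell_fraction fraction of line x environment cells left
#'   unobserved (sparse/unbalanced coverage).
#' @param guard_min_envs if TRUE (default) no line is left missing in two or
#'   more environments, mirroring the exclusion rule applied to real trials.
#' @param seed integer seed; every generator is deterministic given it.
#' @return an object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_lines = 300, n_markers = 2000,
                       maf_range = c(0.05, 0.5), n_envs = 4,
                       env_cov_matrix = NULL, env_means = NULL,
                       h2_per_env = NULL, n_reps = 2,
                       field_rows = NULL, field_cols = NULL,
                       spatial_amplitude = 1, rep_sd = 0.3,
                       missing_cell_fraction = 0.1, guard_min_envs = TRUE,
                       seed = 1L) {
  stop_if(n_lines < 1 || n_markers < 1 || n_envs < 1 || n_reps < 1,
          "dimensions must be positive")
  stop_if(length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
            maf_range[1] > maf_range[2],
          "maf_range must be an interval within (0, 0.5]")
  J <- as.integer(n_envs)
  if (is.null(env_cov_matrix)) {
    env_cov_matrix <- matrix(0.8, J, J); diag(env_cov_matrix) <- 1
  }
  stop_if(!isSymmetric(unname(env_cov_matrix)) ||
            min(eigen(env_cov_matrix, symmetric = TRUE,
                      only.values = TRUE)$values) <= 1e-10,
          "env_cov_matrix must be symmetric positive definite")
  stop_if(nrow(env_cov_matrix) != J, "env_cov_matrix must be n_envs x n_envs")
  env_means <- env_means %||% seq(10, by = 2, length.out = J)
  h2_per_env <- h2_per_env %||% rep(0.4, J)
  stop_if(any(h2_per_env <= 0) || any(h2_per_env >= 1),
          "h2_per_env must lie strictly in (0,1)")
  stop_if(length(env_means) != J || length(h2_per_env) != J,
          "env_means and h2_per_env must have length n_envs")
  if (is.null(field_rows) || is.null(field_cols)) {
    # near-square field in which each replicate occupies a full band of rows
    field_cols <- field_cols %||% ceiling(sqrt(n_lines * n_reps))
    field_rows <- n_reps * ceiling(n_lines / field_cols)
  }
  stop_if(field_rows * field_cols < n_lines * n_reps,
          "field layout too small for n_lines * n_reps plots")
  stop_if(missing_cell_fraction < 0 || missing_cell_fraction >= 1,
          "missing_cell_fraction must be in [0, 1)")
  structure(list(
    n_lines = as.integer(n_lines), n_markers = as.integer(n_markers),
    maf_range = maf_range, n_envs = J, env_cov_matrix = env_cov_matrix,
    env_means = env_means, h2_per_env = h2_per_env,
    n_reps = as.integer(n_reps), field_rows = as.integer(field_rows),
    field_cols = as.integer(field_cols),
    spatial_amplitude = spatial_amplitude, rep_sd = rep_sd,
    missing_cell_fraction = missing_cell_fraction,
    guard_min_envs = isTRUE(guard_min_envs), seed = as.integer(seed)),
    class = "sim_config")
}

env_names <- function(J) sprintf("E%02d", seq_len(J))

#' Simulate inbred-line genotype dosages
#'
#' Draws per-marker allele frequencies uniformly from \code{cfg$maf_range}
#' and, for fully inbred lines, a dosage of 2 with that probability and 0
#' otherwise (no heterozygotes). Markers are mutually independent.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return numeric matrix (lines x markers) with dimnames; entries in {0, 2}.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  p <- runif(cfg$n_markers, cfg$maf_range[1], cfg$maf_range[2])
  G <- matrix(2 * rbinom(cfg$n_lines * cfg$n_markers, 1,
                         rep(p, each = cfg$n_lines)),
              nrow = cfg$n_lines, ncol = cfg$n_markers)
  dimnames(G) <- list(sprintf("L%04d", seq_len(cfg$n_lines)),
                      sprintf("M%05d", seq_len(cfg$n_markers)))
  G
}

#' Simulate environmental covariates
#'
#' Generates a small table of continuous environment-level covariates on the
#' scale of typical season summaries (maximum temperature in deg C, minimum
#' temperature in deg C, total precipitation in mm, then unit-scale extras),
#' one row per environment.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param n_covs number of covariates (>= 1).
#' @return data.frame with rownames = environment ids, \code{n_covs} numeric
#'   columns.
#' @export
simulate_env_covariates <- function(cfg, n_covs = 3) {
  stopifnot(inherits(cfg, "sim_config"))
  stop_if(n_covs < 1, "n_covs must be >= 1")
  set.seed(cfg$seed + 1L)
  J <- cfg$n_envs
  base <- list(
    max_temp_C = rnorm(J, 34, 1.2),
    min_temp_C = rnorm(J, -2.5, 1.5),
    precip_mm  = rnorm(J, 720, 140))
  covs <- base[seq_len(min(n_covs, 3))]
  if (n_covs > 3)
    for (k in seq_len(n_covs - 3))
      covs[[paste0("ec", k + 3)]] <- rnorm(J)
  out <- as.data.frame(covs)
  rownames(out) <- env_names(J)
  out
}

#' Simulate breeding values with a Kronecker covariance
#'
#' Draws the n x J matrix of true breeding values U such that
#' \code{vec(U) ~ N(0, env_cov_matrix \%x\% K)}: rows covary as the genomic
#' relationship matrix K, columns (environments) as the supplied
#' between-environment genetic covariance.
#'
#' @param K n x n symmetric PSD genomic relationship matrix.
#' @param env_cov_matrix J x J symmetric PSD covariance across environments.
#' @param seed integer seed.
#' @return n x J matrix of breeding values (trait units).
#' @export
simulate_breeding_values <- function(K, env_cov_matrix, seed = 1L) {
  stop_if(!isSymmetric(unname(K)) || !isSymmetric(unname(env_cov_matrix)),
          "K and env_cov_matrix must be symmetric")
  n <- nrow(K); J <- nrow(env_cov_matrix)
  set.seed(seed)
  Z <- matrix(rnorm(n * J), n, J)
  U <- psd_sqrt(K) %*% Z %*% psd_sqrt(env_cov_matrix)
  rownames(U) <- rownames(K)
  colnames(U) <- colnames(env_cov_matrix) %||% env_names(J)
  U
}

# Smooth bivariate surface: separable low-frequency sinusoids in the row and
# column directions plus a bilinear row x column term, centered to mean zero
# and rescaled so its standard deviation over occupied plots equals
# `amplitude` (zero mean keeps the environment intercept well defined).
sim_surface <- function(row, col, n_rows, n_cols, amplitude) {
  if (amplitude <= 0) return(rep(0, length(row)))
  r <- (row - 1) / max(n_rows - 1, 1)
  c_ <- (col - 1) / max(n_cols - 1, 1)
  fr <- runif(1, 0.8, 1.8); fc <- runif(1, 0.8, 1.8)
  ph <- runif(2, 0, 2 * pi); w <- rnorm(3)
  s <- w[1] * sin(2 * pi * fr * r + ph[1]) +
    w[2] * sin(2 * pi * fc * c_ + ph[2]) +
    w[3] * (r - 0.5) * (c_ - 0.5) * 4
  s_sd <- pop_sd(s)
  if (s_sd < 1e-12) rep(0, length(row))
  else amplitude * (s - mean(s)) / s_sd
}

#' Simulate a multi-environment row-column field trial
#'
#' Lays out \code{n_reps} complete blocks per environment on the configured
#' field grid (blocks occupy contiguous bands of rows; line order is
#' randomized within each block), then builds plot phenotypes as
#' environment mean + breeding value + smooth spatial surface + replicate
#' effect + Gaussian residual. The residual variance in environment j is set
#' to \code{n_reps * var(u_j) * (1 - h2_j) / h2_j}, so that the genetic
#' fraction of variance of line means over replicates equals the target
#' heritability by construction. Finally a fraction of line x environment
#' cells is dropped at random; with the guard on, no line ends up missing in
#' two or more environments.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param true_u n_lines x n_envs matrix of breeding values, typically from
#'   \code{\link{simulate_breeding_values}}.
#' @return list with \code{plots} (data.frame: env, rep, row, col, genotype,
#'   y) and \code{truth} (list: true_u, true_surface per plot before masking,
#'   residual_sd, rep_effects, env_means, h2).
#' @export
simulate_field_trial <- function(cfg, true_u) {
  stopifnot(inherits(cfg, "sim_config"))
  stop_if(nrow(true_u) != cfg$n_lines || ncol(true_u) != cfg$n_envs,
          "true_u must be n_lines x n_envs")
  set.seed(cfg$seed + 2L)
  J <- cfg$n_envs; n <- cfg$n_lines; R <- cfg$n_reps
  lines <- rownames(true_u) %||% sprintf("L%04d", seq_len(n))
  envs <- colnames(true_u) %||% env_names(J)
  # choose which cells are observed
  obs <- matrix(TRUE, n, J, dimnames = list(lines, envs))
  n_miss <- round(cfg$missing_cell_fraction * n * J)
  if (n_miss > 0) {
    idx <- sample(n * J, n_miss)
    obs[idx] <- FALSE
    if (cfg$guard_min_envs && J >= 2) {
      bad <- which(rowSums(!obs) >= 2)
      for (i in bad) {
        miss_j <- which(!obs[i, ])
        keep_one <- sample(miss_j, 1)
        obs[i, setdiff(miss_j, keep_one)] <- TRUE
      }
    }
  }
  resid_sd <- sqrt(R * apply(true_u, 2, var) *
                     (1 - cfg$h2_per_env) / cfg$h2_per_env)
  rows_per_block <- floor(cfg$field_rows / R)
  stop_if(rows_per_block * cfg$field_cols < n,
          "field layout cannot hold a complete block per replicate")
  plots <- vector("list", J)
  surfaces <- vector("list", J)
  rep_effects <- matrix(rnorm(J * R, 0, cfg$rep_sd), J, R,
                        dimnames = list(envs, paste0("rep", seq_len(R))))
  for (j in seq_len(J)) {
    ij <- which(obs[, j])
    env_plots <- vector("list", R)
    for (r in seq_len(R)) {
      ord <- sample(ij)
      pos <- seq_along(ord) - 1L
      prow <- (r - 1L) * rows_per_block + pos %/% cfg$field_cols + 1L
      pcol <- pos %% cfg$field_cols + 1L
      env_plots[[r]] <- data.frame(
        env = envs[j], rep = r, row = prow, col = pcol,
        genotype = lines[ord], stringsAsFactors = FALSE)
    }
    pj <- do.call(rbind, env_plots)
    surf <- sim_surface(pj$row, pj$col, cfg$field_rows, cfg$field_cols,
                        cfg$spatial_amplitude)
    pj$y <- cfg$env_means[j] + true_u[pj$genotype, j] + surf +
      rep_effects[j, pj$rep] + rnorm(nrow(pj), 0, resid_sd[j])
    surfaces[[j]] <- surf
    plots[[j]] <- pj
  }
  plots <- do.call(rbind, plots)
  rownames(plots) <- NULL
  list(plots = plots,
       truth = list(true_u = true_u, true_surface = unlist(surfaces),
                    residual_sd = resid_sd, rep_effects = rep_effects,
                    env_means = setNames(cfg$env_means, envs),
                    h2 = setNames(cfg$h2_per_env, envs)))
}

#' Raw genotype means per environment
#'
#' Unadjusted line-by-environment means of plot phenotypes; the naive
#' competitor to spatially adjusted BLUEs.
#'
#' @param plots plot table as produced by \code{\link{simulate_field_trial}}.
#' @return genotype x environment matrix (NA where unobserved).
#' @export
line_env_means <- function(plots) {
  ag <- aggregate(y ~ genotype + env, data = plots, FUN = mean)
  lines <- sort(unique(plots$genotype)); envs <- sort(unique(plots$env))
  M <- matrix(NA_real_, length(lines), length(envs),
              dimnames = list(lines, envs))
  M[cbind(ag$genotype, ag$env)] <- ag$y
  M
}
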