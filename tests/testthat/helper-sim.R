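# Shared fixture builders. All are deterministic given their seed and kept
# small so the whole suite stays fast.

# Inbred-style dosage matrix with moderate allele frequencies (no
# zero-variance columns at these sizes/frequencies).
tiny_genotypes <- function(n = 40, p = 120, seed = 1,
                           freq_range = c(0.2, 0.5)) {
  set.seed(seed)
  f <- runif(p, freq_range[1], freq_range[2])
  G <- matrix(2 * rbinom(n * p, 1, rep(f, each = n)), n, p)
  # tiny panels can produce constant columns by chance; flip one entry so
  # every marker is polymorphic (the fixtures model post-QC data)
  mono <- which(apply(G, 2, function(x) length(unique(x)) == 1))
  for (j in mono) G[1, j] <- 2 - G[1, j]
  dimnames(G) <- list(sprintf("L%03d", seq_len(n)),
                      sprintf("M%04d", seq_len(p)))
  G
}

tiny_K <- function(n = 40, p = 120, seed = 1) {
  grm_vanraden(center_standardize(tiny_genotypes(n, p, seed)))
}

# Family-structured panel: pairs of full "sibs" that share most of their
# genome, so held-out lines are genuinely predictable from their relatives.
sib_K <- function(n = 40, p = 200, seed = 1, flip = 0.08) {
  stopifnot(n %% 2 == 0)
  founders <- tiny_genotypes(n / 2, p, seed)
  set.seed(seed + 1)
  sibs <- founders
  flips <- matrix(runif(length(sibs)) < flip, nrow(sibs), ncol(sibs))
  sibs[flips] <- 2 - sibs[flips]
  G <- rbind(founders, sibs)
  rownames(G) <- sprintf("L%03d", seq_len(n))
  mono <- which(apply(G, 2, var) == 0)
  for (j in mono) G[1, j] <- 2 - G[1, j]
  grm_vanraden(center_standardize(G))
}

# Complete multi-environment data set with known truth: genotypes, GRM,
# breeding values, trial and the line-by-environment mean matrix.
quick_sim <- function(n_lines = 60, n_markers = 300, n_envs = 2, seed = 1,
                      h2 = 0.5, rho = 0.8, spatial_amplitude = 0,
                      rep_sd = 0, missing_cell_fraction = 0, ...) {
  E <- matrix(rho, n_envs, n_envs); diag(E) <- 1
  cfg <- sim_config(n_lines = n_lines, n_markers = n_markers,
                    n_envs = n_envs, env_cov_matrix = E,
                    h2_per_env = rep(h2, n_envs),
                    spatial_amplitude = spatial_amplitude, rep_sd = rep_sd,
                    missing_cell_fraction = missing_cell_fraction,
                    seed = seed, ...)
  G <- simulate_genotypes(cfg)
  # fixtures model post-QC data: drop columns monomorphic in this small draw
  G <- G[, apply(G, 2, var) > 0, drop = FALSE]
  K <- grm_vanraden(center_standardize(G))
  U <- simulate_breeding_values(K, E, seed = seed + 7L)
  trial <- simulate_field_trial(cfg, U)
  list(cfg = cfg, G = G, K = K, U = U, trial = trial,
       B = line_env_means(trial$plots),
       ecs = simulate_env_covariates(cfg))
}

# Short chain for unit tests where only qualitative behaviour is checked.
fast_mcmc <- function(seed = 1, n_iter = 1500, burn_in = 500, thin = 5)
  mcmc_config(n_iter = n_iter, burn_in = burn_in, thin = thin, seed = seed)

# The six-marker QC toy: 25 lines so that one carrier gives MAF 1/25 = 0.04
# and three NAs give a 12% missing rate. Markers: two with MAF 0.04, one
# with 12% missing, then three well-behaved markers of which two are exact
# duplicates -> exactly mk4 and mk6 survive.
qc_toy <- function() {
  n <- 25
  set.seed(99)
  base <- 2 * rbinom(n, 1, 0.5)
  other <- 2 * rbinom(n, 1, 0.35)
  rare1 <- c(2, rep(0, n - 1))
  rare2 <- c(rep(0, n - 1), 2)
  missing <- 2 * rbinom(n, 1, 0.4); missing[c(3, 11, 20)] <- NA
  G <- cbind(mk1 = rare1, mk2 = rare2, mk3 = missing,
             mk4 = base, mk5 = base, mk6 = other)
  rownames(G) <- sprintf("L%02d", seq_len(n))
  G
}
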