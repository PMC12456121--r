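test_that("sim_config validates its arguments", {
  expect_s3_class(sim_config(n_lines = 10, n_markers = 20, n_envs = 2),
                  "sim_config")
  expect_error(sim_config(h2_per_env = c(0, 0.5), n_envs = 2), "h2")
  expect_error(sim_config(h2_per_env = rep(1, 4)), "h2")
  expect_error(sim_config(maf_range = c(0.2, 0.6)), "maf_range")
  expect_error(sim_config(maf_range = c(0.4, 0.2)), "maf_range")
  bad_E <- matrix(1, 3, 3)   # singular
  expect_error(sim_config(n_envs = 3, env_cov_matrix = bad_E),
               "positive definite")
  expect_error(sim_config(n_lines = 100, field_rows = 5, field_cols = 5),
               "too small")
})

test_that("genotype simulation is deterministic with inbred dosages", {
  cfg <- sim_config(n_lines = 30, n_markers = 50, seed = 11)
  G1 <- simulate_genotypes(cfg)
  G2 <- simulate_genotypes(cfg)
  expect_identical(G1, G2)
  expect_equal(dim(G1), c(30L, 50L))
  expect_true(all(G1 %in% c(0, 2)))
  expect_false(is.null(rownames(G1)) || is.null(colnames(G1)))
})

test_that("simulated allele frequencies match the configured range", {
  cfg <- sim_config(n_lines = 400, n_markers = 600,
                    maf_range = c(0.3, 0.3), seed = 3)
  G <- simulate_genotypes(cfg)
  expect_equal(mean(G) / 2, 0.3, tolerance = 0.02)
})

test_that("environment covariates are deterministic with sensible scales", {
  cfg <- sim_config(n_lines = 10, n_markers = 10, n_envs = 4, seed = 5)
  ec1 <- simulate_env_covariates(cfg)
  ec2 <- simulate_env_covariates(cfg)
  expect_identical(ec1, ec2)
  expect_equal(dim(ec1), c(4L, 3L))
  expect_named(ec1, c("max_temp_C", "min_temp_C", "precip_mm"))
  expect_true(all(ec1$max_temp_C > 20 & ec1$max_temp_C < 45))
  ec5 <- simulate_env_covariates(cfg, n_covs = 5)
  expect_equal(ncol(ec5), 5L)
})

test_that("breeding values realize the requested Kronecker covariance", {
  n <- 4000
  K <- diag(n); dimnames(K) <- list(sprintf("L%04d", 1:n),
                                    sprintf("L%04d", 1:n))
  E <- matrix(c(1, 0.8, 0.8, 1), 2, 2)
  U <- simulate_breeding_values(K, E, seed = 21)
  expect_identical(U, simulate_breeding_values(K, E, seed = 21))
  expect_equal(cor(U[, 1], U[, 2]), 0.8, tolerance = 0.05)
  expect_equal(unname(apply(U, 2, var)), c(1, 1), tolerance = 0.1)
  # perfectly correlated environments give identical columns
  U1 <- simulate_breeding_values(K[1:50, 1:50],
                                 matrix(1, 2, 2) + diag(1e-8, 2), seed = 2)
  expect_equal(cor(U1[, 1], U1[, 2]), 1, tolerance = 1e-3)
})

test_that("field trial decomposes exactly into its simulated components", {
  sim <- quick_sim(n_lines = 80, n_envs = 2, seed = 31,
                   spatial_amplitude = 0.7, rep_sd = 0.4)
  pl <- sim$trial$plots
  tr <- sim$trial$truth
  eps <- pl$y - tr$env_means[pl$env] -
    tr$true_u[cbind(pl$genotype, pl$env)] - tr$true_surface -
    tr$rep_effects[cbind(pl$env, paste0("rep", pl$rep))]
  for (j in names(tr$env_means)) {
    ej <- eps[pl$env == j]
    expect_equal(sd(ej) / tr$residual_sd[[j]], 1, tolerance = 0.15)
    expect_equal(mean(ej), 0, tolerance = 3 * tr$residual_sd[[j]] /
                   sqrt(length(ej)) + 0.05)
  }
})

test_that("each replicate is a complete block of the observed lines", {
  sim <- quick_sim(n_lines = 50, n_envs = 2, seed = 41,
                   missing_cell_fraction = 0.15)
  pl <- sim$trial$plots
  for (j in unique(pl$env)) {
    pj <- pl[pl$env == j, ]
    lines_j <- sort(unique(pj$genotype))
    for (r in unique(pj$rep))
      expect_setequal(pj$genotype[pj$rep == r], lines_j)
  }
  # no duplicated plot coordinates within an environment
  expect_false(anyDuplicated(pl[, c("env", "row", "col")]) > 0)
})

test_that("the spatial surface is centered with the requested amplitude", {
  sim <- quick_sim(n_lines = 60, n_envs = 2, seed = 51,
                   spatial_amplitude = 1.3)
  pl <- sim$trial$plots
  surf <- sim$trial$truth$true_surface
  for (j in unique(pl$env)) {
    sj <- surf[pl$env == j]
    expect_equal(mean(sj), 0, tolerance = 1e-10)
    expect_equal(sqrt(mean((sj - mean(sj))^2)), 1.3, tolerance = 1e-10)
  }
})

test_that("the missing-cell guard leaves every line observed in J-1+ envs", {
  sim <- quick_sim(n_lines = 60, n_envs = 4, seed = 61,
                   missing_cell_fraction = 0.25)
  miss_per_line <- rowSums(is.na(sim$B))
  expect_true(all(miss_per_line <= 1))
  expect_gt(sum(is.na(sim$B)), 0)   # some cells really are missing
})

test_that("heritability holds by construction at the line-mean level", {
  sim <- quick_sim(n_lines = 250, n_markers = 500, n_envs = 2, seed = 71,
                   h2 = 0.5)
  for (j in 1:2) {
    r2 <- cor(sim$B[, j], sim$U[rownames(sim$B), j])^2
    expect_equal(r2, 0.5, tolerance = 0.1)
  }
})

test_that("line_env_means averages replicates and preserves NA cells", {
  sim <- quick_sim(n_lines = 20, n_envs = 2, seed = 81,
                   missing_cell_fraction = 0.2)
  pl <- sim$trial$plots
  B <- sim$B
  i <- rownames(B)[1]; j <- colnames(B)[1]
  manual <- mean(pl$y[pl$genotype == i & pl$env == j])
  expect_equal(B[i, j], manual)
  observed <- table(factor(pl$genotype, rownames(B)),
                    factor(pl$env, colnames(B))) > 0
  expect_identical(unname(is.na(B)), unname(!as.matrix(observed)))
})
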