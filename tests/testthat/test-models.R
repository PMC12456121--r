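test_that("single-environment GBLUP separates signal from pure noise", {
  # family structure makes the genetic/residual split identifiable
  K <- sib_K(120, 300, seed = 1)
  set.seed(2)
  u <- as.vector(psd_sqrt(K) %*% rnorm(120))
  # nearly noise-free signal -> high heritability
  fit_hi <- fit_gblup_single_env(u + rnorm(120, 0, 0.05), K,
                                 fast_mcmc(3, 3000, 1000))
  expect_gt(heritability(fit_hi), 0.7)
  # pure noise -> low heritability
  fit_lo <- fit_gblup_single_env(rnorm(120), K, fast_mcmc(4, 3000, 1000))
  expect_lt(heritability(fit_lo), 0.4)
  expect_gt(heritability(fit_hi) - heritability(fit_lo), 0.3)
})

test_that("the reaction-norm model exposes its six variance components", {
  sim <- quick_sim(n_lines = 50, n_markers = 250, n_envs = 3, seed = 5)
  Om <- ec_kernel(sim$ecs)
  fit <- fit_gxc(sim$B, sim$K, Om, fast_mcmc(6))
  expect_named(fit$var_comp, c("g", "E", "w", "gE", "gw", "residual"))
  vp <- variance_proportions(fit)
  expect_equal(sum(vp), 1)
  expect_true(all(vp > 0))
  expect_error(fit_gxc(sim$B[, 1, drop = FALSE], sim$K, Om[1, 1,
                                                           drop = FALSE]),
               "two environments")
})

test_that("gxc fitted values respond to environment means", {
  sim <- quick_sim(n_lines = 50, n_markers = 250, n_envs = 3, seed = 7)
  Om <- ec_kernel(sim$ecs)
  fit <- fit_gxc(sim$B, sim$K, Om, fast_mcmc(8))
  # per-env fitted means track the very different simulated env means
  expect_equal(unname(colMeans(fit$fitted)), unname(colMeans(sim$B)),
               tolerance = 0.2)
  expect_gt(cor(as.vector(fit$fitted), as.vector(sim$B)), 0.8)
})

test_that("the marker-by-environment model rejects one environment", {
  K <- tiny_K(20, 80, seed = 9)
  B1 <- matrix(rnorm(20), 20, 1, dimnames = list(rownames(K), "E01"))
  expect_error(fit_mxe(B1, K), "one environment")
  expect_error(fit_mxe(B1, K, parameterization = "ridge"), "ridge")
})

test_that("mxe fits main plus per-environment specific components", {
  sim <- quick_sim(n_lines = 50, n_markers = 250, n_envs = 2, seed = 10)
  fit <- fit_mxe(sim$B, sim$K, fast_mcmc(11))
  expect_named(fit$var_comp,
               c("main", "specific_E01", "specific_E02", "residual"))
  expect_gt(cor(as.vector(fit$fitted), as.vector(sim$B)), 0.7)
})

test_that("GBLUP and ridge parameterizations are the same model", {
  set.seed(12)
  n <- 30; p <- 50; J <- 3
  G <- tiny_genotypes(n, p, seed = 12)
  W <- center_standardize(G)
  K <- grm_vanraden(W)
  U <- simulate_breeding_values(K, diag(J) * 0.8 + 0.2, seed = 13)
  Y <- matrix(rep(c(10, 12, 14), each = n), n, J) + U +
    matrix(rnorm(n * J, 0, 0.5), n, J)
  dimnames(Y) <- list(rownames(K), paste0("E", 1:J))
  Y[2, 1] <- NA; Y[5, 3] <- NA
  s2_b0 <- 0.6 / p; s2_b <- c(0.2, 0.3, 0.25) / p; s2_e <- 0.25
  ridge <- mxe_ridge_blup(Y, W, s2_b0, s2_b, s2_e)
  gblup <- mxe_gblup_blup(Y, K, p * s2_b0, p * s2_b, s2_e)
  expect_lt(max(abs(ridge$fitted - gblup$fitted)), 1e-6)
  expect_equal(ridge$predictions, gblup$predictions, tolerance = 1e-6)
})

test_that("the multi-trait model recovers duplicated environments", {
  K <- tiny_K(60, 250, seed = 14)
  set.seed(15)
  u <- as.vector(psd_sqrt(K) %*% rnorm(60))
  Y <- cbind(e1 = u + rnorm(60, 0, 0.4), e2 = u + rnorm(60, 0, 0.4))
  rownames(Y) <- rownames(K)
  fit <- fit_mtm(Y, K, fast_mcmc(16, 4000, 1500))
  R <- genetic_correlations(fit)
  expect_equal(diag(R), c(e1 = 1, e2 = 1))
  expect_true(isSymmetric(R))
  expect_gt(R[1, 2], 0.75)
})

test_that("the inverse-Wishart prior is configurable and validated", {
  sim <- quick_sim(n_lines = 30, n_markers = 150, n_envs = 2, seed = 23)
  expect_error(fit_mtm(sim$B, sim$K, mcmc_config(200, 50, 2, iw_df = 1)),
               "iw_df")
  f_def <- fit_mtm(sim$B, sim$K, fast_mcmc(24, 600, 200))
  f_df <- fit_mtm(sim$B, sim$K,
                  mcmc_config(600, 200, 5, seed = 24, iw_df = 12))
  f_sc <- fit_mtm(sim$B, sim$K,
                  mcmc_config(600, 200, 5, seed = 24, iw_scale = c(9, 9)))
  # a different prior must change the posterior, deterministically
  expect_false(identical(f_def$E_mean, f_df$E_mean))
  expect_false(identical(f_def$E_mean, f_sc$E_mean))
  f_sc2 <- fit_mtm(sim$B, sim$K,
                   mcmc_config(600, 200, 5, seed = 24, iw_scale = c(9, 9)))
  expect_identical(f_sc$E_mean, f_sc2$E_mean)
})

test_that("MTM2 adds the marker-free component", {
  sim <- quick_sim(n_lines = 40, n_markers = 200, n_envs = 2, seed = 17)
  f2 <- fit_mtm(sim$B, sim$K, fast_mcmc(18), extra_component = TRUE)
  expect_identical(f2$model, "mtm2")
  expect_false(is.null(f2$F_mean))
  expect_equal(dim(f2$F_samples)[1:2], c(2L, 2L))
  f1 <- fit_mtm(sim$B, sim$K, fast_mcmc(18))
  expect_identical(f1$model, "mtm1")
  expect_null(f1$F_mean)
})

test_that("MTM heritabilities and summaries have the right shape", {
  sim <- quick_sim(n_lines = 40, n_markers = 200, n_envs = 3, seed = 19)
  fit <- fit_mtm(sim$B, sim$K, fast_mcmc(20))
  h2 <- heritability(fit)
  expect_length(h2, 3)
  expect_named(h2, colnames(sim$B))
  expect_true(all(h2 > 0 & h2 < 1))
  expect_error(genetic_correlations(list()), "multi-trait")
  expect_error(variance_proportions(fit), "unsupported")
})

test_that("MTM predicts masked cells by data augmentation", {
  sim <- quick_sim(n_lines = 60, n_markers = 250, n_envs = 2, seed = 21,
                   rho = 0.9)
  Bm <- sim$B
  hide <- cbind(1:12, 1)
  Bm[hide] <- NA
  fit <- fit_mtm(Bm, sim$K, fast_mcmc(22, 3000, 1000))
  expect_equal(length(fit$predictions), 12L)
  expect_gt(cor(fit$fitted[hide], sim$B[hide]), 0.3)
})
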