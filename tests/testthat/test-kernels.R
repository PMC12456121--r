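test_that("center_standardize centers and scales by population SD", {
  G <- cbind(a = c(0, 2, 0, 2), b = c(0, 0, 0, 2))
  W <- center_standardize(G)
  expect_equal(colMeans(W), c(a = 0, b = 0))
  expect_equal(sqrt(colMeans(W^2)), c(a = 1, b = 1))
  expect_equal(unname(W[, "a"]), c(-1, 1, -1, 1))
  expect_error(center_standardize(cbind(a = c(0, 0, 0))), "zero-variance")
})

test_that("center_standardize mean-imputes residual missing dosages", {
  G <- cbind(a = c(0, 2, NA, 2))
  W <- center_standardize(G)
  expect_false(anyNA(W))
  expect_equal(mean(W[, 1]), 0)
})

test_that("GRM matches a hand-computed 2x2 case and a brute-force oracle", {
  W <- matrix(c(-1, 1), 2, 1, dimnames = list(c("A", "B"), "m1"))
  expect_equal(grm_vanraden(W),
               matrix(c(1, -1, -1, 1), 2, 2,
                      dimnames = list(c("A", "B"), c("A", "B"))))
  # brute-force double loop on a random standardized matrix
  set.seed(4)
  W2 <- scale(matrix(rnorm(5 * 8), 5, 8)) * sqrt(4 / 5)
  dimnames(W2) <- list(paste0("L", 1:5), paste0("M", 1:8))
  K <- grm_vanraden(W2)
  for (i in 1:5) for (j in 1:5)
    expect_equal(K[i, j], sum(W2[i, ] * W2[j, ]) / 8, tolerance = 1e-12)
})

test_that("GRM is symmetric PSD with grand sum zero", {
  K <- tiny_K(30, 80, seed = 2)
  expect_true(isSymmetric(K))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
  expect_lt(abs(sum(K)), 1e-8)
})

test_that("ec_kernel reproduces an independent hand calculation", {
  ec <- data.frame(max_temp_C = c(35.55, 33.33, 33.89, 33.33),
                   min_temp_C = c(-1.11, -3.89, -3.89, -1.11),
                   precip_mm = c(906.78, 547.12, 760.98, 667.77),
                   row.names = c("C20", "K20", "C21", "K21"))
  Om <- ec_kernel(ec)
  # oracle: scalar arithmetic, no matrix ops
  Cs <- matrix(NA_real_, 4, 3)
  for (q in 1:3) {
    x <- ec[[q]]
    m <- sum(x) / 4
    s <- sqrt(sum((x - m)^2) / 4)
    Cs[, q] <- (x - m) / s
  }
  for (i in 1:4) for (j in 1:4) {
    oij <- 0
    for (q in 1:3) oij <- oij + Cs[i, q] * Cs[j, q]
    expect_equal(Om[i, j], oij / 3, tolerance = 1e-12)
  }
  expect_lt(abs(sum(Om)), 1e-8)
  expect_true(isSymmetric(Om))
})

test_that("identical environment rows give matching kernel entries", {
  ec <- data.frame(a = c(1, 1, 3), b = c(5, 5, 2), c = c(0.2, 0.2, 0.9),
                   row.names = c("E1", "E2", "E3"))
  Om <- ec_kernel(ec)
  expect_equal(Om["E1", "E2"], Om["E1", "E1"])
  expect_equal(Om["E1", "E2"], Om["E2", "E2"])
})

test_that("ec_kernel rejects constant covariates and tiny tables", {
  expect_error(ec_kernel(data.frame(a = c(1, 1, 1), b = c(2, 3, 4))),
               "constant")
  expect_error(ec_kernel(data.frame(a = 1)), "two environments")
})

test_that("the six-marker toy yields exactly two surviving markers", {
  G <- qc_toy()
  res <- qc_markers(G)
  expect_identical(res$report$retained_marker_ids, c("mk4", "mk6"))
  expect_equal(ncol(res$genotypes), 2L)
  expect_equal(res$report$n_removed_maf, 2L)
  expect_equal(res$report$n_removed_missing, 1L)
  expect_equal(res$report$n_removed_corr, 1L)
})

test_that("QC retains everything when nothing violates the thresholds", {
  set.seed(12)
  G <- matrix(2 * rbinom(200 * 6, 1, 0.5), 200, 6,
              dimnames = list(NULL, paste0("m", 1:6)))
  res <- qc_markers(G)
  expect_equal(res$report$n_removed_maf, 0L)
  expect_equal(res$report$n_removed_missing, 0L)
  expect_equal(res$report$n_removed_corr, 0L)
  expect_identical(res$genotypes, G)
})

test_that("the MAF and missing thresholds are inclusive", {
  n <- 20   # 1 carrier of dosage 2 among 20 -> MAF 1/20 = 0.05 exactly
  good <- 2 * rbinom(n, 1, 0.5)
  borderline <- c(2, rep(0, n - 1))
  miss10 <- good; miss10[1:2] <- NA   # exactly 10% missing
  set.seed(8)
  G <- cbind(edge = borderline, m10 = miss10,
             keep = 2 * rbinom(n, 1, 0.45))
  res <- qc_markers(G)
  expect_false("edge" %in% res$report$retained_marker_ids)
  expect_false("m10" %in% res$report$retained_marker_ids)
  expect_true("keep" %in% res$report$retained_marker_ids)
})

test_that("correlation pruning drops the later marker of a pair", {
  set.seed(3)
  a <- 2 * rbinom(50, 1, 0.5)
  b <- 2 * rbinom(50, 1, 0.5)
  G <- cbind(first = a, second = b, dup_of_first = a)
  res <- qc_markers(G)
  expect_identical(res$report$retained_marker_ids, c("first", "second"))
})

test_that("QC does not depend on line order", {
  G <- qc_toy()
  set.seed(1)
  perm <- sample(nrow(G))
  expect_identical(qc_markers(G)$report$retained_marker_ids,
                   qc_markers(G[perm, ])$report$retained_marker_ids)
})

test_that("kin imputation averages the k most related observed lines", {
  K <- matrix(0.5, 3, 3); diag(K) <- 1
  dimnames(K) <- list(c("A", "B", "C"), c("A", "B", "C"))
  B <- matrix(c(NA, 10, 20, 1, 2, 3), 3, 2,
              dimnames = list(c("A", "B", "C"), c("envA", "envB")))
  res <- suppressWarnings(impute_phenotypes_by_kin(B, K, k = 2))
  expect_equal(res$blues["A", "envA"], 15)
  expect_true(res$imputed["A", "envA"])
  # observed cells never altered
  expect_identical(res$blues[!res$imputed], B[!is.na(B)])
})

test_that("lines missing in two or more environments are dropped", {
  K <- tiny_K(10, 60, seed = 5)
  B <- matrix(rnorm(40), 10, 4,
              dimnames = list(rownames(K), paste0("E", 1:4)))
  B[1, 1:2] <- NA     # two missing -> dropped
  B[2, 3] <- NA       # one missing -> imputed
  res <- suppressWarnings(impute_phenotypes_by_kin(B, K, k = 3))
  expect_identical(res$dropped, rownames(K)[1])
  expect_false(rownames(K)[1] %in% rownames(res$blues))
  expect_false(anyNA(res$blues))
})

test_that("kin imputation warns when fewer than k donors exist", {
  K <- tiny_K(5, 60, seed = 6)
  B <- matrix(rnorm(10), 5, 2, dimnames = list(rownames(K), c("e1", "e2")))
  B[1, 1] <- NA
  expect_warning(impute_phenotypes_by_kin(B, K, k = 20), "neighbours")
})
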