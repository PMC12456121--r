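# Per-environment spatial mixed model. The observation model is
#   y = 1 mu + Xs beta_s + Zs s + Zu u + Zg g + eps
# with genotypes fixed, the PS-ANOVA surface split into five penalized
# blocks s (each with its own variance sigma2_sk and smoothing ratio
# lambda_sk = sigma2_eps / sigma2_sk), and random row and column factor
# effects u picking up discontinuous field variation (replicate bands
# included). Variances are estimated by REML with fixed-point updates on
# the smoothing ratios (Schall/SAP-style, via effective dimensions on
# Henderson's equations), monitored by the restricted log-likelihood.

#' Fit the P-spline spatial model for one environment
#'
#' @param plots data.frame with columns \code{row}, \code{col},
#'   \code{genotype} and the response named by \code{trait} (default
#'   \code{"y"}), for a single environment.
#' @param n_knots_r,n_knots_c B-spline segments per dimension (see
#'   \code{\link{build_psanova_basis}}).
#' @param tol convergence tolerance on successive REML log-likelihoods.
#' @param max_iter maximum EM iterations.
#' @param trait response column name.
#' @return object of class \code{spatial_fit}: genotype BLUEs
#'   (\code{blues}, intercept + sum-to-zero genotype effect, with standard
#'   errors), fixed spatial coefficients, penalized-block coefficients,
#'   row/column effects, variance components \code{var_comp} (five surface
#'   blocks, row, col, residual), smoothing ratios \code{lambda}, fitted
#'   values, residuals, the REML log-likelihood trace and a convergence
#'   flag.
#' @export
fit_spatial_model <- function(plots, n_knots_r = NULL, n_knots_c = NULL,
                              tol = 1e-6, max_iter = 200, trait = "y") {
  need <- c("row", "col", "genotype", trait)
  stop_if(!all(need %in% names(plots)),
          "plots must have columns row, col, genotype and the trait")
  stop_if(anyNA(plots[[trait]]), "missing trait values not allowed")
  stop_if(length(unique(plots$env %||% "e")) > 1,
          "fit_spatial_model takes plots from a single environment")
  y <- plots[[trait]]
  n <- length(y)
  basis <- build_psanova_basis(plots$row, plots$col, n_knots_r, n_knots_c)
  geno <- factor(plots$genotype)
  n_g <- nlevels(geno)
  stop_if(n_g < 2, "need at least two genotypes")
  # sum-to-zero genotype contrasts; intercept lives in the basis fixed part
  Xg <- model.matrix(~geno, contrasts.arg = list(geno = "contr.sum"))[, -1,
                                                                      drop = FALSE]
  X <- cbind(basis$X, Xg)
  qrX <- qr(X)
  stop_if(qrX$rank < ncol(X),
          "aliased fixed effects (genotype design confounded with layout)")
  rowf <- factor(plots$row); colf <- factor(plots$col)
  Zlist <- c(basis$Z,
             list(row_effect = model.matrix(~0 + rowf),
                  col_effect = model.matrix(~0 + colf)))
  fit <- sap_reml(y, X, Zlist, tol = tol, max_iter = max_iter)
  if (!fit$converged)
    warning(sprintf(
      "REML did not reach |dll| < %g in %d iterations (last dll = %.3g)",
      tol, max_iter, fit$last_dll))
  p_fix <- ncol(basis$X)
  beta <- fit$beta
  g_eff <- c(beta[(p_fix + 1):length(beta)], 0)
  g_eff[n_g] <- -sum(g_eff[-n_g])
  names(g_eff) <- levels(geno)
  # adjusted mean = genotype effect + average non-genetic part of the fit
  # (intercept plus the mean of the spatial fixed/penalized and row/column
  # effects over the observed plots), so levels are comparable to raw means
  mu <- mean(fit$fitted - g_eff[as.character(geno)])
  # SE of mu + g_i via the fixed-fixed block of the inverse MME
  L <- matrix(0, n_g, length(beta))
  L[, 1] <- 1
  for (i in seq_len(n_g - 1)) L[i, p_fix + i] <- 1
  L[n_g, (p_fix + 1):length(beta)] <- -1
  se <- sqrt(rowSums((L %*% fit$C_fix) * L))
  vc <- fit$sigma2
  lambda <- vc[["residual"]] / vc[names(basis$Z)]
  structure(list(
    blues = setNames(mu + g_eff, levels(geno)),
    se = setNames(se, levels(geno)),
    intercept = mu,
    genotype_effects = g_eff,
    beta_spatial = setNames(beta[2:p_fix], colnames(basis$X)[-1]),
    coef_random = fit$u,
    var_comp = vc,
    lambda = lambda,
    fitted = fit$fitted,
    residuals = y - fit$fitted,
    loglik_trace = fit$ll_trace,
    converged = fit$converged,
    n_knots = basis$n_knots,
    effective_dims = fit$ed),
    class = "spatial_fit")
}

# REML for y = X beta + sum_k Z_k u_k + eps, u_k ~ N(0, sigma2_k I), via
# fixed-point updates sigma2_k = u_k'u_k / ED_k on Henderson's equations
# (ED_k the effective dimension of block k), monitored by the restricted
# log-likelihood; in practice monotone and much faster than EM.
sap_reml <- function(y, X, Zlist, tol = 1e-6, max_iter = 200,
                     floor_frac = 1e-10) {
  n <- length(y)
  p <- ncol(X)
  qk <- vapply(Zlist, ncol, integer(1))
  W <- cbind(X, do.call(cbind, Zlist))
  M <- crossprod(W)
  rhs <- crossprod(W, y)
  yty <- sum(y^2)
  ublocks <- split(p + seq_len(sum(qk)), rep(seq_along(qk), qk))
  vy <- var(y)
  stop_if(vy < 1e-14, "response has (numerically) zero variance")
  s2e <- vy / 2
  s2k <- rep(vy / (2 * length(Zlist)), length(Zlist))
  names(s2k) <- names(Zlist)
  floor_v <- floor_frac * vy
  ll_trace <- numeric(0)
  converged <- FALSE
  last_dll <- NA_real_
  for (it in seq_len(max_iter)) {
    D <- rep(0, ncol(W))
    for (k in seq_along(qk)) D[ublocks[[k]]] <- s2e / s2k[k]
    A <- M
    diag(A) <- diag(A) + D
    ch <- chol(A)
    theta <- backsolve(ch, forwardsolve(t(ch), rhs))
    Ainv <- chol2inv(ch)
    ypy <- (yty - sum(theta * rhs)) / s2e
    ll <- -0.5 * (n * log(s2e) + sum(qk * log(s2k)) +
                    2 * sum(log(diag(ch))) - (p + sum(qk)) * log(s2e) + ypy)
    ll_trace <- c(ll_trace, ll)
    if (it > 1) {
      last_dll <- ll - ll_trace[it - 1]
      if (abs(last_dll) < tol) { converged <- TRUE; break }
    }
    fitted <- as.vector(W %*% theta)
    rss <- sum((y - fitted)^2)
    ed <- numeric(length(qk))
    s2k_new <- s2k
    for (k in seq_along(qk)) {
      ix <- ublocks[[k]]
      trk <- s2e * sum(diag(Ainv)[ix])
      uk <- theta[ix]
      ed[k] <- qk[k] - trk / s2k[k]
      s2k_new[k] <- max(sum(uk^2) / max(ed[k], 1e-8), floor_v)
    }
    s2e <- max(rss / (n - p - sum(ed)), 1e-8 * vy)
    s2k <- s2k_new
  }
  fitted <- as.vector(W %*% theta)
  ed <- numeric(length(qk))
  for (k in seq_along(qk)) {
    trk <- s2e * sum(diag(Ainv)[ix <- ublocks[[k]]])
    ed[k] <- qk[k] - trk / s2k[k]
  }
  list(beta = theta[seq_len(p)],
       u = lapply(ublocks, function(ix) theta[ix]),
       sigma2 = c(s2k, residual = s2e),
       fitted = fitted,
       C_fix = s2e * Ainv[seq_len(p), seq_len(p), drop = FALSE],
       ll_trace = ll_trace, converged = converged, last_dll = last_dll,
       ed = setNames(ed, names(Zlist)))
}

#' Assemble genotype BLUEs across environments
#'
#' Collects the adjusted genotype means from per-environment spatial fits
#' into a genotype x environment matrix. If a genomic relationship matrix is
#' supplied, the exclusion rule (lines missing in two or more environments
#' are dropped) and kinship imputation of single-environment gaps are then
#' applied via \code{\link{impute_phenotypes_by_kin}}.
#'
#' @param fits named list of \code{spatial_fit} objects, one per environment
#'   (names become column names).
#' @param K optional genomic relationship matrix for imputation.
#' @param k neighbours for kinship imputation.
#' @return list: \code{blues} (genotype x environment matrix), \code{se}
#'   (matching standard errors, NA where imputed or unobserved),
#'   \code{imputed} (logical matrix, when \code{K} given), \code{dropped}.
#' @export
extract_blues <- function(fits, K = NULL, k = 20) {
  stop_if(!length(fits), "no fits supplied")
  stop_if(is.null(names(fits)), "fits must be a named list (environments)")
  for (f in fits)
    if (!f$converged) warning("using a non-converged spatial fit")
  lines <- sort(unique(unlist(lapply(fits, function(f) names(f$blues)))))
  B <- SE <- matrix(NA_real_, length(lines), length(fits),
                    dimnames = list(lines, names(fits)))
  for (j in seq_along(fits)) {
    B[names(fits[[j]]$blues), j] <- fits[[j]]$blues
    SE[names(fits[[j]]$se), j] <- fits[[j]]$se
  }
  if (is.null(K))
    return(list(blues = B, se = SE, imputed = NULL, dropped = character(0)))
  imp <- impute_phenotypes_by_kin(B, K, k = k)
  list(blues = imp$blues, se = SE[rownames(imp$blues), , drop = FALSE],
       imputed = imp$imputed, dropped = imp$dropped)
}
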