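# Multi-kernel Gibbs sampler. The response is laid out as an n x J matrix
# (lines x environments; J = 1 for a single environment), records in
# column-major (environment-major) order. Each random term has a separable
# covariance (col_kernel %x% row_kernel) * sigma2_t over vec(Y); supplying
# the eigendecomposition of each factor lets the sampler update every
# coefficient from an independent normal full conditional after rotating
# the residual into the term's eigenbasis. Scalar variances get scaled
# inverse chi-square updates; missing responses are handled by data
# augmentation (sampled from their predictive distribution each sweep, so
# held-out cells never enter the likelihood of the observed data).

#' Define a random term for the Gibbs engine
#'
#' A term's covariance over the vectorized n x J response is
#' \code{(col_kernel \%x\% row_kernel) * sigma2}. Kernels may be passed as
#' symmetric matrices (eigendecomposed here, near-zero eigenvalues dropped)
#' or as precomputed decompositions \code{list(vectors, values)} to share
#' one decomposition across terms.
#'
#' @param label term name (also names its variance component).
#' @param row_kernel n x n kernel among lines (matrix or eigen list).
#' @param col_kernel J x J kernel among environments (matrix or eigen
#'   list); default scalar 1 for single-column responses.
#' @return object of class \code{kernel_term}.
#' @export
kernel_term <- function(label, row_kernel, col_kernel = NULL) {
  as_eig <- function(K) {
    if (is.list(K)) return(K)
    stop_if(!isSymmetric(unname(K), tol = 1e-8), "kernel must be symmetric")
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    stop_if(min(ev) < -1e-6 * max(abs(ev), 1),
            sprintf("kernel for term '%s' is not PSD", label))
    eigen_trim(K)
  }
  row_e <- as_eig(row_kernel)
  col_e <- if (is.null(col_kernel)) {
    list(vectors = matrix(1, 1, 1), values = 1)
  } else as_eig(col_kernel)
  structure(list(label = label, row = row_e, col = col_e),
            class = "kernel_term")
}

#' Dense covariance matrix implied by a term (vec layout)
#' @param term a \code{\link{kernel_term}}.
#' @return NJ x NJ symmetric matrix \code{col \%x\% row}.
#' @export
term_covariance <- function(term) {
  Kr <- term$row$vectors %*% (term$row$values * t(term$row$vectors))
  Kc <- term$col$vectors %*% (term$col$values * t(term$col$vectors))
  Kc %x% Kr
}

#' MCMC settings
#'
#' @param n_iter total Gibbs iterations (default 20000).
#' @param burn_in discarded iterations (default 8000).
#' @param thin thinning interval (default 5).
#' @param seed RNG seed.
#' @param df0 prior degrees of freedom for every scalar variance.
#' @param R2 prior share of phenotypic variance assigned to the model
#'   (split equally over terms) when setting prior scales.
#' @param iw_df inverse-Wishart prior degrees of freedom for unstructured
#'   covariance matrices (multi-trait models). \code{NULL} (default) uses
#'   \code{J + 2} for a J x J covariance. Setting \code{iw_df = df0 + J - 1}
#'   makes the implied per-trait marginal prior identical to the scalar
#'   scaled-inverse-chi-square prior (exactly so at \code{J = 1}).
#' @param iw_scale diagonal of the inverse-Wishart prior scale matrix
#'   (scalar or length-J vector). \code{NULL} (default) sets it so the
#'   implied marginal prior mode per trait equals the same share of
#'   phenotypic variance used for scalar variances.
#' @return list of class \code{mcmc_config}.
#' @export
mcmc_config <- function(n_iter = 20000, burn_in = 8000, thin = 5,
                        seed = 1L, df0 = 5, R2 = 0.5,
                        iw_df = NULL, iw_scale = NULL) {
  stop_if(burn_in >= n_iter, "burn_in must be smaller than n_iter")
  stop_if(thin < 1, "thin must be >= 1")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 df0 = df0, R2 = R2, iw_df = iw_df, iw_scale = iw_scale),
            class = "mcmc_config")
}

rinvchisq <- function(df, scale) df * scale / rchisq(1, df)

#' Gibbs sampler for Gaussian multi-kernel regression
#'
#' Fits \code{vec(Y) = X beta + sum_t g_t + eps} with
#' \code{g_t ~ N(0, (col_t \%x\% row_t) sigma2_t)} and
#' \code{eps ~ N(0, I sigma2_eps)}. Fixed effects default to a single
#' intercept. Missing cells of \code{Y} are imputed by data augmentation
#' and reported as predictions.
#'
#' @param Y numeric vector (treated as n x 1) or n x J matrix; NA = cell to
#'   predict.
#' @param terms list of \code{\link{kernel_term}}s.
#' @param mcmc a \code{\link{mcmc_config}}.
#' @param X optional fixed-effect design over records (vec order); default
#'   intercept. Per-environment intercepts: \code{env_intercepts = TRUE}.
#' @param env_intercepts fit one intercept per column of Y instead of a
#'   single overall mean.
#' @param fixed_variances named numeric; variances to hold fixed (names
#'   among term labels and "residual"); their updates are skipped.
#' @return object of class \code{menvgp_fit}: posterior means of effects
#'   per term (n x J matrices), \code{beta}, \code{fitted} (n x J posterior
#'   mean of the linear predictor), \code{predictions} (fitted values at
#'   originally missing cells), \code{var_samples} (kept draws of every
#'   variance), posterior-mean variances \code{var_comp}, and bookkeeping.
#' @export
gibbs_multikernel <- function(Y, terms, mcmc = mcmc_config(), X = NULL,
                              env_intercepts = FALSE,
                              fixed_variances = NULL) {
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1)
  n <- nrow(Y); J <- ncol(Y); N <- n * J
  # terms may be empty: intercept-plus-residual model
  labs <- vapply(terms, function(t) t$label, character(1))
  stop_if(anyDuplicated(labs) > 0, "term labels must be unique")
  for (t in terms)
    stop_if(nrow(t$row$vectors) != n || nrow(t$col$vectors) != J,
            sprintf("kernel dimensions of term '%s' do not match Y",
                    t$label))
  miss <- is.na(Y)
  y_obs <- Y[!miss]
  stop_if(length(y_obs) < 2, "need at least two observed responses")
  stop_if(length(terms) > 0 && var(y_obs) < 1e-14,
          "observed response is degenerate (zero variance)")
  vy <- max(var(y_obs), 1e-12)
  if (is.null(X)) {
    X <- if (env_intercepts && J > 1) {
      kronecker(diag(J), matrix(1, n, 1))
    } else matrix(1, N, 1)
  }
  XtXi <- chol2inv(chol(crossprod(X)))
  cholXtXi <- chol(XtXi)
  df0 <- mcmc$df0
  # prior scales: equal split of R2 * var(y) across terms, adjusted for the
  # mean kernel eigenvalue so the prior mode refers to effect variance on
  # the phenotype scale (BGLR-style)
  S0 <- vapply(terms, function(t) {
    md <- mean(outer(t$row$values, t$col$values))
    vy * mcmc$R2 / length(terms) * (df0 + 2) / df0 / md
  }, numeric(1))
  names(S0) <- labs
  S0e <- vy * (1 - mcmc$R2) * (df0 + 2) / df0
  fixed <- names(fixed_variances %||% numeric(0))
  s2 <- setNames(rep(vy * mcmc$R2 / length(terms), length(terms)), labs)
  s2e <- vy * (1 - mcmc$R2)
  for (nm in fixed) {
    if (nm == "residual") s2e <- fixed_variances[[nm]]
    else if (nm %in% labs) s2[nm] <- fixed_variances[[nm]]
    else stop("unknown fixed variance: ", nm)
  }
  set.seed(mcmc$seed)
  # state
  Ycur <- Y
  if (any(miss)) Ycur[miss] <- mean(y_obs)
  G <- lapply(terms, function(t) matrix(0, n, J))   # effect of each term
  Delta <- lapply(terms, function(t)
    matrix(0, length(t$row$values), length(t$col$values)))
  beta <- rep(0, ncol(X)); beta[1] <- mean(y_obs)
  keep <- seq(mcmc$burn_in + mcmc$thin, mcmc$n_iter, by = mcmc$thin)
  n_keep <- length(keep)
  var_samples <- matrix(NA_real_, n_keep, length(terms) + 1,
                        dimnames = list(NULL, c(labs, "residual")))
  G_sum <- lapply(terms, function(t) matrix(0, n, J))
  beta_sum <- rep(0, ncol(X))
  eta_sum <- matrix(0, n, J)
  kidx <- 0
  Xb <- matrix(as.vector(X %*% beta), n, J)
  for (it in seq_len(mcmc$n_iter)) {
    # fixed effects (flat prior)
    resid_f <- Ycur - Reduce(`+`, G, matrix(0, n, J))
    bhat <- XtXi %*% crossprod(X, as.vector(resid_f))
    beta <- as.vector(bhat + t(cholXtXi) %*% rnorm(ncol(X)) * sqrt(s2e))
    Xb <- matrix(as.vector(X %*% beta), n, J)
    # random terms
    for (t in seq_along(terms)) {
      tm <- terms[[t]]
      R_part <- Ycur - Xb - Reduce(`+`, G[-t], matrix(0, n, J))
      Tm <- crossprod(tm$row$vectors, R_part) %*% tm$col$vectors
      dvar <- outer(tm$row$values, tm$col$values) * s2[t]
      prec <- 1 / s2e + 1 / dvar
      mu_d <- (Tm / s2e) / prec
      Delta[[t]] <- mu_d + matrix(rnorm(length(prec)), nrow(prec)) /
        sqrt(prec)
      G[[t]] <- tm$row$vectors %*% Delta[[t]] %*% t(tm$col$vectors)
      if (!(labs[t] %in% fixed)) {
        ss <- sum(Delta[[t]]^2 / outer(tm$row$values, tm$col$values))
        qt <- length(Delta[[t]])
        s2[t] <- rinvchisq(df0 + qt, (ss + df0 * S0[t]) / (df0 + qt))
      }
    }
    eta <- Xb + Reduce(`+`, G, matrix(0, n, J))
    # residual variance (observed + augmented residuals)
    if (!("residual" %in% fixed)) {
      e <- Ycur - eta
      s2e <- rinvchisq(df0 + N, (sum(e^2) + df0 * S0e) / (df0 + N))
    }
    # data augmentation for missing cells
    if (any(miss))
      Ycur[miss] <- eta[miss] + rnorm(sum(miss), 0, sqrt(s2e))
    if (it %in% keep) {
      kidx <- kidx + 1
      var_samples[kidx, ] <- c(s2, s2e)
      for (t in seq_along(terms)) G_sum[[t]] <- G_sum[[t]] + G[[t]]
      beta_sum <- beta_sum + beta
      eta_sum <- eta_sum + eta
    }
  }
  G_mean <- lapply(G_sum, function(g) g / n_keep)
  names(G_mean) <- labs
  fitted <- eta_sum / n_keep
  dimnames(fitted) <- dimnames(Y)
  structure(list(
    effects = G_mean,
    beta = beta_sum / n_keep,
    fitted = fitted,
    predictions = fitted[miss],
    missing = miss,
    var_samples = var_samples,
    var_comp = colMeans(var_samples),
    n_samples = n_keep,
    mcmc = mcmc,
    dim = c(n = n, J = J)),
    class = "menvgp_fit")
}

#' Closed-form BLUP for a multi-kernel model (oracle)
#'
#' Solves the mixed model \code{vec(Y) = X beta + sum_t g_t + eps} exactly
#' at known variances via the phenotypic covariance
#' \code{V = sum_t K_t sigma2_t + I sigma2_eps}: GLS fixed effects and
#' \code{g_t = sigma2_t K_t V^{-1} (y - X beta)}. Missing cells are excluded
#' from the system and predicted from the estimated effects.
#'
#' @param Y vector or n x J matrix (NA = predict).
#' @param terms list of \code{\link{kernel_term}}s.
#' @param variances named numeric: one entry per term label plus
#'   \code{residual}, all > 0.
#' @param X,env_intercepts as in \code{\link{gibbs_multikernel}}.
#' @return list: \code{beta}, per-term effect matrices \code{effects},
#'   \code{fitted} (n x J linear predictor incl. predictions at missing
#'   cells), \code{predictions}.
#' @export
blup_closed_form <- function(Y, terms, variances, X = NULL,
                             env_intercepts = FALSE) {
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1)
  n <- nrow(Y); J <- ncol(Y); N <- n * J
  labs <- vapply(terms, function(t) t$label, character(1))
  stop_if(!all(c(labs, "residual") %in% names(variances)),
          "variances must name every term and 'residual'")
  stop_if(any(unlist(variances[c(labs, "residual")]) <= 0),
          "variances must be positive")
  if (is.null(X)) {
    X <- if (env_intercepts && J > 1) {
      kronecker(diag(J), matrix(1, n, 1))
    } else matrix(1, N, 1)
  }
  Ks <- lapply(terms, term_covariance)
  obs <- which(!is.na(as.vector(Y)))
  V <- diag(variances[["residual"]], length(obs))
  for (t in seq_along(terms))
    V <- V + variances[[labs[t]]] * Ks[[t]][obs, obs, drop = FALSE]
  Vi <- chol2inv(chol(V))
  Xo <- X[obs, , drop = FALSE]
  yo <- as.vector(Y)[obs]
  XtVi <- crossprod(Xo, Vi)
  beta <- solve(XtVi %*% Xo, XtVi %*% yo)
  r <- Vi %*% (yo - Xo %*% beta)
  eff <- vector("list", length(terms))
  eta <- as.vector(X %*% beta)
  for (t in seq_along(terms)) {
    g <- variances[[labs[t]]] * Ks[[t]][, obs, drop = FALSE] %*% r
    eff[[t]] <- matrix(as.vector(g), n, J)
    eta <- eta + as.vector(g)
  }
  names(eff) <- labs
  fitted <- matrix(eta, n, J, dimnames = dimnames(Y))
  list(beta = as.vector(beta), effects = eff, fitted = fitted,
       predictions = fitted[is.na(Y)])
}
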