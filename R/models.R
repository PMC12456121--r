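# The five genomic prediction models. All share the response layout
# "lines x environments" and predict NA cells by data augmentation.
#
#   gblup  : y = 1 mu + g + e,           g ~ N(0, K s2g)       (one env)
#   gxc    : y = mu + g + E + w + gE + gw + e   (reaction norm, EC kernel)
#   mxe    : y = mu_j + u0 + u1 + e,     u0 main across envs,
#            u1 environment-specific, each env its own variance
#   mtm1   : y = mu_j + u + e,           vec(u) ~ N(0, E %x% K), E unstructured
#   mtm2   : mtm1 + f,                   vec(f) ~ N(0, F %x% I)

ones_kernel <- function(n) list(vectors = matrix(1 / sqrt(n), n, 1),
                                values = n)
ident_kernel <- function(J) list(vectors = diag(J), values = rep(1, J))
unit_kernel <- function(j, J) {
  v <- matrix(0, J, 1); v[j, 1] <- 1
  list(vectors = v, values = 1)
}

#' Single-environment GBLUP
#'
#' @param y named numeric vector of adjusted means for one environment
#'   (names = line ids, order matching \code{K}); NA = predict.
#' @param K genomic relationship matrix.
#' @param mcmc a \code{\link{mcmc_config}}.
#' @return \code{menvgp_fit} with variance components \code{g} and
#'   \code{residual} and \code{model = "gblup"}.
#' @export
fit_gblup_single_env <- function(y, K, mcmc = mcmc_config()) {
  stop_if(length(y) != nrow(K), "y and K dimensions differ")
  fit <- gibbs_multikernel(y, list(kernel_term("g", K)), mcmc)
  fit$model <- "gblup"
  fit
}

#' Genotype-by-covariate (reaction norm) model
#'
#' Random terms over the stacked line x environment records: genetic main
#' effect (covariance \code{J_J \%x\% K}), environment main effect
#' (\code{I_J \%x\% ones}), environmental-covariate effect
#' (\code{Omega \%x\% ones}), the genetic-by-environment Hadamard
#' interaction (\code{I_J \%x\% K}) and the genetic-by-covariate
#' interaction (\code{Omega \%x\% K}), plus a homogeneous residual.
#'
#' @param blues n x J matrix of adjusted means (NA = predict), columns in
#'   the order of \code{Omega}.
#' @param K genomic relationship matrix (n x n).
#' @param Omega environment kernel from \code{\link{ec_kernel}} (J x J).
#' @param mcmc a \code{\link{mcmc_config}}.
#' @return \code{menvgp_fit}, variance components \code{g, E, w, gE, gw,
#'   residual}.
#' @export
fit_gxc <- function(blues, K, Omega, mcmc = mcmc_config()) {
  n <- nrow(blues); J <- ncol(blues)
  stop_if(J < 2, "the reaction-norm model needs at least two environments")
  stop_if(nrow(Omega) != J, "Omega must match the environments of blues")
  if (!is.null(colnames(blues)) && !is.null(rownames(Omega)))
    stop_if(!all(colnames(blues) %in% rownames(Omega)),
            "environment in phenotypes absent from Omega")
  ev_om <- eigen(Omega, symmetric = TRUE, only.values = TRUE)$values
  stop_if(max(ev_om) <= 1e-10 || min(ev_om) < -1e-6 * max(ev_om),
          "Omega is degenerate or not PSD")
  eigK <- eigen_trim(K)
  eigOm <- eigen_trim(Omega)
  terms <- list(
    kernel_term("g",  eigK,            ones_kernel(J)),
    kernel_term("E",  ones_kernel(n),  ident_kernel(J)),
    kernel_term("w",  ones_kernel(n),  eigOm),
    kernel_term("gE", eigK,            ident_kernel(J)),
    kernel_term("gw", eigK,            eigOm))
  fit <- gibbs_multikernel(blues, terms, mcmc)
  fit$model <- "gxc"
  fit
}

#' Marker-by-environment interaction model (GBLUP parameterization)
#'
#' Decomposes the genetic effect into a main component shared by all
#' environments (covariance \code{J_J \%x\% K} with variance sigma2_u0)
#' and environment-specific deviations (block-diagonal \code{K} with one
#' variance per environment), with per-environment intercepts.
#'
#' @param blues n x J matrix of adjusted means (NA = predict).
#' @param K genomic relationship matrix.
#' @param mcmc a \code{\link{mcmc_config}}.
#' @param parameterization only \code{"gblup"} is sampled; the equivalent
#'   ridge-regression form is available through
#'   \code{\link{mxe_ridge_blup}} for cross-checking.
#' @return \code{menvgp_fit}, variance components \code{main},
#'   \code{specific_<env>}, \code{residual}.
#' @export
fit_mxe <- function(blues, K, mcmc = mcmc_config(),
                    parameterization = c("gblup", "ridge")) {
  parameterization <- match.arg(parameterization)
  stop_if(parameterization == "ridge",
          "the sampled model uses the GBLUP parameterization; see mxe_ridge_blup")
  n <- nrow(blues); J <- ncol(blues)
  stop_if(is.null(dim(blues)) || J < 2,
          "the marker-by-environment model is undefined for one environment")
  envs <- colnames(blues) %||% env_names(J)
  eigK <- eigen_trim(K)
  terms <- c(list(kernel_term("main", eigK, ones_kernel(J))),
             lapply(seq_len(J), function(j)
               kernel_term(paste0("specific_", envs[j]), eigK,
                           unit_kernel(j, J))))
  fit <- gibbs_multikernel(blues, terms, mcmc, env_intercepts = TRUE)
  fit$model <- "mxe"
  fit$envs <- envs
  fit
}

#' Multi-trait model with unstructured environment covariance
#'
#' Treats each environment as a trait: \code{Y = ones \%*\% t(mu) + U (+ F) + Eps}
#' with \code{vec(U) ~ N(0, E \%x\% K)} for an unstructured J x J genetic
#' covariance E (inverse-Wishart updates), optionally an extra component
#' \code{vec(F_mat) ~ N(0, F \%x\% I)} capturing genetic variability not
#' tracked by markers (MTM2), and homogeneous residual variance.
#'
#' @param blues n x J matrix (NA = predict).
#' @param K genomic relationship matrix; ridge-stabilized before inversion.
#' @param mcmc a \code{\link{mcmc_config}}.
#' @param extra_component logical; TRUE fits MTM2.
#' @param ridge diagonal stabilizer added to K.
#' @return object of class \code{menvgp_mtm}: posterior means \code{U}
#'   (and \code{F_mat}), \code{E_mean}, \code{E_samples} (J x J x kept),
#'   \code{F_mean}/\code{F_samples} when applicable, \code{mu},
#'   \code{var_samples} (residual), \code{fitted}, \code{predictions}.
#' @export
fit_mtm <- function(blues, K, mcmc = mcmc_config(), extra_component = FALSE,
                    ridge = 1e-6) {
  Y <- as.matrix(blues)
  n <- nrow(Y); J <- ncol(Y)
  stop_if(nrow(K) != n, "K must match the rows of blues")
  Kr <- K + diag(ridge, n)
  eK <- eigen(Kr, symmetric = TRUE)
  stop_if(min(eK$values) <= 0, "K numerically singular even after ridge")
  V <- eK$vectors; d <- eK$values
  miss <- is.na(Y)
  y_obs <- Y[!miss]
  vy <- apply(Y, 2, function(col) var(col[!is.na(col)]))
  vy[is.na(vy) | vy < 1e-12] <- var(y_obs)
  df0 <- mcmc$df0
  # inverse-Wishart prior E ~ IW(nu0, S0E). Default nu0 = J + 2; the scale
  # is set so the implied per-trait marginal, a scaled-inv-chi-square with
  # nu0 - J + 1 df and mode S0E_jj / (nu0 - J + 3), has its mode at the
  # same share of phenotypic variance used for scalar variances (mean
  # kernel eigenvalue adjustment as in gibbs_multikernel). With
  # iw_df = df0 + J - 1 the marginal is *identical* to the engine's scalar
  # prior, and at J = 1 the whole prior is (IW(nu, S) at J = 1 is
  # Inv-Gamma(nu/2, S/2)).
  nu0 <- mcmc$iw_df %||% (J + 2)
  stop_if(nu0 <= J - 1, "iw_df must exceed J - 1 for a proper prior")
  shareE <- if (extra_component) 0.3 else 0.5
  s0e_diag <- if (is.null(mcmc$iw_scale)) {
    (nu0 - J + 3) * shareE * vy / mean(d)
  } else rep_len(mcmc$iw_scale, J)
  S0E <- diag(s0e_diag, J)
  if (J == 1) S0E <- matrix(s0e_diag, 1, 1)
  s0f_diag <- (nu0 - J + 3) * 0.2 * vy
  S0F <- diag(s0f_diag, J)
  if (J == 1) S0F <- matrix(s0f_diag, 1, 1)
  S0e <- var(y_obs) * 0.5 * (df0 + 2) / df0
  set.seed(mcmc$seed)
  Ycur <- Y
  if (any(miss)) Ycur[miss] <- mean(y_obs)
  U <- matrix(0, n, J); Fm <- matrix(0, n, J)
  Emat <- diag(shareE * vy, J); if (J == 1) Emat <- matrix(shareE * vy, 1, 1)
  Fmat <- diag(0.2 * vy, J); if (J == 1) Fmat <- matrix(0.2 * vy, 1, 1)
  s2e <- var(y_obs) * 0.5
  mu <- colMeans(Y, na.rm = TRUE)
  keep <- seq(mcmc$burn_in + mcmc$thin, mcmc$n_iter, by = mcmc$thin)
  n_keep <- length(keep)
  E_samples <- array(NA_real_, c(J, J, n_keep))
  F_samples <- if (extra_component) array(NA_real_, c(J, J, n_keep)) else NULL
  s2e_samples <- numeric(n_keep)
  U_sum <- matrix(0, n, J); F_sum <- matrix(0, n, J)
  mu_sum <- numeric(J); eta_sum <- matrix(0, n, J)
  kidx <- 0
  sample_matrix_effect <- function(Rmat, rowvals, Cov) {
    # vec(effect) ~ N(0, Cov %x% (V diag(rowvals) V')) prior, iid s2e noise;
    # Rmat already in the V-rotated row space when rowvals given, else raw.
    eC <- eigen(Cov, symmetric = TRUE)
    lam <- pmax(eC$values, 1e-12)
    Tm <- Rmat %*% eC$vectors
    prec <- 1 / s2e + 1 / outer(rowvals, lam)
    Dm <- (Tm / s2e) / prec +
      matrix(rnorm(length(prec)), nrow(prec)) / sqrt(prec)
    Dm %*% t(eC$vectors)
  }
  for (it in seq_len(mcmc$n_iter)) {
    # per-environment intercepts
    R0 <- Ycur - U - Fm
    mu <- colMeans(R0) + rnorm(J, 0, sqrt(s2e / n))
    Mu <- matrix(mu, n, J, byrow = TRUE)
    # U in the eigenbasis of K
    Rt <- crossprod(V, Ycur - Mu - Fm)
    Ut <- sample_matrix_effect(Rt, d, Emat)
    U <- V %*% Ut
    # E | U  ~ IW(nu0 + n, S0E + U' K^-1 U)
    SE <- S0E + crossprod(Ut / sqrt(d))
    Emat <- chol2inv(chol(rWishart(1, nu0 + n, chol2inv(chol(SE)))[, , 1]))
    if (extra_component) {
      Rf <- Ycur - Mu - U
      Fm <- sample_matrix_effect(Rf, rep(1, n), Fmat)
      SF <- S0F + crossprod(Fm)
      Fmat <- chol2inv(chol(rWishart(1, nu0 + n,
                                     chol2inv(chol(SF)))[, , 1]))
    }
    eta <- Mu + U + Fm
    e <- Ycur - eta
    s2e <- rinvchisq(df0 + n * J,
                     (sum(e^2) + df0 * S0e) / (df0 + n * J))
    if (any(miss))
      Ycur[miss] <- eta[miss] + rnorm(sum(miss), 0, sqrt(s2e))
    if (it %in% keep) {
      kidx <- kidx + 1
      E_samples[, , kidx] <- Emat
      if (extra_component) F_samples[, , kidx] <- Fmat
      s2e_samples[kidx] <- s2e
      U_sum <- U_sum + U; F_sum <- F_sum + Fm
      mu_sum <- mu_sum + mu; eta_sum <- eta_sum + eta
    }
  }
  fitted <- eta_sum / n_keep
  dimnames(fitted) <- dimnames(Y)
  structure(list(
    model = if (extra_component) "mtm2" else "mtm1",
    U = U_sum / n_keep,
    F_mat = if (extra_component) F_sum / n_keep else NULL,
    mu = mu_sum / n_keep,
    E_mean = apply(E_samples, c(1, 2), mean),
    E_samples = E_samples,
    F_mean = if (extra_component) apply(F_samples, c(1, 2), mean) else NULL,
    F_samples = F_samples,
    var_samples = cbind(residual = s2e_samples),
    fitted = fitted,
    predictions = fitted[miss],
    missing = miss,
    envs = colnames(Y) %||% env_names(J),
    n_samples = n_keep,
    mcmc = mcmc),
    class = "menvgp_mtm")
}

# Posterior summaries --------------------------------------------------------

#' Genomic heritability
#'
#' Per-environment genomic heritability sigma2_g / (sigma2_g + sigma2_eps),
#' computed per posterior sample and averaged. For single-environment GBLUP
#' this uses the \code{g} variance; for multi-trait fits the diagonal of the
#' genetic covariance E.
#'
#' @param fit a \code{menvgp_fit} from \code{\link{fit_gblup_single_env}} or
#'   a \code{menvgp_mtm}.
#' @return named numeric vector of heritabilities in [0, 1].
#' @export
heritability <- function(fit) {
  if (inherits(fit, "menvgp_mtm")) {
    J <- nrow(fit$E_mean)
    s2e <- fit$var_samples[, "residual"]
    h2 <- vapply(seq_len(J), function(j)
      mean(fit$E_samples[j, j, ] / (fit$E_samples[j, j, ] + s2e)),
      numeric(1))
    return(setNames(h2, fit$envs))
  }
  stop_if(!inherits(fit, "menvgp_fit"), "unsupported fit object")
  vs <- fit$var_samples
  glab <- if ("g" %in% colnames(vs)) "g" else "main"
  stop_if(!glab %in% colnames(vs), "fit has no genetic variance component")
  c(h2 = mean(vs[, glab] / (vs[, glab] + vs[, "residual"])))
}

#' Between-environment genetic correlations
#'
#' Converts each posterior draw of the unstructured genetic covariance E of
#' a multi-trait fit to a correlation matrix and averages; the diagonal is
#' exactly 1. Draws whose diagonal is not strictly positive are skipped and
#' counted.
#'
#' @param fit a \code{menvgp_mtm} from \code{\link{fit_mtm}}.
#' @return J x J symmetric correlation matrix, attribute
#'   \code{n_skipped} counting excluded draws.
#' @export
genetic_correlations <- function(fit) {
  stop_if(!inherits(fit, "menvgp_mtm"),
          "genetic correlations require a multi-trait fit")
  J <- nrow(fit$E_mean)
  acc <- matrix(0, J, J); n_ok <- 0; n_skip <- 0
  for (s in seq_len(dim(fit$E_samples)[3])) {
    Es <- fit$E_samples[, , s, drop = FALSE][, , 1]
    if (J == 1) Es <- matrix(Es, 1, 1)
    if (any(diag(Es) <= 0)) { n_skip <- n_skip + 1; next }
    acc <- acc + stats::cov2cor(Es)
    n_ok <- n_ok + 1
  }
  if (n_skip > 0) warning(n_skip, " non-PD posterior draws excluded")
  R <- acc / n_ok
  R <- (R + t(R)) / 2
  diag(R) <- 1
  dimnames(R) <- list(fit$envs, fit$envs)
  attr(R, "n_skipped") <- n_skip
  R
}

#' Variance-component proportions
#'
#' Each component's posterior-mean variance divided by the total including
#' the residual. For the reaction-norm and marker-by-environment models the
#' kernels average to a unit diagonal, so the raw variances are on a common
#' phenotypic scale.
#'
#' @param fit a \code{menvgp_fit}.
#' @return named proportions summing to 1.
#' @export
variance_proportions <- function(fit) {
  stop_if(!inherits(fit, "menvgp_fit"), "unsupported fit object")
  v <- fit$var_comp
  v / sum(v)
}
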