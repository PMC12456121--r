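# Ridge-regression parameterization of the marker-by-environment model:
# y_ij = mu_j + sum_k w_ijk (b0k + bjk) + e, with b0 ~ N(0, I s2_b0) the
# marker effects shared across environments and bj ~ N(0, I s2_bj) the
# environment-specific deviations. At matched variances this is the same
# model as the GBLUP parameterization with K = WW'/p, sigma2_u0 = p*s2_b0
# and sigma2_uj = p*s2_bj; solving it in marker space provides an
# independent route for checking that equivalence.

#' Closed-form ridge solution of the marker-by-environment model
#'
#' Solves Henderson's equations in marker-effect space (dimension
#' p*(J+1) plus J intercepts) at fixed variances and returns predictions
#' for every line x environment cell, including unobserved ones.
#'
#' @param Y n x J matrix of adjusted means (NA allowed; excluded from the
#'   system and predicted).
#' @param W n x p centered standardized marker matrix.
#' @param s2_b0 variance of the shared marker effects.
#' @param s2_b variance(s) of the environment-specific marker effects
#'   (scalar or length-J vector).
#' @param s2_e residual variance.
#' @return list: \code{mu} (per-environment intercepts), \code{b0},
#'   \code{b} (p x J specific effects), \code{fitted} (n x J),
#'   \code{predictions} at missing cells.
#' @export
mxe_ridge_blup <- function(Y, W, s2_b0, s2_b, s2_e) {
  Y <- as.matrix(Y)
  n <- nrow(Y); J <- ncol(Y); p <- ncol(W)
  stop_if(nrow(W) != n, "W must have one row per line")
  stop_if(J < 2, "needs at least two environments")
  s2_b <- rep(s2_b, length.out = J)
  stop_if(any(c(s2_b0, s2_b, s2_e) <= 0), "variances must be positive")
  obs <- !is.na(as.vector(Y))
  env_of <- rep(seq_len(J), each = n)
  line_of <- rep(seq_len(n), times = J)
  Xmu <- kronecker(diag(J), matrix(1, n, 1))[obs, , drop = FALSE]
  M0 <- W[line_of[obs], , drop = FALSE]
  Mlist <- lapply(seq_len(J), function(j) {
    Mj <- matrix(0, sum(obs), p)
    sel <- env_of[obs] == j
    Mj[sel, ] <- W[line_of[obs][sel], , drop = FALSE]
    Mj
  })
  Mfull <- cbind(Xmu, M0, do.call(cbind, Mlist))
  dinv <- c(rep(0, J), rep(s2_e / s2_b0, p),
            rep(s2_e / s2_b, each = p))
  A <- crossprod(Mfull)
  diag(A) <- diag(A) + dinv
  theta <- solve(A, crossprod(Mfull, as.vector(Y)[obs]))
  mu <- theta[seq_len(J)]
  b0 <- theta[J + seq_len(p)]
  b <- matrix(theta[-(seq_len(J + p))], p, J)
  fitted <- matrix(rep(mu, each = n), n, J) + as.vector(W %*% b0) + W %*% b
  dimnames(fitted) <- dimnames(Y)
  list(mu = mu, b0 = b0, b = b, fitted = fitted,
       predictions = fitted[is.na(Y)])
}

#' Closed-form GBLUP solution of the marker-by-environment model
#'
#' Kernel-space counterpart of \code{\link{mxe_ridge_blup}}: main effect
#' with covariance \code{J_J \%x\% K} and per-environment specific blocks,
#' solved by \code{\link{blup_closed_form}} at fixed variances.
#'
#' @param Y n x J matrix (NA = predict).
#' @param K genomic relationship matrix.
#' @param s2_u0 main-effect variance (equals \code{p * s2_b0} under
#'   \code{K = W W^T / p}).
#' @param s2_u specific-effect variance(s), scalar or length J.
#' @param s2_e residual variance.
#' @return as \code{\link{blup_closed_form}}.
#' @export
mxe_gblup_blup <- function(Y, K, s2_u0, s2_u, s2_e) {
  Y <- as.matrix(Y)
  n <- nrow(Y); J <- ncol(Y)
  s2_u <- rep(s2_u, length.out = J)
  eigK <- eigen_trim(K)
  terms <- c(list(kernel_term("main", eigK, ones_kernel(J))),
             lapply(seq_len(J), function(j)
               kernel_term(paste0("specific_", j), eigK, unit_kernel(j, J))))
  vars <- c(list(main = s2_u0),
            setNames(as.list(s2_u), paste0("specific_", seq_len(J))),
            list(residual = s2_e))
  blup_closed_form(Y, terms, vars, env_intercepts = TRUE)
}
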