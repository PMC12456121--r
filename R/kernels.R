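# Marker quality control, the VanRaden genomic relationship matrix, the
# environmental-covariate kernel, and kinship-based phenotype imputation.

maf_of <- function(col) {
  f <- mean(col, na.rm = TRUE) / 2
  min(f, 1 - f)
}

mean_impute <- function(G) {
  nas <- which(is.na(G))
  if (length(nas)) {
    cm <- colMeans(G, na.rm = TRUE)
    G[nas] <- cm[((nas - 1) %/% nrow(G)) + 1]
  }
  G
}

#' Marker quality control
#'
#' Applies three filters in order: (1) minor allele frequency
#' \eqn{\le} \code{maf_max_removed} (inclusive), (2) missing genotype rate
#' \eqn{\ge} \code{miss_max} (inclusive), (3) pairwise-correlation pruning at
#' \code{|r| >= corr_max} by a greedy left-to-right scan over marker order in
#' which the later marker of an offending pair is dropped. Correlations are
#' computed on per-marker mean-imputed dosages. The retained marker set does
#' not depend on line order.
#'
#' @param G lines x markers dosage matrix, entries in {0,1,2} or NA.
#' @param maf_max_removed markers with MAF at or below this are removed.
#' @param miss_max markers with missing rate at or above this are removed.
#' @param corr_max absolute-correlation threshold for pruning.
#' @return list with \code{genotypes} (filtered matrix) and \code{report}
#'   (counts removed per rule and retained marker ids).
#' @export
qc_markers <- function(G, maf_max_removed = 0.05, miss_max = 0.10,
                       corr_max = 0.99) {
  stop_if(is.null(colnames(G)), "G must have marker ids as colnames")
  bad_vals <- !(G %in% c(0, 1, 2) | is.na(G))
  stop_if(any(bad_vals), "dosages must be 0, 1, 2 or NA")
  maf <- apply(G, 2, maf_of)
  rm_maf <- maf <= maf_max_removed
  miss <- colMeans(is.na(G))
  rm_miss <- !rm_maf & miss >= miss_max
  keep <- !(rm_maf | rm_miss)
  rm_corr <- logical(ncol(G))
  idx <- which(keep)
  if (length(idx) > 1) {
    Gi <- mean_impute(G[, idx, drop = FALSE])
    Cm <- suppressWarnings(abs(cor(Gi)))
    Cm[is.na(Cm)] <- 1    # zero-variance columns count as duplicates
    dropped <- logical(length(idx))
    for (a in seq_along(idx)[-1]) {
      earlier <- which(!dropped[seq_len(a - 1)])
      if (length(earlier) && any(Cm[earlier, a] >= corr_max))
        dropped[a] <- TRUE
    }
    rm_corr[idx[dropped]] <- TRUE
    keep[idx[dropped]] <- FALSE
  }
  stop_if(!any(keep), "no markers survive quality control")
  list(genotypes = G[, keep, drop = FALSE],
       report = list(n_input = ncol(G),
                     n_removed_maf = sum(rm_maf),
                     n_removed_missing = sum(rm_miss),
                     n_removed_corr = sum(rm_corr),
                     retained_marker_ids = colnames(G)[keep]))
}

#' Center and standardize a dosage matrix
#'
#' Residual missing dosages are mean-imputed per marker, then each column is
#' centered to mean zero and scaled by its population (divide-by-n) standard
#' deviation, so every marker contributes unit variance to the relationship
#' matrix.
#'
#' @param G lines x markers dosage matrix.
#' @return W, same shape, columns with mean 0 and population SD 1.
#' @export
center_standardize <- function(G) {
  G <- mean_impute(G)
  mu <- colMeans(G)
  s <- sqrt(colMeans(G^2) - mu^2)
  stop_if(any(s < 1e-12),
          "zero-variance marker column; run qc_markers first")
  sweep(sweep(G, 2, mu, "-"), 2, s, "/")
}

#' VanRaden genomic relationship matrix
#'
#' \eqn{K = W W' / p} from the centered, standardized marker matrix W over
#' p markers. K is symmetric and positive semi-definite with grand sum zero
#' (column centering makes rows of K sum to zero over lines).
#'
#' @param W centered standardized marker matrix (see
#'   \code{\link{center_standardize}}).
#' @param p divisor; defaults to \code{ncol(W)}.
#' @return n x n genomic relationship matrix with line ids as dimnames.
#' @export
grm_vanraden <- function(W, p = ncol(W)) {
  stop_if(p <= 0, "p must be positive")
  K <- tcrossprod(W) / p
  K <- (K + t(K)) / 2
  dimnames(K) <- list(rownames(W), rownames(W))
  K
}

#' Environmental-covariate kernel
#'
#' Builds the environment similarity matrix Omega the same way as the
#' genomic relationship matrix but from environmental covariates: covariate
#' columns are centered and scaled to population SD 1 across environments,
#' then \eqn{\Omega = C C' / q} over the q covariates.
#'
#' @param ec data.frame or matrix of environments x covariates, rownames =
#'   environment ids, no missing values.
#' @return J x J symmetric PSD matrix with environment ids as dimnames.
#' @export
ec_kernel <- function(ec) {
  C <- as.matrix(ec)
  stop_if(nrow(C) < 2, "need at least two environments")
  stop_if(anyNA(C), "environmental covariates must be complete")
  s <- apply(C, 2, pop_sd)
  stop_if(any(s < 1e-12),
          "constant covariate column: kernel would be degenerate")
  Cs <- sweep(sweep(C, 2, colMeans(C), "-"), 2, s, "/")
  Om <- tcrossprod(Cs) / ncol(Cs)
  Om <- (Om + t(Om)) / 2
  dimnames(Om) <- list(rownames(ec), rownames(ec))
  Om
}

#' Kinship-based imputation of genotype-by-environment means
#'
#' Lines missing in two or more environments are removed. A remaining
#' missing cell (line i, environment j) is filled with the unweighted mean
#' of the adjusted means in environment j of the k lines most related to i
#' by the genomic relationship matrix (self excluded, only lines observed in
#' j eligible, ties broken by line order in K).
#'
#' @param blues genotype x environment matrix of adjusted means (NA =
#'   missing), rownames matching rownames of \code{K}.
#' @param K genomic relationship matrix covering at least the lines in
#'   \code{blues}.
#' @param k number of nearest relatives to average (default 20).
#' @return list: \code{blues} (complete matrix, excluded lines dropped),
#'   \code{imputed} (logical matrix), \code{dropped} (line ids removed).
#' @export
impute_phenotypes_by_kin <- function(blues, K, k = 20) {
  stop_if(is.null(rownames(blues)) || is.null(rownames(K)),
          "blues and K need rownames (line ids)")
  stop_if(!all(rownames(blues) %in% rownames(K)),
          "all lines in blues must appear in K")
  n_missing <- rowSums(is.na(blues))
  dropped <- rownames(blues)[n_missing >= 2]
  B <- blues[n_missing < 2, , drop = FALSE]
  imputed <- is.na(B)
  for (j in seq_len(ncol(B))) {
    miss_i <- which(is.na(B[, j]))
    if (!length(miss_i)) next
    donors <- rownames(B)[!is.na(B[, j])]
    stop_if(!length(donors), sprintf(
      "no observed lines in environment %s to impute from", colnames(B)[j]))
    for (i in miss_i) {
      id <- rownames(B)[i]
      kin <- K[id, donors]
      use_k <- min(k, length(donors))
      if (use_k < k)
        warning(sprintf(
          "line %s env %s: only %d eligible neighbours (k = %d requested)",
          id, colnames(B)[j], use_k, k))
      nb <- donors[order(-kin, match(donors, rownames(K)))][seq_len(use_k)]
      B[i, j] <- mean(B[nb, j])
    }
  }
  list(blues = B, imputed = imputed, dropped = dropped)
}
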