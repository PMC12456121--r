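# Cross-validation designs and model comparison. Three masking schemes:
#   single_env : within one environment, 20% of lines held out (repeated
#                random subsampling, per environment)
#   cv1        : 20% of lines hidden in EVERY environment (new lines)
#   cv2        : the same line fraction hidden, but each test line only in
#                a random nonempty proper subset of its observed
#                environments (sparse testing)

#' Build cross-validation plans
#'
#' @param lines character vector of line ids.
#' @param envs character vector of environment ids.
#' @param scheme one of \code{"single_env"}, \code{"cv1"}, \code{"cv2"}.
#' @param n_reps number of random replicates (default 100).
#' @param frac_test fraction of lines in the test set (default 0.2).
#' @param seed RNG seed; plans are reproducible given it.
#' @param observed optional logical lines x envs matrix; cv2 only hides
#'   cells that are observed and always leaves a test line observed
#'   somewhere.
#' @return list of plans, each a list with \code{scheme}, \code{replicate},
#'   \code{test_lines} and \code{masked} (logical lines x envs matrix).
#' @export
make_cv_plans <- function(lines, envs, scheme = c("single_env", "cv1", "cv2"),
                          n_reps = 100, frac_test = 0.2, seed = 1L,
                          observed = NULL) {
  scheme <- match.arg(scheme)
  stop_if(frac_test <= 0 || frac_test >= 1, "frac_test must be in (0,1)")
  n <- length(lines); J <- length(envs)
  n_test <- floor(frac_test * n)
  stop_if(n_test < 1, "too few lines for a nonempty test set")
  stop_if(scheme == "cv2" && J < 2, "cv2 needs at least two environments")
  if (is.null(observed))
    observed <- matrix(TRUE, n, J, dimnames = list(lines, envs))
  set.seed(seed)
  lapply(seq_len(n_reps), function(r) {
    test <- sort(sample(lines, n_test))
    masked <- matrix(FALSE, n, J, dimnames = list(lines, envs))
    if (scheme %in% c("single_env", "cv1")) {
      masked[test, ] <- TRUE
    } else {
      for (id in test) {
        obs_j <- which(observed[id, ])
        if (length(obs_j) < 2) next   # cannot hide and keep one observed
        n_hide <- sample(length(obs_j) - 1L, 1)
        masked[id, sample(obs_j, n_hide)] <- TRUE
      }
    }
    masked <- masked & observed
    list(scheme = scheme, replicate = r, test_lines = test, masked = masked)
  })
}

mask_blues <- function(blues, masked) {
  out <- blues
  out[masked[rownames(blues), colnames(blues)]] <- NA
  out
}

fit_and_predict <- function(blues_masked, model, K, Omega, mcmc) {
  switch(model,
         gxc  = fit_gxc(blues_masked, K, Omega, mcmc),
         mxe  = fit_mxe(blues_masked, K, mcmc),
         mtm1 = fit_mtm(blues_masked, K, mcmc, extra_component = FALSE),
         mtm2 = fit_mtm(blues_masked, K, mcmc, extra_component = TRUE),
         stop("unknown multi-environment model: ", model))
}

#' Run a cross-validation experiment
#'
#' For each plan, masks the held-out cells, fits the requested model on the
#' remaining data (held-out cells never enter the likelihood), predicts the
#' masked cells and scores Pearson's correlation between predictions and the
#' held-out adjusted means, per environment.
#'
#' @param blues complete genotype x environment matrix of adjusted means.
#' @param K genomic relationship matrix over the lines of \code{blues}.
#' @param model \code{"gblup"} (per environment) or one of \code{"gxc"},
#'   \code{"mxe"}, \code{"mtm1"}, \code{"mtm2"}.
#' @param plans list from \code{\link{make_cv_plans}}.
#' @param mcmc a \code{\link{mcmc_config}}; its seed is offset per
#'   replicate so chains are independent but reproducible.
#' @param Omega environment kernel (required for \code{model = "gxc"}).
#' @return data.frame of class \code{cv_result}: scheme, model, env,
#'   replicate, r (NA with a warning when fewer than 3 test observations),
#'   n_test.
#' @export
run_cv <- function(blues, K, model, plans, mcmc = mcmc_config(),
                   Omega = NULL) {
  stop_if(model == "gxc" && is.null(Omega), "gxc requires Omega")
  res <- vector("list", length(plans))
  for (pi in seq_along(plans)) {
    plan <- plans[[pi]]
    Bm <- mask_blues(blues, plan$masked)
    mcmc_r <- mcmc
    mcmc_r$seed <- mcmc$seed + 1000L * plan$replicate
    rows <- list()
    if (model == "gblup") {
      for (j in colnames(blues)) {
        yb <- Bm[, j]
        if (!any(is.na(yb))) next
        fit <- fit_gblup_single_env(yb, K, mcmc_r)
        pred <- fit$fitted[is.na(yb), 1]
        rows[[j]] <- score_env(plan, model, j, pred,
                               blues[is.na(yb), j])
      }
    } else {
      fit <- fit_and_predict(Bm, model, K, Omega, mcmc_r)
      for (j in colnames(blues)) {
        hide <- which(is.na(Bm[, j]) & !is.na(blues[, j]))
        if (!length(hide)) next
        pred <- fit$fitted[hide, j]
        rows[[j]] <- score_env(plan, model, j, pred, blues[hide, j])
      }
    }
    res[[pi]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("cv_result", class(out))
  out
}

score_env <- function(plan, model, env, pred, obs) {
  r <- if (length(obs) < 3) {
    warning(sprintf(
      "fewer than 3 test observations in %s (replicate %d); r set to NA",
      env, plan$replicate))
    NA_real_
  } else cor(pred, obs)
  data.frame(scheme = plan$scheme, model = model, env = env,
             replicate = plan$replicate, r = r, n_test = length(obs),
             stringsAsFactors = FALSE)
}

#' Summarize predictive ability
#'
#' Mean and SD of Pearson predictive ability per environment (and overall)
#' across replicates.
#'
#' @param cv a \code{cv_result} from \code{\link{run_cv}}.
#' @return data.frame: scheme, model, env ("all" row included), mean_r,
#'   sd_r, n_reps.
#' @export
summarize_cv <- function(cv) {
  by_env <- aggregate(r ~ scheme + model + env, data = cv,
                      FUN = function(x) c(mean = mean(x, na.rm = TRUE),
                                          sd = sd(x, na.rm = TRUE),
                                          n = sum(!is.na(x))))
  out <- data.frame(by_env[, 1:3],
                    mean_r = by_env$r[, "mean"], sd_r = by_env$r[, "sd"],
                    n_reps = by_env$r[, "n"])
  overall <- aggregate(r ~ scheme + model, data = cv, FUN = mean,
                       na.rm = TRUE)
  rbind(out, data.frame(scheme = overall$scheme, model = overall$model,
                        env = "all", mean_r = overall$r, sd_r = NA,
                        n_reps = NA))
}

#' Paired one-sided comparison of predictive abilities
#'
#' Tests whether a candidate model improves on a baseline using a paired
#' one-sided Wilcoxon signed-rank test and a paired one-sided t-test
#' (alternative: candidate > baseline), on vectors paired by environment
#' and replicate. The Wilcoxon test is exact for 25 or fewer nonzero pairs
#' and uses the continuity-corrected normal approximation otherwise; zero
#' differences are dropped, ties mid-ranked.
#'
#' @param pa_baseline,pa_candidate equal-length paired numeric vectors of
#'   predictive abilities.
#' @return list: p-values for both tests, mean improvement, percent
#'   improvement relative to the baseline mean, n pairs, and a
#'   \code{degenerate} flag when all differences are zero.
#' @export
compare_models <- function(pa_baseline, pa_candidate) {
  stop_if(length(pa_baseline) != length(pa_candidate),
          "paired vectors must have equal length")
  ok <- !(is.na(pa_baseline) | is.na(pa_candidate))
  b <- pa_baseline[ok]; a <- pa_candidate[ok]
  d <- a - b
  degenerate <- all(d == 0)
  if (degenerate) {
    p_w <- 1
    p_t <- 1
  } else {
    nz <- sum(d != 0)
    ties <- anyDuplicated(abs(d[d != 0])) > 0
    p_w <- suppressWarnings(stats::wilcox.test(
      a, b, paired = TRUE, alternative = "greater",
      exact = nz <= 25 && !ties, correct = TRUE)$p.value)
    p_t <- if (sd(d) < 1e-14) {
      warning("zero-variance nonzero differences; t-test degenerate")
      if (mean(d) > 0) 0 else 1
    } else stats::t.test(a, b, paired = TRUE,
                         alternative = "greater")$p.value
  }
  list(p_wilcoxon = p_w, p_ttest = p_t,
       mean_improvement = mean(d),
       percent_improvement = 100 * mean(d) / mean(b),
       n_pairs = length(d), degenerate = degenerate)
}
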