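#' Randomly split a shared control pool between two diseases
#'
#' The pooled controls are allocated to the two case cohorts as evenly as
#' possible (the larger half goes to disease 1 when the pool is odd),
#' uniformly at random, reproducibly by seed.
#'
#' @param control_ids Character or integer vector of control identifiers.
#' @param seed Integer seed.
#' @return List with `controls1` and `controls2`.
#' @export
split_controls <- function(control_ids, seed = 1L) {
  n <- length(control_ids)
  if (n < 2) stop("need at least 2 controls to split", call. = FALSE)
  set.seed(seed)
  perm <- sample(control_ids, n)
  n1 <- ceiling(n / 2)
  list(controls1 = sort(perm[seq_len(n1)]),
       controls2 = sort(perm[(n1 + 1):n]))
}

#' Bivariate AI-REML: genetic correlation between two disease cohorts
#'
#' Stacks the two cohorts (disjoint case sets, split controls) into one
#' mixed model with genetic variances for each trait, a genetic covariance
#' through the cross-cohort GRM block, and separate residual variances.
#' The residual covariance is structurally zero because no individual is
#' phenotyped for both traits. The genetic correlation is
#' `rG = s_g12 / sqrt(s2_g1 s2_g2)`, kept inside (-1, 1) by clipping the
#' covariance during optimization; its SE comes from the inverse
#' average-information matrix by the delta method. Significance of rG uses
#' a likelihood-ratio test against the model with the genetic covariance
#' fixed at zero (1-df chi-square). rG on the observed scale equals rG on
#' the liability scale, since the correlation is invariant to linear
#' rescaling of each phenotype.
#'
#' @param y1,y2 Binary phenotype vectors for the two cohorts (cohort 1 and
#'   cohort 2 samples respectively; cases = 1, their allocated controls = 0).
#' @param grm A `grm` (or plain matrix) computed over the combined cohort,
#'   rows/columns ordered as `c(cohort1, cohort2)`.
#' @param covariates Optional covariate matrix for the combined cohort
#'   (e.g. top 20 PCs recomputed on the pair); per-trait intercepts are
#'   always included.
#' @param tol,maxit Convergence controls passed to the AI-REML driver.
#' @return Object of class `bivar_fit`: variance components, `rG`, `rG_se`,
#'   `logL`, `logL0` (rG = 0), `lrt_chisq`, `lrt_p`, convergence info.
#' @export
bivar_reml <- function(y1, y2, grm, covariates = NULL,
                       tol = 1e-6, maxit = 100L) {
  n1 <- length(y1); n2 <- length(y2); n <- n1 + n2
  A <- if (inherits(grm, "grm")) grm$K else grm
  stopifnot(is.matrix(A), nrow(A) == n)
  i1 <- seq_len(n1); i2 <- n1 + seq_len(n2)

  # covariance structures: tr1 genetic, tr2 genetic, cross-covariance,
  # residual 1, residual 2
  V1 <- matrix(0, n, n); V1[i1, i1] <- A[i1, i1]
  V2 <- matrix(0, n, n); V2[i2, i2] <- A[i2, i2]
  V12 <- matrix(0, n, n)
  V12[i1, i2] <- A[i1, i2]; V12[i2, i1] <- A[i2, i1]
  E1 <- diag(c(rep(1, n1), rep(0, n2)))
  E2 <- diag(c(rep(0, n1), rep(1, n2)))

  y <- c(y1, y2)
  X <- cbind(c(rep(1, n1), rep(0, n2)), c(rep(0, n1), rep(1, n2)))
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  if (qr(X)$rank < ncol(X)) stop("covariate matrix is singular",
                                 call. = FALSE)

  v1 <- stats::var(y1); v2 <- stats::var(y2)
  floor_val <- 1e-6 * min(v1, v2)
  init <- c(0.5 * v1, 0.5 * v2, 0, 0.5 * v1, 0.5 * v2)
  constrained <- c(TRUE, TRUE, FALSE, TRUE, TRUE)

  fit <- .reml_dense(y, list(V1, V2, V12, E1, E2), X, constrained, init,
                     floor_val, cov_triplets = list(c(3L, 1L, 2L)),
                     tol = tol, maxit = maxit)
  # null model: genetic covariance fixed at zero
  fit0 <- .reml_dense(y, list(V1, V2, E1, E2), X,
                      rep(TRUE, 4), init[-3], floor_val, NULL, tol, maxit)

  th <- fit$theta
  names(th) <- c("g1", "g2", "g12", "e1", "e2")
  at_boundary <- th["g1"] <= floor_val * 1.01 || th["g2"] <= floor_val * 1.01
  if (at_boundary) {
    rg <- NA_real_; rg_se <- NA_real_
    reason <- "a genetic variance is at the zero boundary"
  } else {
    rg <- th[["g12"]] / sqrt(th[["g1"]] * th[["g2"]])
    grad <- c(-0.5 * rg / th[["g1"]], -0.5 * rg / th[["g2"]],
              1 / sqrt(th[["g1"]] * th[["g2"]]), 0, 0)
    rg_se <- sqrt(max(0, drop(t(grad) %*% fit$inv_ai %*% grad)))
    reason <- NA_character_
  }
  lrt <- max(0, 2 * (fit$logL - fit0$logL))
  structure(list(
    components = data.frame(
      component = names(th), variance = th,
      se = sqrt(pmax(0, diag(fit$inv_ai))), stringsAsFactors = FALSE),
    rG = unname(rg), rG_se = unname(rg_se), rG_missing_reason = reason,
    h2_obs1 = th[["g1"]] / (th[["g1"]] + th[["e1"]]),
    h2_obs2 = th[["g2"]] / (th[["g2"]] + th[["e2"]]),
    logL = fit$logL, logL0 = fit0$logL,
    lrt_chisq = lrt,
    lrt_p = stats::pchisq(lrt, 1, lower.tail = FALSE),
    niter = fit$niter, converged = fit$converged,
    logL_history = fit$history), class = "bivar_fit")
}

#' @export
print.bivar_fit <- function(x, ...) {
  cat(sprintf("bivariate REML: rG = %.3f (s.e. %.3f), LRT p = %.3g\n",
              x$rG, x$rG_se, x$lrt_p))
  invisible(x)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, n_tests * p)`.
#'
#' @param p_nominal Nominal p-value(s) in (0, 1\].
#' @param n_tests Number of tests (e.g. 9 per-disease or 45 all-pairs).
#' @return Adjusted p-value(s), capped at 1.
#' @export
bonferroni_adjust <- function(p_nominal, n_tests) {
  if (n_tests < 1) stop("n_tests must be >= 1", call. = FALSE)
  if (any(p_nominal <= 0 | p_nominal > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  pmin(1, n_tests * p_nominal)
}
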