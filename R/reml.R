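# Average-information REML for linear mixed models y = Xb + sum_c g_c + e,
# g_c ~ N(0, A_c s2_c). Two computational paths share one driver:
#  - spectral: exactly one GRM + iid residual; one eigendecomposition makes
#    every iteration O(n p^2)
#  - dense: arbitrary covariance-structure list (multi-component fits and
#    the bivariate model), O(n^3) per iteration
# The driver proposes an AI step, falls back to EM and then to step halving
# whenever the restricted likelihood would decrease, so accepted logL is
# non-decreasing. Variance components are floored at 1e-6 * var(y);
# covariance components (unconstrained sign) are clipped to keep each
# correlation inside (-1, 1).

.ai_reml_driver <- function(eval_fn, grad_fn, init, constrained,
                            floor_val, cov_triplets = NULL,
                            tol = 1e-6, maxit = 100L) {
  clip <- function(theta) {
    theta[constrained] <- pmax(theta[constrained], floor_val)
    if (!is.null(cov_triplets)) {
      for (tr in cov_triplets) {
        lim <- 0.999 * sqrt(theta[tr[2]] * theta[tr[3]])
        theta[tr[1]] <- max(min(theta[tr[1]], lim), -lim)
      }
    }
    theta
  }
  theta <- clip(init)
  st <- eval_fn(theta)
  if (is.null(st)) stop("initial variance structure is not positive definite",
                        call. = FALSE)
  logL <- st$logL
  history <- logL
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxit)) {
    g <- grad_fn(st)
    step <- tryCatch(solve(g$AI, g$dL), error = function(e) NULL)
    accepted <- FALSE
    if (!is.null(step)) {
      cand <- clip(theta + step)
      st2 <- eval_fn(cand)
      if (!is.null(st2) && st2$logL >= logL - 1e-10) {
        theta <- cand; st <- st2; accepted <- TRUE
      } else {
        # step halving on the AI direction
        for (h in 1:8) {
          cand <- clip(theta + step / 2^h)
          st2 <- eval_fn(cand)
          if (!is.null(st2) && st2$logL >= logL - 1e-10) {
            theta <- cand; st <- st2; accepted <- TRUE; break
          }
        }
      }
    }
    if (!accepted) {
      # EM-style update for the constrained components
      em <- theta
      em[constrained] <- theta[constrained] +
        theta[constrained]^2 * g$em_score[constrained] / g$n
      cand <- clip(em)
      st2 <- eval_fn(cand)
      if (!is.null(st2) && st2$logL >= logL - 1e-10) {
        theta <- cand; st <- st2; accepted <- TRUE
      }
    }
    if (!accepted) { converged <- TRUE; break }  # no uphill step remains
    dl <- st$logL - logL
    logL <- st$logL
    history <- c(history, logL)
    if (abs(dl) < tol) { converged <- TRUE; break }
  }
  g <- grad_fn(st)
  inv_ai <- tryCatch(solve(g$AI), error = function(e)
    matrix(NA_real_, length(theta), length(theta)))
  list(theta = theta, logL = logL, inv_ai = inv_ai, niter = it,
       converged = converged, history = history)
}

# Dense-path evaluators over an explicit covariance-structure list.
.reml_dense <- function(y, V_list, X, constrained, init, floor_val,
                        cov_triplets = NULL, tol = 1e-6, maxit = 100L) {
  n <- length(y)
  p <- ncol(X)
  eval_fn <- function(theta) {
    V <- matrix(0, n, n)
    for (i in seq_along(V_list)) V <- V + theta[i] * V_list[[i]]
    C <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(C)) return(NULL)
    Vinv <- chol2inv(C)
    W <- Vinv %*% X
    XtW <- crossprod(X, W)
    B <- tryCatch(solve(XtW), error = function(e) NULL)
    if (is.null(B)) stop("covariate matrix is singular", call. = FALSE)
    Py <- Vinv %*% y - W %*% (B %*% crossprod(W, y))
    logL <- -0.5 * (2 * sum(log(diag(C))) +
                      determinant(XtW, logarithm = TRUE)$modulus +
                      sum(y * Py))
    list(logL = as.numeric(logL), Vinv = Vinv, W = W, B = B, Py = drop(Py))
  }
  grad_fn <- function(st) {
    k <- length(V_list)
    q <- vector("list", k)
    trPV <- numeric(k)
    yPVPy <- numeric(k)
    for (i in seq_len(k)) {
      Vi <- V_list[[i]]
      q[[i]] <- Vi %*% st$Py
      ViW <- Vi %*% st$W
      trPV[i] <- sum(st$Vinv * Vi) - sum(st$B * crossprod(st$W, ViW))
      yPVPy[i] <- sum(st$Py * q[[i]])
    }
    AI <- matrix(0, k, k)
    for (i in seq_len(k)) for (j in i:k) {
      Pqj <- st$Vinv %*% q[[j]] -
        st$W %*% (st$B %*% crossprod(st$W, q[[j]]))
      AI[i, j] <- AI[j, i] <- 0.5 * sum(q[[i]] * Pqj)
    }
    list(dL = -0.5 * (trPV - yPVPy), AI = AI,
         em_score = yPVPy - trPV, n = length(st$Py))
  }
  .ai_reml_driver(eval_fn, grad_fn, init, constrained, floor_val,
                  cov_triplets, tol, maxit)
}

# Spectral path: one GRM (eigenvalues d, data rotated into the eigenbasis).
.reml_spectral <- function(ytil, d, Xtil, init, floor_val,
                           tol = 1e-6, maxit = 100L) {
  p <- ncol(Xtil)
  eval_fn <- function(theta) {
    v <- theta[1] * d + theta[2]
    if (any(v <= 0)) return(NULL)
    W <- Xtil / v
    XtW <- crossprod(Xtil, W)
    B <- solve(XtW)
    Py <- ytil / v - W %*% (B %*% crossprod(W, ytil))
    logL <- -0.5 * (sum(log(v)) +
                      determinant(XtW, logarithm = TRUE)$modulus +
                      sum(ytil * Py))
    list(logL = as.numeric(logL), v = v, W = W, B = B, Py = drop(Py))
  }
  grad_fn <- function(st) {
    q1 <- d * st$Py
    q2 <- st$Py
    tr1 <- sum(d / st$v) -
      sum(st$B * crossprod(st$W, d * st$W))
    tr2 <- sum(1 / st$v) - sum(st$B * crossprod(st$W, st$W))
    Pq <- function(q) q / st$v - st$W %*% (st$B %*% crossprod(st$W, q))
    Pq1 <- Pq(q1); Pq2 <- Pq(q2)
    AI <- 0.5 * matrix(c(sum(q1 * Pq1), sum(q1 * Pq2),
                         sum(q1 * Pq2), sum(q2 * Pq2)), 2)
    yPVPy <- c(sum(st$Py * q1), sum(st$Py * q2))
    list(dL = -0.5 * (c(tr1, tr2) - yPVPy), AI = AI,
         em_score = yPVPy - c(tr1, tr2), n = length(st$Py))
  }
  .ai_reml_driver(eval_fn, grad_fn, init, c(TRUE, TRUE), floor_val,
                  NULL, tol, maxit)
}

# Residual-only REML (the no-genetics null), same logL convention.
.reml_null <- function(y, X) {
  n <- length(y); p <- ncol(X)
  qrX <- qr(X)
  res <- qr.resid(qrX, y)
  rss <- sum(res^2)
  s2 <- rss / (n - p)
  XtX <- crossprod(X)
  logL <- -0.5 * (n * log(s2) +
                    determinant(XtX / s2, logarithm = TRUE)$modulus +
                    rss / s2)
  list(theta = s2, logL = as.numeric(logL))
}

#' Univariate (multi-component) AI-REML fit
#'
#' Estimates variance components for a phenotype given one or more genetic
#' relationship matrices plus an iid residual, by restricted maximum
#' likelihood with average-information updates (expectation-maximization and
#' step-halving fallbacks keep the restricted likelihood non-decreasing).
#' Components are floored at `1e-6 * var(y)`. With a single GRM the model is
#' solved in the GRM's eigenbasis, making iterations O(n); with several GRMs
#' the dense path is used. Standard errors come from the inverse
#' average-information matrix (delta method for ratios); the
#' likelihood-ratio test against the no-genetics model uses the boundary
#' mixture `0.5 chisq_0 + 0.5 chisq_1` for one genetic component (plain
#' chi-square with k df for k > 1, which is conservative).
#'
#' @param y Phenotype vector (0/1 for case-control; any numeric works).
#' @param grms A `grm` object, a list of them, or a list of plain matrices.
#' @param covariates Numeric matrix of covariates (an intercept is added),
#'   e.g. the top 20 PCs; or `NULL` for intercept only.
#' @param tol Convergence tolerance on the change in restricted
#'   log-likelihood (default 1e-6).
#' @param maxit Maximum iterations (default 100).
#' @return An object of class `reml_fit`: `components` (data frame of
#'   variances and SEs, residual last), `h2_obs`, `h2_se`, `shares`,
#'   `logL`, `logL0`, `lrt_chisq`, `lrt_p`, `niter`, `converged`,
#'   `logL_history`.
#' @export
reml_fit <- function(y, grms, covariates = NULL, tol = 1e-6, maxit = 100L) {
  if (inherits(grms, "grm")) grms <- list(grms)
  K_list <- lapply(grms, function(g) if (inherits(g, "grm")) g$K else g)
  k <- length(K_list)
  n <- length(y)
  if (n < 50) stop("need at least 50 samples for REML", call. = FALSE)
  for (K in K_list)
    if (!is.matrix(K) || nrow(K) != n || ncol(K) != n)
      stop("GRM dimensions must match the phenotype length", call. = FALSE)
  X <- if (is.null(covariates)) matrix(1, n, 1)
       else cbind(1, as.matrix(covariates))
  if (qr(X)$rank < ncol(X)) stop("covariate matrix is singular",
                                 call. = FALSE)
  vy <- stats::var(y)
  floor_val <- 1e-6 * vy
  init <- c(rep(0.5 * vy / k, k), 0.5 * vy)

  if (k == 1L) {
    ed <- eigen(K_list[[1]], symmetric = TRUE)
    ytil <- drop(crossprod(ed$vectors, y))
    Xtil <- crossprod(ed$vectors, X)
    fit <- .reml_spectral(ytil, pmax(ed$values, 0), Xtil, init, floor_val,
                          tol, maxit)
  } else {
    V_list <- c(K_list, list(diag(n)))
    fit <- .reml_dense(y, V_list, X, rep(TRUE, k + 1L), init, floor_val,
                       NULL, tol, maxit)
  }

  null <- .reml_null(y, X)
  lrt <- max(0, 2 * (fit$logL - null$logL))
  lrt_p <- if (k == 1L) {
    if (lrt <= 0) 1 else 0.5 * stats::pchisq(lrt, 1, lower.tail = FALSE)
  } else {
    stats::pchisq(lrt, k, lower.tail = FALSE)
  }

  theta <- fit$theta
  tot <- sum(theta)
  gen <- seq_len(k)
  h2 <- sum(theta[gen]) / tot
  # delta method for ratios of summed components
  grad_h2 <- (as.numeric(seq_along(theta) %in% gen) - h2) / tot
  h2_se <- sqrt(max(0, drop(t(grad_h2) %*% fit$inv_ai %*% grad_h2)))
  comp_se <- sqrt(pmax(0, diag(fit$inv_ai)))
  shares <- theta / tot
  share_se <- vapply(seq_along(theta), function(i) {
    gsh <- -shares[i] / tot + as.numeric(seq_along(theta) == i) / tot
    # d(theta_i/tot)/d theta_j = (1(i=j) - share_i)/tot
    g2 <- (as.numeric(seq_along(theta) == i) - shares[i]) / tot
    sqrt(max(0, drop(t(g2) %*% fit$inv_ai %*% g2)))
  }, numeric(1))

  nm <- c(vapply(seq_len(k), function(i) {
    g <- grms[[i]]
    if (inherits(g, "grm")) g$region else paste0("G", i)
  }, character(1)), "residual")
  structure(list(
    components = data.frame(component = nm, variance = theta, se = comp_se,
                            share = shares, share_se = share_se,
                            stringsAsFactors = FALSE),
    h2_obs = h2, h2_se = h2_se,
    logL = fit$logL, logL0 = null$logL,
    lrt_chisq = lrt, lrt_p = lrt_p,
    niter = fit$niter, converged = fit$converged,
    logL_history = fit$history), class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("REML fit: h2_obs = %.4f (s.e. %.4f), LRT p = %.3g, %d iter%s\n",
              x$h2_obs, x$h2_se, x$lrt_p, x$niter,
              if (x$converged) "" else " (NOT converged)"))
  print(x$components, row.names = FALSE)
  invisible(x)
}

#' Observed-scale to liability-scale heritability
#'
#' Case-control ascertainment correction: with population prevalence K,
#' sample case proportion P, liability threshold `t = qnorm(1 - K)` and
#' normal density `z = dnorm(t)`,
#' `h2_liab = h2_obs * K^2 (1 - K)^2 / (P (1 - P) z^2)`.
#' The same multiplier is applied to the standard error (delta method with
#' K and P treated as fixed). When K = P the multiplier reduces to
#' `K (1 - K) / z^2`. A value above 1 is reported unclamped with a warning
#' and `clamped = TRUE`.
#'
#' @param h2_obs Observed-scale heritability (0/1 phenotype).
#' @param K Population prevalence in (0, 1).
#' @param P Sample case proportion in (0, 1).
#' @param se Optional observed-scale standard error.
#' @return List with `h2_liab`, `se_liab`, `multiplier`, `clamped`.
#' @export
observed_to_liability <- function(h2_obs, K, P = K, se = NULL) {
  if (K <= 0 || K >= 1 || P <= 0 || P >= 1)
    stop("K and P must lie in (0, 1)", call. = FALSE)
  t <- stats::qnorm(1 - K)
  z <- stats::dnorm(t)
  mult <- K^2 * (1 - K)^2 / (P * (1 - P) * z^2)
  h2_liab <- h2_obs * mult
  clamped <- FALSE
  if (!is.na(h2_liab) && h2_liab > 1) {
    warning("liability-scale heritability exceeds 1; reported unclamped")
    clamped <- TRUE
  }
  list(h2_liab = h2_liab,
       se_liab = if (is.null(se)) NA_real_ else se * mult,
       multiplier = mult, clamped = clamped)
}

#' Percentage of heritability attributable to the MHC
#'
#' `%MHC = 100 * (h2_auto - h2_exMHC) / h2_auto`: the drop in total
#' autosomal SNP heritability when the extended MHC is excluded from the
#' GRM, expressed as a percentage of the total. Undefined (NA) when the
#' autosomal estimate is not positive.
#'
#' @param h2_auto Heritability from all autosomal SNPs.
#' @param h2_exmhc Heritability with the extended MHC excluded.
#' @return Percentage (possibly negative), or `NA` if `h2_auto <= 0`.
#' @export
pct_mhc <- function(h2_auto, h2_exmhc) {
  if (is.na(h2_auto) || h2_auto <= 0) return(NA_real_)
  100 * (h2_auto - h2_exmhc) / h2_auto
}

#' Region-partition heritability report
#'
#' Combines univariate fits on the full autosomal GRM and the
#' MHC-excluded GRM into the standard per-disease report row: both
#' estimates, their SEs and LRT p-values, and the MHC percentage
#' contribution. Optional joint-fit shares (exMHC + MHC + X + residual) are
#' appended when a multi-component fit is supplied.
#'
#' @param fit_auto,fit_exmhc `reml_fit` objects on the same cohort/scale.
#' @param fit_joint Optional multi-component `reml_fit` (exMHC, MHC, X).
#' @return A one-row data frame.
#' @export
partition_report <- function(fit_auto, fit_exmhc, fit_joint = NULL) {
  out <- data.frame(
    h2_auto = fit_auto$h2_obs, se_auto = fit_auto$h2_se,
    p_auto = fit_auto$lrt_p,
    h2_exmhc = fit_exmhc$h2_obs, se_exmhc = fit_exmhc$h2_se,
    p_exmhc = fit_exmhc$lrt_p,
    pct_mhc = pct_mhc(fit_auto$h2_obs, fit_exmhc$h2_obs))
  if (!is.null(fit_joint)) {
    sh <- fit_joint$components
    for (i in seq_len(nrow(sh))) {
      out[[paste0("share_", sh$component[i])]] <- sh$share[i]
    }
  }
  out
}
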