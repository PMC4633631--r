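test_that("p-to-Z transform hits the standard normal quantiles", {
  expect_equal(pvalues_to_zscores(1), 0)
  expect_equal(pvalues_to_zscores(0.05), 1.959964, tolerance = 1e-6)
  expect_equal(pvalues_to_zscores(5e-8), 5.451310, tolerance = 1e-6)
  expect_true(is.finite(pvalues_to_zscores(1e-310)))
  expect_error(pvalues_to_zscores(0), "lie in")
  expect_error(pvalues_to_zscores(c(0.5, -1)), "lie in")
})

test_that("the max-min statistic follows its definition", {
  expect_equal(gps_statistic(c(3, 1, 2), c(1, 4, 2)), 2)
  X <- c(2.2, 0.4, 1.1)
  expect_equal(gps_statistic(X, X), max(X))
  expect_equal(gps_statistic(5, 3), 3)
  expect_error(gps_statistic(1:3, 1:4), "equal length")
})

test_that("gamma is monotone in every single Z-score", {
  set.seed(140)
  for (r in 1:50) {
    n <- sample(3:20, 1)
    X <- rexp(n); Y <- rexp(n)
    g0 <- gps_statistic(X, Y)
    j <- sample(n, 1)
    X2 <- X; X2[j] <- X2[j] + rexp(1)
    expect_gte(gps_statistic(X2, Y), g0)
  }
})

test_that("analytic p equals exhaustive permutation for every small fixture", {
  # hand-checkable cases first: n=3 a=1 b=1 -> 1/3; n=4 a=2 b=1 -> 1/2
  X <- c(9, 1, 2); Y <- c(8, 0, 1)
  expect_equal(gps_pvalue_analytic(gps_statistic(X, Y), X, Y), 1 / 3)
  X4 <- c(9, 8, 1, 2); Y4 <- c(7, 0.5, 0.2, 0.1)
  g4 <- gps_statistic(X4, Y4)
  expect_equal(gps_pvalue_analytic(g4, X4, Y4), 1 / 2)

  set.seed(141)
  for (n in 3:7) {
    for (r in 1:8) {
      X <- round(rexp(n), 2); Y <- round(rexp(n), 2)
      g <- gps_statistic(X, Y)
      expect_equal(gps_pvalue_analytic(g, X, Y), exhaustive_gps_p(X, Y),
                   tolerance = 1e-12)
    }
  }
})

test_that("analytic and Monte-Carlo permutation p-values agree", {
  set.seed(142)
  X <- pvalues_to_zscores(runif(500))
  Y <- pvalues_to_zscores(runif(500))
  pa <- gps_pvalue_analytic(gps_statistic(X, Y), X, Y)
  pp <- gps_pvalue_permutation(X, Y, n_perm = 10000, seed = 143)
  se <- sqrt(pa * (1 - pa) / 10000)
  expect_lt(abs(pa - pp), 3 * se + 2 / 10001)
  # determinism and the constant-X degenerate case
  expect_equal(gps_pvalue_permutation(X, Y, 1000, seed = 9),
               gps_pvalue_permutation(X, Y, 1000, seed = 9))
  Xc <- rep(1.3, 50)
  expect_equal(gps_pvalue_permutation(Xc, rexp(50), 500, seed = 1), 1)
  expect_equal(gps_pvalue_analytic(gps_statistic(Xc, rexp(50)), Xc,
                                   rexp(50) + 10), 1)
})

test_that("all-pairs sharing scan covers every pair and ranks true sharing", {
  set.seed(144)
  m <- 400
  snp <- sprintf("rs%04d", 1:m)
  mk <- function(p) data.frame(snp = snp, p = p, chr = 1L, bp = 1:m)
  shared <- sample(m, 30)
  p1 <- runif(m); p2 <- runif(m); p3 <- runif(m); p4 <- runif(m)
  # cohorts 1,2 share signals of graded strength at the same SNPs
  p1[shared] <- 10^-runif(30, 4, 12)
  p2[shared] <- 10^-runif(30, 4, 12)
  res <- gps_all_pairs(list(A = mk(p1), B = mk(p2), C = mk(p3),
                            D = mk(p4)), exclude_mhc = FALSE)
  expect_equal(nrow(res$pairs), 6)
  padj <- res$pairs$p_adj[res$pairs$pair == "A-B"]
  null_padj <- res$pairs$p_adj[res$pairs$pair == "C-D"]
  expect_lt(padj, null_padj)
  expect_true(isSymmetric(res$p_matrix))

  res2 <- gps_all_pairs(list(A = mk(p1), B = mk(p2)), exclude_mhc = FALSE)
  expect_equal(nrow(res2$pairs), 1)

  # 10 cohorts -> 45 pairs
  ten <- setNames(lapply(1:10, function(i) mk(runif(m))), LETTERS[1:10])
  expect_equal(nrow(gps_all_pairs(ten, exclude_mhc = FALSE)$pairs), 45)

  # mismatched SNP universes are refused
  bad <- mk(runif(m)); bad$snp[1] <- "rs_other"
  expect_error(gps_all_pairs(list(A = mk(p1), B = bad)), "universe")
})

test_that("MHC SNPs are excluded from the scan by default", {
  m <- 200
  snp <- sprintf("rs%04d", 1:m)
  chr <- c(rep(6L, 50), rep(1L, 150))
  bp <- c(seq(26500000L, 33999999L, length.out = 50), 1:150 * 1000L)
  set.seed(145)
  p1 <- runif(m); p2 <- runif(m)
  # a few strongly shared SNPs, only inside the MHC (sparse sharing is
  # where the max-min statistic is powered)
  p1[1:5] <- 10^-runif(5, 8, 12)
  p2[1:5] <- 10^-runif(5, 8, 12)
  mk <- function(p) data.frame(snp = snp, p = p, chr = chr, bp = bp)
  res_ex <- gps_all_pairs(list(A = mk(p1), B = mk(p2)))
  res_in <- gps_all_pairs(list(A = mk(p1), B = mk(p2)),
                          exclude_mhc = FALSE)
  expect_equal(res_ex$pairs$n, 150)
  expect_lt(res_in$pairs$p_adj, res_ex$pairs$p_adj)
})
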