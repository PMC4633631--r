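test_that("HWE exact test matches an independent enumeration oracle", {
  # oracle: enumerate attainable heterozygote counts with plain factorials
  oracle <- function(hom1, het, hom2) {
    n <- hom1 + het + hom2
    n1 <- 2 * hom1 + het; n2 <- 2 * hom2 + het
    rare <- min(n1, n2)
    hets <- seq(rare %% 2, rare, by = 2)
    pr <- vapply(hets, function(h) {
      a <- (n1 - h) / 2; b <- (n2 - h) / 2
      exp(lfactorial(n) - lfactorial(a) - lfactorial(h) - lfactorial(b) +
            h * log(2) + lfactorial(n1) + lfactorial(n2) -
            lfactorial(2 * n))
    }, numeric(1))
    obs <- pr[match(het, hets)]
    min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
  }
  cases <- list(c(5, 10, 5), c(2, 16, 2), c(10, 0, 10), c(7, 3, 1),
                c(0, 4, 16), c(3, 3, 3))
  for (cs in cases)
    expect_equal(hwe_exact_test(cs[1], cs[2], cs[3]),
                 oracle(cs[1], cs[2], cs[3]), tolerance = 1e-9)
})

test_that("HWE exact test handles degenerate and extreme tables", {
  expect_equal(hwe_exact_test(80, 0, 0), 1)       # monomorphic
  expect_equal(hwe_exact_test(0, 0, 0), 1)
  expect_lt(hwe_exact_test(50, 0, 50), 1e-20)     # total het deficit
  # observed at the modal heterozygote count -> p = 1
  n1 <- 40; n2 <- 40
  hets <- seq(0, 40, by = 2)
  pr <- vapply(hets, function(h)
    hwe_exact_test((n1 - h) / 2, h, (n2 - h) / 2), numeric(1))
  expect_equal(max(pr), 1)
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
})

test_that("SNP filters remove crafted failures in order, with logged counts", {
  set.seed(50)
  n <- 200
  dos <- matrix(rbinom(n * 10, 2, 0.3), n, 10)
  # SNP 1: call rate 0.94
  dos[sample(n, 13), 1] <- NA
  # SNP 2: MAF 0.005
  dos[, 2] <- 0L; dos[sample(n, 2), 2] <- 1L
  # SNP 3: gross HWE violation (all hets)
  dos[, 3] <- 1L
  g <- make_geno(dos)
  y <- rep(c(0L, 1L), each = n / 2)
  out <- filter_snps(g, y, qc_thresholds())
  expect_equal(out$report$n_retained, 7)
  expect_equal(out$report$removed[["call_rate"]], 1)
  expect_equal(out$report$removed[["maf"]], 1)
  expect_equal(out$report$removed[["hwe"]], 1)
  expect_equal(out$report$n_input - sum(out$report$removed),
               out$report$n_retained)
  expect_false(g$snp_map$id[1] %in% out$report$retained_ids)
})

test_that("differential missingness between cases and controls is caught", {
  set.seed(51)
  n <- 400
  dos <- matrix(rbinom(n * 5, 2, 0.4), n, 5)
  y <- rep(c(0L, 1L), each = n / 2)
  dos[y == 1L & runif(n) < 0.25, 4] <- NA  # cases only
  g <- make_geno(dos)
  out <- filter_snps(g, y, qc_thresholds(snp_call_rate_min = 0.8))
  expect_equal(out$report$removed[["diff_missing"]], 1)
  expect_false(g$snp_map$id[4] %in% out$report$retained_ids)
})

test_that("sample call-rate filter removes exactly the bad samples", {
  set.seed(52)
  dos <- matrix(rbinom(50 * 100, 2, 0.3), 50, 100)
  dos[3, sample(100, 10)] <- NA   # 90% call rate
  dos[17, sample(100, 8)] <- NA   # 92%
  g <- make_geno(dos)
  out <- filter_samples(g, qc_thresholds())
  expect_equal(out$report$n_retained, 48)
  expect_false(any(c("i003", "i017") %in% out$report$retained_ids))

  clean <- filter_samples(make_geno(matrix(1L, 20, 10)))
  expect_equal(clean$report$removed[["call_rate"]], 0)
})

test_that("HWE filtering on clean data removes at most its nominal rate", {
  p <- sim_params(500, 10000, maf_range = c(0.05, 0.5), seed = 53)
  g <- simulate_genotypes(p)
  y <- rep(c(0L, 1L), length.out = 500)
  out <- filter_snps(g, y, qc_thresholds())
  frac_hwe <- out$report$removed[["hwe"]] / 10000
  expect_lte(frac_hwe, 0.015)
})
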