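# Small fixture builders shared across test files.

# Wrap a dosage matrix in a genotype_data with a default autosomal map.
make_geno <- function(dosage, chr = NULL, bp = NULL, sex = NULL) {
  n <- nrow(dosage); m <- ncol(dosage)
  if (m == 0) {
    return(genotype_data(
      dosage,
      data.frame(id = character(0), chr = integer(0), bp = integer(0),
                 a1 = character(0), a2 = character(0),
                 region = character(0), stringsAsFactors = FALSE),
      data.frame(id = sprintf("i%03d", seq_len(n)),
                 sex = rep(NA_integer_, n), phenotype = NA_integer_,
                 stringsAsFactors = FALSE)))
  }
  if (is.null(chr)) chr <- rep(1L, m)
  if (is.null(bp)) bp <- seq_len(m) * 1000L
  region <- ifelse(chr == 23L, "X",
                   ifelse(chr == 6L & bp >= 26500000L & bp <= 34000000L,
                          "MHC", "autosome"))
  genotype_data(
    dosage,
    data.frame(id = sprintf("s%03d", seq_len(m)), chr = chr, bp = bp,
               a1 = "A", a2 = "B", region = region,
               stringsAsFactors = FALSE),
    data.frame(id = sprintf("i%03d", seq_len(n)),
               sex = if (is.null(sex)) rep(NA_integer_, n) else sex,
               phenotype = NA_integer_, stringsAsFactors = FALSE))
}

# Brute-force GRM: literal double loop over pairs and SNPs.
brute_grm <- function(dosage) {
  n <- nrow(dosage); m <- ncol(dosage)
  f <- colMeans(dosage, na.rm = TRUE) / 2
  K <- matrix(0, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    s <- 0; cnt <- 0
    for (i in seq_len(m)) {
      if (f[i] <= 0 || f[i] >= 1) next
      xj <- dosage[j, i]; xk <- dosage[k, i]
      if (is.na(xj) || is.na(xk)) next
      s <- s + (xj - 2 * f[i]) * (xk - 2 * f[i]) / (2 * f[i] * (1 - f[i]))
      cnt <- cnt + 1
    }
    K[j, k] <- s / max(cnt, 1)
  }
  K
}

# Exhaustive-permutation p-value for the sharing statistic (n <= 8).
exhaustive_gps_p <- function(X, Y) {
  n <- length(X)
  perms <- .all_perms(n)
  g_obs <- max(pmin(X, Y))
  hits <- vapply(perms, function(pr) max(pmin(X, Y[pr])) >= g_obs,
                 logical(1))
  mean(hits)
}

.all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- .all_perms(n - 1L)
    for (r in rest) out[[length(out) + 1L]] <-
        c(i, setdiff(seq_len(n), i)[r])
  }
  out
}
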