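# Independent brute-force oracles: explicit loops over observations, kept
# deliberately separate from the vectorised package implementations.

oracle_gw_mean <- function(y, w) {
  num <- 0; den <- 0
  for (j in seq_along(y)) {
    num <- num + y[j] * w[j]
    den <- den + w[j]
  }
  num / den
}

oracle_gw_cov <- function(y1, y2, w) {
  m1 <- oracle_gw_mean(y1, w)
  m2 <- oracle_gw_mean(y2, w)
  num <- 0; den <- 0
  for (j in seq_along(y1)) {
    num <- num + w[j] * (y1[j] - m1) * (y2[j] - m2)
    den <- den + w[j]
  }
  num / den
}

oracle_gw_sd <- function(y, w) sqrt(oracle_gw_cov(y, y, w))

oracle_gw_corr <- function(y1, y2, w) {
  oracle_gw_cov(y1, y2, w) / (oracle_gw_sd(y1, w) * oracle_gw_sd(y2, w))
}

oracle_cov_matrix <- function(z, w) {
  p <- ncol(z)
  s <- matrix(NA_real_, p, p)
  for (a in seq_len(p)) {
    for (b in seq_len(p)) {
      s[a, b] <- oracle_gw_cov(z[, a], z[, b], w)
    }
  }
  s
}

# population (n-divisor) moments, loop form
oracle_pop_mean <- function(y) oracle_gw_mean(y, rep(1, length(y)))
oracle_pop_cov <- function(y1, y2) oracle_gw_cov(y1, y2, rep(1, length(y1)))

# quartile by linear interpolation between order statistics (type 7),
# computed from first principles on the sorted sample
oracle_quantile7 <- function(y, prob) {
  ys <- sort(y)
  n <- length(ys)
  h <- (n - 1) * prob + 1
  lo <- floor(h)
  hi <- ceiling(h)
  ys[lo] + (h - lo) * (ys[hi] - ys[lo])
}

# a small random planar sample table
random_table <- function(n, p, seed) {
  set.seed(seed)
  sample_table(
    ids = paste0("loc", seq_len(n)),
    coords = cbind(runif(n), runif(n)),
    values = matrix(rnorm(n * p, mean = 10, sd = 2), n, p,
                    dimnames = list(NULL, paste0("m", seq_len(p))))
  )
}

# planted two-regime recovery configuration: variable A dominates the west,
# variable C the east, loading contrast 1 (well above 0.5), Gaussian marginals
recovery_config <- function(seed, n = 400L) {
  synthetic_config(
    n = n,
    cov_a = diag(c(9, 4, 1)), cov_b = diag(c(1, 4, 9)),
    geometry = "split", boundary = 0.5, direction = "x",
    variable_names = c("A", "B", "C"), seed = seed
  )
}
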