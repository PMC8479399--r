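test_that("uniform weights collapse the local eigenstructure to the global PCA", {
  tab <- random_table(25, 4, seed = 8)
  z <- standardize(tab)
  global <- eigen_pca(cor(tab$values))
  unif <- matrix(1, 25, 25)
  field <- local_eigenstructure(z, unif, k = 2,
                                variable_names = tab$variable_names)
  # population vs sample divisor rescales all eigenvalues by (n-1)/n
  scale <- 24 / 25
  for (i in 1:25) {
    expect_lt(max(abs(field$eigenvalues[i, ] - global$eigenvalues * scale)),
              1e-8)
    expect_lt(max(abs(abs(field$loadings[, , i]) - abs(global$loadings))),
              1e-8)
  }
  # after sign alignment the loadings equal the global ones entrywise
  aligned <- align_signs(field, global)
  expect_lt(max(abs(aligned$loadings[, , 1] - global$loadings)), 1e-8)
  # PTV is scale-free, so it matches the global cumulative PTV exactly
  expect_lt(max(abs(field$ptv - global$cumulative_ptv[2])), 1e-10)
})

test_that("an enormous bi-square bandwidth approaches the global solution", {
  tab <- random_table(20, 3, seed = 15)
  z <- standardize(tab)
  d <- pairwise_distances(tab$coords)
  kw <- bisquare_weights(d, 1e6 * max(d))
  field <- local_eigenstructure(z, kw, k = 2)
  global <- eigen_pca(cor(tab$values))
  scale <- 19 / 20
  expect_lt(max(abs(field$eigenvalues[3, ] - global$eigenvalues * scale)),
            1e-5)
})

test_that("local eigenstructure matches a brute-force oracle at every location", {
  set.seed(55)
  for (rep in 1:5) {
    n <- sample(10:30, 1)
    p <- sample(2:4, 1)
    tab <- random_table(n, p, seed = 300 + rep)
    z <- standardize(tab)
    d <- pairwise_distances(tab$coords)
    kw <- bisquare_weights(d, adaptive_bandwidths(d, max(2L, n %/% 2L)))
    field <- suppressWarnings(local_eigenstructure(z, kw, k = 1))
    for (i in seq_len(n)) {
      sig <- oracle_cov_matrix(z$z, kw$w[i, ])
      e <- eigen(sig, symmetric = TRUE)
      expect_lt(max(abs(field$eigenvalues[i, ] - e$values)), 1e-8)
      # trace conservation
      expect_lt(abs(sum(field$eigenvalues[i, ]) - sum(diag(sig))), 1e-8)
      # per-location reconstruction L V L' = Sigma(i)
      L <- field$loadings[, , i]
      expect_lt(max(abs(L %*% diag(field$eigenvalues[i, ], p) %*% t(L) - sig)),
                1e-8)
    }
  }
})

test_that("local eigenvalues vary continuously with the bandwidth", {
  tab <- random_table(30, 4, seed = 21)
  z <- standardize(tab)
  d <- pairwise_distances(tab$coords)
  tau <- 0.4
  f1 <- local_eigenstructure(z, bisquare_weights(d, tau), k = 2)
  f2 <- local_eigenstructure(z, bisquare_weights(d, tau * (1 + 1e-6)), k = 2)
  rel <- abs(f1$eigenvalues - f2$eigenvalues) /
    pmax(abs(f1$eigenvalues), 1e-12)
  expect_lt(max(rel), 1e-3)
})

test_that("local scores project onto the local loadings and decorrelate", {
  tab <- random_table(20, 3, seed = 31)
  z <- standardize(tab)
  d <- pairwise_distances(tab$coords)
  kw <- bisquare_weights(d, 0.7)
  field <- local_eigenstructure(z, kw, k = 2)
  i <- 7L
  scores <- local_scores(z, field, i)
  expect_equal(scores, z$z %*% field$loadings[, , i])
  # weighted covariance of the score columns is the local eigenvalue diagonal
  sc_cov <- gw_covariance_matrix(scores, kw$w[i, ])
  expect_lt(max(abs(sc_cov - diag(field$eigenvalues[i, ]))), 1e-8)

  # p = 1: scores equal the standardized data up to sign
  tab1 <- random_table(15, 1, seed = 32)
  z1 <- standardize(tab1)
  f1 <- local_eigenstructure(z1, matrix(1, 15, 15), k = 1)
  s1 <- local_scores(z1, f1, 3L)
  expect_lt(min(max(abs(s1 - z1$z)), max(abs(s1 + z1$z))), 1e-10)

  # uniform weights: scores equal global PCA scores up to column signs
  unif <- matrix(1, 20, 20)
  fu <- local_eigenstructure(z, unif, k = 2)
  global <- eigen_pca(cor(tab$values))
  su <- local_scores(z, fu, 1L)
  sg <- z$z %*% global$loadings
  for (j in 1:3) {
    expect_lt(min(max(abs(su[, j] - sg[, j])), max(abs(su[, j] + sg[, j]))),
              1e-8)
  }
  expect_error(local_scores(z, field, 99L), "out of range")
})

test_that("winning variables use absolute loadings with a logged tie rule", {
  tab1 <- random_table(10, 1, seed = 41)
  f1 <- local_eigenstructure(standardize(tab1), matrix(1, 10, 10), k = 1,
                             variable_names = "m1")
  expect_true(all(winning_variables(f1, 1) == "m1"))

  # construct an exact two-way tie analytically
  tie_field <- structure(list(
    loadings = array(rep(c(1, 1, 0) / sqrt(2), 3), c(3, 3, 1)),
    eigenvalues = matrix(c(2, 1, 0.5), 1),
    ptv = 1, k = 1, variable_names = c("a", "b", "c")),
    class = "local_eigen_field")
  expect_message(w <- winning_variables(tie_field, 1), "tie")
  expect_equal(w, "a")
  expect_error(winning_variables(tie_field, 9), "out of range")
})

test_that("ptv surfaces are shares in (0, 1] with k = p giving exactly 1", {
  tab <- random_table(20, 3, seed = 51)
  z <- standardize(tab)
  d <- pairwise_distances(tab$coords)
  field <- local_eigenstructure(z, bisquare_weights(d, 0.8), k = 3)
  expect_true(all(field$ptv == 1))
  p2 <- ptv_surface(field, k = 2)
  expect_true(all(p2 > 0 & p2 <= 1))
  expect_true(all(p2 <= field$ptv))
})

test_that("sign alignment is idempotent and does not change winners", {
  tab <- random_table(20, 4, seed = 61)
  z <- standardize(tab)
  d <- pairwise_distances(tab$coords)
  field <- local_eigenstructure(z, bisquare_weights(d, 0.6), k = 2)
  global <- eigen_pca(cor(tab$values))
  a1 <- align_signs(field, global)
  a2 <- align_signs(a1, global)
  expect_equal(a1$loadings, a2$loadings)
  expect_equal(winning_variables(field, 1), winning_variables(a1, 1))
})

test_that("cross-validation scores are valid and guard degenerate settings", {
  tab <- random_table(25, 3, seed = 71)
  z <- standardize(tab)
  d <- pairwise_distances(tab$coords)
  grid <- c(0.3, 0.6, 1.2)
  cv <- cv_bandwidth(z, tab$coords, k = 2, candidates = grid, d = d)
  expect_true(all(cv$scores >= 0))
  expect_true(cv$selected %in% grid)
  expect_equal(cv$scores[match(cv$selected, cv$candidates)], min(cv$scores))
  expect_error(cv_bandwidth(z, tab$coords, k = 3, candidates = grid, d = d),
               "k < p")
  # a tiny candidate that empties neighbourhoods scores +Inf and warns
  expect_warning(
    cv2 <- cv_bandwidth(z, tab$coords, k = 1, candidates = c(1e-6, 0.8), d = d),
    "empty")
  expect_true(is.infinite(cv2$scores[1]))
  expect_equal(cv2$selected, 0.8)
})

test_that("the gwpca fit object is coherent end to end", {
  sim <- simulate_samples(recovery_config(seed = 5, n = 120L))
  fit <- gwpca(sim$table, k = 1, bandwidth = 0.3)
  expect_s3_class(fit, "gwpca")
  expect_equal(dim(fit$eigenvalues), c(120L, 3L))
  expect_equal(dim(fit$loadings), c(3L, 3L, 120L))
  expect_equal(dim(fit$winners), c(120L, 1L))
  expect_true(all(fit$winners %in% sim$table$variable_names))
  expect_true(all(fit$ptv > 0 & fit$ptv <= 1))
  ftd <- fitted(fit)
  expect_equal(nrow(ftd), 120L)
  expect_output(print(fit), "Geographically weighted PCA")

  # default k comes from the global eigenvalue-greater-than-one count
  fit2 <- gwpca(sim$table, bandwidth = 0.3)
  expect_equal(fit2$k, max(1L, fit2$global$retained))
})
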