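test_that("read_samples parses a CSV, filters incomplete rows, and flags bad cells", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,x,y,As,Zn",
               "a,0.1,0.2,3.5,1.2",
               "b,0.3,0.4,2.2,0.9",
               "c,0.5,0.6,4.1,1.8"), path)
  tab <- read_samples(path, c("x", "y"), c("As", "Zn"), id_column = "id")
  expect_s3_class(tab, "sample_table")
  expect_equal(tab$n, 3L)
  expect_equal(tab$p, 2L)
  expect_equal(tab$variable_names, c("As", "Zn"))
  expect_equal(unname(tab$values[, "As"]), c(3.5, 2.2, 4.1))

  # blank cell: row dropped with its id reported
  writeLines(c("id,x,y,As,Zn",
               "a,0.1,0.2,3.5,1.2",
               "b,0.3,0.4,,0.9",
               "c,0.5,0.6,4.1,1.8"), path)
  expect_message(tab2 <- read_samples(path, c("x", "y"), c("As", "Zn"),
                                      id_column = "id"),
                 "\\bb\\b")
  expect_equal(tab2$n, 2L)
  expect_equal(attr(tab2, "dropped"), "b")

  # non-numeric cell names its column
  writeLines(c("id,x,y,As", "a,east,0.2,3.5", "b,0.3,0.4,2.2"), path)
  expect_error(read_samples(path, c("x", "y"), "As", id_column = "id"), "'x'")

  # missing column is a configuration error
  writeLines(c("id,x,y,As", "a,0.1,0.2,3.5", "b,0.3,0.4,2.2"), path)
  expect_error(read_samples(path, c("x", "y"), c("As", "Pb"),
                            id_column = "id"), "Pb")

  # duplicated ids are rejected
  writeLines(c("id,x,y,As", "a,0.1,0.2,3.5", "a,0.3,0.4,2.2"), path)
  expect_error(read_samples(path, c("x", "y"), "As", id_column = "id"),
               "duplicated")
})

test_that("standardize gives exact z-scores and is invertible", {
  tab <- random_table(20, 3, seed = 11)
  z <- standardize(tab)
  expect_equal(unname(standardize(cbind(v = c(1, 2, 3)))$z[, 1]), c(-1, 0, 1))
  expect_lt(max(abs(colMeans(z$z))), 1e-10)
  expect_lt(max(abs(apply(z$z, 2, sd) - 1)), 1e-10)
  expect_lt(max(abs(unstandardize(z) - tab$values)), 1e-10)
  expect_error(standardize(cbind(a = c(2, 2, 2), b = 1:3)), "\\ba\\b")
})

test_that("describe computes the nine-statistic table with fixed conventions", {
  d <- describe(cbind(v = c(1, 2, 3, 4, 5)))
  expect_equal(d$median, 3)
  expect_equal(d$lq, 2)
  expect_equal(d$uq, 4)
  expect_equal(d$mad, 1)
  expect_equal(d$skewness, 0)
  expect_equal(d$nb, 5)

  y <- c(1, 1, 2, 4, 10)
  d2 <- describe(cbind(v = y))
  expect_equal(d2$mean, 3.6)
  expect_gt(d2$skewness, 0)
  expect_equal(d2$minimum, 1)
  expect_equal(d2$maximum, 10)
  expect_equal(d2$lq, oracle_quantile7(y, 0.25))
  expect_equal(d2$median, oracle_quantile7(y, 0.5))
  expect_equal(d2$uq, oracle_quantile7(y, 0.75))
  expect_equal(d2$mad, median(abs(y - oracle_quantile7(y, 0.5))))

  tab8 <- random_table(30, 8, seed = 5)
  d8 <- describe(tab8)
  expect_equal(names(d8), c("variable", "nb", "minimum", "maximum", "mean",
                            "lq", "median", "uq", "mad", "skewness"))
  expect_equal(nrow(d8), 8L)
  expect_true(all(d8$minimum <= d8$lq & d8$lq <= d8$median &
                  d8$median <= d8$uq & d8$uq <= d8$maximum))
  expect_true(all(d8$mad >= 0))
})

test_that("describe is permutation-invariant and correlation is scale-free", {
  tab <- random_table(25, 4, seed = 7)
  perm <- sample(tab$n)
  shuffled <- sample_table(tab$ids[perm], tab$coords[perm, ],
                           tab$values[perm, ])
  expect_equal(describe(tab), describe(shuffled))

  z <- standardize(tab)
  expect_lt(max(abs(cor(tab$values) - cor(z$z))), 1e-12)
})

test_that("sample_table enforces its invariants", {
  expect_error(sample_table("a", rbind(c(0, 0)), rbind(1)), "at least 2")
  expect_error(sample_table(c("a", "a"), cbind(0:1, 0:1), cbind(1:2)),
               "duplicated")
  expect_error(sample_table(c("a", "b"), cbind(c(0, NA), 0:1), cbind(1:2)),
               "finite")
  bad <- matrix(1:4, 2, dimnames = list(NULL, c("v", "v")))
  expect_error(sample_table(c("a", "b"), cbind(0:1, 0:1), bad), "unique")
})
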