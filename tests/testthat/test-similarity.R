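test_that("pairwise absolute distances form a symmetric zero-diagonal matrix", {
  expect_equal(pairwise_abs_distance(c(1, 2, 4)),
               matrix(c(0, 1, 3, 1, 0, 2, 3, 2, 0), 3, 3))
  expect_equal(pairwise_abs_distance(c(0, 1)), matrix(c(0, 1, 1, 0), 2, 2))
  expect_true(all(pairwise_abs_distance(rep(0.3, 5)) == 0))
  expect_error(pairwise_abs_distance(1), "at least 2")
})

test_that("double centering matches the hand-derived values and the scalar oracle", {
  da <- double_center(pairwise_abs_distance(c(1, 2, 4)))
  expect_equal(attr(da, "row_means"), c(4 / 3, 1, 5 / 3))
  expect_equal(attr(da, "grand_mean"), 4 / 3)
  expect_equal(da[1, ], c(-4 / 3, 0, 4 / 3))
  expect_equal(double_center(matrix(0, 4, 4)),
               matrix(0, 4, 4), ignore_attr = TRUE)
  for (s in 1:10) {
    set.seed(s)
    d <- pairwise_abs_distance(runif(6))
    da <- double_center(d)
    expect_equal(unclass(da), oracle_double_center(d), ignore_attr = TRUE)
    expect_lt(max(abs(rowSums(da))), 1e-9)
    expect_lt(max(abs(colSums(da))), 1e-9)
  }
})

test_that("dcor_pair reproduces the squared energy-statistics distance correlation", {
  for (s in 1:50) {
    set.seed(s)
    n <- sample(5:50, 1)
    x <- runif(n)
    y <- runif(n)
    expect_equal(as.numeric(profile_dcor(x, y)), oracle_dcor2(x, y),
                 tolerance = 1e-10)
    # square-root option gives the classical distance correlation scale
    expect_equal(as.numeric(profile_dcor(x, y, root = TRUE)),
                 sqrt(oracle_dcor2(x, y)), tolerance = 1e-10)
  }
})

test_that("dcor is 1 on self and affine images, 0 with a flag on constants", {
  set.seed(1)
  x <- runif(10)
  expect_equal(as.numeric(profile_dcor(x, x)), 1)
  expect_equal(as.numeric(profile_dcor(x, 2 * x + 3)), 1, tolerance = 1e-12)
  s <- profile_dcor(x, rep(0.4, 10))
  expect_identical(as.numeric(s), 0)
  expect_true(attr(s, "degenerate"))
  da <- double_center(pairwise_abs_distance(x))
  expect_error(dcor_pair(da, double_center(pairwise_abs_distance(runif(9)))),
               "size")
})

test_that("dcor for independent profiles shrinks as the genome count grows", {
  med <- vapply(c(10, 200), function(j) {
    stats::median(vapply(1:200, function(s) {
      set.seed(s)
      as.numeric(profile_dcor(runif(j), runif(j)))
    }, numeric(1)))
  }, numeric(1))
  expect_lt(med[2], med[1])
})

test_that("pearson_pair matches closed-form values and flags constants", {
  expect_equal(as.numeric(pearson_pair(c(1, 2, 3), c(1, 3, 2))), 0.5)
  set.seed(2)
  x <- runif(8)
  expect_equal(as.numeric(pearson_pair(x, x)), 1)
  expect_equal(as.numeric(pearson_pair(x, -x)), -1)
  p <- pearson_pair(x, rep(1, 8))
  expect_identical(as.numeric(p), 0)
  expect_true(attr(p, "degenerate"))
  expect_error(pearson_pair(x, runif(7)), "length")
})

test_that("profile binning uses half-open 0.1 intervals with the last bin closed", {
  b <- bin_profile(c(0.05, 0.1, 1.0))
  expect_equal(b$marginal_x, c(1, 1, 0, 0, 0, 0, 0, 0, 0, 1))
  b2 <- bin_profile(rep(1, 7))
  expect_equal(sum(b2$marginal_x), 7)
  expect_equal(b2$marginal_x[10], 7)
  expect_error(bin_profile(c(0.5, 1.2)), "\\(0, 1\\]")
  expect_error(bin_profile(0.5, width = 0.3), "divide")
  # joint counts marginalize to the marginals
  for (s in 1:10) {
    set.seed(s)
    x <- runif(30)
    y <- runif(30)
    b <- bin_profile(x, y)
    expect_equal(rowSums(b$joint), b$marginal_x)
    expect_equal(colSums(b$joint), b$marginal_y)
    expect_equal(sum(b$joint), 30)
  }
})

test_that("mutual information is symmetric, non-negative, and equals the oracle", {
  # factorizing example: every bin combination appears once
  expect_equal(mutual_information_pair(c(0.05, 0.15, 0.05, 0.15),
                                       c(0.25, 0.35, 0.35, 0.25)),
               0, tolerance = 1e-12)
  for (s in 1:20) {
    set.seed(s)
    x <- runif(25)
    y <- runif(25)
    mi <- mutual_information_pair(x, y)
    expect_equal(mi, oracle_mi(x, y), tolerance = 1e-12)
    expect_identical(mi, mutual_information_pair(y, x))
    expect_gt(mi, -1e-12)
  }
  set.seed(9)
  a <- runif(40)
  expect_identical(mutual_information_pair(a, a), marginal_entropy(a))
  # all values in one bin -> zero marginal entropy -> zero MI
  expect_equal(mutual_information_pair(rep(0.55, 12), runif(12)), 0)
})

test_that("similarity matrices match nested-loop oracles and are exactly symmetric", {
  pm <- random_profile_matrix(10, 15, seed = 21, absence = 0.3)
  m <- unclass(pm)
  for (metric in c("dcor", "pc", "mi")) {
    sm <- similarity_matrix(pm, metric)
    expect_identical(sm[lower.tri(sm)], t(sm)[lower.tri(sm)])
    ref <- matrix(0, 10, 10)
    for (p in 1:10) {
      for (q in 1:10) {
        ref[p, q] <- switch(metric,
          dcor = if (p == q) 1 else oracle_dcor2(m[p, ], m[q, ]),
          pc = if (p == q) 1 else stats::cor(m[p, ], m[q, ]),
          mi = if (p == q) {
            b <- oracle_mi(m[p, ], m[p, ])
            b
          } else {
            oracle_mi(m[p, ], m[q, ])
          }
        )
      }
    }
    expect_equal(unclass(sm), ref, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("dcor scores stay in [0, 1] and duplicate rows score 1", {
  pm <- random_profile_matrix(30, 12, seed = 5)
  sm <- similarity_matrix(pm, "dcor")
  expect_true(all(sm >= -1e-9 & sm <= 1 + 1e-9))
  v <- unclass(pm)
  dup <- profile_matrix(rbind(v, dup1 = v[1, ]))
  for (metric in c("dcor", "pc")) {
    s2 <- similarity_matrix(dup, metric)
    expect_equal(s2["p001", "dup1"], 1, tolerance = 1e-12)
  }
})

test_that("a constant profile is flagged but does not abort the matrix", {
  v <- unclass(random_profile_matrix(4, 10, seed = 8))
  v[2, ] <- 0.7
  pm <- profile_matrix(v)
  for (metric in c("dcor", "pc")) {
    sm <- similarity_matrix(pm, metric)
    expect_equal(attr(sm, "degenerate"), "p002")
    expect_true(all(sm["p002", ] == 0))
  }
})

test_that("similarity TSV round-trips", {
  sm <- similarity_matrix(random_profile_matrix(6, 9, seed = 13), "dcor")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_similarity_tsv(sm, path)
  back <- read_similarity_tsv(path, metric = "dcor")
  expect_equal(unclass(back), unclass(sm), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_identical(attr(back, "metric"), "dcor")
})
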