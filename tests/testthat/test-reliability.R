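test_that("difference functions match their closed forms", {
  expect_equal(difference_squared(5, 5, "ratio"), 0)
  expect_equal(difference_squared(1, 3, "ratio"), 0.25)
  expect_equal(difference_squared(1, 3, "interval"), 4)
  expect_equal(difference_squared(1, 3, "nominal"), 1)
  expect_equal(difference_squared(2, 2, "nominal"), 0)
  expect_true(all(difference_squared(c(1, 2), c(3, 2), "ratio") >= 0))
  expect_error(difference_squared(0, 0, "ratio"), "positive")
})

test_that("coincidence tables match hand enumeration and conserve totals", {
  # identical two-evaluator columns: all weight on the diagonal
  ct <- build_coincidence(cbind(A = 1:3, B = 1:3))
  expect_equal(unname(diag(ct$o)), c(2, 2, 2))
  expect_equal(sum(ct$o) - sum(diag(ct$o)), 0)
  expect_equal(ct$n, 6)

  # units (A=1,B=1) and (A=2,B=3): o_11 = 2, o_23 = o_32 = 1, n = 4
  ct <- build_coincidence(cbind(A = c(1, 2), B = c(1, 3)))
  expect_equal(ct$values, c(1, 2, 3))
  expect_equal(ct$o["1", "1"], 2)
  expect_equal(ct$o["2", "3"], 1)
  expect_equal(ct$o["3", "2"], 1)
  expect_equal(ct$n, 4)

  # one unit rated (2,2,4) by three evaluators: 1/(m_u-1) = 1/2 weights
  ct <- build_coincidence(matrix(c(2, 2, 4), nrow = 1))
  expect_equal(ct$o["2", "2"], 1)
  expect_equal(ct$o["2", "4"], 1)
  expect_equal(ct$o["4", "2"], 1)
  expect_equal(ct$n, 3)

  # conservation and symmetry on random tables
  set.seed(11)
  for (i in 1:20) {
    m <- random_ratings(sample(2:20, 1), sample(2:4, 1))
    ct <- build_coincidence(m)
    expect_equal(sum(ct$o), ct$n)
    expect_equal(ct$o, t(ct$o))
    expect_equal(ct$n_c, rowSums(ct$o))
  }
})

test_that("alpha is 1 for perfect agreement and <=1 generally", {
  r <- cbind(A = c(1, 2, 3, 4), B = c(1, 2, 3, 4))
  expect_equal(krippendorff_alpha(r, "ratio"), 1)
  expect_equal(krippendorff_alpha(r, "nominal"), 1)

  # all values identical everywhere: formally 0/0, returned as 1 + warning
  expect_warning(a <- krippendorff_alpha(cbind(c(2, 2), c(2, 2)), "ratio"),
                 "indeterminate")
  expect_equal(a, 1)
})

test_that("coincidence-matrix alpha equals the pairwise computation", {
  r <- cbind(A = c(1, 2, 3, 4), B = c(1, 2, 3, 5))
  expect_equal(krippendorff_alpha(r, "ratio"), alpha_pairwise(r, "ratio"),
               tolerance = 1e-14)

  set.seed(42)
  for (i in 1:100) {
    m <- random_ratings(sample(2:20, 1), sample(2:4, 1),
                        missing_rate = sample(c(0, 0.15), 1))
    for (metric in c("ratio", "interval", "nominal")) {
      a1 <- krippendorff_alpha(m, metric)
      a2 <- alpha_pairwise(m, metric)
      expect_lt(abs(a1 - a2), 1e-12)
      expect_lte(a1, 1 + 1e-12)
    }
  }
})

test_that("alpha reproduces published worked-example values", {
  tab <- published_example_table()
  for (metric in names(published_example_alpha)) {
    expect_equal(krippendorff_alpha(tab, metric),
                 unname(published_example_alpha[metric]), tolerance = 1e-12)
    expect_equal(alpha_pairwise(tab, metric),
                 unname(published_example_alpha[metric]), tolerance = 1e-12)
  }
  # the customary 3-decimal reporting of the nominal value
  expect_equal(round(krippendorff_alpha(tab, "nominal"), 3), 0.743)
})

test_that("ratio alpha is scale and permutation invariant", {
  set.seed(7)
  for (i in 1:10) {
    m <- random_ratings(12, 3)
    a <- krippendorff_alpha(m, "ratio")
    expect_equal(krippendorff_alpha(m * 10, "ratio"), a, tolerance = 1e-12)
    k <- stats::runif(1, 0.1, 50)
    expect_equal(krippendorff_alpha(m * k, "ratio"), a, tolerance = 1e-12)
    expect_equal(krippendorff_alpha(m[sample(nrow(m)), ], "ratio"), a,
                 tolerance = 1e-12)
    expect_equal(krippendorff_alpha(m[, sample(ncol(m))], "ratio"), a,
                 tolerance = 1e-12)
  }
})

test_that("alpha equals 1 iff all units are internally unanimous", {
  set.seed(3)
  for (i in 1:20) {
    m <- random_ratings(10, 3, missing_rate = 0.1)
    unanimous <- all(apply(m, 1, function(r) {
      v <- r[!is.na(r)]
      length(v) < 2 || all(v == v[1])
    }))
    a <- suppressWarnings(krippendorff_alpha(m, "ratio"))
    expect_equal(a == 1, unanimous)
  }
})

test_that("systematic disagreement yields negative alpha, unclamped", {
  r <- cbind(A = c(1, 2), B = c(2, 1))
  expect_equal(krippendorff_alpha(r, "nominal"), -0.5)
})

test_that("units with fewer than two values contribute nothing", {
  full <- cbind(A = c(1, 2, 3), B = c(1, 3, 3))
  padded <- rbind(full, c(9, NA), c(NA, 7))
  expect_equal(krippendorff_alpha(padded, "ratio"),
               krippendorff_alpha(full, "ratio"))
  expect_error(build_coincidence(cbind(c(1, NA), c(NA, 2))), "no pairable")
  expect_error(alpha_pairwise(cbind(c(1, NA), c(NA, 2))), "no pairable")
})

test_that("ratings validation rejects degenerate input", {
  expect_error(krippendorff_alpha(matrix(1:3, ncol = 1)), "2 evaluators")
  expect_error(krippendorff_alpha(cbind(c(1, -1), c(1, 2)), "ratio"), "positive")
})

test_that("quantization merges float representations of one grid point", {
  r <- cbind(A = c(0.033, 0.066), B = c(0.034, 0.065))
  expect_lt(krippendorff_alpha(r, "ratio"), 1)
  expect_equal(krippendorff_alpha(r, "ratio", resolution = 0.033), 1)
  # values below half a grid step stay positive under ratio quantization
  r2 <- cbind(A = c(0.01, 0.5), B = c(0.034, 0.51))
  expect_no_error(krippendorff_alpha(r2, "ratio", resolution = 0.033))
})

test_that("ratings CSV round-trips with empty cells as missing", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("E1,E2,E3", "1.5,1.5,", "2,2.5,2", ",3,3"), path)
  r <- read_ratings_csv(path)
  expect_equal(dim(r), c(3L, 3L))
  expect_true(is.na(r$E1[3]) && is.na(r$E3[1]))
  expect_s3_class(r, "tbl_df")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("E1,E2", "1.5,2.0", "oops,3"), bad)
  expect_error(read_ratings_csv(bad), "malformed")
})
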