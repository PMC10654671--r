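long_profile <- function(m) {
  tibble::tibble(site_id = rep(rownames(m), times = ncol(m)),
                 unit_id = rep(colnames(m), each = nrow(m)),
                 rel_abundance_pct = as.vector(m))
}

test_that("Bray-Curtis matches the closed forms", {
  same <- long_profile(matrix(c(40, 60, 40, 60), 2, byrow = TRUE,
                              dimnames = list(c("a", "b"), c("t1", "t2"))))
  expect_equal(as.vector(bray_curtis(same)), 0)

  disjoint <- long_profile(matrix(c(100, 0, 0, 100), 2, byrow = TRUE,
                                  dimnames = list(c("a", "b"), c("t1", "t2"))))
  expect_equal(as.vector(bray_curtis(disjoint)), 1)

  half <- long_profile(matrix(c(100, 0, 50, 50), 2, byrow = TRUE,
                              dimnames = list(c("a", "b"), c("t1", "t2"))))
  expect_equal(as.vector(bray_curtis(half)), 0.5)
})

test_that("Bray-Curtis agrees with an elementwise oracle on random profiles", {
  set.seed(11)
  for (i in 1:5) {
    m <- matrix(runif(5 * 8, 0, 10), 5, 8,
                dimnames = list(sprintf("s%d", 1:5), sprintf("t%d", 1:8)))
    m <- 100 * m / rowSums(m)
    d <- as.matrix(bray_curtis(long_profile(m)))
    for (a in 1:4) for (b in (a + 1):5) {
      expect_equal(d[a, b], oracle_bray(m[a, ], m[b, ]), tolerance = 1e-12)
    }
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(d, t(d))
    # permutation equivariance
    perm <- sample(1:5)
    dp <- as.matrix(bray_curtis(long_profile(m[perm, ])))
    expect_equal(dp[rownames(d), colnames(d)], d, tolerance = 1e-12)
  }
})

test_that("degenerate profile pairs are rejected", {
  m <- matrix(c(0, 0, 0, 0, 1, 2), 3, 2, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("t1", "t2")))
  expect_error(bray_curtis(long_profile(m)), "all-zero")
})

test_that("exactly embeddable distances reach near-zero stress", {
  square <- dist(matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE))
  ord <- nmds(square, k = 2, n_restarts = 5, seed = 3)
  expect_lt(ord$stress, 1e-6)
})

test_that("NMDS is deterministic under a fixed seed", {
  d <- bray_curtis(long_profile(matrix(runif(6 * 9, 0, 5), 6, 9,
                                       dimnames = list(sprintf("s%d", 1:6),
                                                       sprintf("t%d", 1:9)))))
  a <- nmds(d, k = 2, n_restarts = 8, seed = 21)
  b <- nmds(d, k = 2, n_restarts = 8, seed = 21)
  expect_identical(a$points, b$points)
  expect_identical(a$stress, b$stress)
})

test_that("stress is invariant under monotone transforms of dissimilarity", {
  set.seed(19)
  m <- matrix(runif(7 * 12, 0, 5), 7, 12,
              dimnames = list(sprintf("s%d", 1:7), sprintf("t%d", 1:12)))
  d <- bray_curtis(long_profile(m))
  s1 <- nmds(d, k = 2, n_restarts = 10, seed = 4)$stress
  s2 <- nmds(d^2, k = 2, n_restarts = 10, seed = 4)$stress
  expect_equal(s1, s2, tolerance = 1e-5)
})

test_that("the kept solution is the best of all restarts", {
  set.seed(23)
  m <- matrix(runif(6 * 10, 0, 5), 6, 10,
              dimnames = list(sprintf("s%d", 1:6), sprintf("t%d", 1:10)))
  ord <- nmds(bray_curtis(long_profile(m)), k = 2, n_restarts = 12, seed = 8)
  expect_length(ord$restart_stress, 12)
  expect_equal(ord$stress, min(ord$restart_stress))
})

test_that("input validation and accessors behave", {
  expect_error(nmds(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  sq <- dist(matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE))
  ord <- nmds(sq, k = 2, n_restarts = 3, seed = 1)
  td <- tidy(ord)
  expect_equal(names(td), c("site_id", "NMDS1", "NMDS2"))
  expect_equal(nrow(td), 4)
  # coordinates are centred
  expect_equal(colSums(ord$points), c(NMDS1 = 0, NMDS2 = 0), tolerance = 1e-8)
  gl <- glance(ord)
  expect_equal(gl$n_sites, 4)
  expect_s3_class(ggplot2::autoplot(ord), "ggplot")
})
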