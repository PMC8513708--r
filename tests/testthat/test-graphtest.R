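test_that("half-vectorization is the expected bijection", {
  expect_equal(vec_sym(matrix(5)), 5)
  R2 <- matrix(c(1, 2, 2, 3), 2)
  expect_equal(vec_sym(R2), c(1, 2, 3))  # order (1,1),(1,2),(2,2)
  set.seed(81)
  for (d in 2:6) {
    R <- crossprod(matrix(rnorm(d * d), d)); R <- (R + t(R)) / 2
    expect_equal(unvec_sym(vec_sym(R)), R, tolerance = 1e-12)
    expect_length(vec_sym(R), d * (d + 1) / 2)
  }
  expect_error(vec_sym(matrix(rnorm(4), 2)), "symmetric")
  expect_error(unvec_sym(c(1, 2, 3, 4)), "triangular")
})

test_that("score covariance handles degenerate and scalar cases", {
  n <- 6
  V <- qr.Q(qr(matrix(rnorm(n * 2), n, 2)))
  # deterministic edges: zero Bernoulli variance
  P01 <- matrix(1, n, n) - diag(n)
  expect_equal(score_covariance(V, P01)$Sigma, matrix(0, 3, 3),
               tolerance = 1e-14)
  # d = 1 collapses to an explicit scalar sum
  v <- matrix(1 / sqrt(n), n, 1)
  P <- matrix(0.3, n, n)
  sc <- score_covariance(v, P)
  ut <- upper.tri(P)
  manual <- sum(P[ut] * (1 - P[ut]) * (2 * v[, 1][row(P)[ut]] *
                                         v[, 1][col(P)[ut]])^2)
  expect_equal(sc$Sigma[1, 1], manual, tolerance = 1e-12)
  expect_equal(sc$r, 1L)
  expect_error(score_covariance(V, matrix(0.5, 4, 4)), "shape")
})

test_that("plug-in covariance matches the Monte Carlo oracle", {
  set.seed(82)
  n <- 8
  V <- qr.Q(qr(matrix(rnorm(n * 2), n, 2)))
  P <- matrix(0.3, n, n) + 0.2 * tcrossprod(V %*% diag(c(1, 0.6)), V)
  P <- pmin(pmax((P + t(P)) / 2, 0.05), 0.95); diag(P) <- 0
  sc <- score_covariance(V, P)
  # oracle: empirical covariance of vec(V' A V) over Monte Carlo graphs
  N <- 20000
  ut <- upper.tri(P)
  Fm <- sapply(seq_len(3), function(j) {
    k <- sc$index_map$k[j]; l <- sc$index_map$l[j]
    M <- outer(V[, k], V[, l]) + outer(V[, l], V[, k])
    M[ut]
  })
  Amat <- matrix(rbinom(N * sum(ut), 1, rep(P[ut], each = N)), N)
  emp <- stats::cov(Amat %*% Fm)
  # entrywise within 3 standard errors of a covariance estimate
  se <- sqrt((outer(diag(emp), diag(emp)) + emp^2) / N)
  expect_true(all(abs(emp - sc$Sigma) < 3 * se + 1e-12))
  # PSD within tolerance
  expect_gte(min(eigen(sc$Sigma, symmetric = TRUE)$values), -1e-12)
})

test_that("test statistic is the squared Frobenius distance", {
  R <- matrix(c(1, 2, 2, 4), 2)
  expect_equal(test_statistic(R, R), 0)
  expect_equal(test_statistic(matrix(3), matrix(1)), 4)
  set.seed(83)
  R1 <- crossprod(matrix(rnorm(9), 3)); R2 <- crossprod(matrix(rnorm(9), 3))
  expect_equal(test_statistic(R1, R2), sum((R1 - R2)^2))
  expect_error(test_statistic(matrix(1), R1), "dimension")
})

test_that("identical graphs give a null statistic and p-value one", {
  set.seed(84)
  mod <- rand_sbm(60, 2, 1)
  A <- simulate(mod, seed = 9)$A[[1]]
  tt <- cosie_test(A, A, d = 2, null = "bootstrap", n_null = 19, seed = 1)
  expect_equal(unname(tt$statistic), 0)
  expect_equal(tt$p.value, 1)
  expect_s3_class(tt, "htest")
})

test_that("a zero observed statistic cannot be rejected", {
  # identical graphs: observed statistic 0, every null draw at least as large
  n <- 20
  A <- matrix(1, n, n) - diag(n)
  tt <- cosie_test(A, A, d = 1, null = "asymptotic", n_null = 50, seed = 1)
  expect_lt(unname(tt$statistic), 1e-12)
  expect_equal(tt$p.value, 1)
  # deterministic edge probabilities give an exactly degenerate null
  V <- matrix(1 / sqrt(n), n, 1)
  expect_equal(score_covariance(V, matrix(1, n, n) - diag(n))$Sigma,
               matrix(0, 1, 1), tolerance = 1e-14)
})

test_that("the test rejects a clear distributional difference", {
  sc <- make_scenario("mmsbm-shift", n = 120, shift = 0.35, seed = 85)
  tb <- cosie_test(sc$sample$A[[1]], sc$sample$A[[2]], d = 3,
                   null = "bootstrap", n_null = 99, seed = 2)
  ta <- cosie_test(sc$sample$A[[1]], sc$sample$A[[2]], d = 3,
                   null = "asymptotic", n_null = 999, seed = 2)
  expect_lt(tb$p.value, 0.05)
  expect_lt(ta$p.value, 0.05)
})

test_that("pairwise score distances form a rotation-invariant metric", {
  set.seed(86)
  R_list <- replicate(4, crossprod(matrix(rnorm(9), 3)), simplify = FALSE)
  D <- pairwise_score_distances(R_list)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  # triangle inequality
  for (i in 1:4) for (j in 1:4) for (k in 1:4)
    expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
  # two-element list reduces to the square root of the test statistic
  expect_equal(pairwise_score_distances(R_list[1:2])[1, 2],
               sqrt(test_statistic(R_list[[1]], R_list[[2]])))
  # identical list gives the zero matrix
  expect_true(all(pairwise_score_distances(rep(R_list[1], 3)) == 0))
  # conjugating every score by one orthogonal matrix leaves D unchanged
  W <- rand_orth(3)
  Drot <- pairwise_score_distances(lapply(R_list, function(R)
    t(W) %*% R %*% W))
  expect_lt(max(abs(D - Drot)), 1e-10)
})
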