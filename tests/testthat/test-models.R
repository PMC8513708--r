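test_that("probability matrices reproduce closed-form special cases", {
  # Erdos-Renyi as a rank-1 model: constant edge probability p
  n <- 40; p <- 0.3
  er <- cosie_model(matrix(1 / sqrt(n), n, 1), matrix(p * n, 1, 1))
  P <- prob_matrices(er)[[1]]
  expect_equal(max(abs(P - p)), 0, tolerance = 1e-12)

  # identity subspace: P equals the score matrix itself
  set.seed(11)
  S <- crossprod(matrix(runif(25, 0, 0.4), 5)) / 5
  idm <- cosie_model(diag(5), S)
  expect_equal(prob_matrices(idm)[[1]], (S + t(S)) / 2, tolerance = 1e-12)

  # balanced 2-block model: the two distinct nonzero eigenvalues are
  # n/2 * (within +/- between) = 75 and 45 at n = 300
  mod <- sbm_model(rep(1:2, each = 150), 0.3 * diag(2) + 0.1)
  P2 <- prob_matrices(sbm_to_cosie(mod))[[1]]
  ev <- eigen(P2, symmetric = TRUE, only.values = TRUE)$values
  nz <- sort(ev[abs(ev) > 1e-8], decreasing = TRUE)
  # oracle: eigendecompose Z B Z' assembled directly
  Pdir <- mod$Z %*% mod$B[[1]] %*% t(mod$Z)
  ev_dir <- eigen(Pdir, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(nz, c(75, 45), tolerance = 1e-8)
  expect_equal(sort(ev_dir[abs(ev_dir) > 1e-8], decreasing = TRUE), nz,
               tolerance = 1e-8)
})

test_that("probability matrices reject out-of-range models", {
  n <- 20
  V <- matrix(1 / sqrt(n), n, 1)
  expect_error(prob_matrices(cosie_model(V, matrix(2 * n, 1, 1),
                                         check = FALSE)),
               "outside")
})

test_that("blockmodel-to-common-subspace conversion is exact", {
  # two rank-2 block matrices whose joint span needs all three communities
  a <- 0.6; b <- 0.2
  B1 <- matrix(c(a, b, b,  b, a, a,  b, a, a), 3, 3, byrow = TRUE)
  B2 <- matrix(c(a, a, b,  a, a, b,  b, b, a), 3, 3, byrow = TRUE)
  expect_equal(qr(B1)$rank, 2)
  expect_equal(qr(B2)$rank, 2)
  mod <- sbm_model(rep(1:3, each = 20), list(B1, B2))
  cp <- sbm_to_cosie(mod)
  expect_equal(cp$d, 3)
  expect_equal(qr(cbind(B1, B2))$rank, 3)

  # single community reduces to the Erdos-Renyi representation
  er <- sbm_to_cosie(sbm_model(rep(1, 30), matrix(0.4, 1, 1)))
  expect_equal(abs(er$V[, 1]), rep(1 / sqrt(30), 30), tolerance = 1e-12)
  expect_equal(abs(er$R[[1]][1, 1]), 0.4 * 30, tolerance = 1e-12)

  # random balanced 3-block model reconstructs exactly
  set.seed(21)
  mod3 <- rand_sbm(90, 3, 1)
  cp3 <- sbm_to_cosie(mod3)
  P <- prob_matrices(cp3)[[1]]
  expect_lt(max(abs(P - mod3$Z %*% mod3$B[[1]] %*% t(mod3$Z))), 1e-8)
})

test_that("conversion reconstructs random models and bounds the dimension", {
  set.seed(31)
  for (rep in 1:8) {
    K <- sample(2:6, 1); n <- sample(20:200, 1); m <- sample(1:5, 1)
    mod <- rand_sbm(n, K, m)
    cp <- sbm_to_cosie(mod)
    expect_lte(cp$d, K)
    expect_lt(max(abs(crossprod(cp$V) - diag(cp$d))), 1e-10)
    # d equals the rank of the concatenated scaled blocks
    sq <- sqrt(mod$sizes)
    Mcat <- do.call(cbind, lapply(mod$B, function(B) B * outer(sq, sq)))
    expect_equal(cp$d, qr(Mcat)$rank)
    for (i in seq_len(m)) {
      err <- max(abs(cp$V %*% cp$R[[i]] %*% t(cp$V) -
                       mod$Z %*% mod$B[[i]] %*% t(mod$Z)))
      expect_lt(err, 1e-8)
    }
  }
})

test_that("probability matrices are invariant to orthogonal rotation", {
  set.seed(41)
  for (rep in 1:5) {
    mod <- rand_sbm(60, 3, 2)
    cp <- sbm_to_cosie(mod)
    W <- rand_orth(cp$d)
    rot <- cosie_model(cp$V %*% W,
                       lapply(cp$R, function(R) t(W) %*% R %*% W),
                       check = FALSE)
    P1 <- prob_matrices(cp); P2 <- prob_matrices(rot)
    for (i in seq_along(P1)) expect_lt(max(abs(P1[[i]] - P2[[i]])), 1e-10)
  }
})

test_that("validation reports defects without raising", {
  mod <- sbm_model(rep(1:2, each = 20), 0.3 * diag(2) + 0.1)
  cp <- sbm_to_cosie(mod)
  rep0 <- validate_cosie(cp)
  expect_true(rep0$valid)
  expect_lt(rep0$orthonormality_defect, 1e-10)

  bad <- cp; bad$V[, 1] <- 2 * bad$V[, 1]
  repv <- validate_cosie(bad)
  expect_false(repv$valid)
  expect_equal(repv$orthonormality_defect, 3, tolerance = 1e-8)

  # scale a score matrix until probabilities exceed 1
  hot <- cp; hot$R[[1]] <- hot$R[[1]] * 10
  reph <- validate_cosie(hot)
  expect_false(reph$valid)
  expect_gt(reph$range_violation, 0)
})

test_that("maximum expected degree matches explicit row sums", {
  n <- 50; p <- 0.2
  P_er <- matrix(p, n, n)
  expect_equal(delta_max_row_sum(P_er), p * n)
  expect_equal(delta_max_row_sum(matrix(0, 4, 4)), 0)
  mod <- sbm_model(rep(1:2, each = 150), 0.3 * diag(2) + 0.1)
  P <- mod$Z %*% mod$B[[1]] %*% t(mod$Z)
  expect_equal(delta_max_row_sum(P), 150 * 0.4 + 150 * 0.1)
  expect_error(delta_max_row_sum(matrix(0, 2, 3)), "square")
})

test_that("embedding error scale matches term-by-term evaluation", {
  # Erdos-Renyi collection: closed form (1/(n m)) sum 1/p_i
  n <- 60; probs <- c(0.2, 0.5, 0.8)
  P_list <- lapply(probs, function(p) matrix(p, n, n))
  R_list <- lapply(probs, function(p) matrix(p * n, 1, 1))
  expect_equal(epsilon_stat(P_list, R_list), sum(1 / probs) / (n * length(probs)),
               tolerance = 1e-12)

  # single-graph identity-scaled case: delta = lambda gives 1/lambda
  lam <- 7
  expect_equal(epsilon_stat(list(diag(rep(lam, 3))), list(diag(rep(lam, 3)))),
               1 / lam, tolerance = 1e-12)

  # blockmodel preset vs brute-force evaluation of the defining sum
  set.seed(51)
  mod <- rand_sbm(90, 3, 3)
  cp <- sbm_to_cosie(mod)
  P_list <- prob_matrices(cp)
  brute <- mean(mapply(function(P, R) {
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    max(rowSums(P)) / min(abs(ev))^2
  }, P_list, cp$R))
  expect_equal(epsilon_stat(P_list, cp$R), brute, tolerance = 1e-12)
  expect_error(epsilon_stat(P_list, lapply(cp$R, function(R) R * 0)),
               "singular")
})
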