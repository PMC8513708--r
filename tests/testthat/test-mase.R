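test_that("single-graph fit reduces to the single spectral embedding", {
  set.seed(61)
  mod <- rand_sbm(60, 2, 1)
  A <- simulate(mod, seed = 1)$A[[1]]
  fit <- mase(list(A), d = 2)
  e <- ase(A, 2)
  expect_lt(subspace_distance(fit$V, e$eigvecs), 1e-8)
  expect_equal(fit$R[[1]], crossprod(fit$V, A %*% fit$V), tolerance = 1e-10)
})

test_that("noiseless probability matrices are fitted exactly", {
  set.seed(62)
  mod <- rand_sbm(80, 3, 3)
  cp <- sbm_to_cosie(mod)
  P_list <- prob_matrices(cp)
  fit <- mase(P_list, d = cp$d)
  expect_lt(subspace_distance(fit$V, cp$V), 1e-8)
  # scores recovered up to the global alignment rotation
  W <- procrustes_align(fit$V, cp$V)
  for (i in 1:3) {
    expect_lt(max(abs(fit$R[[i]] - t(W) %*% cp$R[[i]] %*% W)), 1e-8)
    expect_lt(max(abs(fitted(fit)[[i]] - P_list[[i]])), 1e-8)
  }
})

test_that("least-squares scores match an independent numerical optimizer", {
  set.seed(63)
  A <- crossprod(matrix(rnorm(36), 6)); A <- (A + t(A)) / 2
  V <- qr.Q(qr(matrix(rnorm(12), 6, 2)))
  R <- score_matrices(V, A)[[1]]
  # oracle: minimize ||A - V R V'||_F over symmetric R directly
  obj <- function(theta) {
    Rm <- unvec_sym(theta)
    sum((A - V %*% Rm %*% t(V))^2)
  }
  opt <- optim(rep(0, 3), obj, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  expect_lt(max(abs(vec_sym(R) - opt$par)), 1e-5)
  expect_lte(obj(vec_sym(R)), opt$value + 1e-10)
  # exact cases
  S <- matrix(c(2, 1, 1, -1), 2)
  expect_equal(score_matrices(V, V %*% S %*% t(V))[[1]], S, tolerance = 1e-10)
  expect_equal(score_matrices(V, matrix(0, 6, 6))[[1]], matrix(0, 2, 2))
})

test_that("out-of-sample scores agree with training scores", {
  set.seed(64)
  mod <- rand_sbm(50, 2, 3)
  g <- simulate(mod, seed = 2)
  fit <- mase(g, d = 2)
  expect_equal(predict(fit, g$A[[2]]), fit$R[[2]], tolerance = 1e-12)
  expect_equal(predict(fit, matrix(0, 50, 50)), matrix(0, 2, 2))
  expect_error(predict(fit, matrix(0, 10, 10)), "vertex")
})

test_that("procrustes alignment matches oracles", {
  set.seed(65)
  V <- qr.Q(qr(matrix(rnorm(60), 20, 3)))
  Q <- rand_orth(3)
  expect_equal(procrustes_align(V %*% Q, V), Q, tolerance = 1e-10)
  expect_equal(procrustes_align(V, V), diag(3), tolerance = 1e-10)

  V2 <- qr.Q(qr(matrix(rnorm(60), 20, 3)))
  W <- procrustes_align(V2, V)
  aligned <- sqrt(sum((V2 - V %*% W)^2))
  expect_lte(aligned, sqrt(sum((V2 - V)^2)) + 1e-12)
  # random-search oracle over many orthogonal candidates
  rand_best <- min(vapply(1:2000, function(i)
    sqrt(sum((V2 - V %*% rand_orth(3))^2)), 0))
  expect_lte(aligned, rand_best + 1e-12)
})

test_that("subspace distance identities hold", {
  set.seed(66)
  V <- qr.Q(qr(matrix(rnorm(40), 20, 2)))
  expect_lt(subspace_distance(V, V %*% rand_orth(2)), 1e-10)
  # orthogonal complement: spectral distance 1
  Vfull <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  expect_equal(subspace_distance(Vfull[, 1:2], Vfull[, 3:6]), 1,
               tolerance = 1e-10)
  # closed-form Frobenius identity for equal dimensions
  V2 <- qr.Q(qr(matrix(rnorm(40), 20, 2)))
  expect_equal(subspace_distance(V, V2, norm = "frobenius"),
               sqrt(2 * 2 - 2 * sum(crossprod(V, V2)^2)), tolerance = 1e-10)
  expect_error(subspace_distance(V, Vfull), "same n")
})

test_that("fits are invariant to the rotation of the generating parameters", {
  set.seed(67)
  mod <- rand_sbm(60, 3, 3)
  cp <- sbm_to_cosie(mod)
  W <- rand_orth(cp$d)
  rot <- cosie_model(cp$V %*% W, lapply(cp$R, function(R) t(W) %*% R %*% W),
                     check = FALSE)
  g1 <- simulate(cp, seed = 7)
  g2 <- simulate(rot, seed = 7)
  expect_equal(g1$A, g2$A)   # identical probabilities, identical seed
  f1 <- mase(g1, d = cp$d); f2 <- mase(g2, d = cp$d)
  for (i in 1:3)
    expect_lt(max(abs(fitted(f1)[[i]] - fitted(f2)[[i]])), 1e-10)
  expect_lt(max(abs(pairwise_score_distances(f1) -
                      pairwise_score_distances(f2))), 1e-10)
})

test_that("rank-1 probability estimation concentrates for a single graph", {
  n <- 500; p <- 0.5
  er <- cosie_model(matrix(1 / sqrt(n), n, 1), matrix(p * n, 1, 1))
  A <- simulate(er, seed = 8)$A[[1]]
  fit <- mase(list(A), d = 1)
  P <- prob_matrices(er)[[1]]
  expect_lt(sqrt(sum((fitted(fit)[[1]] - P)^2)) / sqrt(sum(P^2)), 0.1)
})

test_that("automatic dimension selection finds the model rank", {
  set.seed(68)
  mod <- sbm_model(rep(1:3, each = 70),
                   replicate(6, {
                     B <- matrix(0.1, 3, 3); diag(B) <- c(0.6, 0.5, 0.4); B
                   }, simplify = FALSE))
  g <- simulate(mod, seed = 3)
  fit <- mase(g, d = NULL, d_i = 3, n_elbows = 1)
  expect_equal(fit$d, 3)
  expect_equal(length(fit$joint_singular_values), 18)
})

test_that("fit objects expose standard accessors coherently", {
  set.seed(69)
  mod <- rand_sbm(40, 2, 2)
  g <- simulate(mod, seed = 4)
  fit <- mase(g, d = 2)
  expect_identical(coef(fit), fit$R)
  r <- residuals(fit)
  expect_equal(r[[1]] + fitted(fit)[[1]], g$A[[1]], tolerance = 1e-12)
  pf <- fitted(fit, type = "probability")
  expect_true(all(vapply(pf, min, 0) >= 0) && all(vapply(pf, max, 0) <= 1))
  s <- summary(fit)
  expect_s3_class(s, "summary.mase")
  expect_equal(dim(s$score_distances), c(2, 2))
  boot <- simulate(fit, seed = 11)
  expect_s3_class(boot, "graph_sample")
  expect_equal(boot$n, 40)
  expect_output(print(fit), "MASE fit")
})
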