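#' Half-vectorization of a symmetric matrix
#'
#' Stacks the upper triangle (including the diagonal) of a symmetric
#' \code{d x d} matrix into a vector of length \code{r = d (d + 1) / 2},
#' with entry \code{(k, l)}, \code{k <= l}, stored at position
#' \code{k + l (l - 1) / 2} (column-major upper triangle).
#'
#' @param R symmetric numeric matrix.
#' @param tol asymmetry tolerance.
#' @return Numeric vector of length \code{d (d + 1) / 2}.
#' @seealso [unvec_sym()]
#' @export
vec_sym <- function(R, tol = 1e-8) {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R) || max(abs(R - t(R))) > tol)
    stop("R must be symmetric")
  R[upper.tri(R, diag = TRUE)]
}

#' Inverse of the symmetric half-vectorization
#'
#' @param v numeric vector of length \code{d (d + 1) / 2}.
#' @return The symmetric \code{d x d} matrix with upper triangle \code{v}.
#' @export
unvec_sym <- function(v) {
  r <- length(v)
  d <- (sqrt(8 * r + 1) - 1) / 2
  if (d != round(d)) stop("length is not a triangular number")
  d <- as.integer(d)
  R <- matrix(0, d, d)
  R[upper.tri(R, diag = TRUE)] <- v
  R + t(R) - diag(diag(R), nrow = d)
}

# Frobenius norm squared of unvec(y): diagonal slots once, off-diagonal twice.
.sym_vec_weights <- function(d) {
  W <- matrix(2, d, d); diag(W) <- 1
  W[upper.tri(W, diag = TRUE)]
}

#' Asymptotic covariance of the half-vectorized score estimate
#'
#' For edge probabilities \code{P} and a subspace basis \code{V}, the
#' plug-in score estimate \code{V' A V} of a graph \code{A ~ Bernoulli(P)}
#' (symmetric, hollow, independent edges) has half-vectorized covariance
#' \deqn{\Sigma_{(k,l),(k',l')} = \sum_{s<t} P_{st}(1-P_{st})
#'   (V_{sk} V_{tl} + V_{tk} V_{sl})
#'   (V_{sk'} V_{tl'} + V_{tk'} V_{sl'}),}
#' the central-limit covariance of the estimated score matrices around
#' their aligned targets.  Its trace scale is governed by the total edge
#' variance \code{s2 = sum_{s,t} P_st (1 - P_st)}.
#'
#' @param V \code{n x d} matrix with orthonormal columns.
#' @param P symmetric \code{n x n} matrix with entries in \code{[0, 1]}.
#' @return An object of class \code{"score_covariance"}: list with the
#'   \code{r x r} matrix \code{Sigma} (\code{r = d (d + 1) / 2}), the
#'   \code{index_map} data frame mapping vec positions to \code{(k, l)}
#'   pairs, \code{r}, \code{d}, and the total edge variance \code{s2}
#'   (counting both triangles).
#' @export
score_covariance <- function(V, P) {
  V <- as.matrix(V); P <- as.matrix(P)
  n <- nrow(V); d <- ncol(V)
  if (nrow(P) != n || ncol(P) != n) stop("shape mismatch between V and P")
  ut <- upper.tri(P)
  w <- P[ut] * (1 - P[ut])
  r <- d * (d + 1L) / 2L
  Fm <- matrix(0, sum(ut), r)
  idx <- which(upper.tri(diag(d), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 2], idx[, 1]), , drop = FALSE]  # vec order
  for (j in seq_len(r)) {
    k <- idx[j, 1]; l <- idx[j, 2]
    M <- outer(V[, k], V[, l]) + outer(V[, l], V[, k])
    Fm[, j] <- M[ut]
  }
  Sigma <- crossprod(Fm, w * Fm)
  Sigma <- (Sigma + t(Sigma)) / 2
  structure(list(Sigma = Sigma,
                 index_map = data.frame(pos = seq_len(r),
                                        k = idx[, 1], l = idx[, 2]),
                 r = r, d = d, s2 = 2 * sum(w)),
            class = "score_covariance")
}

#' Two-sample score test statistic
#'
#' The squared Frobenius distance \code{||R1 - R2||_F^2} between the score
#' matrices of two graphs embedded in a common subspace; zero exactly when
#' the scores coincide, and invariant to the joint rotation that the
#' subspace basis is identified up to.
#'
#' @param R1,R2 symmetric matrices of equal dimension.
#' @return Nonnegative scalar.
#' @export
test_statistic <- function(R1, R2) {
  R1 <- as.matrix(R1); R2 <- as.matrix(R2)
  if (!all(dim(R1) == dim(R2))) stop("score matrices must match in dimension")
  sum((R1 - R2)^2)
}

# Scaled-embedding plug-in estimate of an edge-probability matrix, clamped.
.ase_prob_estimate <- function(A, d) {
  e <- ase(A, d, scaled = TRUE)
  P <- tcrossprod(e$scaled_positions %*%
                    diag(sign(e$eigvals), nrow = d), e$scaled_positions)
  pmin(pmax((P + t(P)) / 2, 0), 1)
}

# Draw N(0, 2 Sigma) with PSD projection; returns matrix n_draws x r.
.sample_gauss_null <- function(Sigma, n_draws, psd_tol = 1e-8) {
  e <- eigen(Sigma, symmetric = TRUE)
  if (min(e$values) < -psd_tol * max(abs(e$values), 1))
    warning("plug-in covariance has negative eigenvalues; projecting to PSD")
  lam <- pmax(e$values, 0)
  Z <- matrix(stats::rnorm(n_draws * length(lam)), n_draws)
  Z %*% (t(e$vectors) * sqrt(2 * lam))
}

#' Two-sample test of equality of graph distributions
#'
#' Tests whether two graphs on the same vertex set have equal
#' edge-probability matrices.  Both graphs are embedded jointly (common
#' subspace of dimension \code{d}); under the model the null
#' \code{P_1 = P_2} reduces to equality of the score matrices, and the test
#' statistic is \code{T = ||R1 - R2||_F^2}.  Large values are evidence
#' against the null; the p-value is upper-tailed with the add-one
#' correction, \code{p = (1 + #(null >= T)) / (n_null + 1)}.
#'
#' Two null distributions are available:
#' \describe{
#'   \item{\code{"bootstrap"}}{Parametric bootstrap.  Plug-in probability
#'     matrices are built from the scaled spectral embedding of each graph
#'     (clamped to \code{[0, 1]}); half the null replicates draw a pair of
#'     independent graphs from the first plug-in, half from the second, and
#'     each pair is refit by the same joint embedding at the same \code{d}
#'     before recomputing the statistic.}
#'   \item{\code{"asymptotic"}}{Generalized chi-square approximation.  Under
#'     the null the half-vectorized score difference is approximately
#'     Gaussian with covariance \code{2 Sigma}; \code{Sigma} is estimated
#'     by the plug-in [score_covariance()] at the fitted \code{(V, P_i)} of
#'     each graph, and the null statistic \code{||unvec(y)||_F^2} is
#'     sampled by Monte Carlo, half the draws from each plug-in (an
#'     equal-weight mixture).  This route is much cheaper than the
#'     bootstrap, but it neglects the finite-sample bias of the subspace
#'     estimate and requires full-rank score matrices; with only two graphs
#'     it can be anticonservative when those conditions fail.}
#' }
#'
#' @param A1,A2 symmetric adjacency matrices on the same vertex set.
#' @param d joint embedding dimension (\code{NULL} selects by elbow on the
#'   concatenated-embedding spectrum).
#' @param null \code{"bootstrap"} or \code{"asymptotic"}.
#' @param n_null number of null replicates (default 200 for the bootstrap,
#'   2000 for the asymptotic Monte Carlo).
#' @param seed integer seed for the null sampling.
#' @param scaled use scaled embeddings in the joint fit (default
#'   \code{FALSE}).
#' @return An object of classes \code{"cosie_test"} and \code{"htest"}:
#'   \code{statistic}, \code{p.value}, \code{method}, \code{null_samples},
#'   \code{null_type}, \code{n_null}, \code{seed}, and the joint \code{fit}.
#' @examples
#' sc <- make_scenario("mmsbm-shift", n = 80, shift = 0.3, seed = 7)
#' cosie_test(sc$sample$A[[1]], sc$sample$A[[2]], d = 3,
#'            null = "asymptotic", n_null = 500, seed = 1)
#' @export
cosie_test <- function(A1, A2, d = NULL,
                       null = c("bootstrap", "asymptotic"),
                       n_null = NULL, seed = NULL, scaled = FALSE) {
  null <- match.arg(null)
  A1 <- as.matrix(A1); A2 <- as.matrix(A2)
  if (!all(dim(A1) == dim(A2))) stop("graphs must share the vertex set")
  n <- nrow(A1)
  if (is.null(n_null)) n_null <- if (null == "bootstrap") 200L else 2000L
  fit <- mase(list(A1, A2), d = d, scaled = scaled)
  d <- fit$d
  if (d > n) stop("d cannot exceed the number of vertices")
  obs <- test_statistic(fit$R[[1]], fit$R[[2]])

  if (!is.null(seed)) set.seed(seed)
  if (null == "bootstrap") {
    P1 <- .ase_prob_estimate(A1, d)
    P2 <- .ase_prob_estimate(A2, d)
    n1 <- ceiling(n_null / 2)
    null_samples <- vapply(seq_len(n_null), function(b) {
      P <- if (b <= n1) P1 else P2
      Ab1 <- .sample_one_graph(P)
      Ab2 <- .sample_one_graph(P)
      bf <- mase(list(Ab1, Ab2), d = d, d_i = fit$d_i, scaled = scaled)
      test_statistic(bf$R[[1]], bf$R[[2]])
    }, 0)
  } else {
    Phat <- fitted(fit, type = "probability")
    wts <- .sym_vec_weights(d)
    n1 <- ceiling(n_null / 2)
    draws <- rbind(
      .sample_gauss_null(score_covariance(fit$V, Phat[[1]])$Sigma, n1),
      .sample_gauss_null(score_covariance(fit$V, Phat[[2]])$Sigma, n_null - n1))
    null_samples <- as.numeric(draws^2 %*% wts)
  }
  p <- (1 + sum(null_samples >= obs)) / (n_null + 1)
  structure(list(statistic = c(T = obs), p.value = p,
                 method = sprintf(
                   "Two-sample common-subspace score test (%s null, d = %d)",
                   null, d),
                 data.name = "A1 vs A2",
                 null_samples = null_samples, null_type = null,
                 n_null = n_null, seed = seed, fit = fit),
            class = c("cosie_test", "htest"))
}

#' Pairwise Frobenius distances between score matrices
#'
#' Builds the \code{m x m} matrix of distances \code{||R_i - R_j||_F}.
#' These distances are identifiable despite the rotational
#' non-identifiability of the individual score matrices, so they are the
#' natural input to distance-based downstream analysis (multidimensional
#' scaling, nearest-neighbour classification, clustering of graphs).
#'
#' @param R_list list of symmetric score matrices of common dimension, or a
#'   \code{"mase"} fit.
#' @return Symmetric \code{m x m} matrix with zero diagonal.
#' @export
pairwise_score_distances <- function(R_list) {
  if (inherits(R_list, "mase")) R_list <- R_list$R
  m <- length(R_list)
  d <- nrow(R_list[[1]])
  if (any(vapply(R_list, nrow, 0L) != d))
    stop("score matrices must share a common dimension")
  D <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (j > i) D[i, j] <- D[j, i] <- sqrt(sum((R_list[[i]] - R_list[[j]])^2))
  }
  D
}
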