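# Deterministic sign convention: each column's largest-magnitude entry
# (first index on ties) is made positive.
.fix_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' Adjacency spectral embedding
#'
#' Extracts the \code{d} eigenpairs of a symmetric matrix with the largest
#' eigenvalue magnitudes.  The unscaled embedding is the matrix of
#' eigenvectors \code{V}; the scaled embedding is
#' \code{X = V |D|^(1/2)}, which weights each direction by the square root
#' of its eigenvalue magnitude.  Eigenvalues are ordered by decreasing
#' magnitude (ties broken by signed value, then original position), and each
#' eigenvector's sign is fixed so that its largest-magnitude entry is
#' positive, making the output deterministic.
#'
#' A dense symmetric eigensolver is used up to \code{dense_limit} vertices;
#' larger matrices use an implicitly restarted Lanczos iteration for the
#' top-\code{d} pairs by magnitude.
#'
#' @param A symmetric numeric matrix (\code{n x n}).
#' @param d embedding dimension, \code{1 <= d <= n}.
#' @param scaled also return the scaled positions \code{X} (default
#'   \code{FALSE}).
#' @param diag_aug replace the (structurally zero) diagonal with
#'   \code{rowSums(A) / (n - 1)} before embedding.  A hollow adjacency
#'   matrix underestimates its expectation on the diagonal, which biases
#'   spectral estimates by roughly \code{-mean(diag(P))}; degree-based
#'   augmentation is the standard correction.  Default \code{FALSE}.
#' @param dense_limit matrix size above which the iterative solver is used.
#' @return An object of class \code{"ase"}: list with \code{eigvecs}
#'   (\code{n x d}), \code{eigvals} (length \code{d}), \code{scaled_positions}
#'   (\code{NULL} unless \code{scaled}), \code{d}, and logical
#'   \code{degenerate} (all selected eigenvalues numerically zero).
#' @examples
#' P <- 0.3 * diag(2)[rep(1:2, each = 20), ] %*% t(diag(2)[rep(1:2, each = 20), ]) + 0.1
#' e <- ase(P - diag(diag(P)), d = 2)
#' e$eigvals
#' @export
ase <- function(A, d, scaled = FALSE, diag_aug = FALSE, dense_limit = 2000) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (ncol(A) != n) stop("A must be square")
  if (max(abs(A - t(A))) > 1e-8) stop("A must be symmetric")
  if (d < 1 || d > n) stop("d must be between 1 and n")
  A <- (A + t(A)) / 2
  if (diag_aug) diag(A) <- (rowSums(A) - diag(A)) / (n - 1)
  if (n <= dense_limit || d > n / 4) {
    e <- eigen(A, symmetric = TRUE)
    ord <- order(-abs(e$values), -e$values, seq_len(n))[seq_len(d)]
    vals <- e$values[ord]
    vecs <- e$vectors[, ord, drop = FALSE]
  } else {
    res <- igraph::arpack(function(x, extra) A %*% x,
                          options = list(n = n, nev = d,
                                         ncv = min(n, max(4 * d, 20)),
                                         which = "LM", maxiter = 3000),
                          sym = TRUE)
    vals <- res$values
    vecs <- matrix(res$vectors, n, d)
    ord <- order(-abs(vals), -vals, seq_along(vals))
    vals <- vals[ord]
    vecs <- vecs[, ord, drop = FALSE]
  }
  vecs <- .fix_signs(vecs)
  degenerate <- all(abs(vals) < n * .Machine$double.eps * max(abs(A), 1))
  X <- if (scaled) vecs %*% diag(sqrt(abs(vals)), nrow = d) else NULL
  structure(list(eigvecs = vecs, eigvals = vals, scaled_positions = X,
                 d = d, degenerate = degenerate),
            class = "ase")
}

#' @export
print.ase <- function(x, ...) {
  cat(sprintf("Adjacency spectral embedding: %d vertices, d = %d%s\n",
              nrow(x$eigvecs), x$d,
              if (x$degenerate) " (degenerate: zero spectrum)" else ""))
  cat("  eigenvalues:", format(utils::head(x$eigvals, 8), digits = 4), "\n")
  invisible(x)
}

# Gaussian profile log-likelihood of splitting values into (1..q, q+1..p)
# with separate means and a pooled common variance.
.profile_loglik <- function(values, q) {
  p <- length(values)
  g1 <- values[seq_len(q)]
  g2 <- values[-seq_len(q)]
  mu1 <- mean(g1)
  mu2 <- if (length(g2)) mean(g2) else 0
  ss <- sum((g1 - mu1)^2) + sum((g2 - mu2)^2)
  sigma2 <- ss / p
  if (sigma2 <= 0) sigma2 <- .Machine$double.eps
  sum(stats::dnorm(g1, mu1, sqrt(sigma2), log = TRUE)) +
    sum(stats::dnorm(g2, mu2, sqrt(sigma2), log = TRUE))
}

#' Elbow selection of embedding dimension by profile likelihood
#'
#' Automates the scree-plot elbow: for each candidate split point \code{q}
#' the ordered values are modelled as two Gaussian groups with separate
#' means and a common (pooled) variance, and the \code{q} maximizing the
#' profile likelihood is the elbow.  With \code{n_elbows > 1}, the search
#' recurses on the values after the previous elbow, producing a sequence of
#' increasingly deep elbows; the dimension actually used downstream is the
#' last one by default, which in noisy spectra tends to step past the
#' dominant gap to the secondary structure.
#'
#' @param values nonincreasing nonnegative values (eigenvalue magnitudes or
#'   singular values).
#' @param n_elbows how many nested elbows to locate (default 2).
#' @return Integer vector of elbow positions (cumulative indices into
#'   \code{values}), of length at most \code{n_elbows}.
#' @examples
#' select_dim_elbow(c(10, 9.9, 0.1, 0.09))  # first elbow at 2
#' @export
select_dim_elbow <- function(values, n_elbows = 2) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("empty value sequence")
  if (any(diff(values) > 1e-8)) stop("values must be nonincreasing")
  if (length(values) < 2 || stats::sd(values) == 0) {
    if (length(values) >= 2)
      warning("constant value sequence: no elbow information")
    return(1L)
  }
  elbows <- integer(0)
  offset <- 0L
  v <- values
  for (e in seq_len(n_elbows)) {
    p <- length(v)
    if (p < 2) break
    ll <- vapply(seq_len(p), function(q) .profile_loglik(v, q), 0)
    q <- which.max(ll)
    elbows <- c(elbows, offset + q)
    if (q >= p) break
    offset <- offset + q
    v <- v[-seq_len(q)]
  }
  elbows
}
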