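#' Multiple adjacency spectral embedding (MASE)
#'
#' Fits the common-subspace independent-edge model to a sample of graphs on
#' an aligned vertex set.  The estimator proceeds in four steps:
#' \enumerate{
#'   \item embed each graph separately by adjacency spectral embedding on
#'     \code{d_i} dimensions (unscaled eigenvectors by default, or
#'     eigenvalue-scaled positions with \code{scaled = TRUE});
#'   \item concatenate the per-graph embeddings column-wise into an
#'     \code{n x sum(d_i)} matrix \code{U};
#'   \item take the \code{d} leading left singular vectors of \code{U} as
#'     the estimate \code{V} of the common subspace basis — the SVD aligns
#'     the per-graph embeddings, each of which estimates the subspace only
#'     up to its own rotation;
#'   \item estimate each score matrix by the least-squares solution
#'     \code{R_i = V' A_i V}.
#' }
#' Estimated edge-probability matrices are \code{V R_i V'} (see
#' [fitted.mase()]).  When \code{d} or \code{d_i} is missing it is chosen by
#' the profile-likelihood elbow of the relevant spectrum
#' ([select_dim_elbow()]): the per-graph eigenvalue magnitudes for
#' \code{d_i}, the singular values of \code{U} for \code{d}.
#'
#' The subspace estimate improves as the number of graphs grows even when
#' every graph has a different score matrix, which is what distinguishes
#' this estimator from embedding the mean adjacency matrix.
#'
#' @param graphs a \code{"graph_sample"}, or a list of symmetric adjacency
#'   matrices on a common vertex set.
#' @param d joint embedding dimension; \code{NULL} to select by elbow.
#' @param d_i per-graph embedding dimensions: a single integer recycled to
#'   all graphs, a vector of length \code{m}, or \code{NULL} to select per
#'   graph by elbow (defaults to \code{d} when \code{d} is given).
#' @param scaled use the scaled embedding in step 1 (default \code{FALSE};
#'   the unscaled variant is the one with supporting theory, but scaling can
#'   help when some score matrices are nearly singular).
#' @param diag_aug apply degree-based diagonal augmentation (see [ase()]) to
#'   each adjacency matrix before both the embedding and the scoring steps.
#'   Removes the downward bias that the structurally zero diagonal induces
#'   in the score (hence eigenvalue) estimates; default \code{FALSE}.
#' @param n_elbows elbow depth passed to [select_dim_elbow()] when
#'   dimensions are selected automatically; the last elbow found is used.
#' @param elbow which of the located elbows to use (default
#'   \code{n_elbows}, i.e. the deepest).
#' @return An object of class \code{"mase"}: list with \code{V} (\code{n x d},
#'   orthonormal columns), \code{R} (list of \code{m} symmetric \code{d x d}
#'   score matrices), \code{d}, \code{d_i}, \code{variant}
#'   (\code{"unscaled"}/\code{"scaled"}), \code{joint_singular_values} (the
#'   spectrum of \code{U}), \code{n}, \code{m}, and the input \code{graphs}.
#' @seealso [fitted.mase()], [predict.mase()], [cluster_subspace()],
#'   [cosie_test()]
#' @examples
#' mod <- sbm_model(rep(1:2, each = 30),
#'                  replicate(4, 0.3 * diag(2) + 0.1, simplify = FALSE))
#' g <- simulate(mod, seed = 1)
#' fit <- mase(g, d = 2)
#' fit
#' @export
mase <- function(graphs, d = NULL, d_i = NULL, scaled = FALSE,
                 diag_aug = FALSE, n_elbows = 2, elbow = n_elbows) {
  if (inherits(graphs, "graph_sample")) A <- graphs$A
  else if (is.list(graphs)) A <- lapply(graphs, as.matrix)
  else A <- list(as.matrix(graphs))
  m <- length(A)
  n <- nrow(A[[1]])
  if (any(vapply(A, nrow, 0L) != n) || any(vapply(A, ncol, 0L) != n))
    stop("all graphs must be square matrices on the same vertex set")
  if (diag_aug)
    A <- lapply(A, function(Ai) {
      diag(Ai) <- (rowSums(Ai) - diag(Ai)) / (n - 1)
      Ai
    })

  if (is.null(d_i)) {
    if (!is.null(d)) {
      d_i <- rep(as.integer(d), m)
    } else {
      d_i <- vapply(A, function(Ai) {
        vals <- sort(abs(eigen((Ai + t(Ai)) / 2, symmetric = TRUE,
                               only.values = TRUE)$values),
                     decreasing = TRUE)
        el <- select_dim_elbow(vals, n_elbows)
        el[min(elbow, length(el))]
      }, 0L)
    }
  } else {
    d_i <- as.integer(rep(d_i, length.out = m))
  }
  if (any(d_i > n)) stop("per-graph dimension exceeds the number of vertices")

  embeds <- lapply(seq_len(m), function(i) ase(A[[i]], d_i[i], scaled = scaled))
  U <- do.call(cbind, lapply(embeds, function(e)
    if (scaled) e$scaled_positions else e$eigvecs))
  sv <- svd(U, nu = min(nrow(U), ncol(U)), nv = 0)

  if (is.null(d)) {
    el <- select_dim_elbow(sv$d, n_elbows)
    d <- el[min(elbow, length(el))]
  }
  d <- as.integer(d)
  if (d > sum(d_i)) stop("d cannot exceed the total per-graph dimension")
  rank_tol <- max(dim(U)) * .Machine$double.eps * sv$d[1]
  if (d > sum(sv$d > rank_tol))
    warning("d exceeds the numerical rank of the concatenated embeddings")
  V <- .fix_signs(sv$u[, seq_len(d), drop = FALSE])

  R <- lapply(A, function(Ai) {
    Ri <- crossprod(V, Ai %*% V)
    (Ri + t(Ri)) / 2
  })
  structure(list(V = V, R = R, d = d, d_i = d_i,
                 variant = if (scaled) "scaled" else "unscaled",
                 joint_singular_values = sv$d,
                 n = n, m = m, graphs = A),
            class = "mase")
}

#' @export
print.mase <- function(x, ...) {
  cat(sprintf("MASE fit (%s): %d graphs, %d vertices, joint dimension d = %d\n",
              x$variant, x$m, x$n, x$d))
  cat("  per-graph dimensions:", paste(x$d_i, collapse = " "), "\n")
  cat("  leading singular values of concatenated embeddings:",
      format(utils::head(x$joint_singular_values, min(8, length(x$joint_singular_values))),
             digits = 4), "\n")
  invisible(x)
}

#' @export
summary.mase <- function(object, ...) {
  D <- pairwise_score_distances(object$R)
  P <- fitted(object, type = "probability")
  dens <- vapply(seq_along(object$graphs), function(i)
    mean(object$graphs[[i]][upper.tri(object$graphs[[i]])]), 0)
  out <- list(fit = object,
              mean_density = mean(dens),
              score_norms = vapply(object$R, function(R) sqrt(sum(R^2)), 0),
              score_distances = D,
              mean_fitted_range = range(vapply(P, range, numeric(2))))
  class(out) <- "summary.mase"
  out
}

#' @export
print.summary.mase <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  mean observed edge density: %.4f\n", x$mean_density))
  cat("  score-matrix Frobenius norms:",
      format(utils::head(x$score_norms, 8), digits = 4), "\n")
  if (x$fit$m > 1)
    cat(sprintf("  pairwise score distances: min %.3f, median %.3f, max %.3f\n",
                min(x$score_distances[upper.tri(x$score_distances)]),
                stats::median(x$score_distances[upper.tri(x$score_distances)]),
                max(x$score_distances[upper.tri(x$score_distances)])))
  invisible(x)
}

#' @export
coef.mase <- function(object, ...) object$R

#' Fitted edge-probability matrices
#'
#' Reconstructs \code{P_i = V R_i V'} for every graph of a MASE fit.  The
#' raw reconstruction is unconstrained; \code{type = "probability"} clamps
#' entries to \code{[0, 1]}.
#'
#' @param object a \code{"mase"} fit.
#' @param type \code{"raw"} (default) or \code{"probability"}.
#' @param ... unused.
#' @return List of \code{m} symmetric \code{n x n} matrices.
#' @export
fitted.mase <- function(object, type = c("raw", "probability"), ...) {
  type <- match.arg(type)
  lapply(object$R, function(R) {
    P <- object$V %*% R %*% t(object$V)
    P <- (P + t(P)) / 2
    if (type == "probability") P <- pmin(pmax(P, 0), 1)
    P
  })
}

#' @export
residuals.mase <- function(object, ...) {
  P <- fitted(object)
  mapply(function(A, Pi) A - Pi, object$graphs, P, SIMPLIFY = FALSE)
}

#' Out-of-sample score matrix for a new graph
#'
#' Projects a new adjacency matrix on the fitted common subspace without
#' refitting: \code{R_new = V' A_new V}, the least-squares score estimate
#' given \code{V}.  Useful to embed held-out graphs consistently with a
#' training fit, e.g. for nearest-neighbour classification on score
#' distances.
#'
#' @param object a \code{"mase"} fit.
#' @param newdata a symmetric adjacency matrix on the same vertex set, a
#'   list of them, or a \code{"graph_sample"}.
#' @param ... unused.
#' @return A symmetric \code{d x d} score matrix, or a list of them.
#' @export
predict.mase <- function(object, newdata, ...) {
  if (inherits(newdata, "graph_sample")) newdata <- newdata$A
  one <- !is.list(newdata)
  if (one) newdata <- list(as.matrix(newdata))
  out <- lapply(newdata, function(A) {
    A <- as.matrix(A)
    if (nrow(A) != object$n || ncol(A) != object$n)
      stop("new graph does not match the fitted vertex set")
    R <- crossprod(object$V, A %*% object$V)
    (R + t(R)) / 2
  })
  if (one) out[[1]] else out
}

#' Simulate graphs from a fitted model
#'
#' Draws Bernoulli graphs from the fitted edge-probability matrices
#' (clamped to \code{[0, 1]}), i.e. a parametric bootstrap of the fit.
#'
#' @param object a \code{"mase"} fit.
#' @param nsim number of replicate samples.
#' @param seed integer root seed or \code{NULL}.
#' @param ... unused.
#' @return A \code{"graph_sample"} (or a list of them when \code{nsim > 1}).
#' @export
simulate.mase <- function(object, nsim = 1, seed = NULL, ...) {
  P <- fitted(object, type = "probability")
  if (nsim == 1) return(.sample_ie_graphs(P, seed))
  seeds <- .graph_seeds(seed, nsim)
  lapply(seeds, function(s) .sample_ie_graphs(P, s))
}

#' @export
plot.mase <- function(x, which = c("scree", "embedding"), ...) {
  which <- match.arg(which)
  if (which == "scree") {
    graphics::plot(x$joint_singular_values, type = "b", pch = 16,
                   xlab = "index", ylab = "singular value",
                   main = "Concatenated-embedding spectrum", ...)
    graphics::abline(v = x$d + 0.5, lty = 2)
  } else {
    if (x$d == 1) {
      graphics::plot(x$V[, 1], xlab = "vertex", ylab = "v1",
                     main = "Common subspace", ...)
    } else {
      graphics::pairs(x$V[, seq_len(min(x$d, 4)), drop = FALSE],
                      labels = paste0("v", seq_len(min(x$d, 4))),
                      main = "Common subspace", ...)
    }
  }
  invisible(x)
}

#' Least-squares score matrices given a subspace basis
#'
#' For a fixed orthonormal basis \code{V}, the symmetric \code{R} minimizing
#' \code{||A - V R V'||_F} is \code{V' A V} (symmetrized).  This is step 4
#' of the joint embedding, exposed for use with an externally supplied
#' basis.
#'
#' @param V matrix with orthonormal columns (\code{n x d}).
#' @param graphs a \code{"graph_sample"}, list of adjacency matrices, or a
#'   single matrix.
#' @return List of symmetric \code{d x d} matrices (single matrix input
#'   gives a one-element list).
#' @export
score_matrices <- function(V, graphs) {
  if (inherits(graphs, "graph_sample")) graphs <- graphs$A
  if (!is.list(graphs)) graphs <- list(graphs)
  V <- as.matrix(V)
  lapply(graphs, function(A) {
    A <- as.matrix(A)
    if (nrow(A) != nrow(V)) stop("dimension mismatch between V and graph")
    R <- crossprod(V, A %*% V)
    (R + t(R)) / 2
  })
}

#' Orthogonal Procrustes alignment of two bases
#'
#' Finds the orthogonal \code{W} minimizing \code{||V_hat - V_ref W||_F},
#' i.e. the rotation of the reference basis closest to the estimate, from
#' the SVD of \code{V_ref' V_hat}.  Because the common subspace is
#' identifiable only up to rotation, estimates must be aligned this way
#' before entrywise comparison with the truth.
#'
#' @param V_hat,V_ref matrices of equal size with orthonormal columns.
#' @return The \code{d x d} orthogonal alignment matrix \code{W}.
#' @export
procrustes_align <- function(V_hat, V_ref) {
  V_hat <- as.matrix(V_hat); V_ref <- as.matrix(V_ref)
  if (!all(dim(V_hat) == dim(V_ref))) stop("shape mismatch")
  s <- svd(crossprod(V_ref, V_hat))
  s$u %*% t(s$v)
}

#' Distance between subspaces
#'
#' Measures the distance between the column spans of two orthonormal bases
#' as the spectral or Frobenius norm of the difference of the orthogonal
#' projections \code{V V'}.  Zero exactly when the spans coincide; the
#' spectral distance is 1 when some direction of one span is orthogonal to
#' the whole other span.
#'
#' @param V_hat,V_ref orthonormal-column matrices with the same number of
#'   rows (the dimensions may differ).
#' @param norm \code{"spectral"} (default) or \code{"frobenius"}.
#' @return Nonnegative scalar.
#' @export
subspace_distance <- function(V_hat, V_ref, norm = c("spectral", "frobenius")) {
  norm <- match.arg(norm)
  V_hat <- as.matrix(V_hat); V_ref <- as.matrix(V_ref)
  if (nrow(V_hat) != nrow(V_ref)) stop("bases must have the same n")
  D <- tcrossprod(V_hat) - tcrossprod(V_ref)
  if (norm == "spectral") {
    max(abs(eigen((D + t(D)) / 2, symmetric = TRUE, only.values = TRUE)$values))
  } else {
    sqrt(sum(D^2))
  }
}
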