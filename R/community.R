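# Minimum-cost assignment (Hungarian algorithm, shortest augmenting paths).
# cost: square numeric matrix. Returns perm such that row i is assigned to
# column perm[i], minimizing sum(cost[i, perm[i]]).
.solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  INF <- .Machine$double.xmax / 4
  # column indices shifted by 1 so that the virtual column 0 lives at 1
  u <- numeric(n + 1)    # row potentials (index i + 1; u[1] is the virtual row)
  v <- numeric(n + 1)    # column potentials
  p <- integer(n + 1)    # p[j+1]: row currently matched to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) {
            minv[j + 1] <- cur
            way[j + 1] <- j0
          }
          if (minv[j + 1] < delta) {
            delta <- minv[j + 1]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  perm <- integer(n)
  for (j in seq_len(n)) perm[p[j + 1]] <- j
  perm
}

.as_onehot <- function(z, K = NULL) {
  if (is.matrix(z)) return(z)
  z <- as.integer(z)
  if (is.null(K)) K <- max(z)
  diag(K)[z, , drop = FALSE]
}

#' Cluster vertices from an estimated common subspace
#'
#' Recovers community labels in a multilayer blockmodel by clustering the
#' rows of the estimated subspace basis \code{V} into \code{K} groups.  The
#' default is the K-means objective \code{||Z C - V||_F} over one-hot
#' memberships \code{Z} and centroids \code{C}, approximated by Lloyd
#' iterations from multiple seeded restarts with initial centers drawn from
#' distinct rows (best objective kept).  Alternatively a Gaussian mixture
#' with full covariances is fitted and vertices assigned by maximum
#' responsibility.
#'
#' @param V matrix whose rows are vertex positions — typically the \code{V}
#'   of a \code{"mase"} fit (a fit object is also accepted).
#' @param K number of communities, \code{K <= n}.
#' @param method \code{"kmeans"} (default; the objective with supporting
#'   theory) or \code{"gmm"}.
#' @param seed integer seed for the restarts / EM initialization.
#' @param nstart number of K-means restarts (default 20).
#' @return An object of class \code{"cluster_result"}: list with integer
#'   labels \code{z}, one-hot matrix \code{Z}, \code{centroids}
#'   (\code{K x d}), \code{method}, \code{objective} (the K-means Frobenius
#'   objective, or the GMM log-likelihood), and \code{K}.  A warning is
#'   emitted if any cluster is empty.
#' @export
cluster_subspace <- function(V, K, method = c("kmeans", "gmm"), seed = NULL,
                             nstart = 20) {
  if (inherits(V, "mase")) V <- V$V
  V <- as.matrix(V)
  n <- nrow(V)
  if (K > n) stop("K cannot exceed the number of vertices")
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  if (method == "kmeans") {
    uniq <- unique(V)
    best <- NULL
    for (s in seq_len(nstart)) {
      centers <- uniq[sample.int(nrow(uniq), min(K, nrow(uniq))), , drop = FALSE]
      if (nrow(centers) < K)  # fewer distinct rows than clusters
        centers <- rbind(centers,
                         V[sample.int(n, K - nrow(centers)), , drop = FALSE])
      km <- suppressWarnings(
        stats::kmeans(V, centers = centers, iter.max = 100,
                      algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    z <- best$cluster
    centroids <- best$centers
    objective <- sqrt(best$tot.withinss)
  } else {
    gmm <- mclust::Mclust(V, G = K, modelNames = "VVV", verbose = FALSE)
    if (is.null(gmm))
      gmm <- mclust::Mclust(V, G = K, verbose = FALSE)
    if (is.null(gmm)) stop("Gaussian mixture fit failed")
    z <- gmm$classification
    centroids <- t(gmm$parameters$mean)
    objective <- gmm$loglik
  }
  if (length(unique(z)) < K) warning("empty cluster in the solution")
  structure(list(z = as.integer(z), Z = .as_onehot(z, K),
                 centroids = centroids, method = method,
                 objective = objective, K = as.integer(K)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Subspace clustering (%s): %d vertices in %d communities\n",
              x$method, nrow(x$Z), x$K))
  cat("  sizes:", paste(tabulate(x$z, x$K), collapse = ", "), "\n")
  invisible(x)
}

#' Misclustering error up to label permutation
#'
#' Community labels are recovered only up to permutation, so the error
#' between an estimated and a true partition is the minimum over label
#' permutations \code{Q} of the number of disagreeing vertices — equivalently
#' of \code{||Z_hat - Z Q||_F}, which equals \code{sqrt(2 * count)}.  The
#' optimal permutation is found by a minimum-cost assignment on the
#' confusion matrix (padded when the two partitions use different numbers of
#' labels).
#'
#' @param z_hat,z_true estimated and true memberships: integer/factor
#'   vectors, one-hot matrices, or \code{"cluster_result"} objects.
#' @return List with \code{count} (misclustered vertices), \code{fraction},
#'   \code{frobenius} (\code{||Z_hat - Z Q||_F}), and \code{permutation}
#'   (the relabeling applied to \code{z_hat}).
#' @export
misclustering_error <- function(z_hat, z_true) {
  lab <- function(z) {
    if (inherits(z, "cluster_result")) z$z
    else if (is.matrix(z)) max.col(z)
    else as.integer(as.factor(z))
  }
  zh <- lab(z_hat); zt <- lab(z_true)
  if (length(zh) != length(zt)) stop("partitions have different lengths")
  n <- length(zh)
  K <- max(max(zh), max(zt))
  conf <- matrix(0, K, K)  # conf[a, b] = #{zh == a & zt == b}
  for (i in seq_len(n)) conf[zh[i], zt[i]] <- conf[zh[i], zt[i]] + 1
  perm <- .solve_assignment(max(conf) - conf)  # maximize agreement
  count <- n - sum(conf[cbind(seq_len(K), perm)])
  list(count = as.integer(count), fraction = count / n,
       frobenius = sqrt(2 * count), permutation = perm)
}
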