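#' A sample of graphs on a common vertex set
#'
#' Light container for \code{m} symmetric hollow adjacency matrices on
#' \code{n} aligned vertices, with optional vertex and graph labels.
#'
#' @param A list of adjacency matrices (symmetric, zero diagonal).
#' @param vertex_ids optional vertex labels (default \code{1..n}).
#' @param graph_ids optional graph labels (default \code{1..m}).
#' @param labels optional per-graph class labels.
#' @param check verify symmetry and hollowness.
#' @return An object of class \code{"graph_sample"}.
#' @export
graph_sample <- function(A, vertex_ids = NULL, graph_ids = NULL,
                         labels = NULL, check = TRUE) {
  if (!is.list(A)) A <- list(A)
  A <- lapply(A, as.matrix)
  n <- nrow(A[[1]])
  if (check) {
    for (i in seq_along(A)) {
      Ai <- A[[i]]
      if (nrow(Ai) != n || ncol(Ai) != n)
        stop("all graphs must share the same vertex set")
      if (max(abs(Ai - t(Ai))) > 0) stop(sprintf("graph %d is not symmetric", i))
      if (any(diag(Ai) != 0)) stop(sprintf("graph %d has self-loops", i))
      if (any(Ai < 0)) stop(sprintf("graph %d has negative weights", i))
    }
  }
  if (is.null(vertex_ids)) vertex_ids <- seq_len(n)
  if (is.null(graph_ids)) graph_ids <- seq_along(A)
  structure(list(A = A, n = n, m = length(A),
                 vertex_ids = vertex_ids, graph_ids = graph_ids,
                 labels = labels),
            class = "graph_sample")
}

#' @export
print.graph_sample <- function(x, ...) {
  dens <- mean(vapply(x$A, function(A) mean(A[upper.tri(A)] > 0), 0))
  cat(sprintf("Graph sample: %d graphs on %d vertices (mean density %.3f)\n",
              x$m, x$n, dens))
  if (!is.null(x$labels))
    cat("  labels:", paste(utils::head(x$labels, 10), collapse = " "),
        if (x$m > 10) "..." else "", "\n")
  invisible(x)
}

# Per-graph substream seeds derived from one root seed, so graph i is
# reproducible regardless of how many graphs are drawn or in what order.
.graph_seeds <- function(seed, m) {
  if (is.null(seed)) return(rep(list(NULL), m))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  as.list(sample.int(.Machine$integer.max, m))
}

# One Bernoulli graph from a probability matrix; upper triangle sampled,
# mirrored, diagonal forced to zero.
.sample_one_graph <- function(P, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(P)
  A <- matrix(0, n, n)
  ut <- upper.tri(A)
  A[ut] <- stats::rbinom(sum(ut), 1L, P[ut])
  A + t(A)
}

.sample_ie_graphs <- function(P_list, seed = NULL) {
  seeds <- .graph_seeds(seed, length(P_list))
  graph_sample(mapply(.sample_one_graph, P_list, seeds, SIMPLIFY = FALSE),
               check = FALSE)
}

#' Simulate graphs from a COSIE model
#'
#' Draws one Bernoulli graph per score matrix: edge \code{(u, v)} of graph
#' \code{i} is present independently with probability \code{(V R_i V')_uv};
#' graphs are symmetric and hollow.  Each graph uses its own RNG substream
#' derived from \code{seed}, so results do not depend on sampling order.
#'
#' @param object a \code{"cosie"} object.
#' @param nsim number of independent replicate samples (default 1).
#' @param seed integer root seed, or \code{NULL} to use the current RNG state.
#' @param ... unused.
#' @return A \code{"graph_sample"} with \code{m} graphs, or a list of
#'   \code{nsim} such samples when \code{nsim > 1}.
#' @export
simulate.cosie <- function(object, nsim = 1, seed = NULL, ...) {
  P <- prob_matrices(object)
  if (nsim == 1) return(.sample_ie_graphs(P, seed))
  seeds <- .graph_seeds(seed, nsim)
  lapply(seeds, function(s) .sample_ie_graphs(P, s))
}

#' Simulate graphs from a multilayer stochastic blockmodel
#'
#' Each graph \code{i} is an independent SBM draw with the shared membership
#' matrix \code{Z} and its own connectivity \code{B_i}, i.e. edge
#' probabilities \code{Z B_i Z'}.
#'
#' @inheritParams simulate.cosie
#' @param object a \code{"multilayer_sbm"} object.
#' @return A \code{"graph_sample"}, or a list of them when \code{nsim > 1}.
#' @export
simulate.multilayer_sbm <- function(object, nsim = 1, seed = NULL, ...) {
  P <- lapply(object$B, function(B) {
    P <- object$Z %*% B %*% t(object$Z)
    (P + t(P)) / 2
  })
  if (nsim == 1) return(.sample_ie_graphs(P, seed))
  seeds <- .graph_seeds(seed, nsim)
  lapply(seeds, function(s) .sample_ie_graphs(P, s))
}

# Symmetric Dirichlet rows via normalized gammas.
.rdirichlet <- function(n, alpha, K) {
  g <- matrix(stats::rgamma(n * K, shape = alpha), n, K)
  g / rowSums(g)
}

#' Sample a mixed-membership stochastic blockmodel graph
#'
#' Vertex memberships are rows on the \code{K}-simplex drawn from a
#' symmetric Dirichlet with concentration \code{dirichlet_alpha}; the edge
#' probability matrix is \code{P = Z B Z'} and one Bernoulli graph is drawn
#' from it.  Small concentrations put most vertices near a single community;
#' large concentrations mix all communities evenly.
#'
#' @param n number of vertices.
#' @param B symmetric \code{K x K} connectivity matrix in \code{[0, 1]}.
#' @param dirichlet_alpha positive Dirichlet concentration (default 0.1).
#' @param seed integer seed or \code{NULL}.
#' @param Z optional pre-drawn \code{n x K} membership matrix with simplex
#'   rows (used to share memberships across graphs); when supplied only the
#'   graph is random.
#' @return List with the \code{"graph_sample"} (\code{$sample}, one graph),
#'   the membership matrix \code{$Z}, and \code{$P}.
#' @export
sample_mmsbm <- function(n, B, dirichlet_alpha = 0.1, seed = NULL, Z = NULL) {
  B <- as.matrix(B)
  K <- nrow(B)
  if (max(abs(B - t(B))) > 1e-12 || any(B < 0) || any(B > 1))
    stop("B must be symmetric with entries in [0, 1]")
  if (dirichlet_alpha <= 0) stop("dirichlet_alpha must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(Z)) {
    Z <- .rdirichlet(n, dirichlet_alpha, K)
  } else {
    Z <- as.matrix(Z)
    stopifnot(nrow(Z) == n, ncol(Z) == K)
  }
  P <- Z %*% B %*% t(Z)
  P <- (P + t(P)) / 2
  list(sample = graph_sample(list(.sample_one_graph(P)), check = FALSE),
       Z = Z, P = P)
}
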