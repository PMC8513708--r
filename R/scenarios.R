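#' Named simulation scenarios
#'
#' Generates the parameter objects and a graph sample for the benchmark
#' simulation settings used throughout the package, with their standard
#' parameter values built in:
#'
#' \describe{
#'   \item{\code{"homo-3block"}}{A homogeneous three-block multilayer SBM on
#'     \code{n = 729} vertices with balanced communities; every graph shares
#'     the connectivity matrix
#'     \code{rbind(c(.4,.1,.1), c(.1,.4,.2), c(.1,.2,.3))}.}
#'   \item{\code{"hetero-3block"}}{Same partition, but each graph draws its
#'     own symmetric connectivity matrix with entries uniform on
#'     \code{[0, 1]} — a strongly heterogeneous population in which
#'     averaging the adjacency matrices destroys the block signal.}
#'   \item{\code{"four-class"}}{A two-block multilayer SBM on \code{n = 256}
#'     vertices, \code{m = 40} graphs in four classes of 10 (labels
#'     1,...,1,2,...,2,...).  Class \code{k} has connectivity
#'     \code{0.25 + alpha * C_k} with \code{C_1 = diag(.1, .1)},
#'     \code{C_2 = -diag(.1, .1)}, \code{C_3 = diag(.1, 0)},
#'     \code{C_4 = diag(0, .1)}; \code{alpha} controls class separation
#'     (and, at 0, collapses all classes and zeroes the smallest
#'     eigenvalue).}
#'   \item{\code{"mmsbm-shift"}}{Two graphs from a three-community
#'     mixed-membership SBM with shared memberships (symmetric Dirichlet,
#'     concentration 0.1); \code{B_1 = 0.3 I + 0.1} and \code{B_2} equals
#'     \code{B_1} except \code{B[1,1]} is increased by \code{shift}.  A
#'     two-sample testing scenario: \code{shift = 0} is the null.}
#'   \item{\code{"mmsbm-memberships"}}{Two graphs with equal connectivity
#'     \code{B_1 = 0.3 I + 0.1} but the memberships of the first \code{t}
#'     vertices redrawn independently in the second graph.}
#' }
#'
#' @param name scenario name (see Details).
#' @param n,m override the vertex / graph counts (defaults above).
#' @param alpha class-separation parameter for \code{"four-class"}.
#' @param shift increment of \code{B[1,1]} for \code{"mmsbm-shift"}.
#' @param t number of perturbed vertices for \code{"mmsbm-memberships"}.
#' @param seed integer seed controlling both the random parameters (where a
#'   scenario has any) and the graph draws.
#' @return A list with \code{name}, \code{params} (a
#'   \code{"multilayer_sbm"} object, or a list with \code{B}, \code{Z},
#'   \code{P} per graph for the mixed-membership scenarios), \code{sample}
#'   (a \code{"graph_sample"}), and \code{labels} (per-graph classes, where
#'   defined).
#' @export
make_scenario <- function(name, n = NULL, m = NULL, alpha = 1, shift = 0,
                          t = 10, seed = NULL) {
  name <- match.arg(name, c("homo-3block", "hetero-3block", "four-class",
                            "mmsbm-shift", "mmsbm-memberships"))
  seeds <- if (is.null(seed)) list(NULL, NULL) else {
    set.seed(seed); as.list(sample.int(.Machine$integer.max, 2))
  }
  switch(name,
    "homo-3block" = {
      if (is.null(n)) n <- 729
      if (is.null(m)) m <- 1
      B <- matrix(c(.4, .1, .1,
                    .1, .4, .2,
                    .1, .2, .3), 3, 3, byrow = TRUE)
      mod <- sbm_model(rep(1:3, each = n %/% 3), rep(list(B), m))
      list(name = name, params = mod,
           sample = simulate(mod, seed = seeds[[2]]), labels = NULL)
    },
    "hetero-3block" = {
      if (is.null(n)) n <- 729
      if (is.null(m)) m <- 1
      if (!is.null(seeds[[1]])) set.seed(seeds[[1]])
      B <- replicate(m, {
        Bi <- matrix(0, 3, 3)
        Bi[upper.tri(Bi, diag = TRUE)] <- stats::runif(6)
        Bi[lower.tri(Bi)] <- t(Bi)[lower.tri(Bi)]
        Bi
      }, simplify = FALSE)
      mod <- sbm_model(rep(1:3, each = n %/% 3), B)
      list(name = name, params = mod,
           sample = simulate(mod, seed = seeds[[2]]), labels = NULL)
    },
    "four-class" = {
      if (is.null(n)) n <- 256
      if (is.null(m)) m <- 40
      Cmats <- list(diag(c(.1, .1)), -diag(c(.1, .1)),
                    diag(c(.1, 0)), diag(c(0, .1)))
      labels <- rep(1:4, each = ceiling(m / 4))[seq_len(m)]
      B <- lapply(labels, function(k) 0.25 + alpha * Cmats[[k]])
      mod <- sbm_model(rep(1:2, each = n %/% 2), B)
      smp <- simulate(mod, seed = seeds[[2]])
      smp$labels <- labels
      list(name = name, params = mod, sample = smp, labels = labels)
    },
    "mmsbm-shift" = {
      if (is.null(n)) n <- 150
      B1 <- 0.3 * diag(3) + 0.1
      B2 <- B1; B2[1, 1] <- B2[1, 1] + shift
      if (B2[1, 1] > 1) stop("shift pushes B[1,1] above 1")
      g1 <- sample_mmsbm(n, B1, 0.1, seed = seeds[[1]])
      g2 <- sample_mmsbm(n, B2, 0.1, seed = seeds[[2]], Z = g1$Z)
      smp <- graph_sample(c(g1$sample$A, g2$sample$A), check = FALSE)
      list(name = name,
           params = list(B = list(B1, B2), Z = list(g1$Z, g2$Z),
                         P = list(g1$P, g2$P)),
           sample = smp, labels = c(1L, 2L))
    },
    "mmsbm-memberships" = {
      if (is.null(n)) n <- 150
      if (t > n) stop("t cannot exceed n")
      B1 <- 0.3 * diag(3) + 0.1
      g1 <- sample_mmsbm(n, B1, 0.1, seed = seeds[[1]])
      if (!is.null(seeds[[2]])) set.seed(seeds[[2]])
      Z2 <- g1$Z
      if (t > 0) Z2[seq_len(t), ] <- .rdirichlet(t, 0.1, 3)
      g2 <- sample_mmsbm(n, B1, 0.1, Z = Z2)
      smp <- graph_sample(c(g1$sample$A, g2$sample$A), check = FALSE)
      list(name = name,
           params = list(B = list(B1, B1), Z = list(g1$Z, Z2),
                         P = list(g1$P, g2$P)),
           sample = smp, labels = c(1L, 2L))
    })
}
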