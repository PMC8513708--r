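#' Common subspace independent-edge (COSIE) model parameters
#'
#' Constructs the parameter object of a COSIE model for \code{m} graphs on
#' \code{n} aligned vertices: an \code{n x d} matrix \code{V} with orthonormal
#' columns spanning the common invariant subspace, and \code{m} symmetric
#' \code{d x d} score matrices \code{R} giving each graph its own connectivity
#' within that subspace.  The expected adjacency matrix of graph \code{i} is
#' \code{P_i = V R_i V'}, whose entries must all lie in \code{[0, 1]}.
#'
#' The parameters are identifiable only up to a joint orthogonal rotation
#' \code{W}: \code{(V W, W' R_i W)} induces the same edge probabilities.
#' All downstream estimates and tests are invariant to this rotation.
#'
#' @param V numeric matrix with orthonormal columns (\code{n x d}).
#' @param R a symmetric \code{d x d} matrix or a list of \code{m} such
#'   matrices, one per graph.
#' @param check validate the orthonormality, symmetry and probability-range
#'   constraints (default \code{TRUE}).
#' @param tol numeric tolerance for the validity checks.
#' @return An object of class \code{"cosie"}: a list with elements \code{V},
#'   \code{R} (list of score matrices), and integers \code{n}, \code{m},
#'   \code{d}.
#' @seealso [sbm_model()], [sbm_to_cosie()], [prob_matrices()],
#'   [simulate.cosie()], [validate_cosie()]
#' @examples
#' # Erdos-Renyi G(n, p) as a rank-1 COSIE model
#' n <- 50; p <- 0.3
#' er <- cosie_model(matrix(1 / sqrt(n), n, 1), matrix(p * n, 1, 1))
#' range(prob_matrices(er)[[1]])
#' @export
cosie_model <- function(V, R, check = TRUE, tol = 1e-8) {
  V <- as.matrix(V)
  if (!is.list(R)) R <- list(R)
  R <- lapply(R, as.matrix)
  n <- nrow(V); d <- ncol(V); m <- length(R)
  if (m < 1L) stop("at least one score matrix is required")
  for (i in seq_len(m)) {
    if (!all(dim(R[[i]]) == c(d, d)))
      stop(sprintf("score matrix %d is not %d x %d", i, d, d))
  }
  obj <- structure(list(V = V, R = R, n = n, m = m, d = d), class = "cosie")
  if (check) {
    rep <- validate_cosie(obj, tol = tol)
    if (!rep$valid)
      stop("invalid COSIE parameters: ",
           paste(rep$messages, collapse = "; "))
  }
  obj
}

#' @export
print.cosie <- function(x, ...) {
  cat(sprintf("COSIE model: %d graphs on %d vertices, subspace dimension %d\n",
              x$m, x$n, x$d))
  invisible(x)
}

#' Multilayer stochastic blockmodel parameters
#'
#' Constructs the parameters of a multilayer SBM: a fixed community
#' partition of \code{n} vertices into \code{K} blocks shared by all graphs,
#' and per-graph symmetric \code{K x K} block connectivity matrices
#' \code{B} with entries in \code{[0, 1]}.  Graph \code{i} has expected
#' adjacency matrix \code{Z B_i Z'}, where \code{Z} is the one-hot
#' membership matrix.
#'
#' @param z community memberships: either an integer/factor vector of length
#'   \code{n} with values in \code{1..K}, or an \code{n x K} one-hot matrix.
#' @param B a symmetric \code{K x K} matrix in \code{[0, 1]} or a list of
#'   \code{m} such matrices.
#' @return An object of class \code{"multilayer_sbm"}: list with the one-hot
#'   matrix \code{Z}, memberships \code{z}, list \code{B}, community sizes
#'   \code{sizes} and their diagonal matrix \code{Xi}, and integers \code{n},
#'   \code{m}, \code{K}.
#' @seealso [sbm_to_cosie()], [simulate.multilayer_sbm()]
#' @examples
#' mod <- sbm_model(rep(1:2, each = 25), 0.3 * diag(2) + 0.1)
#' mod$sizes
#' @export
sbm_model <- function(z, B) {
  if (is.matrix(z)) {
    Z <- z
    if (any(rowSums(Z) != 1) || !all(Z %in% c(0, 1)))
      stop("membership matrix must have exactly one 1 per row")
    z <- max.col(Z)
  } else {
    z <- as.integer(as.factor(z))
    Z <- diag(max(z))[z, , drop = FALSE]
  }
  K <- ncol(Z); n <- nrow(Z)
  sizes <- colSums(Z)
  if (any(sizes == 0)) stop("empty community")
  if (!is.list(B)) B <- list(B)
  B <- lapply(B, as.matrix)
  for (i in seq_along(B)) {
    Bi <- B[[i]]
    if (!all(dim(Bi) == c(K, K)))
      stop(sprintf("connectivity matrix %d is not %d x %d", i, K, K))
    if (max(abs(Bi - t(Bi))) > 1e-12)
      stop(sprintf("connectivity matrix %d is not symmetric", i))
    if (any(Bi < 0) || any(Bi > 1))
      stop(sprintf("connectivity matrix %d has entries outside [0, 1]", i))
  }
  structure(list(Z = Z, z = z, B = B, sizes = sizes,
                 Xi = diag(sizes, nrow = K), n = n, m = length(B), K = K),
            class = "multilayer_sbm")
}

#' @export
print.multilayer_sbm <- function(x, ...) {
  cat(sprintf(
    "Multilayer SBM: %d graphs, %d vertices, %d communities (sizes %s)\n",
    x$m, x$n, x$K, paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Edge-probability matrices of a COSIE model
#'
#' Computes \code{P_i = V R_i V'} for every graph in the model.
#'
#' @param params a \code{"cosie"} object.
#' @param tol tolerance for the probability-range check.
#' @return List of \code{m} symmetric \code{n x n} matrices with entries in
#'   \code{[0, 1]}.
#' @export
prob_matrices <- function(params, tol = 1e-12) {
  stopifnot(inherits(params, "cosie"))
  lapply(params$R, function(R) {
    P <- params$V %*% R %*% t(params$V)
    P <- (P + t(P)) / 2
    if (min(P) < -tol || max(P) > 1 + tol)
      stop("edge probabilities fall outside [0, 1]: invalid model")
    pmin(pmax(P, 0), 1)
  })
}

#' Validate COSIE parameters
#'
#' Measures how far a parameter set is from satisfying the model constraints:
#' orthonormality of the columns of \code{V}, symmetry of every score
#' matrix, and edge probabilities inside \code{[0, 1]}.  Reports defects
#' instead of raising, so it can be used to diagnose broken inputs.
#'
#' @param params a \code{"cosie"} object (its fields are inspected directly,
#'   so an invalid object built with \code{check = FALSE} is acceptable).
#' @param tol tolerance below which a defect is considered zero.
#' @return A list with \code{orthonormality_defect}
#'   (\code{max |V'V - I|}), \code{asymmetry_defect} (largest
#'   \code{max |R - R'|} over graphs), \code{range_violation} (largest
#'   excursion of any \code{P_i} entry outside \code{[0, 1]}), logical
#'   \code{valid}, and character \code{messages}.
#' @export
validate_cosie <- function(params, tol = 1e-8) {
  V <- params$V
  ortho <- max(abs(crossprod(V) - diag(ncol(V))))
  asym <- max(vapply(params$R, function(R) max(abs(R - t(R))), 0))
  range_viol <- 0
  for (R in params$R) {
    P <- V %*% ((R + t(R)) / 2) %*% t(V)
    range_viol <- max(range_viol, -min(P, 0), max(P - 1, 0))
  }
  msgs <- character()
  if (ortho > tol)
    msgs <- c(msgs, sprintf("columns of V not orthonormal (defect %.3g)", ortho))
  if (asym > tol)
    msgs <- c(msgs, sprintf("score matrices not symmetric (defect %.3g)", asym))
  # probability range uses a tighter floating-point floor than the structural
  # checks: an entry 1e-10 above 1 is a modelling error, not roundoff
  if (range_viol > max(tol, 1e-12))
    msgs <- c(msgs, sprintf("edge probabilities outside [0,1] by %.3g", range_viol))
  list(orthonormality_defect = ortho,
       asymmetry_defect = asym,
       range_violation = range_viol,
       valid = length(msgs) == 0L,
       messages = msgs)
}

#' Represent a multilayer SBM as a COSIE model
#'
#' Every multilayer SBM with \code{K} communities is a COSIE model of
#' dimension \code{d <= K}.  The construction scales the block matrices by
#' the square roots of the community sizes, takes an orthonormal basis
#' \code{W} (via SVD) of the column space of the concatenated scaled blocks
#' \code{Xi^(1/2) B_i Xi^(1/2)}, and sets \code{V = Z Xi^(-1/2) W},
#' \code{R_i = W' Xi^(1/2) B_i Xi^(1/2) W}.  This reproduces
#' \code{Z B_i Z' = V R_i V'} exactly, with \code{d} equal to the rank of
#' the concatenated scaled blocks.  Individual \code{B_i} may be rank
#' deficient while the joint model still needs the full \code{d}: two rank-2
#' block matrices on three communities can jointly span a rank-3 model.
#'
#' @param params a \code{"multilayer_sbm"} object.
#' @param tol relative singular-value threshold for the rank decision;
#'   the default \code{NULL} uses \code{max(K, m * K) * .Machine$double.eps}
#'   times the largest singular value.
#' @return A \code{"cosie"} object with \code{d <= K}.
#' @examples
#' mod <- sbm_model(rep(1:3, each = 30),
#'                  list(matrix(c(.6,.2,.2, .2,.6,.6, .2,.6,.6), 3),
#'                       matrix(c(.6,.6,.2, .6,.6,.2, .2,.2,.6), 3)))
#' sbm_to_cosie(mod)$d  # joint dimension 3 although each B has rank 2
#' @export
sbm_to_cosie <- function(params, tol = NULL) {
  stopifnot(inherits(params, "multilayer_sbm"))
  K <- params$K; m <- params$m
  sq <- sqrt(params$sizes)
  scaled <- lapply(params$B, function(B) B * outer(sq, sq))  # Xi^1/2 B Xi^1/2
  Mcat <- do.call(cbind, scaled)                             # K x (mK)
  sv <- svd(Mcat, nu = K, nv = 0)
  if (is.null(tol)) tol <- max(dim(Mcat)) * .Machine$double.eps * sv$d[1]
  d <- sum(sv$d > tol)
  if (d == 0L) stop("all connectivity matrices are zero")
  W <- sv$u[, seq_len(d), drop = FALSE]
  V <- (params$Z %*% (W / sq))                    # Z Xi^(-1/2) W
  R <- lapply(scaled, function(S) {
    Ri <- crossprod(W, S %*% W)
    (Ri + t(Ri)) / 2
  })
  cosie_model(V, R, check = FALSE)
}

#' Maximum expected degree of a probability matrix
#'
#' The largest row sum \code{delta(P)} of a square nonnegative matrix; for an
#' edge-probability matrix this is the maximum expected vertex degree, the
#' sparsity scale that governs spectral concentration of the adjacency
#' matrix.
#'
#' @param P square numeric matrix.
#' @return The maximum row sum, a single number.
#' @export
delta_max_row_sum <- function(P) {
  P <- as.matrix(P)
  if (nrow(P) != ncol(P)) stop("matrix must be square")
  max(rowSums(P))
}

#' Average per-graph spectral-embedding error scale
#'
#' Computes \code{(1/m) * sum_i delta(P_i) / lambda_min(R_i)^2}, where
#' \code{lambda_min} is the smallest eigenvalue in magnitude.  This is the
#' quantity that controls the expected subspace estimation error of the
#' joint embedding: it averages, over graphs, the ratio of the maximum
#' expected degree to the squared spectral floor of the score matrix.  For
#' \code{m} Erdos-Renyi graphs with probabilities \code{p_i} it reduces to
#' \code{(1/(n m)) * sum_i 1/p_i}.
#'
#' @param P_list list of \code{m} edge-probability matrices.
#' @param R_list list of \code{m} full-rank score matrices.
#' @param tol relative tolerance below which a score matrix is declared
#'   singular.
#' @return Nonnegative scalar.
#' @export
epsilon_stat <- function(P_list, R_list, tol = 1e-10) {
  if (length(P_list) != length(R_list))
    stop("P_list and R_list must have the same length")
  terms <- mapply(function(P, R) {
    ev <- eigen((R + t(R)) / 2, symmetric = TRUE, only.values = TRUE)$values
    lmin <- min(abs(ev))
    if (lmin <= tol * max(abs(ev)))
      stop("score matrix is singular: the error scale is undefined")
    delta_max_row_sum(P) / lmin^2
  }, P_list, R_list)
  mean(terms)
}
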