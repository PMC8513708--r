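# Shared fixtures and independent oracles used across the suite.

# Random orthogonal d x d matrix.
rand_orth <- function(d) {
  qr.Q(qr(matrix(rnorm(d * d), d, d)))
}

# All permutations of 1..K as rows (enumeration oracle for label alignment).
all_perms <- function(K) {
  if (K == 1) return(matrix(1))
  sub <- all_perms(K - 1)
  do.call(rbind, lapply(seq_len(K), function(i)
    cbind(i, matrix((seq_len(K)[-i])[sub], nrow(sub)))))
}

# Random valid multilayer SBM (balanced-ish) with entries bounded away
# from 0 and 1 so the induced COSIE model is valid.
rand_sbm <- function(n, K, m) {
  z <- sort(rep_len(seq_len(K), n))
  B <- replicate(m, {
    Bi <- matrix(0, K, K)
    Bi[upper.tri(Bi, diag = TRUE)] <- runif(K * (K + 1) / 2, 0.05, 0.95)
    Bi[lower.tri(Bi)] <- t(Bi)[lower.tri(Bi)]
    Bi
  }, simplify = FALSE)
  sbm_model(z, B)
}

# Independent re-implementation of the equal-variance Gaussian profile
# log-likelihood split score, written directly from the density.
profile_split_oracle <- function(values) {
  p <- length(values)
  vapply(seq_len(p), function(q) {
    g1 <- values[1:q]
    g2 <- if (q < p) values[(q + 1):p] else numeric(0)
    m1 <- mean(g1)
    m2 <- if (length(g2)) mean(g2) else 0
    s2 <- (sum((g1 - m1)^2) + sum((g2 - m2)^2)) / p
    s2 <- max(s2, .Machine$double.eps)
    -p / 2 * log(2 * pi * s2) -
      (sum((g1 - m1)^2) + sum((g2 - m2)^2)) / (2 * s2)
  }, 0)
}
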