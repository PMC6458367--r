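# Independent sequential-predictive (Polya urn) oracles.
#
# Under Dirichlet(alpha) conjugacy, the probability of a symbol sequence
# given starting counts C is the product of sequential urn predictives
# (alpha_m + C[x, m]) / (alpha0 + C[x, .]), incrementing C as symbols are
# consumed.  The marginal-likelihood family and both cross-validation
# criteria all reduce to such products, so walking the sequences one symbol
# at a time gives expected values without any gamma functions.  Counts are
# kept in environments keyed by context strings; contexts are re-derived
# here with an explicit position loop, independent of the package's
# vectorized counting.

# keys are prefixed so the empty (h = 0) context is a legal environment name
oracle_context_key <- function(s, l, h, boundary) {
  if (h == 0) return("ctx:")
  padded <- c(rep(boundary, h), s)
  paste0("ctx:", paste(padded[l:(l + h - 1)], collapse = ""))
}

oracle_empty <- function() new.env(parent = emptyenv())

oracle_clone <- function(C) list2env(as.list(C), parent = emptyenv())

# Log predictive probability of sequence s given urn C; C is updated in place.
oracle_score_seq <- function(s, h, ab, C, alpha) {
  M <- length(ab$symbols)
  a <- rep(alpha, length.out = M)
  lp <- 0
  for (l in seq_along(s)) {
    key <- oracle_context_key(s, l, h, ab$boundary)
    m <- match(s[l], ab$symbols)
    v <- if (is.null(C[[key]])) rep(0, M) else C[[key]]
    lp <- lp + log((a[m] + v[m]) / (sum(a) + sum(v)))
    v[m] <- v[m] + 1
    C[[key]] <- v
  }
  lp
}

# Urn loaded with the counts of trajectories `idx`.
oracle_load <- function(trajs, h, idx, alpha) {
  C <- oracle_empty()
  for (j in idx) oracle_score_seq(trajs$sequences[[j]], h, trajs$alphabet,
                                  C, alpha)
  C
}

oracle_nLML <- function(trajs, h, alpha = 1) {
  C <- oracle_empty()
  -2 * sum(vapply(trajs$sequences, oracle_score_seq, numeric(1L),
                  h = h, ab = trajs$alphabet, C = C, alpha = alpha))
}

oracle_nLPPD <- function(trajs, h, alpha = 1) {
  full <- oracle_load(trajs, h, seq_along(trajs$sequences), alpha)
  -2 * sum(vapply(trajs$sequences, function(s)
    oracle_score_seq(s, h, trajs$alphabet, oracle_clone(full), alpha),
    numeric(1L)))
}

oracle_LOO <- function(trajs, h, alpha = 1) {
  J <- length(trajs$sequences)
  -2 * sum(vapply(seq_len(J), function(j) {
    C <- oracle_load(trajs, h, setdiff(seq_len(J), j), alpha)
    oracle_score_seq(trajs$sequences[[j]], h, trajs$alphabet, C, alpha)
  }, numeric(1L)))
}

oracle_LHO <- function(trajs, h, alpha = 1) {
  J <- length(trajs$sequences)
  i1 <- seq_len(ceiling(J / 2))
  i2 <- setdiff(seq_len(J), i1)
  score_against <- function(score_idx, train_idx) {
    sum(vapply(score_idx, function(j) {
      C <- oracle_load(trajs, h, train_idx, alpha)
      oracle_score_seq(trajs$sequences[[j]], h, trajs$alphabet, C, alpha)
    }, numeric(1L)))
  }
  -2 * (score_against(i1, i2) + score_against(i2, i1))
}

# Monte-Carlo posterior draws for a single-context (order 0) table:
# R draws of log Pr(N | p), p ~ Dirichlet(alpha + N).
mc_loglik_draws <- function(N, alpha, R) {
  M <- length(N)
  a <- rep(alpha, length.out = M) + N
  G <- matrix(stats::rgamma(R * M, shape = rep(a, each = R)), nrow = R)
  P <- G / rowSums(G)
  as.vector(log(P) %*% N)
}
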