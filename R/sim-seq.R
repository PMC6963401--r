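# Sequence evolution along a tree under HKY85 with i.i.d. gamma site rates.
#
# The HKY rate matrix (transition/transversion ratio kappa, stationary base
# frequencies pi) is normalized to one expected substitution per site per
# unit branch length. Transition probabilities for arbitrary per-site
# distances are computed from the spectral decomposition of the normalized
# generator: P_ij(t) = sum_k c_ijk exp(lambda_k t), with the coefficient
# array precomputed once per model. Reversibility makes the symmetrized
# generator symmetric, so the eigendecomposition is real and stable.

hky_model <- function(kappa = 2, base_freqs = c(A = 0.25, C = 0.25,
                                                G = 0.25, T = 0.25)) {
  stopifnot(kappa > 0, length(base_freqs) == 4L,
            abs(sum(base_freqs) - 1) < 1e-12, all(base_freqs > 0))
  names(base_freqs) <- DNA_BASES
  Q <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  transitions <- rbind(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))
  for (i in DNA_BASES) for (j in DNA_BASES) {
    if (i == j) next
    rate <- base_freqs[[j]]
    if (any(transitions[, 1] == i & transitions[, 2] == j)) rate <- rate * kappa
    Q[i, j] <- rate
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(base_freqs * diag(Q))  # expected rate under stationarity
  Q <- Q / mu
  # symmetrize: S = D^{1/2} Q D^{-1/2} with D = diag(pi)
  sq <- sqrt(base_freqs)
  S <- diag(sq) %*% Q %*% diag(1 / sq)
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  # P(t) = D^{-1/2} V exp(Lt) V' D^{1/2}
  V <- es$vectors
  A <- diag(1 / sq) %*% V      # left factor rows i
  B <- t(V) %*% diag(sq)       # right factor cols j
  # c_ijk = A[i, k] * B[k, j]
  coef <- array(0, c(4, 4, 4))
  for (k in 1:4) coef[, , k] <- A[, k] %o% B[k, ]
  list(kappa = kappa, base_freqs = base_freqs, Q = Q,
       eigenvalues = es$values, coef = coef)
}

# transition probability rows for a vector of distances and one parent state
# returns a length(d) x 4 matrix of P(state -> j | d)
hky_probs_from <- function(model, state_i, d) {
  E <- exp(outer(d, model$eigenvalues))       # |d| x 4
  P <- E %*% t(model$coef[state_i, , ])       # |d| x 4 (coef[i, j, k])
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Evolve an alignment along a tree under HKY + gamma
#'
#' The root sequence is drawn from the stationary base frequencies and
#' evolved to the tips; site rates are i.i.d. gamma with shape
#' `gamma_shape` and mean 1 (set `gamma_shape = Inf` for homogeneous
#' rates). Branch lengths are expected substitutions per site at rate 1.
#' With `kappa = 1` and equal frequencies the model reduces to JC69.
#'
#' @param tree A `phylo` with branch lengths.
#' @param locus_length Number of sites (> 0).
#' @param kappa Transition/transversion rate ratio.
#' @param base_freqs Stationary frequencies (A, C, G, T; sum to 1).
#' @param gamma_shape Gamma shape for i.i.d. site rates (`Inf` = none).
#' @param rate Overall rate multiplier applied to every branch.
#' @param seed Optional integer seed.
#' @return A gap-free alignment matrix with one row per tip.
#' @export
evolve_alignment <- function(tree, locus_length, kappa = 2,
                             base_freqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                             gamma_shape = Inf, rate = 1, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (locus_length < 1L) abort("Input error: locus_length must be positive.")
  if (!is.null(seed)) set.seed(seed)
  model <- hky_model(kappa, base_freqs)
  L <- as.integer(locus_length)
  n <- length(tree$tip.label)
  nnode <- n + tree$Nnode
  root <- n + 1L
  site_rates <- if (is.finite(gamma_shape)) {
    rgamma(L, shape = gamma_shape, rate = gamma_shape)
  } else {
    rep(1, L)
  }
  states <- matrix(NA_integer_, nrow = nnode, ncol = L)
  states[root, ] <- sample.int(4L, L, replace = TRUE, prob = model$base_freqs)
  eo <- rev(ape::postorder(tree))
  for (k in eo) {
    par <- tree$edge[k, 1]; chi <- tree$edge[k, 2]
    d <- tree$edge.length[k] * rate * site_rates
    child <- integer(L)
    for (s in 1:4) {
      idx <- which(states[par, ] == s)
      if (!length(idx)) next
      P <- hky_probs_from(model, s, d[idx])
      u <- runif(length(idx))
      cp <- t(apply(P, 1L, cumsum))
      child[idx] <- max.col(cp >= u, ties.method = "first")
    }
    states[chi, ] <- child
  }
  mat <- matrix(DNA_BASES[states[seq_len(n), , drop = FALSE]], nrow = n)
  rownames(mat) <- tree$tip.label
  as_alignment(mat)
}
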