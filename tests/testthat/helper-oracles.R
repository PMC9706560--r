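# Independent oracles used across the test files.

# Brute-force weighted least squares via explicit normal equations:
# eps = (S' W S)^-1 S' W chi with W = diag(1/se^2), plus the classical
# covariance sigma^2 (S' W S)^-1. Deliberately written with solve() so it
# shares no code path with the production SVD-based fit.
brute_force_wls <- function(S, y, se = rep(1, length(y))) {
  W <- diag(1 / se^2)
  XtWX <- t(S) %*% W %*% S
  XtWX_inv <- solve(XtWX)
  est <- XtWX_inv %*% t(S) %*% W %*% y
  resid <- y - S %*% est
  sigma2 <- sum((resid / se)^2) / (nrow(S) - ncol(S))
  list(estimate = drop(est), se = sqrt(diag(sigma2 * XtWX_inv)))
}

# Random valid PNA sequence of length L.
random_seq <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# Expected duration (in frames) of a pair-level melting event for m
# independent bonds, each breaking with probability p_open and reforming
# with probability p_close per frame. The number of broken bonds is a
# Markov chain on {0..m}; an event is a maximal excursion away from 0.
# g(k) = expected number of broken frames from state k (counting the
# current frame) solves g(k) = 1 + sum_j P(k -> j) g(j) for k >= 1,
# g(0) = 0; the entry distribution is the first transition out of 0
# conditioned on leaving. Solved exactly by a small linear system.
analytic_event_frames <- function(m, p_open, p_close) {
  trans_prob <- function(k, j) {
    # k broken -> j broken: b of the k broken close, d of the m-k bonded
    # break, j = k - b + d
    p <- 0
    for (b in 0:k) {
      d <- j - k + b
      if (d >= 0 && d <= m - k) {
        p <- p + stats::dbinom(b, k, p_close) * stats::dbinom(d, m - k, p_open)
      }
    }
    p
  }
  P <- outer(0:m, 0:m, Vectorize(trans_prob))
  # g over states 1..m: (I - Q) g = 1, Q = P[broken, broken]
  Q <- P[-1, -1, drop = FALSE]
  g <- solve(diag(m) - Q, rep(1, m))
  entry <- P[1, -1] / sum(P[1, -1])
  sum(entry * g)
}
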