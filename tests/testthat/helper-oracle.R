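# Independent dense-linear-algebra oracle for the absorbing variant-count
# chain. Deliberately built from the full (N+1)-state transition matrix
# and base solve(), sharing no code path with the package's log-space
# product formulas. A few steps of iterative refinement recover
# componentwise accuracy for very small absorption probabilities (strong
# conformity makes pi_1 ~ 1e-8 at N = 50, below plain LU's relative
# accuracy there).

refined_solve <- function(M, b) {
  x <- solve(M, b)
  for (it in 1:3) x <- x + solve(M, b - M %*% x)
  drop(x)
}

dense_chain_solve <- function(kernel) {
  N <- kernel$N
  n <- N - 1L
  P <- matrix(0, n, n)  # interior-to-interior block, self-loops included
  for (i in seq_len(n)) {
    P[i, i] <- 1 - kernel$alpha[i] - kernel$beta[i]
    if (i < n) P[i, i + 1L] <- kernel$alpha[i]
    if (i > 1L) P[i, i - 1L] <- kernel$beta[i]
  }
  M <- diag(n) - P
  pi_j <- refined_solve(M, c(rep(0, n - 1L), kernel$alpha[n]))  # absorb at N
  # row 1 of the fundamental matrix (I - P)^{-1}: expected visits from
  # a single starting copy
  t1j <- refined_solve(t(M), c(1, rep(0, n - 1L)))
  list(pi_j = pi_j, t1j = t1j, t1 = sum(t1j))
}
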