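# random parameter draws over the open cube, spanning the extremes used on
# the sweep grid
random_params <- function(n, lo = 0.01, hi = 0.99) {
  data.frame(r = runif(n, lo, hi), s = runif(n, lo, hi),
             alpha = runif(n, lo, hi), beta = runif(n, lo, hi),
             omega = runif(n, lo, hi))
}

model_from_row <- function(p, i) {
  valence_model(r = p$r[i], s = p$s[i], alpha = p$alpha[i],
                beta = p$beta[i], omega = p$omega[i])
}

# independent factorized sampler: draws M and E from their own 2x2 chains
# and V from the retention probabilities, never touching the joint matrix
simulate_factorized <- function(model, n_steps, seed) {
  set.seed(seed)
  p <- coef(model)
  V <- integer(n_steps + 1); M <- integer(n_steps + 1); E <- integer(n_steps + 1)
  V[1] <- sample(0:1, 1); M[1] <- sample(0:1, 1); E[1] <- sample(0:1, 1)
  for (t in seq_len(n_steps)) {
    vt <- valence_terms(model, V[t], M[t], E[t])
    keep <- if (V[t] == 0) vt$p00 else vt$p11
    V[t + 1] <- if (runif(1) < keep) V[t] else 1L - V[t]
    M[t + 1] <- if (runif(1) < p[["r"]]) M[t] else 1L - M[t]
    E[t + 1] <- if (runif(1) < p[["s"]]) E[t] else 1L - E[t]
  }
  data.frame(step = 0:n_steps, state = 4L * V + 2L * M + E + 1L,
             V = V, M = M, E = E, syntonic = V == M)
}
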