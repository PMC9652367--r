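# shared fixtures: tiny graphs and quick synthetic tables

path_graph <- function(labels = c("A", "B", "C")) {
  zone_graph(labels, cbind(labels[-length(labels)], labels[-1]))
}

# small geo-additive dataset with known truth, for smoke-scale fits
small_sim <- function(n = 500, rows = 2, cols = 3, seed = 1) {
  g <- make_zone_lattice(rows, cols)
  truth <- default_truth(g, seed = seed)
  list(graph = g, truth = truth,
       data = generate_households(g, truth, n = n, seed = seed))
}

# quadrature posterior mean of plogis(alpha0) for an intercept-only logistic
# model with a flat prior on alpha0
quadrature_mean_p <- function(successes, trials, lo = -6, hi = 6, m = 20001) {
  grid <- seq(lo, hi, length.out = m)
  loglik <- successes * grid - trials * log1p(exp(grid))
  w <- exp(loglik - max(loglik))
  sum(plogis(grid) * w) / sum(w)
}
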