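# Small deterministic fixtures built in code.

# A piecewise-linear gene/protein pair satisfying the generative identity
# y(t) = sum_k beta_k x_k(t - tau) with clamping at the mRNA boundaries.
make_pl_pair <- function(beta, tau, times = c(0, 1, 2, 6, 24),
                         protein_times = times, seed = 1, sigma = 0) {
  set.seed(seed)
  k <- length(beta)
  X <- matrix(exp(matrix(rnorm(k * length(times), 0, 0.6), k)) + 1,
              nrow = k)
  X <- X * 10
  rownames(X) <- paste0("t", seq_len(k))
  g <- ts_gene("g1", rownames(X), X, times)
  xq <- sapply(seq_len(k), function(j)
    approx(times, X[j, ], xout = pmax(protein_times - tau, times[1]),
           rule = 2)$y)
  yv <- as.numeric(xq %*% beta)
  if (sigma > 0) yv <- yv + rnorm(length(yv), 0, sigma)
  p <- protein_series("p1", "g1", yv, protein_times)
  list(gene = g, protein = p, noiseless = as.numeric(xq %*% beta))
}

# delay-grid interval index of a delay (for "within one grid step")
grid_interval <- function(tau, grid) findInterval(tau, grid)

tau_within_one_step <- function(tau_hat, tau_true, grid) {
  abs(grid_interval(tau_hat, grid) - grid_interval(tau_true, grid)) <= 1
}

# dominant transcript on the contribution scale: |beta| times the
# trajectory's temporal sd (what actually drives the protein signal)
dominant_transcript <- function(truth, gene) {
  which.max(abs(truth$beta_true) * apply(gene$X, 1, stats::sd))
}
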