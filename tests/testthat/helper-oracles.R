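# Independent brute-force oracles used across test files.

# 1-nearest-neighbour prediction by exhaustive distance comparison.
oracle_1nn <- function(train_x, train_y, test_x) {
  apply(test_x, 1, function(p) {
    d2 <- rowSums(sweep(train_x, 2, p)^2)
    train_y[which.min(d2)]
  })
}

# Direct summation-layer evaluation of the class-conditional Parzen mean:
# f_c(x) = (1/n_c) sum_{i in c} exp(-||x - w_i||^2 / (2 sigma^2)).
oracle_parzen_scores <- function(centers, labels, sigma, x) {
  classes <- sort(unique(labels))
  vapply(classes, function(cl) {
    idx <- which(labels == cl)
    phis <- vapply(idx, function(i) {
      exp(-sum((x - centers[i, ])^2) / (2 * sigma^2))
    }, numeric(1))
    mean(phis)
  }, numeric(1))
}

# Exact two-sided signed-rank p-value by literal enumeration of all 2^n
# sign assignments (feasible for n <= 12).
oracle_wilcoxon_enumeration <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Small separable blob dataset used by several files.
toy_blobs <- function(n = 60, d = 2, seed = 1, separation = 6, noise = 0) {
  synth_dataset(dataset_spec("toy", n = n, d = d, separation = separation,
                             noise_rate = noise, seed = seed))
}
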