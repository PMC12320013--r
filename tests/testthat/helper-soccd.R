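# Shared fixtures for the test suite. All data are generated in code.

# Matrix of m instances whose sample covariance (divisor m) is exactly C:
# whiten an arbitrary draw empirically, then color by chol(C).
exact_cov_instances <- function(C, m, seed = 1) {
  p <- ncol(C)
  set.seed(seed)
  Z <- matrix(rnorm(m * p), m, p)
  Z <- sweep(Z, 2, colMeans(Z))
  S <- crossprod(Z) / m
  Z <- Z %*% solve(chol(S))
  Z %*% chol(C)
}

# Canonical simulated pair in the identifiable regime (truth: x -> y)
make_pair <- function(n = 2000, alpha = 0.5, r = 0.8, noise_coef = 0.2,
                      snr = Inf, innovation = "gaussian", seed = 1) {
  simulate_pair(
    pair_spec(alpha = alpha,
              regressor = ar_spec(r, innovation = innovation),
              noise = ar_spec(noise_coef, innovation = innovation),
              n_samples = n, snr = snr),
    seed = seed
  )
}

# Reference cohort for network/consistency tests: 8 sources, four disjoint
# edges with mixed orientations, heterogeneous AR spectra per node.
cohort_spec <- function(n_samples = 600, edge_weights = c(0.2, 0.3, 0.4, 0.5)) {
  network_spec(
    8,
    rbind(c(1, 2), c(4, 3), c(5, 6), c(8, 7)),
    edge_weights = edge_weights,
    node_ar = lapply(c(0.9, 0.2, 0.3, 0.75, 0.6, 0.25, 0.35, 0.45), ar_spec),
    n_samples = n_samples
  )
}

make_cohort <- function(n_subjects = 5, spec = cohort_spec(), seed = 1) {
  lapply(seq_len(n_subjects), function(s) {
    simulate_network(spec, seed = seed * 1000 + s)$X
  })
}

# Strong-edge network used for recovery checks (distinct AR spectra so
# every parent/child pair is identifiable pairwise).
recovery_spec <- function(n_samples = 5000) {
  network_spec(
    5,
    rbind(c(1, 2), c(1, 3), c(2, 4), c(3, 5)),
    edge_weights = 0.8,
    node_ar = lapply(c(0.9, 0.2, 0.3, 0.45, 0.6), ar_spec),
    n_samples = n_samples
  )
}

# 99% binomial band around chance for k successes out of n
chance_band <- function(n, level = 0.99) {
  half <- qnorm(1 - (1 - level) / 2) * sqrt(0.25 / n)
  c(0.5 - half, 0.5 + half)
}

# Recall / orientation accuracy of an estimated directed network against
# the true edge list (matrix with columns from, to)
score_network <- function(net, true_edges) {
  true_key <- paste(true_edges[, 1], true_edges[, 2])
  und_key <- paste(pmin(true_edges[, 1], true_edges[, 2]),
                   pmax(true_edges[, 1], true_edges[, 2]))
  found_und <- paste(net$edges$i, net$edges$j)
  recall <- mean(und_key %in% found_und)
  hit <- net$edges[found_und %in% und_key, , drop = FALSE]
  if (nrow(hit) == 0) return(list(recall = recall, orientation = NA_real_))
  ok <- mapply(function(i, j, d) {
    if (d == "i_to_j") paste(i, j) %in% true_key
    else if (d == "j_to_i") paste(j, i) %in% true_key
    else NA
  }, hit$i, hit$j, hit$direction)
  list(recall = recall, orientation = mean(ok, na.rm = TRUE))
}
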