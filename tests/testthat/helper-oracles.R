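# Independent oracles used across test files.

# Numeric profile of the binomial log likelihood on the logit scale:
# curvature by central finite differences, interval from the generic
# MLE-normal recipe. Independent of the closed form under test.
numeric_logit_ci <- function(x, n, level = 0.90, h = 1e-3) {
  loglik <- function(theta) x * theta - n * log(1 + exp(theta))
  theta_hat <- log(x / (n - x))
  curv <- -(loglik(theta_hat + h) - 2 * loglik(theta_hat) +
              loglik(theta_hat - h)) / h^2
  z <- qnorm(1 - (1 - level) / 2)
  theta_hat + c(-1, 1) * z / sqrt(curv)
}

# Exhaustive double-loop pixel-pair count for the co-occurrence matrix.
glcm_oracle <- function(q, levels, displacement) {
  dr <- displacement[1]; dc <- displacement[2]
  counts <- matrix(0, levels, levels)
  for (i in seq_len(nrow(q) - dr)) {
    for (j in seq_len(ncol(q) - dc)) {
      a <- q[i, j]; b <- q[i + dr, j + dc]
      counts[a, b] <- counts[a, b] + 1
    }
  }
  counts / sum(counts)
}

# Direct evaluation of the plate-isolation success probability.
isolation_prob <- function(n_plates, target_probs, colonies_per_plate) {
  m <- n_plates * colonies_per_plate
  prod(1 - (1 - target_probs)^m)
}

# Sequenced stool reference at the spec's read depth (shared fixture).
sequence_stool <- function(stool, spec, stream = 20L) {
  counts <- dropcult:::with_seed(
    dropcult:::child_seed(spec$seed, stream),
    as.integer(rmultinom(1L, spec$read_depth, stool))
  )
  setNames(counts, names(stool))
}
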