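# Brute-force oracles, deliberately independent of the package internals:
# plain loops over the defining formulas, used to pin down the vectorized
# implementations.

# Tolerance breadth by the literal two-step definition: weighted centroid of
# occupied samples, then weighted mean distance to it.
tb_oracle <- function(counts, env, otu) {
  a <- counts[otu, ]
  keep <- which(a > 0)
  x <- env[colnames(counts)[keep], , drop = FALSE]
  a <- a[keep]
  centroid <- rep(0, ncol(x))
  for (i in seq_len(ncol(x))) centroid[i] <- sum(a * x[, i]) / sum(a)
  z <- numeric(length(keep))
  for (j in seq_along(keep)) z[j] <- sqrt(sum((x[j, ] - centroid)^2))
  sum(a * z) / sum(a)
}

# Spearman rho via explicit rank transform then the Pearson formula.
spearman_oracle <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# CMRA by explicit double loop over unordered pairs.
cmra_oracle <- function(a, ra, selected) {
  num <- 0
  den <- 0
  for (i in seq_along(selected)) {
    for (j in seq_along(selected)) {
      if (j <= i) next
      r <- ra[selected[i], selected[j]]
      if (is.na(r)) next
      w <- a[selected[i]] * a[selected[j]]
      num <- num + w * r
      den <- den + w
    }
  }
  if (den == 0) NA_real_ else unname(num / den)
}

# Random fixture builders ----------------------------------------------------

random_count_table <- function(n_otus, n_samples, lambda = 5, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_otus * n_samples, lambda), nrow = n_otus,
              dimnames = list(sprintf("OTU%03d", seq_len(n_otus)),
                              sprintf("S%02d", seq_len(n_samples))))
  # guarantee every sample has at least one read
  zero <- colSums(m) == 0
  m[1L, zero] <- 1
  storage.mode(m) <- "double"
  m
}

random_env_table <- function(n_samples, n_vars = 3, seed = 1) {
  set.seed(seed + 1000)
  env <- matrix(rnorm(n_samples * n_vars), nrow = n_samples,
                dimnames = list(sprintf("S%02d", seq_len(n_samples)),
                                paste0("var", seq_len(n_vars))))
  env
}

# Small deterministic table used by several example-based tests.
tiny_counts <- function() {
  m <- matrix(c(5, 0,
                1, 2,
                0, 3), nrow = 3, byrow = TRUE,
              dimnames = list(c("OTU1", "OTU2", "OTU3"), c("A", "B")))
  storage.mode(m) <- "double"
  m
}
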