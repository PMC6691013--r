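# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force (loops, enumeration, closed forms) and share no
# code with the implementation they check.

# Haralick correlation by explicit enumeration of every pixel pair at the
# given offset, including the min-max quantization.
brute_glcm_correlation <- function(image, distance, direction, n_levels) {
  rng <- range(image)
  q <- floor((image - rng[1]) / (rng[2] - rng[1]) * n_levels) + 1
  q[q > n_levels] <- n_levels
  shift <- switch(as.character(direction),
                  "0" = c(0, distance), "90" = c(-distance, 0),
                  "180" = c(0, -distance), "270" = c(distance, 0))
  pairs_i <- c(); pairs_j <- c()
  for (r in seq_len(nrow(q))) {
    for (cc in seq_len(ncol(q))) {
      r2 <- r + shift[1]; c2 <- cc + shift[2]
      if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
        pairs_i <- c(pairs_i, q[r, cc])
        pairs_j <- c(pairs_j, q[r2, c2])
      }
    }
  }
  n <- length(pairs_i)
  p <- matrix(0, n_levels, n_levels)
  for (k in seq_len(n)) p[pairs_i[k], pairs_j[k]] <-
      p[pairs_i[k], pairs_j[k]] + 1 / n
  mu_i <- sum(rowSums(p) * seq_len(n_levels))
  mu_j <- sum(colSums(p) * seq_len(n_levels))
  sd_i <- sqrt(sum(rowSums(p) * (seq_len(n_levels) - mu_i)^2))
  sd_j <- sqrt(sum(colSums(p) * (seq_len(n_levels) - mu_j)^2))
  acc <- 0
  for (i in seq_len(n_levels))
    for (j in seq_len(n_levels))
      acc <- acc + p[i, j] * (i - mu_i) * (j - mu_j)
  acc / (sd_i * sd_j)
}

# Single-linkage components by union-find over all pairs.
brute_components <- function(x, y, radius) {
  n <- length(x)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) <= radius) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  # path compression pass
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Expected misclassification rate of a midpoint threshold between two
# Gaussian lifetime populations (equal sizes): untreated cells below the
# threshold and treated cells at/above it are wrong.
gaussian_misclassification <- function(mu_untreated, mu_treated, sd, thr) {
  (pnorm((thr - mu_untreated) / sd) +
     (1 - pnorm((thr - mu_treated) / sd))) / 2
}

# Hand-computed Hertz force in pN: F = 4/3 * E/(1-nu^2) * sqrt(R) d^1.5 (SI).
hand_hertz_pN <- function(delta_nm, E_pa, R_um, nu) {
  4 / 3 * E_pa / (1 - nu^2) * sqrt(R_um * 1e-6) * (delta_nm * 1e-9)^1.5 * 1e12
}

# Step-down Sidak adjustment written directly from its definition.
enum_holm_sidak <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (rank in seq_len(m)) {
    a <- 1 - (1 - p[o[rank]])^(m - rank + 1)
    running <- max(running, a)
    adj[o[rank]] <- min(running, 1)
  }
  adj
}
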