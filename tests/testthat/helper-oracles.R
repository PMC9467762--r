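# Independent brute-force oracles for the partition metrics, plus small
# fixture builders.  These deliberately avoid the contingency-table code
# paths used by the package.

# Rand index by explicit enumeration of all unordered pixel pairs
ri_bruteforce <- function(s1, s2) {
  a <- as.vector(s1); b <- as.vector(s2)
  n <- length(a)
  agree <- 0L
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      same1 <- a[i] == a[j]
      same2 <- b[i] == b[j]
      if (same1 == same2) agree <- agree + 1L
    }
  }
  agree / (n * (n - 1) / 2)
}

# GCE by per-pixel region set arithmetic
gce_bruteforce <- function(s1, s2) {
  a <- as.vector(s1); b <- as.vector(s2)
  n <- length(a)
  e12 <- 0; e21 <- 0
  for (i in seq_len(n)) {
    r1 <- which(a == a[i])
    r2 <- which(b == b[i])
    e12 <- e12 + length(setdiff(r1, r2)) / length(r1)
    e21 <- e21 + length(setdiff(r2, r1)) / length(r2)
  }
  min(e12, e21) / n
}

# VI by per-pixel plug-in surprisal: H(S) = mean(-log2 p(label at pixel))
vi_bruteforce <- function(s1, s2) {
  a <- as.vector(s1); b <- as.vector(s2)
  n <- length(a)
  pa <- sapply(seq_len(n), function(i) mean(a == a[i]))
  pb <- sapply(seq_len(n), function(i) mean(b == b[i]))
  pj <- sapply(seq_len(n), function(i) mean(a == a[i] & b == b[i]))
  h1 <- mean(-log2(pa)); h2 <- mean(-log2(pb)); hj <- mean(-log2(pj))
  mi <- h1 + h2 - hj
  h1 + h2 - 2 * mi
}

random_label_map <- function(nr, nc, k) {
  matrix(sample.int(k, nr * nc, replace = TRUE) - 1L, nr, nc)
}

dice_coef <- function(pred, truth) {
  2 * sum(pred == 1 & truth == 1) / (sum(pred == 1) + sum(truth == 1))
}

# texture-free two-class phantom used across filter tests
flat_phantom <- function(seed = 7) {
  make_phantom(phantom_spec(cone = NULL, texture_sd = 0, rng_seed = seed))
}

# brute-force sliding weighted median with replicated borders (R loops)
wm_bruteforce <- function(img, weights) {
  h <- nrow(img); w <- ncol(img)
  hw <- nrow(weights) %/% 2
  out <- matrix(0L, h, w)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      vals <- integer(0)
      for (dr in -hw:hw) {
        for (dc in -hw:hw) {
          rr <- min(max(r + dr, 1), h)
          cc <- min(max(c + dc, 1), w)
          wt <- weights[dr + hw + 1, dc + hw + 1]
          vals <- c(vals, rep(img[rr, cc], wt))
        }
      }
      vals <- sort(vals)
      out[r, c] <- vals[ceiling(length(vals) / 2)]
    }
  }
  out
}
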