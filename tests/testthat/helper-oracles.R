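# Independent oracles used across the suite. These re-derive expected values
# by brute force or closed form and must stay independent of the package's
# own code paths.

# hypergeometric upper tail by direct enumeration of choose() terms
fisher_enum <- function(n_hit, n_cluster, n_unit, n_genome) {
  j <- n_hit:min(n_cluster, n_unit)
  sum(exp(lchoose(n_unit, j) + lchoose(n_genome - n_unit, n_cluster - j) -
            lchoose(n_genome, n_cluster)))
}

# Holm step-down by the textbook formula
holm_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

# mean silhouette by the O(n^2) definition, one point at a time
sil_brute <- function(x, lab, is_dist = FALSE) {
  d <- if (is_dist) x else as.matrix(dist(x))
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(lab == lab[i]), i)
    if (length(own) == 0L) next            # singleton -> 0
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(lab), lab[i]),
                    function(g) mean(d[i, lab == g]), numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# exhaustive minimum-SSE bipartition of the rows of x (n <= ~15)
best_bipartition <- function(x) {
  n <- nrow(x)
  sse <- function(m) {
    if (nrow(m) == 0L) return(0)
    sum(sweep(m, 2, colMeans(m))^2)
  }
  best <- Inf
  best_lab <- NULL
  for (mask in 1:(2^(n - 1) - 1)) {
    lab <- as.integer(intToBits(mask))[seq_len(n)] + 1L
    v <- sse(x[lab == 1L, , drop = FALSE]) + sse(x[lab == 2L, , drop = FALSE])
    if (v < best) {
      best <- v
      best_lab <- lab
    }
  }
  list(labels = best_lab, sse = best)
}

# pooled-variance two-sample t, closed form
pooled_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# same partition up to label permutation
same_partition <- function(a, b) {
  all(table(a, b) %in% c(0, table(a))) && length(unique(a)) == length(unique(b))
}
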