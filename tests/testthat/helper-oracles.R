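# Independent brute-force oracles, written from the textbook formulas and
# kept free of any package internals.

o_mean <- function(x) sum(x) / length(x)

o_sd <- function(x) {
  m <- o_mean(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

o_rsd_percent <- function(x) 100 * o_sd(x) / o_mean(x)

o_pearson <- function(u, v) {
  mu <- o_mean(u); mv <- o_mean(v)
  sum((u - mu) * (v - mv)) /
    sqrt(sum((u - mu)^2) * sum((v - mv)^2))
}

o_cor_distance <- function(u, v) {
  if (o_sd(u) == 0 || o_sd(v) == 0) return(1)
  1 - o_pearson(u, v)
}

o_t_test_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - o_mean(a))^2) / (na - 1)
  vb <- sum((b - o_mean(b))^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  t <- (o_mean(a) - o_mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  2 * stats::pt(-abs(t), df = na + nb - 2)
}

# sum over clusters of correlation distances of members to the cluster's
# mean-vector centroid
o_partition_objective <- function(X, assign) {
  obj <- 0
  for (g in unique(assign)) {
    rows <- X[assign == g, , drop = FALSE]
    cen <- colMeans(rows)
    obj <- obj + sum(apply(rows, 1, function(r) o_cor_distance(r, cen)))
  }
  obj
}

# exhaustive minimum over all 2-partitions (both sides nonempty)
o_best_bipartition <- function(X) {
  n <- nrow(X)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    assign <- as.integer(intToBits(code))[1:n]
    if (all(assign == 0) || all(assign == 1)) next
    best <- min(best, o_partition_objective(X, assign))
  }
  best
}

rel_err <- function(x, ref) abs(x - ref) / abs(ref)
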