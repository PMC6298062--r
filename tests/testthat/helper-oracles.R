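# Independent oracles, kept deliberately naive and separate from the package
# implementation paths they check.

# exact conditional permutation P values by exhaustive enumeration of all
# C(N, k) affected-label assignments over a single family's phenotyped pool
enumerate_exact_p <- function(K, pool, k, obs, statistic_fun, condition_fun) {
  stopifnot(k <= length(pool))
  subsets <- utils::combn(pool, k, simplify = FALSE)
  vals <- numeric(0)
  for (s in subsets) {
    if (!condition_fun(s)) next
    vals <- c(vals, statistic_fun(s))
  }
  # exact permutation P over qualifying assignments (tail includes ties)
  mean(vals >= obs - 1e-12)
}

# brute-force mean pairwise kinship over affected via explicit double loop
brute_if <- function(K, affected) {
  tot <- 0; np <- 0
  for (i in seq_along(affected)) for (j in seq_along(affected)) {
    if (i < j) {
      tot <- tot + kinship_phi(K, affected[i], affected[j])
      np <- np + 1
    }
  }
  tot / np
}

# manual step-up BH, written independently of stats::p.adjust
manual_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (r in m:1) {
    running <- min(running, p[ord[r]] * m / r)
    adj[ord[r]] <- min(1, running)
  }
  adj
}

# sort-based tie-averaged ranks, independent of base::rank
manual_ranks <- function(p) {
  out <- numeric(length(p))
  for (i in seq_along(p)) {
    below <- sum(p < p[i])
    ties <- sum(p == p[i])
    out[i] <- below + (1 + ties) / 2
  }
  out
}
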