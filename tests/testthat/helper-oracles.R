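# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities by enumeration so they share no code with the
# implementation paths they check.

# all permutations of 1..n as a matrix with one permutation per row
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# exhaustive-search maximum assignment: value and the lexicographically
# smallest optimal permutation
brute_assignment <- function(J) {
  n <- nrow(J)
  perms <- all_perms(n)
  vals <- apply(perms, 1, function(p) sum(J[cbind(seq_len(n), p)]))
  best <- max(vals)
  opt <- perms[vals >= best - 1e-12, , drop = FALSE]
  ord <- do.call(order, as.data.frame(opt))
  list(value = best, perm = opt[ord[1], ])
}

# 1-D squared 2-Wasserstein by exhaustive minimum-cost perfect matching
# (equal sample sizes only)
brute_w2sq_1d <- function(p, q) {
  stopifnot(length(p) == length(q))
  n <- length(p)
  perms <- all_perms(n)
  min(apply(perms, 1, function(pm) mean((p - q[pm])^2)))
}

# small two-domain grid dataset used by several io / pipeline tests
toy_dataset <- function() {
  spatial_dataset(cbind(c(0, 1, 0, 1), c(0, 0, 1, 1)),
                  true_labels = c("A", "A", "B", "B"),
                  pred_labels = c("p1", "p1", "p2", "p2"))
}

fast_config <- function(seed = 1L) {
  discrepancy_config(n_batches = 6, batch_size = 60, n_projections = 20,
                     seed = seed)
}
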