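#' Bandwidth / kernel-decay sensitivity experiment
#'
#' Evaluates the discrepancy score over a grid of KDE bandwidths `h` and
#' exponential-kernel decays `gamma` on a series of datasets with graded
#' mislabel counts (by default the 360-spot [sensitivity_series()]).
#' Because `gamma` only enters after the pairwise sliced-Wasserstein
#' distances are computed, each `(dataset, h)` pair is sampled once and all
#' `gamma` values reuse its distance matrix.
#'
#' @param datasets List of [spatial_dataset()]s carrying `mislabels` and
#'   `error_rate` attributes; defaults to [sensitivity_series()].
#' @param h_values Bandwidth grid (default `c(0.001, 0.01, 0.1, 0.5)`).
#' @param gamma_values Kernel decay grid (default `c(0.5, 1, 5, 10)`).
#' @param weights Severity weight scheme (default `"expression"`; the
#'   series datasets carry synthetic expression).
#' @param n_batches,batch_size,n_projections,seed Sampling parameters, as
#'   in [discrepancy_config()].
#' @return Long-format data frame with columns `mislabels`, `error_rate`,
#'   `h`, `gamma`, `d`.
#' @export
sensitivity_grid <- function(datasets = sensitivity_series(),
                             h_values = c(0.001, 0.01, 0.1, 0.5),
                             gamma_values = c(0.5, 1, 5, 10),
                             weights = "expression",
                             n_batches = 20L, batch_size = 200L,
                             n_projections = 50L, seed = 1L) {
  rows <- vector("list", 0)
  for (ds in datasets) {
    match <- match_dataset(ds)
    adj <- build_adjacency(ds$coords, "knn", 6L)
    graphs <- build_labeled_graphs(ds, match$remapped, adj, weights)
    K <- ds$K
    Z0 <- weight_adjust(one_hot_encode(graphs$truth$edge_codes, K),
                        graphs$truth$weights)
    Z1 <- weight_adjust(one_hot_encode(graphs$clustering$edge_codes, K),
                        graphs$clustering$weights)
    D <- unit_directions(n_projections, K, derive_seed(seed, "projections"))
    for (h in h_values) {
      b0 <- sample_batches(fit_kde(Z0, h), n_batches, batch_size,
                           derive_seed(seed, "truth-sampling"))
      b1 <- sample_batches(fit_kde(Z1, h), n_batches, batch_size,
                           derive_seed(seed, "clustering-sampling"))
      W <- sw2sq_gram(c(b0, b1), D)
      i0 <- seq_len(n_batches)
      i1 <- n_batches + seq_len(n_batches)
      for (gamma in gamma_values) {
        G <- exp_kernel(W, gamma)
        d <- mean(G[i0, i0]) + mean(G[i1, i1]) - 2 * mean(G[i0, i1])
        rows[[length(rows) + 1L]] <- data.frame(
          mislabels = attr(ds, "mislabels"),
          error_rate = attr(ds, "error_rate"),
          h = h, gamma = gamma, d = max(0, d))
      }
    }
  }
  do.call(rbind, rows)
}
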