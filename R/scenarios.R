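# Synthetic benchmarking scenarios. Each generator lays spots on a regular
# grid and produces a ground truth plus two competing clustering results
# whose documented mislabel counts, locations, and directions isolate one
# evaluation factor (label agreement, mislabel location, error severity).

grid_coords <- function(n_rows, n_cols) {
  cbind(x = rep(seq_len(n_cols), times = n_rows),
        y = rep(seq_len(n_rows), each = n_cols))
}

scenario_pair <- function(truth_ds, labels_I, labels_II, expected_order,
                          extra = list()) {
  mk <- function(pred) {
    spatial_dataset(truth_ds$coords,
                    true_labels = truth_ds$true_levels[truth_ds$true_codes],
                    pred_labels = pred,
                    expression = truth_ds$expression,
                    spot_ids = truth_ds$spot_ids)
  }
  structure(c(list(truth = truth_ds,
                   result_I = mk(labels_I),
                   result_II = mk(labels_II),
                   expected_order = expected_order),
              extra),
            class = "scenario_pair")
}

#' Label-agreement scenario: few vs many mislabels with swapped colors
#'
#' A two-domain cortical layout of 342 spots on a 19 x 18 grid: 3 layer-1
#' spots at the upper margin and 339 layer-2/3 spots. Result I mislabels a
#' contiguous band of 47 layer-2/3 spots as layer 1; Result II mislabels
#' the complementary band of 292 spots. The two results are color-swapped
#' versions of each other, so their spatial label continuity is nearly
#' identical, but Result I is the better clustering because far fewer
#' layer-2/3 spots are absorbed into layer 1.
#'
#' @return A `scenario_pair`: `truth` (prediction = truth), `result_I`,
#'   `result_II` ([spatial_dataset()]s), `expected_order = "I_better"`.
#' @export
scenario_label_agreement <- function() {
  n_rows <- 19L; n_cols <- 18L
  coords <- grid_coords(n_rows, n_cols)   # row-major: row 1 first
  n <- n_rows * n_cols                    # 342
  truth <- rep("layer2/3", n)
  truth[1:3] <- "layer1"                  # three spots at the upper margin
  l23 <- which(truth == "layer2/3")
  band_I <- l23[1:47]                     # contiguous band nearest layer 1
  band_II <- l23[48:length(l23)]          # the complementary 292 spots
  res_I <- truth; res_I[band_I] <- "layer1"
  res_II <- truth; res_II[band_II] <- "layer1"
  truth_ds <- spatial_dataset(coords, truth, truth)
  scenario_pair(truth_ds, res_I, res_II, "I_better")
}

#' Mislabel-location scenario: boundary vs core errors
#'
#' A two-band layout of 400 spots on a 20 x 20 grid: rows 1-8 are cortical
#' layer 6, rows 9-20 are white matter (WM). WM expression profiles follow
#' a spatial gradient: spots near the layer-6 boundary interpolate toward
#' the layer-6 class mean, emulating the greater biological similarity of
#' peripheral WM to the adjacent layer. Result I mislabels 29 boundary WM
#' spots as layer 6; Result II mislabels 29 spots in the WM core. Both
#' results have identical confusion tables, so external metrics cannot
#' separate them, but Result I is biologically the milder error.
#'
#' @param seed Integer seed for the expression noise.
#' @param n_genes Number of synthetic genes (default 30).
#' @return A `scenario_pair` with expression attached and
#'   `expected_order = "I_better"`.
#' @export
scenario_mislabel_location <- function(seed = 1L, n_genes = 30L) {
  n_rows <- 20L; n_cols <- 20L
  coords <- grid_coords(n_rows, n_cols)
  row_of <- rep(seq_len(n_rows), each = n_cols)
  truth <- ifelse(row_of <= 8L, "layer6", "WM")

  half <- n_genes %/% 2
  mu6 <- c(rep(10, half), rep(1, n_genes - half))
  muWM <- c(rep(1, half), rep(10, n_genes - half))
  # boundary-proximal WM profiles blend toward the layer-6 mean
  blend <- numeric(length(truth))
  wm <- truth == "WM"
  depth <- row_of[wm] - 8L                 # 1 at the boundary, 12 at the base
  blend[wm] <- 0.6 * exp(-(depth - 1) / 2)
  X <- with_seed(seed, {
    prof <- outer(1 - blend, muWM) + outer(blend, mu6)
    prof[!wm, ] <- matrix(mu6, sum(!wm), n_genes, byrow = TRUE)
    pmax(prof + matrix(rnorm(length(prof), sd = 0.3), nrow(prof)), 0)
  })

  boundary <- which(wm)[1:29]              # row-major: the shallowest 29
  core_rows <- row_of %in% c(14L, 15L)                   # middle of the WM band
  core <- which(wm & core_rows)[1:29]
  res_I <- truth; res_I[boundary] <- "layer6"
  res_II <- truth; res_II[core] <- "layer6"
  truth_ds <- spatial_dataset(coords, truth, truth, expression = X)
  scenario_pair(truth_ds, res_I, res_II, "I_better")
}

#' Error-severity scenario: false positives vs false negatives
#'
#' A mirror-symmetric layout of 48 spots on a 6 x 8 grid: the left four
#' columns are connective tissue (24 spots), the right four are cancer in
#' situ (24 spots). Result I mislabels the 12 connective spots nearest the
#' boundary as cancer (false positives); Result II mislabels their mirror
#' images as connective (false negatives). The two mislabel sets are mirror
#' images under the layout's vertical symmetry axis, so the topology and
#' every conventional metric are identical — only a severity-aware weight
#' (false negatives costlier than false positives) separates them.
#'
#' @return A `scenario_pair` with
#'   `expected_order = "equal_under_symmetric_weights"` and an
#'   `fn_cost_table` element encoding cost 2 for false negatives (cancer
#'   predicted connective) and cost 1 otherwise, under which Result II
#'   scores worse.
#' @export
scenario_error_severity <- function() {
  n_rows <- 6L; n_cols <- 8L
  coords <- grid_coords(n_rows, n_cols)
  col_of <- rep(seq_len(n_cols), times = n_rows)
  truth <- ifelse(col_of <= 4L, "connective", "cancer")
  fp <- which(col_of %in% c(3L, 4L))       # 12 connective spots at the boundary
  fn <- which(col_of %in% c(5L, 6L))       # their mirror images (cancer spots)
  res_I <- truth; res_I[fp] <- "cancer"    # false positives
  res_II <- truth; res_II[fn] <- "connective"  # false negatives
  truth_ds <- spatial_dataset(coords, truth, truth)
  fn_cost <- data.frame(
    true_class = c("cancer", "connective"),
    pred_class = c("connective", "cancer"),
    cost = c(2, 1),
    stringsAsFactors = FALSE
  )
  scenario_pair(truth_ds, res_I, res_II, "equal_under_symmetric_weights",
                extra = list(fn_cost_table = fn_cost))
}

#' Sensitivity-analysis series: graded mislabel counts on 360 spots
#'
#' An 18 x 20 grid of 360 spots, half breast-gland and half cancerous, with
#' synthetic two-class expression profiles. One dataset is produced per
#' requested mislabel count, flipping that many gland spots to the cancer
#' label; flip sets are nested (drawn from one seeded permutation), so the
#' series is monotone by construction and the error rate of dataset `m`
#' equals `counts[m] / 360` exactly.
#'
#' @param mislabel_counts Integer vector of flip counts in `[0, 180]`;
#'   defaults to ten counts evenly spaced from 9 to 95.
#' @param seed Integer seed for the flip permutation and expression noise.
#' @param n_genes Number of synthetic genes (default 30).
#' @return List of [spatial_dataset()]s, one per count, each with
#'   attributes `mislabels` and `error_rate`.
#' @export
sensitivity_series <- function(mislabel_counts = round(seq(9, 95,
                                                           length.out = 10)),
                               seed = 1L, n_genes = 30L) {
  mislabel_counts <- as.integer(mislabel_counts)
  if (any(mislabel_counts < 0L) || any(mislabel_counts > 180L)) {
    stop("mislabel counts must lie in [0, 180]", call. = FALSE)
  }
  n_rows <- 18L; n_cols <- 20L
  coords <- grid_coords(n_rows, n_cols)
  col_of <- rep(seq_len(n_cols), times = n_rows)
  truth <- ifelse(col_of <= 10L, "gland", "cancer")
  gland <- which(truth == "gland")

  half <- n_genes %/% 2
  mu_g <- c(rep(8, half), rep(1, n_genes - half))
  mu_c <- c(rep(1, half), rep(8, n_genes - half))
  gen <- with_seed(seed, {
    mu <- matrix(mu_g, length(truth), n_genes, byrow = TRUE)
    mu[truth == "cancer", ] <- matrix(mu_c, sum(truth == "cancer"), n_genes,
                                      byrow = TRUE)
    list(X = pmax(mu + matrix(rnorm(length(mu), sd = 0.5), nrow(mu)), 0),
         flip_order = sample(gland))
  })

  lapply(mislabel_counts, function(m) {
    pred <- truth
    if (m > 0L) pred[gen$flip_order[seq_len(m)]] <- "cancer"
    ds <- spatial_dataset(coords, truth, pred, expression = gen$X)
    attr(ds, "mislabels") <- m
    attr(ds, "error_rate") <- m / length(truth)
    ds
  })
}

#' Stress suite of random, inverted, and constant labelings
#'
#' Builds square-grid truths with `n_domains` horizontal striped domains
#' and, per seed, adversarial predictions: a uniform random labeling, the
#' stripe-order inversion, a constant labeling, and (optionally) the
#' identity. Used to exercise the score across its full range.
#'
#' @param n_side Grid side length (>= 4).
#' @param n_domains Number of striped domains (between 2 and `n_side`).
#' @param seeds Integer vector of seeds, one suite member set per seed.
#' @param kinds Which predictions to generate; subset of
#'   `c("random", "inverted", "constant", "identity")`.
#' @return List of [spatial_dataset()]s with attributes `kind` and `seed`.
#' @export
random_labeling_suite <- function(n_side, n_domains, seeds,
                                  kinds = c("random", "inverted",
                                            "constant")) {
  n_side <- as.integer(n_side)
  n_domains <- as.integer(n_domains)
  if (n_side < 4L) stop("`n_side` must be >= 4", call. = FALSE)
  if (n_domains < 2L || n_domains > n_side) {
    stop("`n_domains` must lie in [2, n_side]", call. = FALSE)
  }
  kinds <- match.arg(kinds, c("random", "inverted", "constant", "identity"),
                     several.ok = TRUE)
  coords <- grid_coords(n_side, n_side)
  row_of <- rep(seq_len(n_side), each = n_side)
  truth <- ceiling(row_of * n_domains / n_side)  # horizontal stripes 1..D
  out <- list()
  for (s in seeds) {
    for (kind in kinds) {
      pred <- switch(kind,
        random = with_seed(derive_seed(s, "stress-random"), {
          sample.int(n_domains, length(truth), replace = TRUE)
        }),
        inverted = n_domains + 1L - truth,
        constant = rep(1L, length(truth)),
        identity = truth
      )
      ds <- spatial_dataset(coords, truth, pred)
      attr(ds, "kind") <- kind
      attr(ds, "seed") <- s
      out[[length(out) + 1L]] <- ds
    }
  }
  out
}
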