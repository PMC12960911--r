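#' Jaccard coefficient matrix between predicted clusters and true domains
#'
#' Entry `(u, v)` is `|C_u intersect C_v| / |C_u union C_v|` where `C_u` is
#' the spot set of predicted cluster `u` and `C_v` the spot set of true
#' domain `v`.
#'
#' @param pred_labels Length-n predicted cluster labels (K1 distinct values).
#' @param true_labels Length-n ground-truth domain labels (K distinct values).
#' @return A `K1 x K` numeric matrix with entries in `[0, 1]`, rows named by
#'   predicted labels and columns by true labels.
#' @examples
#' jaccard_matrix(c("a", "a", "b"), c(1, 2, 2))
#' @export
jaccard_matrix <- function(pred_labels, true_labels) {
  if (length(pred_labels) != length(true_labels)) {
    stop("`pred_labels` and `true_labels` must have equal length",
         call. = FALSE)
  }
  pf <- factor(pred_labels)
  tf <- factor(true_labels)
  inter <- table(pf, tf)                      # K1 x K intersection counts
  nu <- rowSums(inter)
  nv <- colSums(inter)
  uni <- outer(nu, nv, `+`) - inter
  J <- as.matrix(inter / uni)
  dimnames(J) <- list(levels(pf), levels(tf))
  J
}

#' Match predicted clusters to ground-truth domains
#'
#' Aligns the K1 predicted clusters with the K true domains by maximizing
#' total Jaccard similarity with the Hungarian method. When `K1 > K` the
#' Jaccard matrix is padded with zero columns; clusters landing on a dummy
#' column are assigned the true label maximizing their Jaccard row. When
#' `K1 < K` it is padded with zero rows; for each true label matched to a
#' dummy row, the predicted cluster with the highest Jaccard coefficient
#' against it is re-matched to that label if its spots lie closer (mean
#' Euclidean distance to the domain's spot centroid) to that domain than to
#' their originally matched domain.
#'
#' @param J `K1 x K` Jaccard matrix from [jaccard_matrix()].
#' @param pred_codes Length-n integer predicted-cluster codes in `1..K1`
#'   (row order of `J`).
#' @param true_codes Length-n integer true-domain codes in `1..K` (column
#'   order of `J`).
#' @param coords `n x 2` spot coordinates, used only by the `K1 < K`
#'   re-match rule.
#' @return A `match_result` list: `jaccard` (the input matrix), `mapping`
#'   (integer vector, true label per predicted cluster; many-to-one when
#'   `K1 > K`), `remapped` (length-n codes in `1..K`), and `rematched`
#'   (predicted clusters moved by the `K1 < K` rule).
#' @export
match_clusters <- function(J, pred_codes, true_codes, coords) {
  J <- as.matrix(J)
  K1 <- nrow(J)
  K <- ncol(J)
  mapping <- integer(K1)
  rematched <- integer(0)

  if (K1 == K) {
    mapping <- hungarian_assign(J)
  } else if (K1 > K) {
    Jp <- cbind(J, matrix(0, K1, K1 - K))
    perm <- hungarian_assign(Jp)
    for (u in seq_len(K1)) {
      if (perm[u] <= K) {
        mapping[u] <- perm[u]
      } else {
        if (max(J[u, ]) == 0) {
          warning("predicted cluster ", u, " shares no spots with any true ",
                  "domain; assigning true label 1 by tie-break")
        }
        mapping[u] <- which.max(J[u, ])  # ties -> smallest true index
      }
    }
  } else {  # K1 < K
    Jp <- rbind(J, matrix(0, K - K1, K))
    perm <- hungarian_assign(Jp)
    mapping <- perm[seq_len(K1)]
    dummy_truths <- sort(perm[(K1 + 1):K])
    centroids <- vapply(seq_len(K), function(v) {
      colMeans(coords[true_codes == v, , drop = FALSE])
    }, numeric(2))
    mean_dist_to <- function(spots, v) {
      mean(sqrt(colSums((t(coords[spots, , drop = FALSE]) -
                           centroids[, v])^2)))
    }
    for (t in dummy_truths) {
      if (max(J[, t]) == 0) {
        warning("no predicted cluster overlaps true domain ", t,
                "; it remains unmatched")
        next
      }
      u <- which.max(J[, t])
      spots <- which(pred_codes == u)
      if (mean_dist_to(spots, t) < mean_dist_to(spots, mapping[u])) {
        mapping[u] <- t
        rematched <- c(rematched, u)
      }
    }
  }

  structure(list(jaccard = J,
                 mapping = mapping,
                 remapped = mapping[pred_codes],
                 rematched = rematched),
            class = "match_result")
}

#' Apply a cluster-to-domain mapping to predicted labels
#'
#' Converts predicted cluster codes into the ground-truth label space using
#' the mapping in a [match_clusters()] result (including any `K1 < K`
#' re-matches, which are already folded into the mapping).
#'
#' @param pred_codes Length-n integer predicted-cluster codes in `1..K1`.
#' @param match A `match_result`.
#' @return Length-n integer codes in `1..K`.
#' @export
relabel <- function(pred_codes, match) {
  stopifnot(inherits(match, "match_result"))
  pred_codes <- as.integer(pred_codes)
  if (any(pred_codes < 1L | pred_codes > length(match$mapping))) {
    stop("predicted label code outside the matched alphabet", call. = FALSE)
  }
  match$mapping[pred_codes]
}

# Run the matching step on a dataset. The step exists to convert predicted
# labels into the ground-truth label space; under "auto" (the default), a
# prediction whose label alphabet already lies inside the truth alphabet is
# taken as pre-aligned and the conversion is the identity, so deliberate
# label semantics (e.g. synthesized mislabelings) are preserved. "always"
# forces Jaccard-Hungarian matching; "never" requires pre-aligned labels.
match_dataset <- function(dataset, mode = c("auto", "always", "never")) {
  mode <- match.arg(mode)
  aligned <- all(dataset$pred_levels %in% dataset$true_levels)
  if (mode == "never" && !aligned) {
    stop("match_mode = \"never\" requires predicted labels drawn from the ",
         "ground-truth alphabet", call. = FALSE)
  }
  if (aligned && mode != "always") {
    mapping <- match(dataset$pred_levels, dataset$true_levels)
    return(structure(list(jaccard = NULL,
                          mapping = mapping,
                          remapped = mapping[dataset$pred_codes],
                          rematched = integer(0),
                          pre_aligned = TRUE),
                     class = "match_result"))
  }
  J <- jaccard_matrix(dataset$pred_codes, dataset$true_codes)
  match_clusters(J, dataset$pred_codes, dataset$true_codes, dataset$coords)
}
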