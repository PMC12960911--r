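#' External clustering metrics against ground truth
#'
#' Computes the five standard external metrics from the pairwise
#' contingency table of the two labelings: Adjusted Rand Index (ARI),
#' Normalized Mutual Information (NMI, geometric-mean normalization), the
#' pair-counting Jaccard index, the Fowlkes-Mallows Index (FMI), and
#' V-measure (harmonic mean of homogeneity and completeness). All are
#' higher-is-better and invariant to label-name permutations on either
#' side.
#'
#' @param true_labels,pred_labels Equal-length label vectors.
#' @return A `metric_panel`: `values` (named numeric vector) and
#'   `directions` (named character vector, all `"higher_better"`).
#' @export
external_panel <- function(true_labels, pred_labels) {
  if (length(true_labels) != length(pred_labels)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  n <- length(true_labels)
  tab <- table(true_labels, pred_labels)
  ai <- rowSums(tab)
  bj <- colSums(tab)
  c2 <- function(x) x * (x - 1) / 2
  S11 <- sum(c2(tab))
  P1 <- sum(c2(ai))
  P2 <- sum(c2(bj))
  Npairs <- c2(n)

  expected <- P1 * P2 / Npairs
  denom <- (P1 + P2) / 2 - expected
  ari <- if (denom == 0) 1 else (S11 - expected) / denom

  jacc <- if (P1 + P2 - S11 == 0) 1 else S11 / (P1 + P2 - S11)
  fmi <- if (P1 == 0 || P2 == 0) 0 else S11 / sqrt(P1 * P2)

  pt <- ai / n
  pp <- bj / n
  pj <- tab / n
  Ht <- -sum(pt[pt > 0] * log(pt[pt > 0]))
  Hp <- -sum(pp[pp > 0] * log(pp[pp > 0]))
  nz <- pj > 0
  I <- sum(pj[nz] * log(pj[nz] / (pt[row(pj)[nz]] * pp[col(pj)[nz]])))
  nmi <- if (Ht == 0 && Hp == 0) 1 else if (Ht == 0 || Hp == 0) 0 else
    I / sqrt(Ht * Hp)
  homog <- if (Ht == 0) 1 else I / Ht
  compl <- if (Hp == 0) 1 else I / Hp
  vmeas <- if (homog + compl == 0) 0 else 2 * homog * compl / (homog + compl)

  vals <- c(ARI = ari, NMI = nmi, Jaccard = jacc, FMI = fmi,
            V_measure = vmeas)
  structure(list(values = vals,
                 directions = setNames(rep("higher_better", length(vals)),
                                       names(vals))),
            class = "metric_panel")
}

#' Spatial continuity index from within-cluster nearest neighbors
#'
#' Standardizes coordinates to zero mean and unit variance per axis, then
#' averages over spots the Euclidean distance to the nearest spot carrying
#' the same cluster label. Lower values indicate spatially more continuous
#' labelings. Spots in singleton clusters are skipped with a warning.
#'
#' @param coords `n x 2` coordinates.
#' @param labels Length-n cluster labels.
#' @return A nonnegative scalar (lower is better).
#' @export
chaos <- function(coords, labels) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(length(labels) == n)
  z <- scale(coords)
  z[is.nan(z)] <- 0  # constant axis
  labels <- as.integer(factor(labels))
  sizes <- tabulate(labels)
  if (any(sizes[labels] < 2L)) {
    warning("singleton cluster(s): their spots are skipped")
  }
  d <- as.matrix(dist(z))
  diag(d) <- Inf
  vals <- vapply(seq_len(n), function(i) {
    same <- labels == labels[i]
    same[i] <- FALSE
    if (!any(same)) return(NA_real_)
    min(d[i, same])
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

#' Percentage of abnormal spots
#'
#' Fraction of spots for which more than `threshold` of their `k` spatial
#' nearest neighbors carry a different cluster label. Lower values indicate
#' spatially more coherent labelings.
#'
#' @param coords `n x 2` coordinates.
#' @param labels Length-n cluster labels.
#' @param k Neighborhood size (default 10; must satisfy `k < n`).
#' @param threshold Disagreement count above which a spot is abnormal
#'   (default 6).
#' @return A value in `[0, 1]` (lower is better).
#' @export
pas <- function(coords, labels, k = 10L, threshold = 6L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(length(labels) == n)
  k <- as.integer(k)
  if (k >= n) stop("`k` must be smaller than the number of spots",
                   call. = FALSE)
  labels <- as.integer(factor(labels))
  d <- as.matrix(dist(coords))
  diag(d) <- Inf
  abnormal <- vapply(seq_len(n), function(i) {
    nb <- order(d[i, ])[seq_len(k)]  # ties broken by smaller index
    sum(labels[nb] != labels[i]) > threshold
  }, logical(1))
  mean(abnormal)
}

#' Min-max normalize a table of metric scores across methods
#'
#' Rescales each metric column to `[0, 1]` across methods and inverts
#' lower-is-better metrics, so that after normalization larger is always
#' better. A metric that is constant across methods maps to 0.5 everywhere,
#' with a warning.
#'
#' @param values Numeric matrix or data frame, methods in rows and metrics
#'   in columns (>= 2 rows).
#' @param directions Named character vector (`"higher_better"` or
#'   `"lower_better"`) covering every column of `values`.
#' @return A numeric matrix of normalized scores in `[0, 1]`.
#' @export
normalize_panel <- function(values, directions) {
  values <- as.matrix(values)
  if (nrow(values) < 2L) {
    stop("normalization needs at least 2 methods per metric", call. = FALSE)
  }
  if (!all(colnames(values) %in% names(directions))) {
    stop("every metric column needs a declared direction", call. = FALSE)
  }
  out <- values
  for (j in seq_len(ncol(values))) {
    v <- values[, j]
    rng <- range(v)
    if (rng[1] == rng[2]) {
      warning("metric '", colnames(values)[j],
              "' is constant across methods; normalized to 0.5")
      out[, j] <- 0.5
      next
    }
    u <- (v - rng[1]) / (rng[2] - rng[1])
    if (directions[[colnames(values)[j]]] == "lower_better") u <- 1 - u
    out[, j] <- u
  }
  out
}
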