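#' Construct a spatial clustering dataset
#'
#' Bundles per-spot 2-D coordinates, ground-truth tissue-domain labels, and
#' predicted cluster labels (plus an optional spots x genes expression
#' matrix) into a validated `spatial_dataset` object. Label alphabets are
#' recoded internally to dense 1-based integer codes; the original names are
#' retained for reporting.
#'
#' @param coords Numeric matrix or data frame with n rows and 2 columns
#'   (x, y), in arbitrary Euclidean slide units.
#' @param true_labels Length-n vector of ground-truth domain labels (any
#'   atomic type); defines the K-level truth alphabet.
#' @param pred_labels Length-n vector of predicted cluster labels over an
#'   arbitrary alphabet of K1 levels.
#' @param expression Optional n x g nonnegative numeric matrix of gene
#'   expression (genes in columns).
#' @param spot_ids Optional length-n character vector of unique spot
#'   identifiers; defaults to `spot_1 ... spot_n`.
#' @return An object of class `spatial_dataset` with elements `coords`,
#'   `true_codes` (integers in 1..K), `pred_codes` (integers in 1..K1),
#'   `true_levels`, `pred_levels`, `expression`, `spot_ids`, `n`, `K`, `K1`.
#' @examples
#' d <- spatial_dataset(cbind(c(0, 1, 0, 1), c(0, 0, 1, 1)),
#'                      true_labels = c("A", "A", "B", "B"),
#'                      pred_labels = c(1, 1, 2, 2))
#' d$K; d$K1
#' @export
spatial_dataset <- function(coords, true_labels, pred_labels,
                            expression = NULL, spot_ids = NULL) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 2L) {
    stop("`coords` must be a numeric matrix with 2 columns (x, y)",
         call. = FALSE)
  }
  n <- nrow(coords)
  if (n < 2L) stop("a spatial dataset needs at least 2 spots", call. = FALSE)
  if (!all(is.finite(coords))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  if (length(true_labels) != n || length(pred_labels) != n) {
    stop("label vectors must have one entry per coordinate row",
         call. = FALSE)
  }
  if (anyNA(true_labels) || anyNA(pred_labels)) {
    stop("spots with missing truth or prediction labels are not allowed",
         call. = FALSE)
  }
  if (is.null(spot_ids)) {
    spot_ids <- paste0("spot_", seq_len(n))
  }
  spot_ids <- as.character(spot_ids)
  if (length(spot_ids) != n) {
    stop("`spot_ids` must have one entry per spot", call. = FALSE)
  }
  if (anyDuplicated(spot_ids)) {
    stop("duplicate spot_ids are not allowed", call. = FALSE)
  }

  tf <- factor(true_labels)
  pf <- factor(pred_labels)

  if (!is.null(expression)) {
    expression <- as.matrix(expression)
    if (nrow(expression) != n) {
      stop("expression matrix must have one row per spot (got ",
           nrow(expression), " rows for ", n, " spots)", call. = FALSE)
    }
    if (ncol(expression) < 1L) {
      stop("expression matrix needs at least one gene column", call. = FALSE)
    }
    if (!is.numeric(expression) || anyNA(expression)) {
      stop("expression entries must be numeric and non-missing",
           call. = FALSE)
    }
    if (any(expression < 0)) {
      stop("expression entries must be nonnegative", call. = FALSE)
    }
  }

  structure(list(
    coords      = unname(coords),
    true_codes  = as.integer(tf),
    pred_codes  = as.integer(pf),
    true_levels = levels(tf),
    pred_levels = levels(pf),
    expression  = expression,
    spot_ids    = spot_ids,
    n           = n,
    K           = nlevels(tf),
    K1          = nlevels(pf)
  ), class = "spatial_dataset")
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat("<spatial_dataset> ", x$n, " spots, K = ", x$K,
      " true domains, K1 = ", x$K1, " predicted clusters\n", sep = "")
  if (!is.null(x$expression)) {
    cat("  expression: ", nrow(x$expression), " x ", ncol(x$expression),
        " matrix\n", sep = "")
  }
  invisible(x)
}

# error rate of the prediction in truth-label space (used by generators)
error_rate <- function(dataset, remapped = NULL) {
  pred <- if (is.null(remapped)) dataset$pred_codes else remapped
  mean(pred != dataset$true_codes)
}
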