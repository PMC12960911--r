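#' Assign edge label codes from a node labeling
#'
#' For each spatially adjacent pair, the edge code is `k > 0` when both
#' endpoints carry label `k`, and `0` when the endpoint labels differ
#' (a "disconnected" edge in the encoding). Applied identically to the
#' ground-truth labeling and to the matched clustering labeling over the
#' same adjacency.
#'
#' @param adj An [build_adjacency()] result.
#' @param labels Length-n integer label codes in `1..K` (code 0 is reserved
#'   for the mismatch state and is rejected on input).
#' @return Integer vector of edge codes in `0..K`, aligned with
#'   `adj$pairs`.
#' @export
label_edges <- function(adj, labels) {
  stopifnot(inherits(adj, "adjacency"))
  labels <- as.integer(labels)
  if (length(labels) != adj$n) {
    stop("`labels` must cover all ", adj$n, " nodes", call. = FALSE)
  }
  if (any(labels < 1L)) {
    stop("label code 0 (and below) is reserved for the mismatch state",
         call. = FALSE)
  }
  la <- labels[adj$pairs[, 1]]
  lb <- labels[adj$pairs[, 2]]
  ifelse(la == lb, la, 0L)
}

#' Scaled cosine similarity between two expression profiles
#'
#' Maps the cosine similarity from `[-1, 1]` to `[0, 1]` via
#' `(cos + 1) / 2`, so identical profiles score 1, orthogonal profiles 0.5,
#' and opposite profiles 0.
#'
#' @param x_u,x_v Numeric vectors of equal length, each with at least one
#'   nonzero entry.
#' @return A number in `[0, 1]`.
#' @export
scaled_cosine <- function(x_u, x_v) {
  nu <- sqrt(sum(x_u^2))
  nv <- sqrt(sum(x_v^2))
  if (nu == 0 || nv == 0) {
    stop("scaled cosine similarity is undefined for a zero expression profile",
         call. = FALSE)
  }
  (sum(x_u * x_v) / (nu * nv) + 1) / 2
}

#' Expression-based edge severity weights
#'
#' Weights each adjacent pair by the similarity of its endpoints'
#' expression profiles: same-label edges get `Sim(x_u, x_v)` and
#' label-mismatch edges get `1 - Sim(x_u, x_v)`, penalizing errors more
#' heavily when transcriptionally similar spots are split across clusters
#' or dissimilar spots merged into one.
#'
#' @param adj An [build_adjacency()] result.
#' @param edge_codes Edge codes from [label_edges()], aligned with
#'   `adj$pairs`.
#' @param X `n x g` expression matrix.
#' @param sim Similarity function on two profile vectors returning a value
#'   in `[0, 1]`; defaults to [scaled_cosine()].
#' @return Numeric vector of per-edge weights in `[0, 1]`.
#' @export
expression_weights <- function(adj, edge_codes, X, sim = scaled_cosine) {
  stopifnot(inherits(adj, "adjacency"))
  if (is.null(X)) {
    stop("configuration error: expression weights requested but no ",
         "expression matrix is attached; use cost weights or uniform ",
         "weights instead", call. = FALSE)
  }
  X <- as.matrix(X)
  if (nrow(X) != adj$n) {
    stop("expression matrix rows must match the number of nodes",
         call. = FALSE)
  }
  if (length(edge_codes) != nrow(adj$pairs)) {
    stop("`edge_codes` must align with `adj$pairs`", call. = FALSE)
  }
  s <- if (identical(sim, scaled_cosine)) {
    # vectorized fast path for the default similarity
    norms <- sqrt(rowSums(X^2))
    if (any(norms == 0)) {
      stop("scaled cosine similarity is undefined for a zero expression ",
           "profile", call. = FALSE)
    }
    u <- adj$pairs[, 1]
    v <- adj$pairs[, 2]
    (rowSums(X[u, , drop = FALSE] * X[v, , drop = FALSE]) /
       (norms[u] * norms[v]) + 1) / 2
  } else {
    vapply(seq_len(nrow(adj$pairs)), function(e) {
      sim(X[adj$pairs[e, 1], ], X[adj$pairs[e, 2], ])
    }, numeric(1))
  }
  ifelse(edge_codes != 0L, s, 1 - s)
}

#' Cost-table edge severity weights
#'
#' Weights each adjacent pair from an explicit per-class-pair cost table
#' (e.g. false negatives costlier than false positives in tumor calling).
#' Each endpoint's cost is looked up from its (true class, predicted
#' class) confusion status, with concordant spots defaulting to cost 1
#' when the table omits them; the pair weight is the mean of the two
#' endpoint costs. The same weight vector applies to both graphs.
#'
#' @param adj An [build_adjacency()] result.
#' @param true_codes Length-n true-domain codes in `1..K`.
#' @param pred_codes Length-n matched prediction codes in `1..K` (i.e.
#'   after [relabel()]).
#' @param cost_table Data frame with columns `true_class`, `pred_class`
#'   (character names in the truth alphabet), `cost` (positive), as read by
#'   [read_cost_table()].
#' @param true_levels Character vector naming the truth alphabet in code
#'   order; defaults to `1..K` as character.
#' @return Numeric vector of per-edge weights (positive).
#' @export
cost_weights <- function(adj, true_codes, pred_codes, cost_table,
                         true_levels = NULL) {
  stopifnot(inherits(adj, "adjacency"))
  true_codes <- as.integer(true_codes)
  pred_codes <- as.integer(pred_codes)
  K <- max(true_codes, pred_codes)
  if (is.null(true_levels)) true_levels <- as.character(seq_len(K))
  cost <- matrix(NA_real_, K, K)
  diag(cost) <- 1  # concordant default
  ti <- match(cost_table$true_class, true_levels)
  pi <- match(cost_table$pred_class, true_levels)
  if (anyNA(ti) || anyNA(pi)) {
    bad <- which(is.na(ti) | is.na(pi))[1]
    stop("configuration error: cost table names unknown class pair (",
         cost_table$true_class[bad], ", ", cost_table$pred_class[bad], ")",
         call. = FALSE)
  }
  cost[cbind(ti, pi)] <- cost_table$cost
  node_cost <- cost[cbind(true_codes, pred_codes)]
  if (anyNA(node_cost)) {
    bad <- which(is.na(node_cost))[1]
    stop("configuration error: cost table has no entry for observed class ",
         "pair (", true_levels[true_codes[bad]], ", ",
         true_levels[pred_codes[bad]], ")", call. = FALSE)
  }
  (node_cost[adj$pairs[, 1]] + node_cost[adj$pairs[, 2]]) / 2
}

# Assemble the labeled graph pair for a dataset: shared adjacency, per-graph
# edge codes, and severity weights under the chosen scheme. Expression
# weights are computed per graph from that graph's own edge codes; cost
# weights are shared between the two graphs.
build_labeled_graphs <- function(dataset, remapped, adj,
                                 weights = c("uniform", "expression", "cost"),
                                 cost_table = NULL, sim = scaled_cosine) {
  weights <- match.arg(weights)
  codes0 <- label_edges(adj, dataset$true_codes)
  codes1 <- label_edges(adj, remapped)
  w <- switch(weights,
    uniform = {
      w1 <- rep(1, nrow(adj$pairs))
      list(w0 = w1, w1 = w1)
    },
    expression = list(
      w0 = expression_weights(adj, codes0, dataset$expression, sim),
      w1 = expression_weights(adj, codes1, dataset$expression, sim)
    ),
    cost = {
      if (is.null(cost_table)) {
        stop("configuration error: cost weights requested without a cost ",
             "table", call. = FALSE)
      }
      shared <- cost_weights(adj, dataset$true_codes, remapped, cost_table,
                             dataset$true_levels)
      list(w0 = shared, w1 = shared)
    }
  )
  list(adjacency = adj,
       truth = list(edge_codes = codes0, weights = w$w0),
       clustering = list(edge_codes = codes1, weights = w$w1))
}
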