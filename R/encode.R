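#' One-hot encode edge label codes
#'
#' Maps edge code `k > 0` to the unit vector `e_k` in `K` dimensions and
#' the mismatch code 0 to the zero vector, preserving edge order. With
#' three label types A, B, C the encodings are `[1,0,0]`, `[0,1,0]`,
#' `[0,0,1]`, and `[0,0,0]` for a mismatch edge.
#'
#' @param edge_codes Integer vector of codes in `0..K`.
#' @param K Number of label types (encoding dimension).
#' @return An `m x K` binary matrix.
#' @export
one_hot_encode <- function(edge_codes, K) {
  edge_codes <- as.integer(edge_codes)
  K <- as.integer(K)
  if (any(edge_codes < 0L) || any(edge_codes > K)) {
    stop("edge codes must lie in 0..K (K = ", K, ")", call. = FALSE)
  }
  Z <- matrix(0, nrow = length(edge_codes), ncol = K)
  pos <- which(edge_codes > 0L)
  Z[cbind(pos, edge_codes[pos])] <- 1
  Z
}

# inverse of one_hot_encode: index of the row maximum, 0 for zero rows
decode_one_hot <- function(Z) {
  out <- integer(nrow(Z))
  nz <- rowSums(Z) > 0
  out[nz] <- max.col(Z[nz, , drop = FALSE], ties.method = "first")
  out
}

#' Scale one-hot edge encodings by severity weights
#'
#' Multiplies each row of the binary encoding matrix by its edge weight
#' (elementwise product with the K-fold column replication of the weight
#' vector). Zero rows stay zero.
#'
#' @param Z `m x K` binary matrix from [one_hot_encode()].
#' @param weights Length-m nonnegative edge weights.
#' @return `m x K` numeric matrix.
#' @export
weight_adjust <- function(Z, weights) {
  Z <- as.matrix(Z)
  if (length(weights) != nrow(Z)) {
    stop("one weight per encoding row is required", call. = FALSE)
  }
  if (any(weights < 0)) {
    stop("edge weights must be nonnegative", call. = FALSE)
  }
  Z * weights
}

#' Fit a Gaussian kernel density over weighted edge encodings
#'
#' Places an isotropic Gaussian kernel of bandwidth `h` at every row of the
#' weighted encoding matrix, with the standard K-dimensional normalization
#' so the density integrates to 1.
#'
#' @param Z_weighted `m x K` numeric matrix of weighted edge encodings.
#' @param h Positive kernel bandwidth (default 0.1).
#' @return An `attribute_density` object with fields `support` (the rows),
#'   `h`, and `K`.
#' @export
fit_kde <- function(Z_weighted, h = 0.1) {
  Z_weighted <- as.matrix(Z_weighted)
  if (nrow(Z_weighted) < 1L) {
    stop("at least one support point is required", call. = FALSE)
  }
  if (!is.numeric(h) || length(h) != 1L || h <= 0) {
    stop("bandwidth `h` must be a positive number", call. = FALSE)
  }
  structure(list(support = Z_weighted, h = h, K = ncol(Z_weighted)),
            class = "attribute_density")
}

#' Evaluate an edge-encoding kernel density
#'
#' @param density An [fit_kde()] result.
#' @param x Numeric matrix of query points (rows) in K dimensions, or a
#'   single length-K vector.
#' @return Numeric vector of density values.
#' @export
density_at <- function(density, x) {
  stopifnot(inherits(density, "attribute_density"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != density$K) {
    stop("query points must have dimension K = ", density$K, call. = FALSE)
  }
  h <- density$h
  S <- density$support
  norm_const <- (2 * pi)^(-density$K / 2) / h^density$K
  vapply(seq_len(nrow(x)), function(i) {
    d2 <- rowSums((S - matrix(x[i, ], nrow(S), density$K, byrow = TRUE))^2)
    norm_const * mean(exp(-d2 / (2 * h^2)))
  }, numeric(1))
}

#' Draw reproducible sample batches from an edge-encoding density
#'
#' Each batch is an i.i.d. sample from the kernel mixture: a uniformly
#' chosen support row plus isotropic Gaussian jitter of scale `h`. The
#' caller's RNG state is left untouched; the same `(density, seed)` pair
#' always yields identical batches.
#'
#' @param density An [fit_kde()] result.
#' @param n_batches Number of batches to draw (>= 1).
#' @param batch_size Points per batch (>= 1).
#' @param seed Integer seed for this sampling substream.
#' @return List of `n_batches` matrices, each `batch_size x K`.
#' @export
sample_batches <- function(density, n_batches, batch_size, seed) {
  stopifnot(inherits(density, "attribute_density"))
  n_batches <- as.integer(n_batches)
  batch_size <- as.integer(batch_size)
  if (n_batches < 1L || batch_size < 1L) {
    stop("`n_batches` and `batch_size` must be >= 1", call. = FALSE)
  }
  S <- density$support
  K <- density$K
  h <- density$h
  with_seed(seed, {
    lapply(seq_len(n_batches), function(b) {
      idx <- sample.int(nrow(S), batch_size, replace = TRUE)
      S[idx, , drop = FALSE] +
        matrix(rnorm(batch_size * K, sd = h), batch_size, K)
    })
  })
}
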