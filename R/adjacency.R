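#' Build a spatial adjacency structure over spots
#'
#' Constructs the shared neighborhood graph used by both the ground-truth
#' and the clustering graph. Three constructions are offered: symmetrized
#' k-nearest neighbors (an edge is kept if either endpoint is among the
#' other's k nearest; the default, with `k = 6` matching hexagonal Visium
#' packing), a fixed radius, and Delaunay triangulation. Distance ties are
#' broken toward the smaller spot index.
#'
#' @param coords `n x 2` numeric matrix of finite spot coordinates.
#' @param method `"knn"` (default), `"radius"`, or `"delaunay"`.
#' @param param Method parameter: neighbor count `k` for `"knn"`
#'   (default 6), the radius for `"radius"`; ignored for `"delaunay"`.
#' @return An `adjacency` object: `pairs` (m x 2 integer matrix of
#'   unordered spot-index pairs with `pairs[, 1] < pairs[, 2]`), `method`,
#'   `param`, `n`.
#' @examples
#' adj <- build_adjacency(cbind(c(0, 1, 2), c(0, 0, 0)), "radius", 1.1)
#' adj$pairs
#' @export
build_adjacency <- function(coords, method = c("knn", "radius", "delaunay"),
                            param = NULL) {
  coords <- as.matrix(coords)
  method <- match.arg(method)
  n <- nrow(coords)
  if (n < 2L || !all(is.finite(coords)) || ncol(coords) != 2L) {
    stop("`coords` must be an n x 2 finite numeric matrix with n >= 2",
         call. = FALSE)
  }
  pairs <- switch(method,
    knn = {
      k <- if (is.null(param)) 6L else as.integer(param)
      if (k < 1L || k >= n) {
        stop("knn requires 1 <= k < n (got k = ", k, ", n = ", n, ")",
             call. = FALSE)
      }
      knn_pairs(coords, k)
    },
    radius = {
      if (is.null(param) || param <= 0) {
        stop("radius adjacency requires a positive radius", call. = FALSE)
      }
      p <- radius_pairs(coords, param)
      touched <- unique(as.vector(p))
      if (length(touched) < n) {
        warning(n - length(touched),
                " spot(s) are isolated at this radius; they are kept ",
                "as degree-0 nodes")
      }
      p
    },
    delaunay = delaunay_pairs(coords)
  )
  structure(list(pairs = pairs, method = method,
                 param = if (method == "knn" && is.null(param)) 6L else param,
                 n = n),
            class = "adjacency")
}

# symmetrized k-nearest-neighbour pairs, computed blockwise so that the
# full n x n distance matrix is never materialized
knn_pairs <- function(coords, k) {
  n <- nrow(coords)
  block <- max(1L, min(n, as.integer(2e6 / n)))
  from <- integer(0)
  to <- integer(0)
  sq <- rowSums(coords^2)
  starts <- seq(1L, n, by = block)
  for (s in starts) {
    rows <- s:min(s + block - 1L, n)
    d2 <- outer(sq[rows], sq, `+`) - 2 * coords[rows, , drop = FALSE] %*%
      t(coords)
    for (r in seq_along(rows)) {
      i <- rows[r]
      di <- d2[r, ]
      di[i] <- Inf
      nb <- order(di)[seq_len(k)]  # order() breaks ties by smaller index
      from <- c(from, rep.int(i, k))
      to <- c(to, nb)
    }
  }
  canonical_pairs(from, to)
}

radius_pairs <- function(coords, radius) {
  n <- nrow(coords)
  r2 <- radius^2 * (1 + 1e-12)
  block <- max(1L, min(n, as.integer(2e6 / n)))
  sq <- rowSums(coords^2)
  from <- integer(0)
  to <- integer(0)
  for (s in seq(1L, n, by = block)) {
    rows <- s:min(s + block - 1L, n)
    d2 <- outer(sq[rows], sq, `+`) - 2 * coords[rows, , drop = FALSE] %*%
      t(coords)
    hit <- which(d2 <= r2, arr.ind = TRUE)
    i <- rows[hit[, 1]]
    j <- hit[, 2]
    keep <- i < j
    from <- c(from, i[keep])
    to <- c(to, j[keep])
  }
  canonical_pairs(from, to)
}

canonical_pairs <- function(from, to) {
  a <- pmin(from, to)
  b <- pmax(from, to)
  keep <- a != b
  a <- a[keep]
  b <- b[keep]
  ord <- order(a, b)
  m <- cbind(a, b)[ord, , drop = FALSE]
  m <- m[!duplicated(m), , drop = FALSE]
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

# Delaunay triangulation via incremental Bowyer-Watson insertion with a
# strict (open-disc) in-circle test, so cocircular point sets resolve
# deterministically by insertion order.
delaunay_pairs <- function(coords) {
  n <- nrow(coords)
  rngx <- range(coords[, 1])
  rngy <- range(coords[, 2])
  span <- max(rngx[2] - rngx[1], rngy[2] - rngy[1])
  if (span == 0) {
    stop("degenerate geometry: all points coincident; Delaunay ",
         "triangulation undefined", call. = FALSE)
  }
  cx <- mean(rngx)
  cy <- mean(rngy)
  big <- 50 * span
  pts <- rbind(coords,
               c(cx - big, cy - big),
               c(cx + big, cy - big),
               c(cx, cy + big))
  eps <- (1e-10 * span)^2

  circum <- function(tri) {
    a <- pts[tri[1], ]; b <- pts[tri[2], ]; c <- pts[tri[3], ]
    d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) +
                c[1] * (a[2] - b[2]))
    if (abs(d) < 1e-14 * span^2) return(c(NA, NA, Inf))
    asq <- sum(a^2); bsq <- sum(b^2); csq <- sum(c^2)
    ux <- (asq * (b[2] - c[2]) + bsq * (c[2] - a[2]) + csq * (a[2] - b[2])) / d
    uy <- (asq * (c[1] - b[1]) + bsq * (a[1] - c[1]) + csq * (b[1] - a[1])) / d
    c(ux, uy, (ux - a[1])^2 + (uy - a[2])^2)
  }

  tris <- list(as.integer(c(n + 1, n + 2, n + 3)))
  ccs <- list(circum(tris[[1]]))
  for (p in seq_len(n)) {
    px <- pts[p, 1]; py <- pts[p, 2]
    bad <- which(vapply(ccs, function(cc) {
      is.finite(cc[3]) && ((px - cc[1])^2 + (py - cc[2])^2 < cc[3] - eps)
    }, logical(1)))
    if (!length(bad)) next  # duplicate / cocircular-degenerate point
    edges <- do.call(rbind, lapply(tris[bad], function(tr) {
      rbind(sort(tr[c(1, 2)]), sort(tr[c(2, 3)]), sort(tr[c(1, 3)]))
    }))
    key <- paste(edges[, 1], edges[, 2])
    boundary <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    tris[bad] <- NULL
    ccs[bad] <- NULL
    for (e in seq_len(nrow(boundary))) {
      tr <- as.integer(c(boundary[e, ], p))
      tris[[length(tris) + 1L]] <- tr
      ccs[[length(ccs) + 1L]] <- circum(tr)
    }
  }
  real <- Filter(function(tr) all(tr <= n), tris)
  if (!length(real)) {
    stop("degenerate geometry: points do not span the plane (collinear ",
         "or coincident); Delaunay triangulation undefined", call. = FALSE)
  }
  edges <- do.call(rbind, lapply(real, function(tr) {
    rbind(tr[c(1, 2)], tr[c(2, 3)], tr[c(1, 3)])
  }))
  canonical_pairs(edges[, 1], edges[, 2])
}
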