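# Linear assignment by the O(n^3) shortest-augmenting-path (potentials)
# method, minimizing total cost over permutations. Written here because no
# assignment solver ships with the declared dependencies.

# cost: square numeric matrix; returns integer vector: column per row
solve_assignment_min <- function(cost) {
  n <- nrow(cost)
  # columns indexed 0..n stored at positions 1..n+1 (position 1 = virtual col)
  u <- numeric(n + 1)          # row potentials (u[i+1] for row i)
  v <- numeric(n + 1)          # column potentials
  p <- integer(n + 1)          # p[j+1]: row matched to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- logical(n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) {
            minv[j + 1] <- cur
            way[j + 1] <- j0
          }
          if (minv[j + 1] < delta) {
            delta <- minv[j + 1]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign_col <- integer(n)
  for (j in seq_len(n)) assign_col[p[j + 1]] <- j
  assign_col
}

min_assignment_value <- function(cost) {
  perm <- solve_assignment_min(cost)
  sum(cost[cbind(seq_len(nrow(cost)), perm)])
}

#' Optimal cluster-to-domain assignment by the Hungarian method
#'
#' Finds the permutation (one true-label column per predicted-cluster row)
#' maximizing the total selected similarity, e.g. the summed Jaccard
#' coefficients from [jaccard_matrix()]. Among co-optimal assignments the
#' lexicographically smallest one (row by row) is returned, so results are
#' deterministic.
#'
#' @param J Square numeric similarity matrix with finite entries.
#' @return Integer vector `perm` with `perm[u]` the column assigned to row
#'   `u`; a permutation of `1:nrow(J)`.
#' @examples
#' hungarian_assign(rbind(c(0.9, 0.1), c(0.2, 0.8)))  # 1 2
#' @export
hungarian_assign <- function(J) {
  J <- as.matrix(J)
  if (nrow(J) != ncol(J)) {
    stop("`J` must be square; pad rectangular matrices before assignment",
         call. = FALSE)
  }
  if (!all(is.finite(J))) stop("`J` must have finite entries", call. = FALSE)
  n <- nrow(J)
  if (n == 1L) return(1L)
  cost <- -J  # maximize similarity == minimize negated similarity
  opt <- min_assignment_value(cost)
  tol <- 1e-9 * max(1, max(abs(J)))
  # lexicographically smallest optimum: fix rows in order, trying columns
  # in ascending order and keeping the first choice that still admits an
  # optimal completion of the remaining subproblem
  perm <- integer(n)
  rows_left <- seq_len(n)
  cols_left <- seq_len(n)
  fixed <- 0
  for (i in seq_len(n)) {
    rows_left <- rows_left[rows_left != i]
    for (j in cols_left) {
      rest <- if (length(rows_left)) {
        min_assignment_value(cost[rows_left, cols_left[cols_left != j],
                                  drop = FALSE])
      } else 0
      if (fixed + cost[i, j] + rest <= opt + tol) {
        perm[i] <- j
        fixed <- fixed + cost[i, j]
        cols_left <- cols_left[cols_left != j]
        break
      }
    }
  }
  perm
}
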