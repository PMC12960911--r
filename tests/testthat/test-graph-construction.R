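test_that("adjacency constructions match geometric oracles", {
  # 3 collinear points at spacing 1, radius 1.1 -> the two consecutive pairs
  adj <- build_adjacency(cbind(0:2, c(0, 0, 0)), "radius", 1.1)
  expect_equal(adj$pairs, rbind(c(1L, 2L), c(2L, 3L)))

  # unit-square corners, knn k=2 -> the 4 side pairs, diagonals excluded
  sq <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  adj2 <- build_adjacency(sq, "knn", 2)
  expect_equal(adj2$pairs, rbind(c(1L, 2L), c(1L, 3L), c(2L, 4L),
                                 c(3L, 4L)))

  # unit-square corners, delaunay -> 4 sides plus exactly one diagonal
  adj3 <- build_adjacency(sq, "delaunay")
  expect_equal(nrow(adj3$pairs), 5L)
  sides <- rbind(c(1L, 2L), c(1L, 3L), c(2L, 4L), c(3L, 4L))
  expect_true(all(apply(sides, 1, function(s) {
    any(adj3$pairs[, 1] == s[1] & adj3$pairs[, 2] == s[2])
  })))
})

test_that("adjacency structures are symmetric, deduplicated, and bounded", {
  set.seed(3)
  coords <- cbind(runif(40), runif(40))
  for (adj in list(build_adjacency(coords, "knn", 5),
                   build_adjacency(coords, "delaunay"),
                   build_adjacency(coords, "radius", 0.3))) {
    expect_true(all(adj$pairs[, 1] < adj$pairs[, 2]))
    expect_false(any(duplicated(adj$pairs)))
    expect_true(all(adj$pairs <= 40))
  }
  expect_error(build_adjacency(coords[1, , drop = FALSE], "knn", 1), "n >= 2")
  expect_error(build_adjacency(coords, "knn", 40), "k < n")
  expect_error(build_adjacency(matrix(1, 5, 2), "delaunay"), "degenerate")
  expect_warning(build_adjacency(rbind(c(0, 0), c(0.1, 0), c(9, 9)),
                                 "radius", 0.5), "isolated")
})

test_that("knn and delaunay adjacency are rigid-motion invariant", {
  set.seed(7)
  coords <- cbind(runif(30, 0, 5), runif(30, 0, 5))
  base_knn <- build_adjacency(coords, "knn", 4)$pairs
  base_del <- build_adjacency(coords, "delaunay")$pairs
  for (r in 1:5) {
    th <- runif(1, 0, 2 * pi)
    R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
    moved <- coords %*% R + matrix(runif(2, -10, 10), 30, 2, byrow = TRUE)
    expect_equal(build_adjacency(moved, "knn", 4)$pairs, base_knn)
    expect_equal(build_adjacency(moved, "delaunay")$pairs, base_del)
  }
})

test_that("edge codes follow the shared-label rule", {
  adj <- build_adjacency(cbind(0:3, rep(0, 4)), "radius", 1.1)
  # pairs: (1,2),(2,3),(3,4)
  codes <- label_edges(adj, c(2L, 2L, 1L, 3L))
  expect_equal(codes, c(2L, 0L, 0L))
  expect_equal(label_edges(adj, rep(4L, 4)), rep(4L, 3))
  expect_error(label_edges(adj, c(0L, 1L, 1L, 1L)), "reserved")
  # identical labelings give identical codes pair-by-pair
  set.seed(9)
  coords <- cbind(runif(25), runif(25))
  lab <- sample(1:3, 25, replace = TRUE)
  a2 <- build_adjacency(coords, "knn", 4)
  expect_identical(label_edges(a2, lab), label_edges(a2, lab + 0L))
})

test_that("scaled cosine maps alignment onto [0, 1]", {
  expect_equal(scaled_cosine(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(scaled_cosine(c(1, 0), c(0, 1)), 0.5)
  expect_equal(scaled_cosine(c(1, 1), -c(1, 1)), 0)
  expect_error(scaled_cosine(c(0, 0), c(1, 1)), "zero")
})

test_that("expression weights implement both similarity branches", {
  coords <- rbind(c(0, 0), c(1, 0), c(2, 0))
  adj <- build_adjacency(coords, "radius", 1.1)  # pairs (1,2), (2,3)
  X <- rbind(c(1, 0), c(1, 0), c(0, 1))
  w <- expression_weights(adj, edge_codes = c(1L, 1L), X)
  expect_equal(w, c(1, 0.5))     # identical -> 1; orthogonal same-label -> 0.5
  w0 <- expression_weights(adj, edge_codes = c(0L, 0L), X)
  expect_equal(w0, c(0, 0.5))    # mismatch edges flip to 1 - Sim
  expect_equal(w0, 1 - w)        # flipping a code maps w to 1 - w
  expect_error(expression_weights(adj, c(1L, 1L), NULL), "configuration")

  # weights stay in [0, 1] on random nonnegative expression
  set.seed(13)
  Xr <- matrix(rexp(3 * 8), 3)
  wr <- expression_weights(adj, c(1L, 0L), Xr)
  expect_true(all(wr >= 0 & wr <= 1))
})

test_that("cost weights aggregate endpoint confusion costs by mean", {
  coords <- rbind(c(0, 0), c(1, 0), c(2, 0))
  adj <- build_adjacency(coords, "radius", 1.1)
  tabl <- data.frame(true_class = c("cancer", "normal"),
                     pred_class = c("normal", "cancer"),
                     cost = c(2, 1), stringsAsFactors = FALSE)
  lv <- c("cancer", "normal")
  # two cancer-truth spots predicted normal (FN pair) -> weight 2
  w <- cost_weights(adj, true_codes = c(1L, 1L, 1L),
                    pred_codes = c(2L, 2L, 1L), cost_table = tabl,
                    true_levels = lv)
  expect_equal(w, c(2, 1.5))     # FN+FN -> 2; FN+concordant -> (2+1)/2
  # all-ones table reduces every weight to 1
  ones <- data.frame(true_class = rep(lv, each = 2),
                     pred_class = rep(lv, 2), cost = 1,
                     stringsAsFactors = FALSE)
  expect_equal(cost_weights(adj, c(1L, 2L, 1L), c(2L, 1L, 1L), ones, lv),
               rep(1, 2))
  bad <- data.frame(true_class = "cancer", pred_class = "normal", cost = 2,
                    stringsAsFactors = FALSE)
  expect_error(cost_weights(adj, c(2L, 2L, 1L), c(1L, 1L, 1L), bad, lv),
               "no entry")
})
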