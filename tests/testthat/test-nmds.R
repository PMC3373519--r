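test_that("exact Euclidean distances embed with ~zero stress and recover the layout", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  D <- as.matrix(dist(sq))
  dimnames(D) <- list(paste0("p", 1:4), paste0("p", 1:4))
  em <- fit_nmds(D, p = 2, restarts = 4, seed = 1)
  expect_lt(em$stress, 1e-3)
  expect_lt(procrustes_residual(em$coords, sq), 1e-3)
  expect_lt(max(abs(colMeans(em$coords))), 1e-8)
  # stress is non-increasing within the reported restart
  expect_true(all(diff(em$stress_trace) <= 1e-12))
})

test_that("any 3-point dissimilarity embeds in the plane with ~zero stress", {
  D <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3)
  dimnames(D) <- list(letters[1:3], letters[1:3])
  em <- fit_nmds(D, p = 2, restarts = 4, seed = 2)
  expect_lt(em$stress, 1e-6)
})

test_that("fixed seed is bit-reproducible and labels are equivariant", {
  g <- gen_outlines(seed = 3, m_points = 48,
                    groups = data.frame(label = c("a", "b"),
                                        ratio = c(2, 3.2),
                                        pointedness = 2, count = c(3, 3)))
  D <- pairwise_distances(g$shapes, m = 32)
  e1 <- fit_nmds(D, seed = 7)
  e2 <- fit_nmds(D, seed = 7)
  expect_identical(e1$coords, e2$coords)
  expect_identical(e1$stress, e2$stress)

  # permuting the input rows permutes the output rows (deterministic
  # classical-scaling start)
  perm <- c(4, 2, 6, 1, 3, 5)
  Dp <- shape_dist(D$d[perm, perm], D$labels[perm])
  ep <- fit_nmds(Dp, restarts = 1, seed = 1)
  e0 <- fit_nmds(D, restarts = 1, seed = 1)
  expect_equal(ep$stress, e0$stress, tolerance = 1e-10)
  # same configuration up to row order and axis sign/rotation
  expect_lt(procrustes_residual(ep$coords, e0$coords[perm, ]), 1e-6)
})

test_that("stress-1 matches a direct textbook recomputation", {
  set.seed(5)
  X <- matrix(rnorm(12), 6, 2)
  D <- as.matrix(dist(X)) + 0.05 * as.matrix(dist(matrix(rnorm(12), 6, 2)))
  D <- (D + t(D)) / 2; diag(D) <- 0
  coords <- matrix(rnorm(12), 6, 2)
  s_pkg <- nmds_stress(D, coords)
  # independent recomputation: isotonic regression via PAVA on ranked
  # dissimilarities, Kruskal stress-1 formula
  d <- as.vector(dist(coords))
  delta <- D[lower.tri(D)]
  ord <- order(delta, d)
  y <- d[ord]
  # pool-adjacent-violators
  w <- rep(1, length(y))
  repeat {
    v <- which(diff(y) < 0)
    if (!length(v)) break
    i <- v[1]
    newv <- (w[i] * y[i] + w[i + 1] * y[i + 1]) / (w[i] + w[i + 1])
    y <- c(y[seq_len(i - 1)], newv, y[-seq_len(i + 1)])
    w <- c(w[seq_len(i - 1)], w[i] + w[i + 1], w[-seq_len(i + 1)])
  }
  dhat <- rep(y, times = w)
  s_ref <- sqrt(sum((d[ord] - dhat)^2) / sum(d^2))
  expect_equal(s_pkg, s_ref, tolerance = 1e-10)

  # perfect configuration: zero; degenerate configuration: one
  expect_lt(nmds_stress(as.matrix(dist(X)), X), 1e-10)
  expect_equal(nmds_stress(D, matrix(0, 6, 2)), 1.0)
})

test_that("stress is invariant to monotone transforms of the dissimilarities", {
  g <- gen_outlines(seed = 11, m_points = 48,
                    groups = data.frame(label = c("a", "b"),
                                        ratio = c(2, 3.2),
                                        pointedness = 2, count = c(4, 4)))
  D <- pairwise_distances(g$shapes, m = 32)
  e0 <- fit_nmds(D, restarts = 10, seed = 1)
  Dt <- D$d^1.7 * 3.1          # strictly increasing transform
  et <- fit_nmds(shape_dist(Dt, D$labels), restarts = 10, seed = 1)
  expect_lt(abs(e0$stress - et$stress), 1e-3)
})

test_that("aspect-ratio groups separate linearly in the 2D embedding", {
  ok <- 0
  for (s in 1:5) {
    g <- gen_outlines(seed = 100 + s, m_points = 64, noise_sd = 0.02,
                      groups = data.frame(label = c("lo", "hi"),
                                          ratio = c(2.0, 3.2),
                                          pointedness = 2, count = c(5, 5)))
    D <- pairwise_distances(g$shapes, m = 48)
    em <- fit_nmds(D, p = 2, restarts = 4, seed = s)
    grp <- sub("_.*", "", em$labels)
    if (linearly_separable(em$coords, grp)) ok <- ok + 1
  }
  expect_gte(ok, 4)
})
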