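test_that("SRVF is unit norm, translation- and scale-invariant", {
  circ <- circle_curve(256)
  q <- to_srvf(circ, 128)
  expect_equal(srvf_inner(q, q), 1, tolerance = 1e-10)

  shifted <- outline_curve(sweep(5 * circ$points, 2, c(100, -3), "+"), "c2")
  q2 <- to_srvf(shifted, 128)
  expect_lt(max(abs(q$q - q2$q)), 1e-8)

  # constant-speed straight segment gives a constant vector field
  seg <- outline_curve(cbind(seq(0, 1, length.out = 32), 0), "seg",
                       closed = FALSE)
  qs <- to_srvf(seg, 32)
  expect_lt(max(abs(sweep(qs$q, 2, qs$q[1, ]))), 1e-10)

  expect_error(to_srvf(circ, 3), "m >= 4")
})

test_that("integrating q back recovers the shape up to translation/scale", {
  # smooth closed fixture (an ellipse with a gentle radial bump)
  th <- seq(0, 2 * pi, length.out = 257)[-257]
  r <- 1 + 0.1 * cos(2 * th)
  cv <- outline_curve(cbind(r * cos(th), 1.6 * r * sin(th)), "smooth")
  m <- 128
  q <- to_srvf(cv, m)
  rec <- srvf_to_curve(q)
  # compare normalized shapes (center, unit RMS size)
  norm_shape <- function(p) {
    p <- scale(p, scale = FALSE)
    p / sqrt(mean(rowSums(p^2)))
  }
  a <- norm_shape(resample_curve(cv, m)$points)
  b <- norm_shape(rec$points)
  expect_lt(max(sqrt(rowSums((a - b)^2))), 1e-3)
})

test_that("optimal rotation solves the Procrustes problem over SO(2)", {
  circ <- circle_curve(200)
  tear <- gen_outlines(noise_sd = 0.05, jitter = FALSE, seed = 2,
                       groups = data.frame(label = "t", ratio = 2.2,
                                           pointedness = 2,
                                           count = 1))$shapes[[1]]
  q1 <- to_srvf(tear, 64)

  # identical input: identity rotation
  O <- optimal_rotation(q1, q1)
  expect_equal(O, diag(2), tolerance = 1e-8)

  # a 90-degree rotated copy is undone exactly
  R90 <- matrix(c(0, 1, -1, 0), 2)
  q90 <- apply_rotation(q1, R90)
  Ob <- optimal_rotation(q1, q90)
  aligned <- apply_rotation(q90, Ob)
  expect_lt(max(abs(aligned$q - q1$q)), 1e-8)

  # random pair: closed form beats a dense 720-angle grid
  q2 <- to_srvf(circle_curve(200), 64)
  Oc <- optimal_rotation(q1, q2)
  v_closed <- srvf_inner(q1, apply_rotation(q2, Oc))
  angles <- seq(0, 2 * pi, length.out = 721)[-721]
  v_grid <- max(vapply(angles, function(a) {
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
    srvf_inner(q1, apply_rotation(q2, R))
  }, numeric(1)))
  expect_gte(v_closed, v_grid - 1e-9)
  expect_true(abs(det(Oc) - 1) < 1e-10)
})

test_that("DP reparameterization is optimal over the lattice and recovers warps", {
  set.seed(31)
  # identical inputs: identity warp is returned (diagonal tie-break)
  tear <- gen_outlines(noise_sd = 0.05, jitter = FALSE, seed = 5,
                       groups = data.frame(label = "t", ratio = 2.6,
                                           pointedness = 2,
                                           count = 1))$shapes[[1]]
  q <- to_srvf(tear, 32)
  rp <- optimal_reparam(q, q)
  expect_lt(max(abs(rp$gamma - seq(0, 1, length.out = 32))), 1e-9)

  # m = 16 random pairs: DP equals memoized max over all lattice paths
  for (i in 1:5) {
    s1 <- gen_outlines(noise_sd = 0.1, jitter = FALSE, seed = 100 + i,
                       groups = data.frame(label = "a", ratio = 2,
                                           pointedness = 2,
                                           count = 1))$shapes[[1]]
    s2 <- gen_outlines(noise_sd = 0.1, jitter = FALSE, seed = 200 + i,
                       groups = data.frame(label = "b", ratio = 3,
                                           pointedness = 2,
                                           count = 1))$shapes[[1]]
    qa <- to_srvf(s1, 16); qb <- to_srvf(s2, 16)
    rp <- optimal_reparam(qa, qb)
    expect_equal(rp$value, oracle_dp_value(qa, qb), tolerance = 1e-9)
  }

  # tiny grid: memoized recursion agrees with exhaustive path enumeration
  qa6 <- to_srvf(tear, 8)
  qb6 <- to_srvf(circle_curve(64), 8)
  expect_equal(oracle_dp_value(qa6, qb6),
               oracle_dp_value_exhaustive(qa6, qb6), tolerance = 1e-12)

  # synthetic warp recovery: warping q1 by a known smooth gamma and
  # matching back recovers the inverse warp within 2/m in sup norm
  m <- 64
  q1 <- to_srvf(tear, m)
  tt <- seq(0, 1, length.out = m)
  gam <- tt + 0.06 * sin(2 * pi * tt)
  q2 <- apply_reparam(q1, gam)
  rp2 <- optimal_reparam(q1, q2)
  ginv <- approx(gam, tt, xout = tt)$y
  expect_lt(max(abs(rp2$gamma - ginv)), 2 / m)
  expect_true(all(diff(rp2$gamma) >= -1e-12))
  expect_equal(rp2$gamma[c(1, m)], c(0, 1), tolerance = 1e-9)
})

test_that("elastic distance is a symmetric pseudo-metric with the stated invariances", {
  g <- gen_outlines(noise_sd = 0.02, jitter = FALSE, seed = 10,
                    groups = data.frame(label = c("a", "b"),
                                        ratio = c(2.0, 3.2),
                                        pointedness = 2,
                                        count = c(2, 2)))
  A <- g$shapes[[1]]; B <- g$shapes[[3]]
  expect_lt(elastic_distance(A, A, m = 64), 1e-8)
  d_ab <- elastic_distance(A, B, m = 64)
  d_ba <- elastic_distance(B, A, m = 64)
  expect_lt(abs(d_ab - d_ba), 1e-6)
  expect_gte(d_ab, 0); expect_lte(d_ab, pi)

  # invariance: rotated + scaled + translated + re-seeded copy
  pts <- A$points
  R <- matrix(c(cos(0.7), sin(0.7), -sin(0.7), cos(0.7)), 2)
  sh <- 41
  moved <- sweep(2.5 * pts[c((sh + 1):nrow(pts), 1:sh), ] %*% t(R),
                 2, c(7, -2), "+")
  copy <- outline_curve(moved, "copy")
  expect_lt(elastic_distance(A, copy, m = 128), 1e-3)
})

test_that("circle-to-ellipse distance matches a dense-grid reference", {
  # frozen reference 0.251524 rad, computed once by an exhaustive search
  # over all 128 integer seeds x a dense rotation grid x DP
  circ <- circle_curve(512)
  ell <- ellipse_curve(1, 2, 512)
  expect_equal(elastic_distance(circ, ell, m = 128), 0.251524,
               tolerance = 1e-3)
})

test_that("pairwise distances form a valid matrix consistent with single calls", {
  g <- gen_outlines(noise_sd = 0.03, jitter = TRUE, seed = 21, m_points = 64,
                    groups = data.frame(label = c("a", "b"),
                                        ratio = c(2.0, 3.0),
                                        pointedness = 2,
                                        count = c(2, 1)))
  D <- pairwise_distances(g$shapes, m = 48)
  expect_s3_class(D, "shape_dist")
  expect_equal(D$d, t(D$d))
  expect_equal(diag(D$d), setNames(rep(0, 3), D$labels))
  d12 <- elastic_distance(g$shapes[[1]], g$shapes[[2]], m = 48)
  expect_equal(unname(D$d[1, 2]), d12, tolerance = 1e-9)

  # triple duplicate labels rejected
  dup <- g$shapes
  dup[[2]]$label <- dup[[1]]$label
  expect_error(pairwise_distances(dup, m = 48), "duplicate")

  # three copies of one shape: zero matrix
  copies <- list(g$shapes[[1]], g$shapes[[1]], g$shapes[[1]])
  copies[[2]]$label <- "c2"; copies[[3]]$label <- "c3"
  D0 <- pairwise_distances(copies, m = 48)
  expect_lt(max(D0$d), 1e-8)

  # CSV round trip
  f <- tempfile(fileext = ".csv")
  write_distmat_csv(D, f)
  back <- read_distmat_csv(f)
  expect_equal(back$d, D$d, tolerance = 1e-12)
  unlink(f)
})
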