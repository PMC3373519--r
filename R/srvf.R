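#' Square-root velocity representation of a curve
#'
#' Maps a curve \eqn{\beta(t)} to \eqn{q(t) = \dot\beta(t)/\sqrt{\|\dot\beta(t)\|}}
#' on a uniform parameter grid over \eqn{[0,1]}, then rescales to unit
#' L2 norm.  The representation is exactly invariant to translation and
#' (after normalization) to uniform scaling, so each shape becomes a
#' point on the unit pre-shape sphere where geodesic distance is the
#' arccosine of the L2 inner product.
#'
#' @param curve an [outline_curve()].
#' @param m number of grid samples; the curve is arc-length resampled to
#'   `m` points first (`m >= 4`).
#' @return An object of class `srvf_curve`: list with `q` (m x 2 matrix),
#'   `grid`, quadrature weights `w`, `closed`, `label`.
#' @export
to_srvf <- function(curve, m = 128L) {
  stopifnot(inherits(curve, "outline_curve"))
  m <- as.integer(m)
  if (m < 4L) stop("SRVF grid needs m >= 4", call. = FALSE)
  rc <- resample_curve(curve, m)
  .srvf_from_points(rc$points, rc$closed, curve$label)
}

# SRVF from points assumed already uniformly spaced by arc length
# (avoids re-resampling, which moves samples at high-curvature corners)
.srvf_from_points <- function(pts, closed, label) {
  m <- nrow(pts)
  if (closed) {
    dt <- 1 / m
    up <- rbind(pts[-1, ], pts[1, ])
    dn <- rbind(pts[m, ], pts[-m, ])
    v <- (up - dn) / (2 * dt)
    grid <- (seq_len(m) - 1) / m
    w <- rep(1 / m, m)
  } else {
    dt <- 1 / (m - 1)
    v <- rbind(pts[2, ] - pts[1, ],
               (pts[-(1:2), , drop = FALSE] - pts[1:(m - 2), , drop = FALSE]) / 2,
               pts[m, ] - pts[m - 1, ]) / dt
    grid <- seq(0, 1, length.out = m)
    w <- c(0.5, rep(1, m - 2), 0.5) * dt
  }
  speed <- sqrt(rowSums(v^2))
  if (all(speed < 1e-14))
    stop("all-zero derivative: cannot form SRVF", call. = FALSE)
  q <- v / sqrt(pmax(speed, 1e-14))
  nrm <- sqrt(sum(w * rowSums(q^2)))
  q <- q / nrm
  structure(list(q = q, grid = grid, w = w, closed = closed,
                 label = label),
            class = "srvf_curve")
}

#' @export
print.srvf_curve <- function(x, ...) {
  cat(sprintf("<srvf_curve '%s': m = %d, %s, |q| = %.8f>\n", x$label,
              nrow(x$q), if (x$closed) "closed" else "open",
              sqrt(srvf_inner(x, x))))
  invisible(x)
}

#' L2 inner product of two SRVFs on a common grid
#'
#' @param q1,q2 `srvf_curve` objects with equal grid size.
#' @return Numeric scalar in `[-1, 1]` for unit-norm inputs.
#' @export
srvf_inner <- function(q1, q2) {
  if (nrow(q1$q) != nrow(q2$q))
    stop("SRVFs must share a grid size", call. = FALSE)
  sum(q1$w * rowSums(q1$q * q2$q))
}

#' Integrate an SRVF back to a curve
#'
#' Reconstructs \eqn{\beta(t) = \int q(s)\|q(s)\| ds} by cumulative
#' summation; the result equals the original shape up to translation and
#' scale.  Used as a numerical round-trip check of [to_srvf()].
#'
#' @param q an `srvf_curve`.
#' @return An [outline_curve()] starting at the origin with unit "energy".
#' @export
srvf_to_curve <- function(q) {
  v <- q$q * sqrt(rowSums(q$q^2))
  m <- nrow(v)
  dt <- if (q$closed) 1 / m else 1 / (m - 1)
  # trapezoidal cumulative integration (second-order, matching the
  # central-difference derivative used by to_srvf)
  mid <- (v[-m, , drop = FALSE] + v[-1, , drop = FALSE]) / 2 * dt
  pts <- rbind(c(0, 0), apply(mid, 2, cumsum))
  outline_curve(pts, label = q$label, closed = FALSE)
}

#' Optimal rotation aligning one SRVF to another
#'
#' Closed-form Procrustes solution over SO(2) (or O(2) when reflections
#' are allowed) maximizing the L2 inner product.
#'
#' @param q1,q2 `srvf_curve` objects with equal grid size.
#' @param allow_reflection logical; permit determinant -1 (off by
#'   default: anatomical sidedness is meaningful, mirror explicitly).
#' @return 2 x 2 orthogonal matrix `O`; apply with `q2$q %*% t(O)`.
#' @export
optimal_rotation <- function(q1, q2, allow_reflection = FALSE) {
  if (nrow(q1$q) != nrow(q2$q))
    stop("SRVFs must share a grid size", call. = FALSE)
  # f(O) = sum_i w_i q1_i . (O q2_i) = tr(O %*% M) with M = sum w q2 q1^T
  M <- t(q2$q * q1$w) %*% q1$q
  sv <- svd(M)
  O <- sv$v %*% t(sv$u)
  if (!allow_reflection && det(O) < 0) {
    D <- diag(c(1, -1))
    O <- sv$v %*% D %*% t(sv$u)
  }
  O
}

.rot_value <- function(q1, q2, allow_reflection = FALSE) {
  M <- t(q2$q * q1$w) %*% q1$q
  sv <- svd(M)
  if (allow_reflection) return(sum(sv$d))
  if (det(sv$v %*% t(sv$u)) < 0) sv$d[1] - sv$d[2] else sum(sv$d)
}

#' Apply a rotation to an SRVF
#' @param q an `srvf_curve`.
#' @param O 2 x 2 orthogonal matrix from [optimal_rotation()].
#' @return Rotated `srvf_curve`.
#' @export
apply_rotation <- function(q, O) {
  q$q <- q$q %*% t(O)
  q
}

.shift_srvf <- function(q, s) {
  # cyclic seed shift for closed curves: rotate sample rows; fractional
  # shifts interpolate circularly (sub-sample starting points matter at
  # high-curvature regions)
  m <- nrow(q$q)
  s <- s %% m
  if (s == 0) return(q)
  if (abs(s - round(s)) < 1e-12) {
    s <- round(s) %% m
    if (s == 0) return(q)
    idx <- c((s + 1):m, 1:s)
    q$q <- q$q[idx, , drop = FALSE]
    return(q)
  }
  i0 <- floor(s)
  fr <- s - i0
  idx1 <- ((seq_len(m) - 1 + i0) %% m) + 1
  idx2 <- (idx1 %% m) + 1
  qn <- (1 - fr) * q$q[idx1, , drop = FALSE] + fr * q$q[idx2, , drop = FALSE]
  nrm <- sqrt(sum(q$w * rowSums(qn^2)))
  q$q <- qn / max(nrm, 1e-12)
  q
}

#' Warp an SRVF by a reparameterization
#'
#' Applies the group action \eqn{(q, \gamma) \mapsto (q\circ\gamma)\sqrt{\dot\gamma}}
#' with linear interpolation of `q` and finite-difference \eqn{\dot\gamma},
#' then renormalizes to unit L2 norm.
#'
#' @param q an `srvf_curve`.
#' @param gamma non-decreasing vector of length `m` with `gamma[1] = 0`,
#'   `gamma[m] = 1`, or `NULL` for the identity.
#' @return Warped `srvf_curve`.
#' @export
apply_reparam <- function(q, gamma) {
  if (is.null(gamma)) return(q)
  m <- nrow(q$q)
  if (length(gamma) != m)
    stop("gamma must match the SRVF grid size", call. = FALSE)
  if (any(diff(gamma) < -1e-12) || abs(gamma[1]) > 1e-9 ||
      abs(gamma[m] - 1) > 1e-9)
    stop("gamma must be monotone with fixed endpoints", call. = FALSE)
  pos <- gamma * (m - 1) + 1
  dg <- c(gamma[2] - gamma[1],
          (gamma[-(1:2)] - gamma[1:(m - 2)]) / 2,
          gamma[m] - gamma[m - 1]) * (m - 1)
  dg <- pmax(dg, 0)
  xi <- seq_len(m)
  qx <- approx(xi, q$q[, 1], xout = pos, rule = 2)$y
  qy <- approx(xi, q$q[, 2], xout = pos, rule = 2)$y
  qn <- cbind(qx, qy) * sqrt(dg)
  nrm <- sqrt(sum(q$w * rowSums(qn^2)))
  if (nrm < 1e-12)
    stop("degenerate warp collapsed the SRVF", call. = FALSE)
  q$q <- qn / nrm
  q
}

#' Optimal reparameterization between two SRVFs
#'
#' Dynamic programming over monotone lattice paths on the m x m grid
#' with local slopes restricted to \eqn{[1/4, 4]}, maximizing
#' \eqn{\langle q_1, (q_2\circ\gamma)\sqrt{\dot\gamma}\rangle}.  Ties are
#' broken toward the diagonal so identical inputs return the identity.
#'
#' @param q1,q2 `srvf_curve` objects with equal grid size `m`
#'   (`m <= dp_limit`).
#' @param dp_limit largest grid size accepted (guards the m^2 table).
#' @return List with `gamma` (length-m warp) and `value` (DP objective).
#' @export
optimal_reparam <- function(q1, q2, dp_limit = 1024L) {
  m <- nrow(q1$q)
  if (nrow(q2$q) != m)
    stop("SRVFs must share a grid size", call. = FALSE)
  if (m > dp_limit)
    stop("DP grid too large; reduce m or raise dp_limit", call. = FALSE)
  .dp_reparam_cpp(q1$q, q2$q)
}

# sample m uniform arc-length points on a closed curve, starting at a
# continuous offset of `c_samples` output sample spacings; interpolates
# the raw polyline directly so no double-resampling error accrues
.reseed_closed <- function(curve, c_samples, m) {
  pts <- curve$points
  ptsw <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(ptsw)^2))
  s <- c(0, cumsum(seg))
  keep <- c(TRUE, diff(s) > 0)
  s <- s[keep]; ptsw <- ptsw[keep, , drop = FALSE]
  L <- s[length(s)]
  u <- ((c_samples %% m) / m * L + (seq_len(m) - 1) / m * L) %% L
  curve$points <- cbind(approx(s, ptsw[, 1], xout = u)$y,
                        approx(s, ptsw[, 2], xout = u)$y)
  curve
}

# SRVF of a curve re-seeded at a continuous offset, built directly from
# the uniformly re-seeded samples (a second arc-length resampling would
# move samples at corners and spoil sub-sample alignment)
.srvf_reseed <- function(curve, c_samples, m) {
  rs <- .reseed_closed(curve, c_samples, m)
  .srvf_from_points(rs$points, TRUE, curve$label)
}

.elastic_one_way <- function(qa, qb, rcb, closed_seed_search,
                             allow_reflection, tol, max_rounds) {
  m <- nrow(qa$q)
  shifts <- if (closed_seed_search) 0:(m - 1) else 0L
  rotmat <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  try_dp <- function(qsr) {
    # DP warp, kept only when it improves the evaluated inner product
    # (the DP quadrature is an approximation of the evaluation metric)
    rp <- optimal_reparam(qa, qsr)
    v_id <- srvf_inner(qa, qsr)
    qw <- apply_reparam(qsr, rp$gamma)
    v_g <- srvf_inner(qa, qw)
    if (v_g >= v_id) list(gamma = rp$gamma, val = v_g)
    else list(gamma = NULL, val = v_id)
  }
  align_at_shift <- function(qs, angle_search) {
    O0 <- optimal_rotation(qa, qs, allow_reflection)
    best <- try_dp(apply_rotation(qs, O0))
    best$angle <- atan2(O0[2, 1], O0[1, 1])
    if (angle_search) {
      # rotation basins differ once warping enters; scan a coarse angle
      # grid through the DP and polish the winner continuously
      for (a in seq(0, 2 * pi, length.out = 9)[-9]) {
        r <- try_dp(apply_rotation(qs, rotmat(a)))
        if (r$val > best$val) { best <- r; best$angle <- a }
      }
      g <- function(a) try_dp(apply_rotation(qs, rotmat(a)))$val
      op <- stats::optimize(g, best$angle + c(-pi / 8, pi / 8),
                            maximum = TRUE, tol = 1e-3)
      if (op$objective > best$val) {
        best <- try_dp(apply_rotation(qs, rotmat(op$maximum)))
        best$angle <- op$maximum
      }
    }
    best
  }

  # round 1: integer seed scan; when the rotation-only profile is nearly
  # flat (symmetric shapes) spread several seed candidates and search
  # rotation basins through the DP
  vals <- vapply(shifts, function(s)
    .rot_value(qa, .shift_srvf(qb, s), allow_reflection), numeric(1))
  s_best <- shifts[which.max(vals)]
  flat <- length(shifts) > 1L &&
    sum(vals > max(vals) - 1e-3) > length(shifts) / 4
  cand <- s_best
  if (flat)
    cand <- unique(c(s_best,
                     shifts[round(seq(1, length(shifts), length.out = 9))[-9]]))
  best <- list(val = -Inf, gamma = NULL)
  for (sc in cand) {
    r <- align_at_shift(.shift_srvf(qb, sc), angle_search = flat)
    if (r$val > best$val) { best <- r; best$shift <- sc }
  }
  if (length(shifts) > 1L) {
    # sub-sample starting-point refinement in the curve domain before
    # any warping: integer shifts quantize the seam to one sample, which
    # high-curvature outlines convert into spurious distance
    f0 <- function(ss)
      .rot_value(qa, .srvf_reseed(rcb, ss, m),
                 allow_reflection)
    op0 <- stats::optimize(f0, c(best$shift - 1, best$shift + 1),
                           maximum = TRUE, tol = 1e-4)
    if (op0$objective > vals[match(best$shift, shifts)] + 1e-12) {
      r <- align_at_shift(.srvf_reseed(rcb, op0$maximum, m),
                          angle_search = FALSE)
      if (r$val > best$val) { best <- r; best$shift <- op0$maximum }
    }
  }
  gamma <- best$gamma

  # later rounds: alternate seed shift -> rotation -> reparameterization,
  # accepting a round only when the evaluated inner product improves
  if (max_rounds > 1L) {
    for (round in 2:max_rounds) {
      qbg <- apply_reparam(qb, gamma)
      vals <- vapply(shifts, function(s)
        .rot_value(qa, .shift_srvf(qbg, s), allow_reflection), numeric(1))
      s <- shifts[which.max(vals)]
      qs <- .shift_srvf(qb, s)
      if (length(shifts) > 1L) {
        # refine the starting point to sub-sample resolution in the
        # curve domain (interpolating the SRVF itself is inaccurate at
        # corners); integer shifts stay exact row rotations
        f <- function(ss)
          .rot_value(qa, apply_reparam(.srvf_reseed(rcb, ss, m),
                                       gamma), allow_reflection)
        op <- stats::optimize(f, c(s - 1, s + 1), maximum = TRUE,
                              tol = 1e-4)
        if (op$objective > max(vals) + 1e-12)
          qs <- .srvf_reseed(rcb, op$maximum, m)
      }
      O <- optimal_rotation(qa, apply_reparam(qs, gamma), allow_reflection)
      r <- try_dp(apply_rotation(qs, O))
      if (!is.finite(r$val))
        stop("non-finite value in elastic alignment", call. = FALSE)
      if (r$val > best$val + tol) {
        best <- r
        gamma <- r$gamma
      } else {
        break
      }
    }
  }
  # arccos amplifies a 1-ulp inner-product rounding error near 1 into
  # ~2e-8 of distance; snap within machine noise of a perfect match
  v <- best$val
  if (1 - v < 5e-16) v <- 1
  acos(max(-1, min(1, v)))
}

#' Elastic geodesic shape distance between two outlines
#'
#' Geodesic distance on the unit pre-shape sphere,
#' \eqn{d = \arccos\langle q_1, O\,(q_2\circ\gamma)\sqrt{\dot\gamma}\rangle},
#' minimized by alternating optimization over cyclic seed shifts (closed
#' curves), rotations, and reparameterizations, iterated to convergence
#' (improvement `< tol`) or `max_rounds`.  The distance is invariant to
#' translation, scale, rotation, starting point and reparameterization
#' of either input.  Both argument orders are optimized and the smaller
#' value returned, which makes the result symmetric.
#'
#' @param a,b [outline_curve()] objects.
#' @param m common SRVF grid size (`>= 16`; default 128).
#' @param closed_seed_search search all m cyclic starting points; default
#'   `TRUE` when both curves are closed.
#' @param allow_reflection permit mirror alignment (default `FALSE`).
#' @param tol convergence tolerance on the aligned inner product.
#' @param max_rounds maximum alternation rounds.
#' @return Distance in radians, in `[0, pi]`.
#' @export
elastic_distance <- function(a, b, m = 128L, closed_seed_search = NULL,
                             allow_reflection = FALSE, tol = 1e-8,
                             max_rounds = 20L) {
  stopifnot(inherits(a, "outline_curve"), inherits(b, "outline_curve"))
  m <- as.integer(m)
  if (m < 16L) stop("elastic_distance needs m >= 16", call. = FALSE)
  if (is.null(closed_seed_search))
    closed_seed_search <- a$closed && b$closed
  qa <- to_srvf(a, m)
  qb <- to_srvf(b, m)
  d1 <- .elastic_one_way(qa, qb, b, closed_seed_search, allow_reflection,
                         tol, max_rounds)
  d2 <- .elastic_one_way(qb, qa, a, closed_seed_search, allow_reflection,
                         tol, max_rounds)
  min(d1, d2)
}

#' Pairwise elastic distance matrix
#'
#' Computes [elastic_distance()] once per unordered pair and mirrors it
#' into a symmetric matrix with zero diagonal.
#'
#' @param shapes list of [outline_curve()] with unique labels.
#' @param m,closed_seed_search,allow_reflection passed to
#'   [elastic_distance()].
#' @return An object of class `shape_dist`: list with `labels` and the
#'   k x k matrix `d` (radians).
#' @export
pairwise_distances <- function(shapes, m = 128L, closed_seed_search = NULL,
                               allow_reflection = FALSE) {
  if (length(shapes) < 2L) stop("need at least two shapes", call. = FALSE)
  labels <- vapply(shapes, function(s) s$label, character(1))
  if (anyDuplicated(labels))
    stop("duplicate shape labels", call. = FALSE)
  k <- length(shapes)
  D <- matrix(0, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      D[i, j] <- D[j, i] <- elastic_distance(
        shapes[[i]], shapes[[j]], m = m,
        closed_seed_search = closed_seed_search,
        allow_reflection = allow_reflection)
    }
  }
  shape_dist(D, labels)
}

#' Construct/validate a shape distance matrix
#'
#' @param d k x k numeric matrix of geodesic distances (radians).
#' @param labels k identifiers (defaults to `rownames(d)`).
#' @return `shape_dist` object; the matrix is symmetrized after the
#'   symmetry check and the diagonal zeroed.
#' @export
shape_dist <- function(d, labels = rownames(d)) {
  d <- as.matrix(d)
  k <- nrow(d)
  if (is.null(labels)) labels <- paste0("S", seq_len(k))
  labels <- unname(as.character(labels))
  stopifnot(ncol(d) == k, length(labels) == k)
  if (max(abs(d - t(d))) > 1e-6)
    stop("distance matrix is not symmetric (tolerance 1e-6)", call. = FALSE)
  if (max(abs(diag(d))) > 1e-8)
    stop("distance matrix diagonal is not zero (tolerance 1e-8)", call. = FALSE)
  if (any(d < -1e-12) || any(d > pi + 1e-9))
    stop("distances must lie in [0, pi]", call. = FALSE)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d[d < 0] <- 0
  dimnames(d) <- list(labels, labels)
  structure(list(labels = as.character(labels), d = d), class = "shape_dist")
}

#' @export
print.shape_dist <- function(x, ...) {
  cat(sprintf("<shape_dist: %d shapes, distances in [%.4g, %.4g] rad>\n",
              length(x$labels), min(x$d[upper.tri(x$d)]),
              max(x$d[upper.tri(x$d)])))
  invisible(x)
}

#' Write a shape distance matrix to CSV (labels as first row/column)
#' @param D a [shape_dist()] object.
#' @param path output file.
#' @return Invisibly, the path.
#' @export
write_distmat_csv <- function(D, path) {
  stopifnot(inherits(D, "shape_dist"))
  write.csv(D$d, path, row.names = TRUE)
  invisible(path)
}

#' Read a shape distance matrix written by [write_distmat_csv()]
#' @param path CSV file.
#' @return A [shape_dist()] object.
#' @export
read_distmat_csv <- function(path) {
  m <- as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
  shape_dist(m, rownames(m))
}
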