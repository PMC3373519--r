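#' Construct a 2D outline curve
#'
#' An `outline_curve` stores an ordered sequence of `(x, y)` vertices
#' describing an anatomical boundary, e.g. the lateral outline of an
#' external naris.  Closed curves implicitly connect the final vertex
#' back to the first; the last vertex must not repeat the first.
#'
#' @param points numeric matrix (or two-column data frame) of vertices,
#'   one row per point, in digitization order.
#' @param label character identifier for the shape.
#' @param closed logical; `TRUE` for a closed boundary.
#' @return An object of class `outline_curve` with elements `label`,
#'   `points` (n x 2 matrix) and `closed`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 65)[-65]
#' circ <- outline_curve(cbind(cos(th), sin(th)), "circle")
#' aspect_ratio(circ)
#' @export
outline_curve <- function(points, label = "shape", closed = TRUE) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 2L)
    stop("outline points must have two columns (x, y)", call. = FALSE)
  if (nrow(points) < (if (isTRUE(closed)) 4L else 2L))
    stop("an outline needs at least 4 points (2 for an open polyline)",
         call. = FALSE)
  if (any(!is.finite(points)))
    stop("outline coordinates must be finite", call. = FALSE)
  if (curve_arc_length_raw(points, closed) <= 0)
    stop("degenerate outline: total arc length is zero", call. = FALSE)
  # drop an explicit duplicate of the first vertex on closed curves
  n <- nrow(points)
  if (closed && all(abs(points[n, ] - points[1, ]) < 1e-12))
    points <- points[-n, , drop = FALSE]
  structure(list(label = as.character(label), points = points,
                 closed = isTRUE(closed)),
            class = "outline_curve")
}

#' @export
print.outline_curve <- function(x, ...) {
  cat(sprintf("<outline_curve '%s': %d points, %s, arc length %.4g>\n",
              x$label, nrow(x$points), if (x$closed) "closed" else "open",
              curve_arc_length(x)))
  invisible(x)
}

curve_arc_length_raw <- function(pts, closed) {
  seg <- diff(pts)
  len <- sum(sqrt(rowSums(seg^2)))
  if (closed)
    len <- len + sqrt(sum((pts[1, ] - pts[nrow(pts), ])^2))
  len
}

#' Total arc length of an outline curve
#'
#' @param curve an [outline_curve()].
#' @return Numeric scalar, including the closing segment for closed curves.
#' @export
curve_arc_length <- function(curve) {
  stopifnot(inherits(curve, "outline_curve"))
  curve_arc_length_raw(curve$points, curve$closed)
}

#' Resample a curve uniformly by arc length
#'
#' Places exactly `m` vertices at uniform spacing in cumulative arc
#' length along the polyline.  Open curves keep both endpoints; closed
#' curves keep the starting vertex and distribute points over the full
#' perimeter (spacing `L/m`).
#'
#' @param curve an [outline_curve()].
#' @param m number of output points (`>= 2`).
#' @return A resampled `outline_curve`.
#' @export
resample_curve <- function(curve, m) {
  stopifnot(inherits(curve, "outline_curve"))
  m <- as.integer(m)
  if (m < 2L) stop("m must be at least 2", call. = FALSE)
  pts <- curve$points
  if (curve$closed) pts <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  if (L <= 0) stop("degenerate outline: total arc length is zero", call. = FALSE)
  # collapse zero-length segments so approx() has unique abscissae
  keep <- c(TRUE, diff(s) > 0)
  s <- s[keep]; pts <- pts[keep, , drop = FALSE]
  u <- if (curve$closed) seq(0, L, length.out = m + 1L)[seq_len(m)]
       else seq(0, L, length.out = m)
  out <- cbind(approx(s, pts[, 1], xout = u)$y,
               approx(s, pts[, 2], xout = u)$y)
  outline_curve(out, label = curve$label, closed = curve$closed)
}

#' Length/width aspect ratio of an outline
#'
#' The ratio of the outline's extent along its major principal axis to
#' the extent along the perpendicular axis, always `>= 1`.  This is the
#' length/width measure used to bin narial outlines into diagnostic
#' states.  Extents are taken over the supplied vertices, so curves
#' should be sampled reasonably uniformly (see [resample_curve()]).
#'
#' @param curve a closed [outline_curve()].
#' @return Numeric ratio `>= 1`.
#' @export
aspect_ratio <- function(curve) {
  stopifnot(inherits(curve, "outline_curve"))
  pts <- scale(curve$points, scale = FALSE)
  pc <- prcomp(pts, center = FALSE)
  ext <- apply(pc$x, 2, function(v) diff(range(v)))
  if (min(ext) <= max(ext) * 1e-9)
    stop("degenerate (collinear) outline: width is zero", call. = FALSE)
  max(ext) / min(ext)
}

#' Diagnostic state of a narial length/width ratio
#'
#' Bins a length/width ratio at the cut points 1.85 and 2.85 used to
#' code the external-naris character.  The central interval is closed:
#' a ratio exactly at a cut point falls inside `[1.85, 2.85]`.
#'
#' @param ratio positive numeric (vectorized).
#' @return Factor with levels `below_1.85`, `between_1.85_and_2.85`,
#'   `above_2.85`.
#' @examples
#' naris_ratio_state(c(1.2, 2.4, 3.1))
#' @export
naris_ratio_state <- function(ratio) {
  if (any(!is.finite(ratio)) || any(ratio <= 0))
    stop("ratio must be positive and finite", call. = FALSE)
  states <- ifelse(ratio < 1.85, "below_1.85",
                   ifelse(ratio > 2.85, "above_2.85",
                          "between_1.85_and_2.85"))
  factor(states, levels = c("below_1.85", "between_1.85_and_2.85",
                            "above_2.85"))
}

#' Read outlines from long-format CSV
#'
#' Expects columns `shape_id`, `point_index`, `x`, `y` (one row per
#' vertex, `point_index` strictly increasing within each shape) and an
#' optional logical `closed` column (default `TRUE`).
#'
#' @param path CSV file path.
#' @return Named list of [outline_curve()] objects.
#' @export
read_outlines_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("shape_id", "point_index", "x", "y")
  if (!all(need %in% names(df)))
    stop("outline CSV needs columns shape_id, point_index, x, y",
         call. = FALSE)
  out <- lapply(split(df, df$shape_id), function(g) {
    g <- g[order(g$point_index), ]
    if (any(diff(g$point_index) <= 0))
      stop("point_index must be strictly increasing within a shape",
           call. = FALSE)
    closed <- if ("closed" %in% names(g)) isTRUE(as.logical(g$closed[1])) else TRUE
    outline_curve(cbind(g$x, g$y), label = g$shape_id[1], closed = closed)
  })
  out[unique(df$shape_id)]
}

#' Write outlines to long-format CSV
#'
#' @param shapes list of [outline_curve()] objects.
#' @param path output CSV file path.
#' @return Invisibly, the path.
#' @export
write_outlines_csv <- function(shapes, path) {
  rows <- lapply(shapes, function(sh) {
    data.frame(shape_id = sh$label,
               point_index = seq_len(nrow(sh$points)),
               x = sh$points[, 1], y = sh$points[, 2],
               closed = sh$closed)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
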