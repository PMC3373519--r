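#' Kruskal stress-1 of a configuration against dissimilarities
#'
#' Computes \eqn{\sqrt{\sum (d_{ij} - \hat d_{ij})^2 / \sum d_{ij}^2}}
#' where \eqn{d_{ij}} are configuration distances and \eqn{\hat d_{ij}}
#' are disparities fitted by isotonic (monotone) regression of the
#' configuration distances on the ranked input dissimilarities.  A
#' configuration with zero spread is assigned stress 1 (maximal-misfit
#' convention, avoiding division by zero).
#'
#' @param D a [shape_dist()] object or symmetric dissimilarity matrix.
#' @param coords k x p configuration matrix.
#' @return Stress-1 value in `[0, 1]`.
#' @export
nmds_stress <- function(D, coords) {
  delta <- .as_dissim(D)
  coords <- as.matrix(coords)
  if (nrow(coords) != attr(delta, "k"))
    stop("coords and dissimilarity matrix sizes differ", call. = FALSE)
  d <- as.vector(dist(coords))
  ss <- sum(d^2)
  if (ss < 1e-300) return(1.0)
  dhat <- .isotonic_disparities(d, delta)
  sqrt(sum((d - dhat)^2) / ss)
}

.as_dissim <- function(D) {
  if (inherits(D, "shape_dist")) D <- D$d
  D <- as.matrix(D)
  k <- nrow(D)
  if (ncol(D) != k || max(abs(D - t(D))) > 1e-6)
    stop("dissimilarity matrix must be square and symmetric", call. = FALSE)
  if (any(D < -1e-12))
    stop("dissimilarities must be non-negative", call. = FALSE)
  v <- D[lower.tri(D)]
  attr(v, "k") <- k
  v
}

.isotonic_disparities <- function(d, delta) {
  # primary approach to ties: order by dissimilarity, then by distance
  ord <- order(delta, d)
  fit <- isoreg(d[ord])$yf
  out <- numeric(length(d))
  out[ord] <- fit
  out
}

.guttman_update <- function(X, d, dhat) {
  k <- nrow(X)
  Dm <- matrix(0, k, k)
  Dm[lower.tri(Dm)] <- d
  Dm <- Dm + t(Dm)
  Dh <- matrix(0, k, k)
  Dh[lower.tri(Dh)] <- dhat
  Dh <- Dh + t(Dh)
  B <- ifelse(Dm > 1e-12, -Dh / pmax(Dm, 1e-12), 0)
  diag(B) <- 0
  diag(B) <- -rowSums(B)   # row sums of B are zero
  (B %*% X) / k
}

#' Non-metric multidimensional scaling of a shape distance matrix
#'
#' Embeds a dissimilarity matrix into `p` Euclidean dimensions by
#' minimizing Kruskal stress-1 with isotonically fitted disparities.
#' The first restart is initialized from classical (metric) MDS, the
#' remaining restarts from seeded Gaussian configurations; within each
#' restart the update is a majorization (Guttman) step with step-halving
#' so the stress trace is non-increasing.  The best (lowest-stress)
#' restart is returned with centered coordinates.
#'
#' @param D a [shape_dist()] object or symmetric dissimilarity matrix.
#' @param p embedding dimension (default 2, the two plotted ordination
#'   axes).
#' @param restarts number of starts (default 8).
#' @param seed integer seed; a fixed seed gives bit-identical output.
#' @param maxit,tol iteration cap and convergence tolerance on stress.
#' @return An object of class `nmds_embedding`: `labels`, `coords`
#'   (k x p, centroid at the origin), `stress`, `stress_trace` (per
#'   iteration, best restart), `n_restarts_used`, `seed`.
#' @export
fit_nmds <- function(D, p = 2L, restarts = 8L, seed = 1L,
                     maxit = 300L, tol = 1e-10) {
  labels <- if (inherits(D, "shape_dist")) D$labels else rownames(as.matrix(D))
  delta <- .as_dissim(D)
  k <- attr(delta, "k")
  if (is.null(labels)) labels <- paste0("S", seq_len(k))
  p <- as.integer(p)
  if (p < 1L || p > k - 1L) stop("need 1 <= p <= k - 1", call. = FALSE)
  if (restarts < 1L) stop("restarts must be >= 1", call. = FALSE)
  Dm <- matrix(0, k, k)
  Dm[lower.tri(Dm)] <- delta
  Dm <- Dm + t(Dm)

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  inits <- vector("list", restarts)
  cm <- suppressWarnings(cmdscale(Dm, k = p))
  if (ncol(cm) < p) cm <- cbind(cm, matrix(0, k, p - ncol(cm)))
  inits[[1]] <- cm
  if (restarts > 1) {
    sc <- max(delta, 1e-8)
    for (r in 2:restarts)
      inits[[r]] <- matrix(rnorm(k * p, sd = sc), k, p)
  }

  best <- NULL
  for (r in seq_len(restarts)) {
    X <- inits[[r]]
    S <- nmds_stress(Dm, X)
    trace <- S
    for (it in seq_len(maxit)) {
      d <- as.vector(dist(X))
      if (sum(d^2) < 1e-300) break
      dhat <- .isotonic_disparities(d, delta)
      Xn <- .guttman_update(X, d, dhat)
      Sn <- nmds_stress(Dm, Xn)
      tries <- 0
      while (Sn > S && tries < 30) {
        Xn <- (Xn + X) / 2
        Sn <- nmds_stress(Dm, Xn)
        tries <- tries + 1
      }
      if (Sn > S) break
      X <- Xn
      trace <- c(trace, Sn)
      if (S - Sn < tol) { S <- Sn; break }
      S <- Sn
    }
    if (is.null(best) || S < best$stress)
      best <- list(coords = X, stress = S, trace = trace, restart = r)
  }

  coords <- scale(best$coords, scale = FALSE)
  attr(coords, "scaled:center") <- NULL
  dimnames(coords) <- list(labels, paste0("axis", seq_len(p)))
  structure(list(labels = labels, coords = coords, stress = best$stress,
                 stress_trace = best$trace,
                 n_restarts_used = as.integer(restarts),
                 seed = as.integer(seed)),
            class = "nmds_embedding")
}

#' @export
print.nmds_embedding <- function(x, ...) {
  cat(sprintf("<nmds_embedding: %d points in %d dims, stress-1 = %.6g (%d restarts, seed %d)>\n",
              nrow(x$coords), ncol(x$coords), x$stress,
              x$n_restarts_used, x$seed))
  invisible(x)
}

#' Procrustes residual between two configurations
#'
#' Root-mean-square residual after optimally translating, scaling and
#' rotating/reflecting `X` onto `Y`; used to compare an embedding with a
#' known generating configuration.
#'
#' @param X,Y k x p coordinate matrices.
#' @return Non-negative scalar (0 for a perfect match), scaled by the
#'   RMS size of `Y`.
#' @export
procrustes_residual <- function(X, Y) {
  X <- scale(as.matrix(X), scale = FALSE)
  Y <- scale(as.matrix(Y), scale = FALSE)
  sv <- svd(t(Y) %*% X)
  R <- sv$v %*% t(sv$u)
  s <- sum(sv$d) / sum(X^2)
  res <- Y - s * X %*% R
  sqrt(mean(rowSums(res^2))) / sqrt(mean(rowSums(Y^2)))
}

#' Test linear separability of two labeled groups in a configuration
#'
#' Runs a perceptron with margin on centered coordinates (bounded
#' iterations); returns `TRUE` if a separating hyperplane is found.
#'
#' @param coords k x p matrix.
#' @param groups length-k factor/character with exactly two levels.
#' @param max_epochs iteration bound.
#' @return Logical.
#' @export
linearly_separable <- function(coords, groups, max_epochs = 2000L) {
  y <- as.integer(factor(groups))
  if (length(unique(y)) != 2L)
    stop("need exactly two groups", call. = FALSE)
  y <- ifelse(y == 1L, -1, 1)
  X <- cbind(1, scale(as.matrix(coords), scale = FALSE))
  X <- X / max(abs(X))
  w <- numeric(ncol(X))
  for (ep in seq_len(max_epochs)) {
    marg <- y * (X %*% w)
    bad <- which(marg <= 1e-10)
    if (length(bad) == 0) return(TRUE)
    i <- bad[1]
    w <- w + y[i] * X[i, ]
  }
  all(y * (X %*% w) > 0)
}
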