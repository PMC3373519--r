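# Fitch (unordered) and Farris-interval (ordered) parsimony scoring on
# the internal utree representation; the exported interface accepts ape
# "phylo" trees.

# state-set masks per tip, folded bottom-up: intersection if non-empty,
# else union and +weight.  Vectorized across characters.
.fitch_score_utree <- function(ut, M) {
  unord <- which(!M$ordered)
  ordd <- which(M$ordered)
  ord <- .utree_order(ut)
  steps <- 0
  nid <- ut$max_id
  if (length(unord)) {
    masks <- matrix(0L, nid, length(unord))
    first <- rep(TRUE, nid)
    tipmask <- M$mask[, unord, drop = FALSE]
    for (v in ord$post) {
      if (v <= ut$n) {
        mv <- tipmask[v, ]
      } else {
        mv <- NULL
        for (w in ut$adj[[v]]) {
          if (w == ord$parent[v]) next
          cm <- masks[w, ]
          if (is.null(mv)) {
            mv <- cm
          } else {
            inter <- bitwAnd(mv, cm)
            zero <- inter == 0L
            if (any(zero)) {
              steps <- steps + sum(M$weights[unord][zero])
              inter[zero] <- bitwOr(mv, cm)[zero]
            }
            mv <- inter
          }
        }
      }
      masks[v, ] <- mv
    }
  }
  if (length(ordd)) {
    # ordered characters: Farris intervals [lo, hi]; polymorphic and
    # missing entries enter as the interval spanned by their states
    lo <- matrix(0L, nid, length(ordd))
    hi <- matrix(0L, nid, length(ordd))
    tiplo <- tiphi <- matrix(0L, ut$n, length(ordd))
    for (jj in seq_along(ordd)) {
      for (i in seq_len(ut$n)) {
        st <- .mask_states(M$mask[i, ordd[jj]], M$nstates)
        tiplo[i, jj] <- min(st); tiphi[i, jj] <- max(st)
      }
    }
    for (v in ord$post) {
      if (v <= ut$n) {
        lo[v, ] <- tiplo[v, ]; hi[v, ] <- tiphi[v, ]
      } else {
        cl <- ch <- NULL
        for (w in ut$adj[[v]]) {
          if (w == ord$parent[v]) next
          if (is.null(cl)) {
            cl <- lo[w, ]; ch <- hi[w, ]
          } else {
            nl <- pmax(cl, lo[w, ]); nh <- pmin(ch, hi[w, ])
            gap <- nl > nh
            if (any(gap)) {
              steps <- steps + sum(M$weights[ordd][gap] *
                                     (nl[gap] - nh[gap]))
              tmp <- nl[gap]; nl[gap] <- nh[gap]; nh[gap] <- tmp
            }
            cl <- nl; ch <- nh
          }
        }
        lo[v, ] <- cl; hi[v, ] <- ch
      }
    }
  }
  steps
}

#' Parsimony length of a tree on a character matrix
#'
#' Fitch bottom-up scoring (set intersection if non-empty, else union
#' and one step) summed over characters times their weights; ordered
#' characters are scored by the interval (additive) variant.  The length
#' is a property of the unrooted topology: any rooting of the same tree
#' gives the same value.
#'
#' @param tree a `phylo` object whose tips match the matrix taxa.
#' @param M a [character_matrix()].
#' @return Numeric length (an integer when all weights are integral).
#' @examples
#' M <- character_matrix(matrix(c("0","0","1","1"), 4, 1,
#'                       dimnames = list(c("A","B","C","D"), NULL)))
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' fitch_length(tr, M)
#' @export
fitch_length <- function(tree, M) {
  stopifnot(inherits(M, "char_matrix"))
  if (!setequal(tree$tip.label, M$taxa))
    stop("tree tips and matrix taxa differ", call. = FALSE)
  ut <- utree_from_phylo(tree, taxa = M$taxa)
  .fitch_score_utree(ut, M)
}

.resolve_polymorphic <- function(M) {
  # resolve each polymorphic entry to its contained state that is most
  # frequent over all scored (non-missing) entries; ties -> lowest state
  full <- bitwShiftL(1L, M$nstates) - 1L
  res <- matrix(NA_integer_, nrow(M$mask), ncol(M$mask))
  for (j in seq_len(ncol(M$mask))) {
    col <- M$mask[, j]
    freq <- numeric(M$nstates)
    for (i in seq_along(col)) {
      if (col[i] == full) next
      st <- .mask_states(col[i], M$nstates)
      freq[st + 1L] <- freq[st + 1L] + 1 / length(st)
    }
    for (i in seq_along(col)) {
      if (col[i] == full) next
      st <- .mask_states(col[i], M$nstates)
      res[i, j] <- st[which.max(freq[st + 1L])]
    }
  }
  res
}

#' Per-character minimum and maximum conceivable steps
#'
#' `char_min_steps` is the number of distinct observed states minus one
#' (the length on a perfectly congruent tree); `char_max_steps` is the
#' length on a completely unresolved bush: scored taxa minus the
#' frequency of the most common state for an unordered character, and
#' the minimum absolute deviation from a median state for an ordered
#' one.  Missing entries are ignored; polymorphic entries are resolved
#' to their globally most frequent contained state.  Both are 0 for
#' constant or single-taxon characters.
#'
#' @param M a [character_matrix()].
#' @param j character index (default: all, vectorized).
#' @return Numeric vector of per-character step counts (unweighted).
#' @export
char_min_steps <- function(M, j = NULL) {
  res <- .resolve_polymorphic(M)
  idx <- if (is.null(j)) seq_len(ncol(res)) else j
  vapply(idx, function(jj) {
    st <- res[!is.na(res[, jj]), jj]
    if (length(st) <= 1L) return(0)
    if (M$ordered[jj]) diff(range(st)) else length(unique(st)) - 1
  }, numeric(1))
}

#' @rdname char_min_steps
#' @export
char_max_steps <- function(M, j = NULL) {
  res <- .resolve_polymorphic(M)
  idx <- if (is.null(j)) seq_len(ncol(res)) else j
  vapply(idx, function(jj) {
    st <- res[!is.na(res[, jj]), jj]
    if (length(st) <= 1L) return(0)
    if (M$ordered[jj]) {
      min(vapply(min(st):max(st), function(a) sum(abs(st - a)), numeric(1)))
    } else {
      length(st) - max(table(st))
    }
  }, numeric(1))
}

#' Consistency and retention indices
#'
#' \eqn{CI = \sum_i w_i m_i / L} and
#' \eqn{RI = (\sum_i w_i g_i - L)/(\sum_i w_i g_i - \sum_i w_i m_i)},
#' where \eqn{m_i} and \eqn{g_i} are the per-character minimum and
#' maximum steps and \eqn{L} the tree length.  Values are never rounded
#' internally.  All included characters enter the sums by default; pass
#' `informative_only = TRUE` to drop characters with `g == m` (both
#' reporting conventions exist in practice).
#'
#' @param trees a `phylo` tree or list of equally parsimonious trees.
#' @param M a [character_matrix()].
#' @param informative_only restrict the sums to parsimony-informative
#'   characters.
#' @return List with `ci`, `ri` (`NA` when no character can show
#'   homoplasy) and `length`.
#' @export
ci_ri <- function(trees, M, informative_only = FALSE) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  L <- vapply(trees, fitch_length, numeric(1), M = M)
  if (max(L) - min(L) > 1e-9)
    stop("trees have unequal lengths; CI/RI need equally optimal trees",
         call. = FALSE)
  L <- L[1]
  m <- char_min_steps(M)
  g <- char_max_steps(M)
  w <- M$weights
  keep <- if (informative_only) g > m else rep(TRUE, length(m))
  sm <- sum(w[keep] * m[keep])
  sg <- sum(w[keep] * g[keep])
  # uninformative characters contribute exactly their minimum on any
  # tree, so drop that fixed amount from L when excluding them
  L <- L - sum(w[!keep] * m[!keep])
  ci <- if (L > 0) sm / L else 1
  ri <- if (sg > sm) (sg - L) / (sg - sm) else NA_real_
  list(ci = ci, ri = ri, length = L)
}
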