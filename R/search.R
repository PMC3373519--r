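# Heuristic parsimony search: random-addition starting trees followed
# by SPR/TBR branch swapping, keeping up to `hold` equally optimal
# trees per replicate and pooling distinct optima over replicates.

.restore_rng <- function() {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  function() {
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
}

.ras_tree <- function(M, score_fn, order = NULL) {
  n <- length(M$taxa)
  if (is.null(order)) order <- sample(n)
  ut <- utree_init3(M$taxa, tips = order[1:3])
  for (k in order[-(1:3)]) {
    E <- utree_edges(ut)
    cands <- lapply(seq_len(nrow(E)), function(e)
      utree_add_tip(ut, k, E[e, ]))
    sc <- vapply(cands, score_fn, numeric(1))
    best <- which(sc <= min(sc) + 1e-9)
    pick <- if (length(best) > 1) best[sample.int(length(best), 1)] else best
    ut <- cands[[pick]]
  }
  ut
}

.swap_search <- function(ut, score_fn, swap = "tbr", hold = 10L) {
  nbrfun <- switch(swap, tbr = tbr_neighbors, spr = spr_neighbors,
                   stop("swap must be 'tbr' or 'spr'", call. = FALSE))
  best_len <- score_fn(ut)
  pool <- list(ut)
  keys <- utree_key(ut)
  explored <- character(0)
  repeat {
    improved <- FALSE
    todo <- which(!(keys %in% explored))
    if (!length(todo)) break
    i <- todo[1]
    explored <- c(explored, keys[i])
    for (nb in nbrfun(pool[[i]])) {
      l <- score_fn(nb)
      if (l < best_len - 1e-9) {
        best_len <- l
        pool <- list(nb)
        keys <- utree_key(nb)
        explored <- character(0)
        improved <- TRUE
        break
      } else if (l <= best_len + 1e-9) {
        nk <- utree_key(nb)
        if (!(nk %in% keys) && length(pool) < hold) {
          pool <- c(pool, list(nb))
          keys <- c(keys, nk)
        }
      }
    }
    if (!improved && all(keys %in% explored)) break
  }
  list(pool = pool, keys = keys, length = best_len)
}

#' Heuristic maximum-parsimony search
#'
#' Runs `replicates` random-addition-sequence starting trees, each
#' refined by branch swapping (tree-bisection-reconnection or
#' subtree-pruning-regrafting) to a local optimum while holding up to
#' `hold` equally parsimonious trees; distinct optimal trees are pooled
#' over replicates.  A fixed seed reproduces the result exactly.
#'
#' @param M a [character_matrix()] with at least 4 taxa.
#' @param replicates number of random-addition replicates.
#' @param swap `"tbr"` (default) or `"spr"`.
#' @param hold maximum equally optimal trees kept per replicate.
#' @param seed integer RNG seed.
#' @return An object of class `parsimony_result`: `best_trees` (list of
#'   unrooted `phylo`), `length`, `ci`, `ri`, `search_log`.
#' @export
heuristic_search <- function(M, replicates = 10L, swap = c("tbr", "spr"),
                             hold = 10L, seed = 1L) {
  stopifnot(inherits(M, "char_matrix"))
  swap <- match.arg(swap)
  if (length(M$taxa) < 4L)
    stop("heuristic search needs at least 4 taxa", call. = FALSE)
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  restore <- .restore_rng(); on.exit(restore())
  set.seed(seed)
  score_fn <- function(u) .fitch_score_utree(u, M)
  best_len <- Inf
  pool <- list(); keys <- character(0)
  for (r in seq_len(replicates)) {
    start <- .ras_tree(M, score_fn)
    res <- .swap_search(start, score_fn, swap = swap, hold = hold)
    if (res$length < best_len - 1e-9) {
      best_len <- res$length
      pool <- res$pool
      keys <- res$keys
    } else if (res$length <= best_len + 1e-9) {
      for (i in seq_along(res$pool)) {
        if (!(res$keys[i] %in% keys)) {
          pool <- c(pool, res$pool[i])
          keys <- c(keys, res$keys[i])
        }
      }
    }
  }
  trees <- lapply(pool, utree_to_phylo)
  stats <- ci_ri(trees, M)
  structure(list(best_trees = trees, length = best_len,
                 ci = stats$ci, ri = stats$ri,
                 search_log = list(replicates = as.integer(replicates),
                                   swap = swap, hold = as.integer(hold),
                                   seed = as.integer(seed),
                                   n_best = length(trees))),
            class = "parsimony_result")
}

#' @export
print.parsimony_result <- function(x, ...) {
  cat(sprintf(
    "<parsimony_result: %d optimal tree(s) of length %g, CI = %.4f, RI = %s>\n",
    length(x$best_trees), x$length, x$ci,
    if (is.na(x$ri)) "NA" else sprintf("%.4f", x$ri)))
  cat(sprintf("  search: %d replicates, %s swapping, hold %d, seed %d\n",
              x$search_log$replicates, toupper(x$search_log$swap),
              x$search_log$hold, x$search_log$seed))
  invisible(x)
}

#' Bootstrap proportions for bipartitions
#'
#' Resamples characters with replacement (same count), re-runs a
#' reduced heuristic search per pseudo-replicate, and scores each
#' bipartition by the percentage of replicates whose strict consensus
#' contains it.  Trivial splits are excluded.
#'
#' @param M a [character_matrix()].
#' @param reps number of bootstrap pseudo-replicates.
#' @param replicates,swap,hold search settings used within each
#'   pseudo-replicate (reduced by default).
#' @param seed integer RNG seed (fixed seed, identical supports).
#' @return An object of class `support_values`: data frame `splits` with
#'   columns `split` (bitmask), `label`, `bootstrap` (percent), plus the
#'   canonical `taxa` order.
#' @export
bootstrap_support <- function(M, reps = 100L, replicates = 2L,
                              swap = "spr", hold = 5L, seed = 1L) {
  stopifnot(inherits(M, "char_matrix"), reps >= 1L)
  restore <- .restore_rng(); on.exit(restore())
  set.seed(seed)
  nc <- ncol(M$mask)
  counts <- new.env(parent = emptyenv())
  for (r in seq_len(reps)) {
    cnt <- tabulate(sample.int(nc, nc, replace = TRUE), nbins = nc)
    keep <- cnt > 0L
    Mr <- M
    Mr$mask <- M$mask[, keep, drop = FALSE]
    Mr$weights <- M$weights[keep] * cnt[keep]
    Mr$ordered <- M$ordered[keep]
    Mr$orig_index <- M$orig_index[keep]
    score_fn <- function(u) .fitch_score_utree(u, Mr)
    best_len <- Inf; pools <- list(); keys <- character(0)
    for (rr in seq_len(replicates)) {
      res <- .swap_search(.ras_tree(Mr, score_fn), score_fn,
                          swap = swap, hold = hold)
      if (res$length < best_len - 1e-9) {
        best_len <- res$length; pools <- res$pool; keys <- res$keys
      } else if (res$length <= best_len + 1e-9) {
        for (i in seq_along(res$pool)) if (!(res$keys[i] %in% keys)) {
          pools <- c(pools, res$pool[i]); keys <- c(keys, res$keys[i])
        }
      }
    }
    sp <- Reduce(intersect, lapply(pools, utree_splits))
    for (s in sp) {
      k <- as.character(s)
      counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
    }
  }
  ks <- ls(counts)
  splits <- as.integer(ks)
  df <- data.frame(split = splits,
                   label = vapply(splits, format_split, character(1),
                                  taxa = M$taxa),
                   bootstrap = vapply(ks, function(k)
                     100 * counts[[k]] / reps, numeric(1)))
  df <- df[order(-df$bootstrap), ]
  rownames(df) <- NULL
  structure(list(splits = df, taxa = M$taxa, reps = as.integer(reps),
                 seed = as.integer(seed)),
            class = "support_values")
}

#' @export
print.support_values <- function(x, ...) {
  cat(sprintf("<support_values over %d taxa>\n", length(x$taxa)))
  print(head(x$splits, 10))
  invisible(x)
}

#' Bremer decay indices for clades of an optimal tree
#'
#' For each clade (bipartition) the decay index is the length of the
#' shortest tree *lacking* the clade minus the optimal length, found by
#' converse-constraint heuristic searches (a large penalty on trees
#' containing the clade).  Values that would exceed `max_extra_steps`
#' are reported capped at that bound.
#'
#' @param M a [character_matrix()].
#' @param best a `parsimony_result` from [heuristic_search()].
#' @param clades integer split bitmasks to evaluate (default: every
#'   nontrivial split of the strict consensus of the optimal trees).
#' @param max_extra_steps reporting cap for effectively unbreakable
#'   clades.
#' @param replicates,swap,hold settings of each constrained search.
#' @param seed integer RNG seed.
#' @return A `support_values` object whose `splits` data frame has a
#'   `bremer` column.
#' @export
bremer_support <- function(M, best, clades = NULL, max_extra_steps = 10L,
                           replicates = 5L, swap = "tbr", hold = 10L,
                           seed = 1L) {
  stopifnot(inherits(M, "char_matrix"), inherits(best, "parsimony_result"))
  restore <- .restore_rng(); on.exit(restore())
  set.seed(seed)
  consensus <- Reduce(intersect,
                      lapply(best$best_trees, tree_splits, taxa = M$taxa))
  if (is.null(clades)) clades <- consensus
  if (!all(clades %in% consensus))
    stop("a requested clade is not in the strict consensus of the optimal trees",
         call. = FALSE)
  L <- best$length
  BIG <- 1e6
  decay <- vapply(clades, function(s) {
    score_fn <- function(u)
      .fitch_score_utree(u, M) + BIG * utree_has_split(u, s)
    best_lack <- Inf
    for (r in seq_len(replicates)) {
      res <- .swap_search(.ras_tree(M, score_fn), score_fn,
                          swap = swap, hold = hold)
      best_lack <- min(best_lack, res$length)
    }
    if (best_lack >= BIG / 2) return(as.numeric(max_extra_steps))
    min(best_lack - L, max_extra_steps)
  }, numeric(1))
  df <- data.frame(split = clades,
                   label = vapply(clades, format_split, character(1),
                                  taxa = M$taxa),
                   bremer = decay)
  rownames(df) <- NULL
  structure(list(splits = df, taxa = M$taxa, seed = as.integer(seed)),
            class = "support_values")
}

#' Attach bootstrap/Bremer supports to a tree as node labels
#'
#' @param tree a `phylo` tree (will be kept as supplied; supports are
#'   matched by bipartition).
#' @param boot,bremer `support_values` objects (either may be `NULL`).
#' @param taxa canonical taxon order used for split encoding.
#' @return The tree with `node.label` strings `"boot/bremer"`.
#' @export
annotate_supports <- function(tree, boot = NULL, bremer = NULL,
                              taxa = NULL) {
  if (is.null(taxa))
    taxa <- if (!is.null(boot)) boot$taxa else bremer$taxa
  ut <- utree_from_phylo(tree, taxa)
  n <- length(taxa)
  full <- bitwShiftL(1L, n) - 1L
  lab <- character(tree$Nnode)
  for (node in seq_len(tree$Nnode) + length(tree$tip.label)) {
    tips <- ape::extract.clade(tree, node)$tip.label
    s <- sum(bitwShiftL(1L, match(tips, taxa) - 1L))
    if (bitwAnd(s, 1L) == 1L) s <- bitwAnd(bitwXor(s, full), full)
    parts <- character(0)
    if (!is.null(boot)) {
      i <- match(s, boot$splits$split)
      parts <- c(parts, if (is.na(i)) "-" else
        sprintf("%.0f", boot$splits$bootstrap[i]))
    }
    if (!is.null(bremer)) {
      i <- match(s, bremer$splits$split)
      parts <- c(parts, if (is.na(i)) "-" else
        sprintf("%g", bremer$splits$bremer[i]))
    }
    lab[node - length(tree$tip.label)] <- paste(parts, collapse = "/")
  }
  tree$node.label <- lab
  tree
}
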