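# Internal light-weight unrooted tree representation ("utree"):
# tips carry fixed ids 1..n matching a canonical taxon order, internal
# nodes ids > n; `adj` is an adjacency list.  All parsimony search moves
# (addition, SPR, TBR) operate on this structure; conversion to ape
# "phylo" happens only at the interface.

utree_init3 <- function(labels, tips = 1:3) {
  n <- length(labels)
  stopifnot(n >= 3, length(tips) == 3)
  adj <- vector("list", n + 1L)
  int <- n + 1L
  adj[[int]] <- as.integer(tips)
  for (t in tips) adj[[t]] <- int
  list(n = as.integer(n), labels = labels, adj = adj, max_id = int)
}

.adj_rm <- function(adj, a, b) {
  adj[[a]] <- adj[[a]][adj[[a]] != b]
  adj
}

.adj_add <- function(adj, a, b) {
  adj[[a]] <- c(adj[[a]], as.integer(b))
  adj
}

utree_edges <- function(ut) {
  out <- list()
  for (u in seq_along(ut$adj)) {
    nb <- ut$adj[[u]]
    if (is.null(nb)) next
    for (v in nb) if (u < v) out[[length(out) + 1L]] <- c(u, v)
  }
  do.call(rbind, out)
}

utree_add_tip <- function(ut, tip, edge) {
  w <- ut$max_id + 1L
  adj <- ut$adj
  adj <- .adj_rm(adj, edge[1], edge[2])
  adj <- .adj_rm(adj, edge[2], edge[1])
  adj[[w]] <- integer(0)
  adj <- .adj_add(adj, edge[1], w); adj <- .adj_add(adj, w, edge[1])
  adj <- .adj_add(adj, edge[2], w); adj <- .adj_add(adj, w, edge[2])
  adj <- .adj_add(adj, tip, w);     adj <- .adj_add(adj, w, tip)
  ut$adj <- adj
  ut$max_id <- w
  ut
}

# postorder node list and parent pointers from an internal root
.utree_order <- function(ut, root = NULL) {
  if (is.null(root)) {
    deg <- vapply(ut$adj, length, integer(1))
    root <- which(deg >= 2L)[1L]
    if (is.na(root)) root <- which(deg >= 1L)[1L]
  }
  parent <- integer(ut$max_id)
  stack <- root
  parent[root] <- -1L
  disc <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    disc <- c(disc, v)
    for (w in ut$adj[[v]]) {
      if (w == parent[v]) next
      parent[w] <- v
      stack <- c(stack, w)
    }
  }
  list(post = rev(disc), parent = parent, root = root)
}

# nontrivial unrooted splits as integer tip bitmasks (n <= 31),
# normalized to the side not containing tip 1; sorted unique
utree_splits <- function(ut) {
  n <- ut$n
  if (n > 31L) stop("split bitmasks support up to 31 taxa", call. = FALSE)
  ord <- .utree_order(ut)
  full <- bitwShiftL(1L, n) - 1L
  mask <- integer(ut$max_id)
  out <- integer(0)
  for (v in ord$post) {
    if (v <= n) {
      mask[v] <- bitwShiftL(1L, v - 1L)
    } else {
      ms <- 0L
      for (w in ut$adj[[v]]) if (w != ord$parent[v]) ms <- bitwOr(ms, mask[w])
      mask[v] <- ms
    }
    if (ord$parent[v] > 0) {
      s <- mask[v]
      if (bitwAnd(s, 1L) == 1L) s <- bitwAnd(bitwXor(s, full), full)
      pc <- .popcount(s)
      if (pc >= 2L && pc <= n - 2L) out <- c(out, s)
    }
  }
  sort(unique(out))
}

.popcount <- function(x) {
  k <- 0L
  while (any(x > 0L)) {
    k <- k + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  k
}

utree_key <- function(ut) paste(utree_splits(ut), collapse = ",")

utree_has_split <- function(ut, split) split %in% utree_splits(ut)

utree_to_newick <- function(ut) {
  ord <- .utree_order(ut)
  lab <- function(v) gsub("[ ,():;]", "_", ut$labels[v])
  build <- function(v, parent) {
    kids <- ut$adj[[v]][ut$adj[[v]] != parent]
    if (length(kids) == 0) return(lab(v))
    paste0("(", paste(vapply(kids, build, character(1), parent = v),
                      collapse = ","), ")")
  }
  paste0(build(ord$root, -1L), ";")
}

utree_to_phylo <- function(ut) ape::read.tree(text = utree_to_newick(ut))

utree_from_phylo <- function(tree, taxa = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(taxa)) taxa <- sort(tree$tip.label)
  n <- length(taxa)
  if (!setequal(tree$tip.label, taxa) || length(tree$tip.label) != n)
    stop("tree tips do not match the taxon set", call. = FALSE)
  nn <- tree$Nnode
  adj <- vector("list", n + nn)
  id <- integer(n + nn)
  id[seq_len(n)] <- match(tree$tip.label, taxa)      # phylo tips 1..n
  id[n + seq_len(nn)] <- n + seq_len(nn)             # internals keep offset
  for (e in seq_len(nrow(tree$edge))) {
    a <- id[tree$edge[e, 1]]; b <- id[tree$edge[e, 2]]
    adj <- .adj_add(adj, a, b); adj <- .adj_add(adj, b, a)
  }
  ut <- list(n = as.integer(n), labels = taxa, adj = adj,
             max_id = as.integer(n + nn))
  # suppress a degree-2 root so the tree is properly unrooted
  deg2 <- which(vapply(ut$adj, length, integer(1)) == 2L)
  for (w in deg2) {
    ab <- ut$adj[[w]]
    ut$adj <- .adj_rm(ut$adj, ab[1], w)
    ut$adj <- .adj_rm(ut$adj, ab[2], w)
    ut$adj[[w]] <- integer(0)
    ut$adj <- .adj_add(ut$adj, ab[1], ab[2])
    ut$adj <- .adj_add(ut$adj, ab[2], ab[1])
  }
  ut
}

.utree_component <- function(ut, start, block_a, block_b) {
  seen <- integer(0)
  stack <- start
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v %in% seen) next
    seen <- c(seen, v)
    for (w in ut$adj[[v]]) {
      if ((v == block_a && w == block_b) || (v == block_b && w == block_a))
        next
      if (!(w %in% seen)) stack <- c(stack, w)
    }
  }
  seen
}

.edges_within <- function(ut, nodes) {
  out <- list()
  for (u in nodes) {
    for (v in ut$adj[[u]]) {
      if (u < v && v %in% nodes) out[[length(out) + 1L]] <- c(u, v)
    }
  }
  out
}

# detach the subtree on the `v` side of edge (u, v); returns the pruned
# utree (with u suppressed if needed) plus bookkeeping
.detach <- function(ut, u, v) {
  adj <- ut$adj
  adj <- .adj_rm(adj, u, v); adj <- .adj_rm(adj, v, u)
  ut$adj <- adj
  freed <- NA_integer_
  seed <- u
  if (length(ut$adj[[u]]) == 2L) {
    ab <- ut$adj[[u]]
    ut$adj <- .adj_rm(ut$adj, ab[1], u)
    ut$adj <- .adj_rm(ut$adj, ab[2], u)
    ut$adj[[u]] <- integer(0)
    ut$adj <- .adj_add(ut$adj, ab[1], ab[2])
    ut$adj <- .adj_add(ut$adj, ab[2], ab[1])
    freed <- u
    seed <- ab[1]
  }
  list(ut = ut, freed = freed, seed = seed)
}

.subdivide_connect <- function(ut, edge, node, new_id) {
  # put `new_id` in the middle of `edge` and connect it to `node`
  adj <- ut$adj
  adj <- .adj_rm(adj, edge[1], edge[2]); adj <- .adj_rm(adj, edge[2], edge[1])
  adj[[new_id]] <- integer(0)
  adj <- .adj_add(adj, edge[1], new_id); adj <- .adj_add(adj, new_id, edge[1])
  adj <- .adj_add(adj, edge[2], new_id); adj <- .adj_add(adj, new_id, edge[2])
  adj <- .adj_add(adj, node, new_id);    adj <- .adj_add(adj, new_id, node)
  ut$adj <- adj
  ut
}

# all subtree-prune-regraft neighbors (distinct topologies, original
# excluded)
spr_neighbors <- function(ut) {
  key0 <- utree_key(ut)
  seen <- key0
  out <- list()
  E <- utree_edges(ut)
  for (e in seq_len(nrow(E))) {
    for (dir in 1:2) {
      u <- if (dir == 1) E[e, 1] else E[e, 2]
      v <- if (dir == 1) E[e, 2] else E[e, 1]
      # move the subtree rooted at v (attachment node v keeps its edges)
      det <- .detach(ut, u, v)
      base <- det$ut
      compA <- .utree_component(base, det$seed, -1L, -1L)
      if (length(compA) < 2L) next
      edgesA <- .edges_within(base, compA)
      new_id <- if (is.na(det$freed)) base$max_id + 1L else det$freed
      for (e1 in edgesA) {
        # subdivide the target edge with a junction and hang the pruned
        # subtree (rooted at v, which kept degree 2, or a bare tip) on it
        cand <- .subdivide_connect(base, e1, v, new_id)
        cand$max_id <- max(cand$max_id, new_id)
        k <- utree_key(cand)
        if (!(k %in% seen)) {
          seen <- c(seen, k)
          out[[length(out) + 1L]] <- cand
        }
      }
    }
  }
  out
}

# all tree-bisection-reconnection neighbors (distinct topologies)
tbr_neighbors <- function(ut) {
  key0 <- utree_key(ut)
  seen <- key0
  out <- list()
  E <- utree_edges(ut)
  for (e in seq_len(nrow(E))) {
    u <- E[e, 1]; v <- E[e, 2]
    adj <- ut$adj
    adj <- .adj_rm(adj, u, v); adj <- .adj_rm(adj, v, u)
    base <- ut; base$adj <- adj
    free <- integer(0)
    seedA <- u; seedB <- v
    for (w in c(u, v)) {
      if (length(base$adj[[w]]) == 2L) {
        ab <- base$adj[[w]]
        base$adj <- .adj_rm(base$adj, ab[1], w)
        base$adj <- .adj_rm(base$adj, ab[2], w)
        base$adj[[w]] <- integer(0)
        base$adj <- .adj_add(base$adj, ab[1], ab[2])
        base$adj <- .adj_add(base$adj, ab[2], ab[1])
        free <- c(free, w)
        if (w == u) seedA <- ab[1] else seedB <- ab[1]
      }
    }
    compA <- .utree_component(base, seedA, -1L, -1L)
    compB <- .utree_component(base, seedB, -1L, -1L)
    attachA <- if (length(compA) == 1L) list(compA) else .edges_within(base, compA)
    attachB <- if (length(compB) == 1L) list(compB) else .edges_within(base, compB)
    for (a in attachA) {
      for (b in attachB) {
        cand <- base
        ids <- free
        if (length(a) == 2L) {
          x <- ids[1]; ids <- ids[-1]
          cand <- .subdivide_connect_pair(cand, a, x)
        } else x <- a[1]
        if (length(b) == 2L) {
          y <- ids[1]; ids <- ids[-1]
          cand <- .subdivide_connect_pair(cand, b, y)
        } else y <- b[1]
        cand$adj <- .adj_add(cand$adj, x, y)
        cand$adj <- .adj_add(cand$adj, y, x)
        k <- utree_key(cand)
        if (!(k %in% seen)) {
          seen <- c(seen, k)
          out[[length(out) + 1L]] <- cand
        }
      }
    }
  }
  out
}

.subdivide_connect_pair <- function(ut, edge, new_id) {
  adj <- ut$adj
  adj <- .adj_rm(adj, edge[1], edge[2]); adj <- .adj_rm(adj, edge[2], edge[1])
  adj[[new_id]] <- integer(0)
  adj <- .adj_add(adj, edge[1], new_id); adj <- .adj_add(adj, new_id, edge[1])
  adj <- .adj_add(adj, edge[2], new_id); adj <- .adj_add(adj, new_id, edge[2])
  ut$adj <- adj
  ut
}

#' Random binary tree topology over a set of labels
#'
#' Builds a rooted binary topology by uniform coalescent-style joins
#' (no branch lengths); a fixed RNG state gives a fixed topology.
#'
#' @param labels character vector of taxon labels (length >= 2).
#' @param rooted return a rooted tree (default `TRUE`).
#' @return An [ape::read.tree()] `phylo` object.
#' @export
random_topology <- function(labels, rooted = TRUE) {
  stopifnot(length(labels) >= 2)
  reps <- gsub("[ ,():;]", "_", labels)
  while (length(reps) > 1) {
    i <- sample(length(reps), 2)
    merged <- paste0("(", reps[i[1]], ",", reps[i[2]], ")")
    reps <- c(reps[-i], merged)
  }
  tr <- ape::read.tree(text = paste0(reps, ";"))
  if (!rooted) tr <- ape::unroot(tr)
  tr
}

#' Enumerate all unrooted binary topologies over a label set
#'
#' Recursive stepwise addition; feasible for up to 8 taxa
#' (1 x 3 x 5 x ... trees).
#'
#' @param labels character vector (3 to 8 labels).
#' @return List of internal `utree` objects (use with the parsimony
#'   engine) — convert with `utree_to_phylo` if needed.
#' @keywords internal
all_utree_topologies <- function(labels) {
  n <- length(labels)
  stopifnot(n >= 3, n <= 8)
  out <- list()
  grow <- function(ut, k) {
    if (k > n) {
      out[[length(out) + 1L]] <<- ut
      return(invisible())
    }
    E <- utree_edges(ut)
    for (e in seq_len(nrow(E)))
      grow(utree_add_tip(ut, k, E[e, ]), k + 1L)
  }
  grow(utree_init3(labels), 4L)
  out
}

#' Nontrivial bipartitions (splits) of a tree
#'
#' @param tree a `phylo` object (rooted or unrooted).
#' @param taxa canonical taxon order defining the split encoding
#'   (default: sorted tip labels).
#' @return Integer vector of tip bitmasks, each normalized to the side
#'   not containing the first canonical taxon.
#' @export
tree_splits <- function(tree, taxa = NULL) {
  ut <- utree_from_phylo(tree, taxa)
  utree_splits(ut)
}

#' Human-readable rendering of a split bitmask
#' @param split integer bitmask from [tree_splits()].
#' @param taxa canonical taxon order.
#' @return Character: taxa on the split side, pipe, the rest.
#' @export
format_split <- function(split, taxa) {
  inb <- which(bitwAnd(split, bitwShiftL(1L, seq_along(taxa) - 1L)) > 0L)
  paste(paste(taxa[inb], collapse = " "), "|",
        paste(taxa[-inb], collapse = " "))
}

#' Strict-consensus splits of a set of trees
#'
#' @param trees list of `phylo` objects over the same taxa.
#' @param taxa canonical taxon order (default: sorted tips of the first
#'   tree).
#' @return Integer vector of splits present in every tree.
#' @export
strict_consensus_splits <- function(trees, taxa = NULL) {
  if (is.null(taxa)) taxa <- sort(trees[[1]]$tip.label)
  sp <- lapply(trees, tree_splits, taxa = taxa)
  Reduce(intersect, sp)
}
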