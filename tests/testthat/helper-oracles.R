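# Independent oracles and small fixture builders shared across tests.
# These deliberately avoid the implementation paths they check.

circle_curve <- function(n = 256, label = "circle") {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  outline_curve(cbind(cos(th), sin(th)), label)
}

ellipse_curve <- function(a = 1, b = 2, n = 256, label = "ellipse") {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  outline_curve(cbind(a * cos(th), b * sin(th)), label)
}

# brute-force parsimony length: minimize changes over every assignment
# of single states to internal nodes (tips resolve their own sets on
# their single pendant edge)
oracle_tree_length <- function(tree, M) {
  ut <- morphoclade:::utree_from_phylo(tree, M$taxa)
  ord <- morphoclade:::.utree_order(ut)
  internals <- ord$post[ord$post > ut$n]
  edges <- morphoclade:::utree_edges(ut)
  total <- 0
  for (j in seq_len(ncol(M$mask))) {
    tipst <- lapply(seq_len(ut$n), function(i)
      morphoclade:::.mask_states(M$mask[i, j], M$nstates))
    obs <- sort(unique(unlist(tipst)))
    if (length(obs) <= 1) next
    asn <- expand.grid(rep(list(obs), length(internals)))
    best <- Inf
    for (r in seq_len(nrow(asn))) {
      a <- as.integer(asn[r, ])
      names(a) <- internals
      cost <- 0
      for (e in seq_len(nrow(edges))) {
        su <- if (edges[e, 1] <= ut$n) tipst[[edges[e, 1]]]
              else a[as.character(edges[e, 1])]
        sv <- if (edges[e, 2] <= ut$n) tipst[[edges[e, 2]]]
              else a[as.character(edges[e, 2])]
        cost <- cost + min(outer(su, sv, function(x, y)
          as.numeric(x != y)))
      }
      best <- min(best, cost)
    }
    total <- total + best * M$weights[j]
  }
  total
}

# exhaustive dispersal-vicariance oracle: enumerate every assignment of
# a distribution to every internal node; per-node cost is the best free
# split of the node range against the two daughter ranges
oracle_diva <- function(tree, ranges, areas) {
  na <- length(areas)
  cand <- 1:(2^na - 1)
  ntip <- length(tree$tip.label)
  nodes <- ntip + seq_len(tree$Nnode)
  kids <- vector("list", ntip + tree$Nnode)
  for (e in seq_len(nrow(tree$edge)))
    kids[[tree$edge[e, 1]]] <- c(kids[[tree$edge[e, 1]]], tree$edge[e, 2])
  obs <- vapply(tree$tip.label, function(t)
    sum(bitwShiftL(1L, match(ranges[[t]], areas) - 1L)), numeric(1))
  pc <- function(x) sum(bitwAnd(bitwShiftR(as.integer(x), 0:30), 1L))
  node_cost <- function(F, g1, g2) {
    best <- Inf
    for (s in split_scenarios(F))
      best <- min(best,
                  pc(bitwXor(s$left, g1)) + pc(bitwXor(s$right, g2)),
                  pc(bitwXor(s$right, g1)) + pc(bitwXor(s$left, g2)))
    best
  }
  asn <- expand.grid(rep(list(cand), length(nodes)))
  best <- Inf
  opt <- vector("list", length(nodes))
  for (r in seq_len(nrow(asn))) {
    a <- as.integer(asn[r, ])
    names(a) <- nodes
    tot <- 0
    for (v in nodes) {
      ch <- kids[[v]]
      g <- vapply(ch, function(c_) if (c_ <= ntip) obs[c_]
                  else a[as.character(c_)], numeric(1))
      tot <- tot + node_cost(a[as.character(v)], g[1], g[2])
      if (tot > best) break
    }
    if (tot < best) {
      best <- tot
      opt <- as.list(a)
    } else if (tot == best) {
      for (i in seq_along(nodes)) opt[[i]] <- union(opt[[i]], a[i])
    }
  }
  list(cost = best, opt = lapply(opt, function(x) sort(as.integer(x))))
}

# top-down memoized maximum over all monotone lattice paths with the
# same step set and local cost as the DP kernel (independent R
# implementation, recursion instead of a bottom-up table)
oracle_dp_value <- function(q1, q2) {
  m <- nrow(q1$q)
  steps <- cbind(a = c(1, 1, 2, 1, 3, 2, 3, 1, 4, 3, 4),
                 b = c(1, 2, 1, 3, 1, 3, 2, 4, 1, 4, 3))
  dt <- 1 / (m - 1)
  memo <- array(NA_real_, c(m, m))
  interp_q2 <- function(gj) {
    j0 <- min(floor(gj), m - 1)     # 0-based sample index
    w <- gj - j0
    j1 <- j0 + 1
    if (j1 > m - 1) { j1 <- m - 1; w <- 0 }
    (1 - w) * q2$q[j0 + 1, ] + w * q2$q[j1 + 1, ]
  }
  rec <- function(i, j) {
    i <- unname(i); j <- unname(j)
    if (i == 1 && j == 1) return(0)
    if (!is.na(memo[i, j])) return(memo[i, j])
    best <- -Inf
    for (s in seq_len(nrow(steps))) {
      a <- steps[s, 1]; b <- steps[s, 2]
      pi <- i - a; pj <- j - b
      if (pi < 1 || pj < 1) next
      prev <- rec(pi, pj)
      if (!is.finite(prev)) next
      slope <- b / a
      cc <- 0
      for (k in seq_len(a)) {
        gj <- (pj - 1) + k * slope
        q2v <- interp_q2(gj)
        cc <- cc + sum(q1$q[pi + k, ] * q2v)
      }
      v <- prev + cc * sqrt(slope) * dt
      if (v > best) best <- v
    }
    memo[i, j] <<- best
    best
  }
  unname(rec(m, m))
}

# truly exhaustive path enumeration (no memoization) for tiny grids
oracle_dp_value_exhaustive <- function(q1, q2) {
  m <- nrow(q1$q)
  steps <- cbind(a = c(1, 1, 2, 1, 3, 2, 3, 1, 4, 3, 4),
                 b = c(1, 2, 1, 3, 1, 3, 2, 4, 1, 4, 3))
  dt <- 1 / (m - 1)
  best <- -Inf
  segcost <- function(pi, pj, a, b) {
    slope <- b / a
    cc <- 0
    for (k in seq_len(a)) {
      gj <- (pj - 1) + k * slope
      j0 <- min(floor(gj), m - 1)
      w <- gj - j0
      j1 <- j0 + 1
      if (j1 > m - 1) { j1 <- m - 1; w <- 0 }
      q2v <- (1 - w) * q2$q[j0 + 1, ] + w * q2$q[j1 + 1, ]
      cc <- cc + sum(q1$q[pi + k, ] * q2v)
    }
    cc * sqrt(slope) * dt
  }
  walk2 <- function(i, j, acc) {
    if (i == m && j == m) {
      if (acc > best) best <<- acc
      return(invisible())
    }
    for (s in seq_len(nrow(steps))) {
      a <- steps[s, 1]; b <- steps[s, 2]
      if (i + a > m || j + b > m) next
      walk2(i + a, j + b, acc + segcost(i, j, a, b))
    }
  }
  best <- -Inf
  walk2(1, 1, 0)
  unname(best)
}

# canonical unrooted-topology key for a phylo tree
topo_key <- function(tree, taxa) {
  paste(tree_splits(tree, taxa = taxa), collapse = ",")
}

# every unrooted binary topology over a small label set, as phylo
all_topo_phylo <- function(labels) {
  lapply(morphoclade:::all_utree_topologies(labels),
         morphoclade:::utree_to_phylo)
}
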