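# Event-cost dispersal-vicariance reconstruction: vicariance and
# within-area (sympatric) speciation are free, dispersal and extinction
# cost one per area added to / deleted from a distribution.  Ranges are
# bitsets over an ordered area list.

.range_to_bits <- function(x, areas) {
  if (is.numeric(x)) return(as.integer(x))
  idx <- match(x, areas)
  if (any(is.na(idx)))
    stop(sprintf("unknown area code(s): %s",
                 paste(x[is.na(idx)], collapse = ", ")), call. = FALSE)
  as.integer(sum(bitwShiftL(1L, unique(idx) - 1L)))
}

.bits_to_areas <- function(bits, areas) {
  areas[bitwAnd(bits, bitwShiftL(1L, seq_along(areas) - 1L)) > 0L]
}

#' Event cost of transforming one range into another
#'
#' One unit per area gained (dispersal) plus one per area lost
#' (extinction): the size of the symmetric difference.
#'
#' @param start,end non-empty area sets: character vectors of area codes
#'   (with `areas` supplied) or integer bitmasks.
#' @param areas ordered area code list (needed for character input).
#' @return Integer cost.
#' @examples
#' transition_cost(c("A"), c("A", "B"), areas = c("A", "B", "C"))
#' @export
transition_cost <- function(start, end, areas = NULL) {
  s <- .range_to_bits(start, areas)
  e <- .range_to_bits(end, areas)
  if (s == 0L || e == 0L)
    stop("ranges must be non-empty", call. = FALSE)
  .popcount(bitwXor(s, e))
}

#' Cost-free speciation scenarios for an ancestral range
#'
#' A single-area ancestor speciates by duplication (both daughters
#' inherit the area); a widespread ancestor speciates by vicariance
#' into any pair of non-empty disjoint subsets covering the range
#' (`2^(k-1) - 1` unordered bipartitions for `k` areas).  With
#' `single_area_split = TRUE` one daughter is restricted to exactly one
#' area, the stricter variant used by some implementations.
#'
#' @param range non-empty area set (character codes or bitmask).
#' @param areas ordered area code list (needed for character input).
#' @param single_area_split restrict one side of each vicariance split
#'   to a single area.
#' @return List of unordered scenario pairs; each element is a list of
#'   two bitmasks (`left`, `right`).
#' @export
split_scenarios <- function(range, areas = NULL, single_area_split = FALSE) {
  F <- .range_to_bits(range, areas)
  if (F == 0L) stop("range must be non-empty", call. = FALSE)
  k <- .popcount(F)
  if (k == 1L) return(list(list(left = F, right = F)))
  bits <- which(bitwAnd(F, bitwShiftL(1L, 0:30)) > 0L) - 1L
  out <- list()
  # enumerate subsets containing the lowest bit -> unordered bipartitions
  low <- bits[1]
  rest <- bits[-1]
  for (msk in 0:(2^length(rest) - 1)) {
    S1 <- bitwShiftL(1L, low)
    mm <- msk
    for (b in rest) {
      if (bitwAnd(mm, 1L) == 1L) S1 <- bitwOr(S1, bitwShiftL(1L, b))
      mm <- bitwShiftR(mm, 1L)
    }
    S2 <- bitwAnd(bitwXor(F, S1), F)
    if (S2 == 0L) next
    if (single_area_split && .popcount(S1) > 1L && .popcount(S2) > 1L) next
    out[[length(out) + 1L]] <- list(left = S1, right = S2)
  }
  out
}

#' Read a taxon-to-areas table
#'
#' CSV with columns `taxon` and `areas`, areas given as
#' semicolon-separated codes (e.g. `"NNA;SNA"`).
#'
#' @param path CSV file.
#' @param areas ordered area code list; defaults to the four continental
#'   areas `E` (Europe), `AS` (Asia), `NNA` (northern North America),
#'   `SNA` (southern North America).
#' @return Named list of character vectors of area codes.
#' @export
read_area_csv <- function(path, areas = c("E", "AS", "NNA", "SNA")) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("taxon", "areas") %in% names(df)))
    stop("area CSV needs columns taxon, areas", call. = FALSE)
  out <- lapply(strsplit(df$areas, ";"), trimws)
  names(out) <- df$taxon
  lapply(out, function(a) {
    if (!all(a %in% areas))
      stop("area code outside the configured area list", call. = FALSE)
    a
  })
}

#' Dispersal-vicariance reconstruction of ancestral ranges
#'
#' Exact dynamic program over all candidate distributions per node
#' (non-empty subsets of the area list up to `maxareas` areas):
#' \deqn{cost(v, F) = \min_{(S_1,S_2) \in splits(F)} \sum_{d}
#'   \min_G [\,|S_d \triangle G| + cost(d, G)\,]}
#' with leaves fixed at their observed ranges.  Returns the global
#' minimum number of dispersal + extinction events and, for every
#' internal node, *all* distributions occurring in at least one
#' globally optimal reconstruction (deterministically ordered by bitset
#' value).
#'
#' @param tree rooted binary `phylo`; every tip must have a range.
#' @param terminal_ranges named list/character vector mapping taxon to
#'   area codes (character vectors, or `"A;B"` strings).
#' @param areas ordered area code list (default: union of terminal
#'   codes in first-appearance order).
#' @param maxareas largest ancestral range size allowed (default: all
#'   areas).
#' @param single_area_split see [split_scenarios()].
#' @return An object of class `diva_reconstruction`: `cost`,
#'   `node_optima` (list per internal node, ape node ids, of character
#'   vectors like `"NNA+SNA"`), `node_table` (data frame), `areas`,
#'   `tree`.
#' @export
diva_reconstruct <- function(tree, terminal_ranges, areas = NULL,
                             maxareas = NULL, single_area_split = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree))
    stop("DIVA needs a rooted tree", call. = FALSE)
  if (!ape::is.binary(tree))
    stop("non-binary node: resolve polytomies first", call. = FALSE)
  if (is.character(terminal_ranges))
    terminal_ranges <- as.list(terminal_ranges)
  terminal_ranges <- lapply(terminal_ranges, function(x)
    if (is.character(x) && length(x) == 1L && grepl(";", x))
      trimws(strsplit(x, ";")[[1]]) else x)
  if (is.null(areas)) {
    areas <- unique(unlist(terminal_ranges))
    if (!is.character(areas))
      stop("supply `areas` when ranges are given as bitmasks", call. = FALSE)
  }
  na <- length(areas)
  if (na > 16L) stop("at most 16 areas supported", call. = FALSE)
  if (is.null(maxareas)) maxareas <- na
  tips <- tree$tip.label
  if (!all(tips %in% names(terminal_ranges)))
    stop("every tip needs a terminal range", call. = FALSE)
  obs <- vapply(terminal_ranges[tips], .range_to_bits, integer(1),
                areas = areas)
  if (max(vapply(obs, .popcount, integer(1))) > maxareas)
    stop("maxareas is smaller than an observed terminal range",
         call. = FALSE)

  cand <- Filter(function(s) .popcount(s) <= maxareas,
                 seq_len(2^na - 1L))
  nc <- length(cand)
  cidx <- integer(2^na); cidx[cand] <- seq_len(nc)
  trans <- outer(cand, cand, function(a, b)
    vapply(bitwXor(a, b), .popcount, integer(1)))
  splits <- lapply(cand, function(F)
    split_scenarios(F, single_area_split = single_area_split))

  ntip <- length(tips)
  nnode <- tree$Nnode
  nodes <- ntip + seq_len(nnode)
  kids <- vector("list", ntip + nnode)
  for (e in seq_len(nrow(tree$edge)))
    kids[[tree$edge[e, 1]]] <- c(kids[[tree$edge[e, 1]]], tree$edge[e, 2])
  # postorder: repeatedly take nodes whose children are all done
  done <- c(rep(TRUE, ntip), rep(FALSE, nnode))
  po <- integer(0)
  while (length(po) < nnode) {
    ready <- which(!done & vapply(kids, function(k)
      length(k) > 0 && all(done[k]), logical(1)))
    po <- c(po, ready)
    done[ready] <- TRUE
  }

  INF <- .Machine$integer.max %/% 4L
  cost <- matrix(INF, ntip + nnode, nc)
  for (i in seq_len(ntip)) cost[i, cidx[obs[i]]] <- 0L
  hmin <- vector("list", ntip + nnode)  # h_d(S) = min_G trans(S,G)+cost(d,G)
  for (v in c(seq_len(ntip), po)) {
    if (v > ntip) {
      ch <- kids[[v]]
      h1 <- hmin[[ch[1]]]; h2 <- hmin[[ch[2]]]
      for (fi in seq_len(nc)) {
        best <- INF
        for (sc in splits[[fi]]) {
          val <- h1[cidx[sc$left]] + h2[cidx[sc$right]]
          v2 <- h1[cidx[sc$right]] + h2[cidx[sc$left]]
          if (v2 < val) val <- v2
          if (val < best) best <- val
        }
        cost[v, fi] <- best
      }
    }
    # h for the branch above v
    cv <- cost[v, ]
    hmin[[v]] <- vapply(seq_len(nc), function(si)
      min(trans[si, ] + cv), numeric(1))
  }

  root <- nodes[!(nodes %in% tree$edge[, 2])]
  total <- min(cost[root, ])

  # top-down marking of node states used by >= 1 optimal reconstruction
  opt <- vector("list", ntip + nnode)
  opt[[root]] <- cand[cost[root, ] == total]
  order_td <- rev(po)
  for (v in order_td) {
    ch <- kids[[v]]
    h1 <- hmin[[ch[1]]]; h2 <- hmin[[ch[2]]]
    use1 <- integer(0); use2 <- integer(0)
    for (F in opt[[v]]) {
      fi <- cidx[F]
      for (sc in splits[[fi]]) {
        a <- cidx[sc$left]; b <- cidx[sc$right]
        for (ordp in list(c(a, b), c(b, a))) {
          if (h1[ordp[1]] + h2[ordp[2]] == cost[v, fi]) {
            g1 <- which(trans[ordp[1], ] + cost[ch[1], ] == h1[ordp[1]])
            g2 <- which(trans[ordp[2], ] + cost[ch[2], ] == h2[ordp[2]])
            use1 <- union(use1, g1); use2 <- union(use2, g2)
          }
        }
      }
    }
    if (ch[1] > ntip) opt[[ch[1]]] <- sort(cand[use1])
    if (ch[2] > ntip) opt[[ch[2]]] <- sort(cand[use2])
  }
  for (i in seq_len(ntip)) opt[[i]] <- obs[i]

  fmt <- function(b) paste(.bits_to_areas(b, areas), collapse = "+")
  node_optima <- lapply(nodes, function(v)
    vapply(sort(opt[[v]]), fmt, character(1)))
  names(node_optima) <- as.character(nodes)
  clade_of <- vapply(nodes, function(v)
    paste(sort(ape::extract.clade(tree, v)$tip.label), collapse = ","),
    character(1))
  node_table <- data.frame(
    node = nodes,
    clade = clade_of,
    optimal_ranges = vapply(node_optima, paste, character(1),
                            collapse = " | "))
  structure(list(cost = as.integer(total), node_optima = node_optima,
                 node_table = node_table, node_bits = opt,
                 areas = areas, tree = tree,
                 maxareas = as.integer(maxareas)),
            class = "diva_reconstruction")
}

#' @export
print.diva_reconstruction <- function(x, ...) {
  cat(sprintf(
    "<diva_reconstruction: %d areas (%s), optimal cost %d event(s)>\n",
    length(x$areas), paste(x$areas, collapse = ", "), x$cost))
  print(head(x$node_table, 10))
  invisible(x)
}
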