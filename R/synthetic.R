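# Seeded generators producing inputs with the statistical structure
# each analysis stage assumes: tear-shaped closed outlines with
# controlled length/width ratio, morphology-like discrete matrices
# evolved on a known tree, dispersal-vicariance range histories, and
# linear allometric samples.  Every generator is a pure function of its
# arguments + seed.

.teardrop <- function(m, ratio, pointedness = 2) {
  t <- 2 * pi * (seq_len(m) - 1) / m
  x <- cos(t)
  y <- sin(t) * sin(t / 2)^pointedness
  pts <- cbind(x, y)
  pts <- scale(pts, scale = FALSE)
  ext <- apply(pts, 2, function(v) diff(range(v)))
  # symmetric about the x axis, so principal axes are the coordinate
  # axes; rescale y so the extent ratio hits the target exactly
  pts[, 2] <- pts[, 2] * ext[1] / (ratio * ext[2])
  pts
}

#' Generate synthetic tear-shaped outline groups
#'
#' Emulates digitized external-naris outlines: closed tear-shaped
#' curves (`x = cos t`, `y = sin t * sin(t/2)^p`) anisotropically
#' rescaled so the pre-noise length/width [aspect_ratio()] equals each
#' group's target exactly, then optionally perturbed by smooth radial
#' noise and randomized rotation/translation/scale/starting point.
#' Defaults mirror the study sample: 30 outlines in two ratio classes,
#' one inside the diagnostic `[1.85, 2.85]` band (at the published 2.4
#' value) and one above 2.85.
#'
#' @param groups data frame with columns `label`, `ratio`,
#'   `pointedness`, `count`.
#' @param noise_sd standard deviation of the smooth radial noise, as a
#'   fraction of outline scale (0 disables).
#' @param jitter randomize rotation, translation, scale and starting
#'   point.
#' @param m_points vertices per outline.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return List with `shapes` (named list of [outline_curve()]) and
#'   `truth` (data frame: group, exact pre-noise ratio, applied
#'   transform, seed).
#' @export
gen_outlines <- function(groups = data.frame(
                           label = c("intermediate", "elongate"),
                           ratio = c(2.4, 3.2),
                           pointedness = c(2, 2),
                           count = c(15, 15)),
                         noise_sd = 0.02, jitter = TRUE,
                         m_points = 128L, seed = 1L) {
  stopifnot(all(groups$ratio >= 1), all(groups$count >= 1), noise_sd >= 0)
  restore <- .restore_rng(); on.exit(restore())
  set.seed(seed)
  shapes <- list()
  truth <- list()
  for (g in seq_len(nrow(groups))) {
    for (i in seq_len(groups$count[g])) {
      id <- sprintf("%s_%02d", groups$label[g], i)
      pts <- .teardrop(m_points, groups$ratio[g], groups$pointedness[g])
      if (noise_sd > 0) {
        t <- 2 * pi * (seq_len(m_points) - 1) / m_points
        mult <- rep(1, m_points)
        for (k in 2:4)
          mult <- mult + rnorm(1, 0, noise_sd) * cos(k * t) +
            rnorm(1, 0, noise_sd) * sin(k * t)
        pts <- pts * mult
      }
      rot <- 0; sc <- 1; tx <- 0; ty <- 0; shift <- 0L
      if (jitter) {
        rot <- runif(1, 0, 2 * pi)
        sc <- exp(runif(1, -0.5, 0.5))
        tx <- rnorm(1, 0, 2); ty <- rnorm(1, 0, 2)
        shift <- sample.int(m_points, 1) - 1L
        R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
        pts <- sc * pts %*% t(R)
        pts <- sweep(pts, 2, c(-tx, -ty))
        if (shift > 0)
          pts <- pts[c((shift + 1):m_points, 1:shift), , drop = FALSE]
      }
      shapes[[id]] <- outline_curve(pts, label = id, closed = TRUE)
      truth[[length(truth) + 1L]] <- data.frame(
        shape_id = id, group = groups$label[g],
        target_ratio = groups$ratio[g], rotation = rot, scale = sc,
        tx = tx, ty = ty, seed_shift = shift, noise_sd = noise_sd,
        seed = seed)
    }
  }
  list(shapes = shapes, truth = do.call(rbind, truth))
}

#' Generate a morphology-like discrete character matrix on a known tree
#'
#' Each character receives a fixed budget of state changes placed on
#' randomly chosen branches of the true tree; a budget of one change
#' per character yields a homoplasy-free matrix (consistency index 1 on
#' the generating topology by construction).  Optionally masks a
#' fraction of entries as missing.
#'
#' @param n_taxa number of taxa for a random coalescent-join topology
#'   (ignored when `true_tree` is given).
#' @param n_characters number of characters.
#' @param n_states alphabet size used by the change walk.
#' @param changes_per_char state changes placed per character (>= 1).
#' @param missing_fraction expected fraction of `?` entries.
#' @param seed integer seed.
#' @param true_tree optional rooted binary `phylo` to evolve on.
#' @return List with `matrix` (a [character_matrix()]), `tree` (rooted
#'   `phylo`), and `truth` (data frame with each character's change
#'   branches, by `tree$edge` row index).
#' @export
gen_matrix <- function(n_taxa = 8L, n_characters = 40L, n_states = 2L,
                       changes_per_char = 1L, missing_fraction = 0,
                       seed = 1L, true_tree = NULL) {
  stopifnot(n_characters >= 1, n_states >= 2, changes_per_char >= 0,
            missing_fraction >= 0, missing_fraction < 1)
  restore <- .restore_rng(); on.exit(restore())
  set.seed(seed)
  tree <- if (is.null(true_tree))
    random_topology(sprintf("t%02d", seq_len(n_taxa))) else true_tree
  tree <- stats::reorder(tree, "cladewise")  # edges parent-before-child
  ntip <- length(tree$tip.label)
  nedge <- nrow(tree$edge)
  pre <- seq_len(nedge)
  states <- matrix(0L, ntip, n_characters)
  truth_edges <- character(n_characters)
  for (j in seq_len(n_characters)) {
    k <- min(changes_per_char, nedge)
    marked <- if (k > 0) sample.int(nedge, k) else integer(0)
    truth_edges[j] <- paste(sort(marked), collapse = ";")
    nodestate <- integer(ntip + tree$Nnode)
    for (e in pre) {
      p <- tree$edge[e, 1]; c_ <- tree$edge[e, 2]
      s <- nodestate[p]
      if (e %in% marked) s <- (s + 1L) %% n_states
      nodestate[c_] <- s
    }
    states[, j] <- nodestate[seq_len(ntip)]
  }
  mask <- matrix(bitwShiftL(1L, states), ntip, n_characters)
  full <- bitwShiftL(1L, 10L) - 1L
  if (missing_fraction > 0) {
    miss <- matrix(runif(length(mask)) < missing_fraction, ntip,
                   n_characters)
    mask[miss] <- full
    for (i in seq_len(ntip)) {
      if (all(mask[i, ] == full))
        mask[i, sample.int(n_characters, 1)] <-
          bitwShiftL(1L, states[i, 1L])
    }
  }
  rownames(mask) <- tree$tip.label
  M <- character_matrix(mask, taxa = tree$tip.label, nstates = 10L)
  list(matrix = M, tree = tree,
       truth = data.frame(char = seq_len(n_characters),
                          change_edges = truth_edges, seed = seed))
}

#' Simulate a dispersal-vicariance range history on a tree
#'
#' Forward simulation under the event-cost model: the root draws a
#' random non-empty range; every internal node speciates for free by
#' duplication (single-area range) or a random vicariant bipartition
#' (widespread range); exactly `n_dispersals` area gains and
#' `n_extinctions` area losses are inserted on random branches.  An
#' event that cannot apply (dispersal into a full range, extinction of
#' a single-area range) triggers a logged re-draw of the event
#' placement.
#'
#' @param n_taxa taxa for a random topology (ignored when `true_tree`
#'   given).
#' @param n_areas number of areas (codes `A`, `B`, ...).
#' @param n_dispersals,n_extinctions event counts to place.
#' @param seed integer seed.
#' @param true_tree optional rooted binary `phylo`.
#' @return List with `ranges` (named list of area-code vectors),
#'   `tree`, `areas`, `root_range`, `events` (data frame: edge, type,
#'   area), and `retries`.
#' @export
gen_ranges <- function(n_taxa = 8L, n_areas = 4L, n_dispersals = 0L,
                       n_extinctions = 0L, seed = 1L, true_tree = NULL) {
  stopifnot(n_areas >= 2, n_dispersals >= 0, n_extinctions >= 0)
  restore <- .restore_rng(); on.exit(restore())
  set.seed(seed)
  tree <- if (is.null(true_tree))
    random_topology(sprintf("t%02d", seq_len(n_taxa))) else true_tree
  areas <- LETTERS[seq_len(n_areas)]
  ntip <- length(tree$tip.label)
  nedge <- nrow(tree$edge)
  kids <- vector("list", ntip + tree$Nnode)
  edge_of <- matrix(NA_integer_, ntip + tree$Nnode, 1)
  for (e in seq_len(nedge)) {
    kids[[tree$edge[e, 1]]] <- c(kids[[tree$edge[e, 1]]], tree$edge[e, 2])
    edge_of[tree$edge[e, 2]] <- e
  }
  root <- ntip + 1L
  retries <- 0L
  repeat {
    ok <- TRUE
    ev_edge <- c(if (n_dispersals > 0) sample.int(nedge, n_dispersals,
                                                  replace = TRUE),
                 if (n_extinctions > 0) sample.int(nedge, n_extinctions,
                                                   replace = TRUE))
    ev_type <- c(rep("dispersal", n_dispersals),
                 rep("extinction", n_extinctions))
    rsz <- sample.int(n_areas, 1)
    root_range <- sort(sample.int(n_areas, rsz))
    ranges <- vector("list", ntip)
    events <- list()
    walk <- function(v, range_in) {
      if (!ok) return(invisible())
      if (v <= ntip) {
        ranges[[v]] <<- range_in
        return(invisible())
      }
      sc <- split_scenarios(sum(bitwShiftL(1L, range_in - 1L)))
      pick <- sc[[sample.int(length(sc), 1)]]
      sides <- if (runif(1) < 0.5) c(pick$left, pick$right)
               else c(pick$right, pick$left)
      ch <- kids[[v]]
      for (d in 1:2) {
        r <- which(bitwAnd(sides[d], bitwShiftL(1L, 0:(n_areas - 1))) > 0L)
        eidx <- which(ev_edge == edge_of[ch[d]])
        for (ei in eidx) {
          if (ev_type[ei] == "dispersal") {
            gain <- setdiff(seq_len(n_areas), r)
            if (!length(gain)) { ok <<- FALSE; return(invisible()) }
            a <- if (length(gain) == 1) gain else
              gain[sample.int(length(gain), 1)]
            r <- sort(c(r, a))
          } else {
            if (length(r) <= 1) { ok <<- FALSE; return(invisible()) }
            a <- r[sample.int(length(r), 1)]
            r <- setdiff(r, a)
          }
          events[[length(events) + 1L]] <<- data.frame(
            edge = edge_of[ch[d]], type = ev_type[ei], area = areas[a])
        }
        walk(ch[d], r)
      }
    }
    walk(root, root_range)
    if (ok) break
    retries <- retries + 1L
    if (retries > 200L)
      stop("could not place the requested events on this tree", call. = FALSE)
  }
  names(ranges) <- tree$tip.label
  list(ranges = lapply(ranges, function(r) areas[r]),
       tree = tree, areas = areas, root_range = areas[root_range],
       events = if (length(events)) do.call(rbind, events) else
         data.frame(edge = integer(0), type = character(0),
                    area = character(0)),
       retries = retries)
}

#' Generate a synthetic allometric sample
#'
#' Draws predictor lengths uniformly over `x_range` and responses from
#' `intercept + slope * x + N(0, sigma^2)`.
#'
#' @param n sample size (>= 3).
#' @param slope,intercept,sigma linear-model truth (`sigma = 0` gives
#'   an exact line).
#' @param x_range range of predictor lengths.
#' @param seed integer seed.
#' @return List with `data` (data frame `x`, `y`) and `truth`.
#' @export
gen_allometry <- function(n = 12L, slope = 1.05, intercept = 100,
                          sigma = 10, x_range = c(250, 450), seed = 1L) {
  stopifnot(n >= 3, sigma >= 0)
  restore <- .restore_rng(); on.exit(restore())
  set.seed(seed)
  x <- sort(runif(n, x_range[1], x_range[2]))
  y <- intercept + slope * x + rnorm(n, 0, sigma)
  list(data = data.frame(x = x, y = y),
       truth = list(slope = slope, intercept = intercept, sigma = sigma,
                    n = n, x_range = x_range, seed = seed))
}
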