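test_that("four-taxon search finds the single informative split", {
  M <- character_matrix(matrix(c("0", "0", "1", "1"), 4, 1,
                               dimnames = list(c("A", "B", "C", "D"), NULL)))
  res <- heuristic_search(M, replicates = 3, swap = "spr", hold = 5,
                          seed = 1)
  expect_equal(res$length, 1)
  expect_equal(length(res$best_trees), 1L)
  expect_equal(tree_splits(res$best_trees[[1]], taxa = M$taxa), 12L)
})

test_that("search is seed-reproducible and recovers homoplasy-free trees", {
  gm <- gen_matrix(8, 40, changes_per_char = 1, seed = 5)
  r1 <- heuristic_search(gm$matrix, replicates = 3, swap = "tbr",
                         hold = 10, seed = 2)
  r2 <- heuristic_search(gm$matrix, replicates = 3, swap = "tbr",
                         hold = 10, seed = 2)
  expect_equal(r1$length, r2$length)
  expect_equal(lapply(r1$best_trees, ape::write.tree),
               lapply(r2$best_trees, ape::write.tree))
  # length equals the sum of per-character minima; true topology found
  expect_equal(r1$length, sum(char_min_steps(gm$matrix)))
  keys <- vapply(r1$best_trees, topo_key, character(1),
                 taxa = gm$matrix$taxa)
  expect_true(topo_key(gm$tree, gm$matrix$taxa) %in% keys)
  expect_equal(r1$ci, 1)
})

test_that("SPR and TBR neighborhoods are valid and complete at small n", {
  tr <- random_topology(letters[1:6])
  ut <- morphoclade:::utree_from_phylo(tr, letters[1:6])
  valid <- function(u) {
    deg <- vapply(u$adj, length, integer(1))
    all(deg[1:6] %in% c(0L, 1L)) && all(deg[-(1:6)] %in% c(0L, 3L))
  }
  ns <- morphoclade:::spr_neighbors(ut)
  nt <- morphoclade:::tbr_neighbors(ut)
  expect_true(all(vapply(ns, valid, logical(1))))
  expect_true(all(vapply(nt, valid, logical(1))))
  # distinct unrooted SPR neighborhood size is 2(n-3)(2n-7) = 30 at n=6
  expect_equal(length(ns), 30L)
  expect_gte(length(nt), length(ns))
  # TBR from any start can reach the global optimum of a clean matrix
  gm <- gen_matrix(6, 20, changes_per_char = 1, seed = 9)
  res <- heuristic_search(gm$matrix, replicates = 2, swap = "tbr",
                          hold = 5, seed = 3)
  exhaustive_best <- min(vapply(all_topo_phylo(gm$matrix$taxa),
                                function(t) fitch_length(t, gm$matrix),
                                numeric(1)))
  expect_equal(res$length, exhaustive_best)
})

test_that("bootstrap gives 100% to a universally supported split and is deterministic", {
  M <- character_matrix(matrix(rep(c("0", "0", "1", "1"), 20), 4, 20,
                               dimnames = list(c("A", "B", "C", "D"), NULL)))
  bs <- bootstrap_support(M, reps = 25, replicates = 1, swap = "spr",
                          hold = 3, seed = 4)
  expect_equal(bs$splits$bootstrap[bs$splits$split == 12L], 100)
  bs2 <- bootstrap_support(M, reps = 25, replicates = 1, swap = "spr",
                           hold = 3, seed = 4)
  expect_identical(bs$splits, bs2$splits)
})

test_that("stronger character support gives strictly higher bootstrap", {
  # 6 taxa: clade (a,b) supported by 10 characters, clade (c,d) by 1
  taxa <- letters[1:6]
  strong <- matrix(rep(c("1", "1", "0", "0", "0", "0"), 10), 6, 10)
  weak <- matrix(c("0", "0", "1", "1", "0", "0"), 6, 1)
  filler <- matrix(rep(c("1", "0", "0", "0", "0", "0"), 2), 6, 2)
  M <- character_matrix(cbind(strong, weak, filler),
                        taxa = taxa)
  bs <- bootstrap_support(M, reps = 100, replicates = 1, swap = "spr",
                          hold = 2, seed = 6)
  # split keys are normalized to the side not containing the first taxon
  norm_split <- function(idx, n) {
    s <- sum(bitwShiftL(1L, idx - 1L))
    full <- bitwShiftL(1L, n) - 1L
    if (bitwAnd(s, 1L) == 1L) bitwAnd(bitwXor(s, full), full) else s
  }
  sup <- function(key) {
    i <- match(key, bs$splits$split)
    if (is.na(i)) 0 else bs$splits$bootstrap[i]
  }
  expect_gt(sup(norm_split(1:2, 6)), sup(norm_split(3:4, 6)))
})

test_that("Bremer decay matches exhaustive enumeration on five taxa", {
  taxa <- c("A", "B", "C", "D", "E")
  M <- character_matrix(matrix(c(
    "1", "1", "0", "0", "0",
    "1", "1", "0", "0", "0",
    "1", "1", "0", "0", "0",
    "0", "0", "1", "1", "0"), 5, 4), taxa = taxa)
  res <- heuristic_search(M, replicates = 5, swap = "tbr", hold = 10,
                          seed = 1)
  br <- bremer_support(M, res, seed = 2)
  s_ab <- sum(bitwShiftL(1L, c(0, 1)))  # encoded on the non-A side below
  # exhaustive oracle over all 15 unrooted topologies
  L <- res$length
  topos <- all_topo_phylo(taxa)
  lens <- vapply(topos, function(t) fitch_length(t, M), numeric(1))
  for (k in seq_len(nrow(br$splits))) {
    s <- br$splits$split[k]
    lacking <- vapply(topos, function(t) !(s %in% tree_splits(t, taxa)),
                      logical(1))
    expect_equal(br$splits$bremer[k], min(lens[lacking]) - L)
  }
  # the clade with three uncontradicted characters decays at 3
  lab3 <- br$splits$label[br$splits$bremer == 3]
  expect_match(lab3, "A B")
  # at L+1 no tree lacking that clade exists -> decay >= 2 consistency
  s3 <- br$splits$split[br$splits$bremer == 3]
  lacking3 <- vapply(topos, function(t) !(s3 %in% tree_splits(t, taxa)),
                     logical(1))
  expect_true(all(lens[lacking3] > L + 1))
})

test_that("requesting Bremer for a clade outside the consensus errors", {
  gm <- gen_matrix(6, 20, changes_per_char = 1, seed = 11)
  res <- heuristic_search(gm$matrix, replicates = 2, swap = "spr",
                          hold = 5, seed = 1)
  all_splits <- 0:(2^6 - 1)
  cons <- Reduce(intersect, lapply(res$best_trees, tree_splits,
                                   taxa = gm$matrix$taxa))
  absent <- setdiff(c(6L, 20L, 24L), cons)[1]
  expect_error(bremer_support(gm$matrix, res, clades = absent),
               "not in the strict consensus")
})
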