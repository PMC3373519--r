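dm <- function(x, taxa) {
  character_matrix(matrix(x, length(taxa), length(x) / length(taxa),
                          dimnames = list(taxa, NULL)))
}

test_that("Fitch length matches hand-worked four-taxon cases", {
  taxa <- c("A", "B", "C", "D")
  M <- dm(c("0", "0", "1", "1"), taxa)
  t_ab <- ape::read.tree(text = "((A,B),(C,D));")
  t_ac <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(fitch_length(t_ab, M), 1)
  expect_equal(fitch_length(t_ac, M), 2)
  # constant character costs nothing on any tree
  Mc <- dm(rep("1", 4), taxa)
  expect_equal(fitch_length(t_ab, Mc), 0)
  expect_equal(fitch_length(t_ac, Mc), 0)
  expect_error(fitch_length(ape::read.tree(text = "((A,B),(C,E));"), M),
               "differ")
})

test_that("Fitch equals brute-force minimization on random small trees", {
  set.seed(99)
  for (i in 1:20) {
    n <- sample(4:6, 1)
    gm <- gen_matrix(n, n_characters = 4, n_states = sample(2:4, 1),
                     changes_per_char = sample(1:3, 1),
                     missing_fraction = 0.15, seed = 1000 + i)
    for (tr in list(gm$tree, random_topology(gm$matrix$taxa))) {
      expect_equal(fitch_length(tr, gm$matrix),
                   oracle_tree_length(tr, gm$matrix))
    }
  }
})

test_that("length is invariant to rooting and taxon input order", {
  gm <- gen_matrix(7, 15, n_states = 3, changes_per_char = 2, seed = 14)
  tr <- gm$tree
  L <- fitch_length(tr, gm$matrix)
  for (tx in gm$matrix$taxa) {
    rerooted <- ape::root(ape::unroot(tr), outgroup = tx,
                          resolve.root = TRUE)
    expect_equal(fitch_length(rerooted, gm$matrix), L)
  }
  # permute matrix rows
  perm <- sample(7)
  Mp <- character_matrix(gm$matrix$mask[perm, ],
                         taxa = gm$matrix$taxa[perm])
  expect_equal(fitch_length(tr, Mp), L)
})

test_that("per-character min and max steps follow their definitions", {
  taxa <- letters[1:4]
  expect_equal(char_min_steps(dm(c("0", "0", "1", "1"), taxa)), 1)
  expect_equal(char_max_steps(dm(c("0", "0", "1", "1"), taxa)), 2)
  t5 <- letters[1:5]
  M5 <- dm(c("0", "1", "2", "2", "2"), t5)
  expect_equal(char_min_steps(M5), 2)
  expect_equal(char_max_steps(M5), 2)
  # bush-tree brute force for the max: worst binary tree length equals g
  worst <- max(vapply(all_topo_phylo(t5), function(tr)
    fitch_length(tr, M5), numeric(1)))
  expect_equal(worst, char_max_steps(M5))
  # effectively constant characters (second column keeps rows scored)
  Mq <- dm(c("0", "?", "0", "?", "1", "1", "0", "0"), taxa)
  expect_equal(char_min_steps(Mq, 1), 0)
  expect_equal(char_max_steps(Mq, 1), 0)
})

test_that("CI and RI match hand computation and are 1 without homoplasy", {
  taxa <- c("A", "B", "C", "D")
  M <- dm(c("0", "0", "1", "1", "0", "1", "0", "1"), taxa)
  st <- ci_ri(ape::read.tree(text = "((A,B),(C,D));"), M)
  expect_equal(st$length, 3)
  expect_equal(st$ci, 2 / 3, tolerance = 1e-12)
  expect_equal(st$ri, 0.5, tolerance = 1e-12)

  gm <- gen_matrix(8, 30, changes_per_char = 1, seed = 4)
  st2 <- ci_ri(gm$tree, gm$matrix)
  expect_equal(st2$ci, 1)
  expect_equal(st2$ri, 1)

  # adding a constant character never changes the length
  Mplus <- character_matrix(cbind(gm$matrix$mask, 1L),
                            taxa = gm$matrix$taxa)
  expect_equal(fitch_length(gm$tree, Mplus), st2$length)

  # no informative character: RI undefined
  Mu <- dm(c("0", "0", "0", "1"), taxa)
  expect_true(is.na(ci_ri(ape::read.tree(text = "((A,B),(C,D));"), Mu)$ri))
})

test_that("ordered characters are scored additively", {
  taxa <- c("A", "B", "C", "D")
  M <- character_matrix(matrix(c("0", "0", "2", "2"), 4, 1,
                               dimnames = list(taxa, NULL)),
                        ordered = TRUE)
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(fitch_length(tr, M), 2)  # 0 -> 2 costs two steps
  expect_equal(char_min_steps(M), 2)
  Mu <- character_matrix(M$mask, taxa = taxa)  # unordered: one step
  expect_equal(fitch_length(tr, Mu), 1)
})
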