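test_that("transition costs count areas added plus areas deleted", {
  ar <- c("A", "B", "C")
  expect_equal(transition_cost("A", c("A", "B"), areas = ar), 1)
  expect_equal(transition_cost(c("A", "B"), "C", areas = ar), 3)
  expect_equal(transition_cost(c("A", "C"), c("A", "C"), areas = ar), 0)
  expect_error(transition_cost(character(0), "A", areas = ar))
})

test_that("split scenarios: duplication for single areas, all bipartitions otherwise", {
  ar <- c("A", "B", "C")
  s1 <- split_scenarios("A", areas = ar)
  expect_length(s1, 1)
  expect_equal(s1[[1]]$left, s1[[1]]$right)
  expect_length(split_scenarios(c("A", "B"), areas = ar), 1)
  expect_length(split_scenarios(c("A", "B", "C"), areas = ar), 3)
  # 2^(k-1) - 1 bipartitions for k = 4 (bitmask input)
  expect_length(split_scenarios(15L), 7)
  # restricted variant: one daughter confined to a single area
  s3 <- split_scenarios(c("A", "B", "C"), areas = ar,
                        single_area_split = TRUE)
  expect_true(all(vapply(s3, function(p)
    min(morphoclade:::.popcount(p$left),
        morphoclade:::.popcount(p$right)) == 1L, logical(1))))
})

test_that("textbook reconstructions come out exactly", {
  # free vicariance of sister singletons
  tr2 <- ape::read.tree(text = "(X,Y);")
  dv2 <- diva_reconstruct(tr2, list(X = "A", Y = "B"))
  expect_equal(dv2$cost, 0L)
  expect_equal(dv2$node_optima[[1]], "A+B")

  # uniform terminals stay put at zero cost
  tr3 <- ape::read.tree(text = "((X,Y),(Z,W));")
  dv3 <- diva_reconstruct(tr3, list(X = "A", Y = "A", Z = "A", W = "A"),
                          areas = c("A", "B"))
  expect_equal(dv3$cost, 0L)
  expect_true(all(unlist(dv3$node_optima) == "A"))

  # ((X:A, Y:A), Z:B): widespread root at zero cost
  tr <- ape::read.tree(text = "((X,Y),Z);")
  dv <- diva_reconstruct(tr, list(X = "A", Y = "A", Z = "B"))
  expect_equal(dv$cost, 0L)
  root_opt <- dv$node_optima[[as.character(length(tr$tip.label) + 1L)]]
  expect_equal(root_opt, "A+B")

  expect_error(diva_reconstruct(ape::read.tree(text = "(X,Y,Z);"),
                                list(X = "A", Y = "A", Z = "B")),
               "binary|rooted")
})

test_that("DP cost and optimal node sets equal exhaustive enumeration", {
  set.seed(123)
  for (i in 1:20) {
    n <- sample(3:5, 1)
    na <- sample(2:3, 1)
    areas <- LETTERS[seq_len(na)]
    tr <- random_topology(paste0("t", seq_len(n)))
    rg <- lapply(seq_len(n), function(j)
      sample(areas, sample.int(na, 1)))
    names(rg) <- tr$tip.label
    dv <- diva_reconstruct(tr, rg, areas = areas)
    oc <- oracle_diva(tr, rg, areas)
    expect_equal(dv$cost, oc$cost)
    for (k in seq_len(tr$Nnode)) {
      expect_equal(sort(as.integer(dv$node_bits[[n + k]])),
                   oc$opt[[k]])
    }
  }
})

test_that("simulated histories bound the inferred cost", {
  for (s in 1:8) {
    h0 <- gen_ranges(6, n_areas = 3, n_dispersals = 0, n_extinctions = 0,
                     seed = 300 + s)
    dv0 <- diva_reconstruct(h0$tree, h0$ranges, areas = h0$areas)
    expect_equal(dv0$cost, 0L)

    k <- sample(1:3, 1)
    hk <- gen_ranges(6, n_areas = 4, n_dispersals = k, seed = 400 + s)
    dvk <- diva_reconstruct(hk$tree, hk$ranges, areas = hk$areas)
    expect_lte(dvk$cost, k)
  }
})

test_that("restricting maxareas never lowers the optimal cost", {
  for (s in 1:5) {
    h <- gen_ranges(6, n_areas = 4, n_dispersals = 2, n_extinctions = 1,
                    seed = 500 + s)
    sizes <- vapply(h$ranges, length, integer(1))
    costs <- vapply(max(sizes):4, function(ma)
      diva_reconstruct(h$tree, h$ranges, areas = h$areas,
                       maxareas = ma)$cost, integer(1))
    expect_true(all(diff(costs) <= 0))  # increasing maxareas can only help
  }
})

test_that("the transcribed lambeosaurine fixture reconstructs a widespread North American ancestor", {
  tr <- lambeosaurine_tree()
  rg <- lambeosaurine_areas()
  dv <- diva_reconstruct(tr, rg, areas = c("E", "AS", "NNA", "SNA"))
  # node uniting the southern (Velafrons + Magnapaulia) clade with the
  # northern helmet-crested clade
  want <- c("Velafrons_coahuilensis", "Magnapaulia_laticaudus",
            "Lambeosaurus_lambei", "Lambeosaurus_magnicristatus",
            "Corythosaurus_casuarius", "Corythosaurus_intermedius",
            "Hypacrosaurus_stebingeri", "Hypacrosaurus_altispinus",
            "Olorotitan_arharensis")
  node <- ape::getMRCA(tr, want)
  opt <- dv$node_optima[[as.character(node)]]
  expect_true("NNA+SNA" %in% opt)
})
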