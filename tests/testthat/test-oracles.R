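test_that("pair oracle reproduces hand-enumerated optima", {
  fx <- fixture_e1()
  expect_equal(exhaustive_pair_optimum(fx$ta, fx$tb, fx$cl), 6)

  # two chains: both merges are compatible (a1-b1 above a2-b2)
  ta <- chain_tree(3, "A") # a0 -> a1 -> a2
  tb <- chain_tree(3, "B")
  cl <- closeness_matrix(data.frame(a = c("a1", "a2"), b = c("b1", "b2"),
                                    s = c(1, 2)), ta, tb)
  expect_equal(exhaustive_pair_optimum(ta, tb, cl), 3)

  tx <- single_tree("x", "X")
  ty <- single_tree("y", "Y")
  cl1 <- closeness_matrix(data.frame(a = "x", b = "y", s = 4.2), tx, ty)
  expect_equal(exhaustive_pair_optimum(tx, ty, cl1), 4.2)

  big <- random_tree(12, seed = 1, id = "A")
  expect_error(exhaustive_pair_optimum(big, big, NULL), "size guard")
})

test_that("the two independent pair oracles agree on random instances", {
  # recursion-with-exhaustive-matching versus LCA-closed order-preserving
  # partial injections: structurally different derivations of the same
  # optimum, so agreement guards against a shared systematic error
  for (seed in 1:30) {
    ins <- random_pair_instance(seed, nmin = 2L, nmax = 5L)
    a <- exhaustive_pair_optimum(ins$ta, ins$tb, ins$cl)
    b <- ontofuse:::mapping_pair_optimum(ins$ta, ins$tb, ins$cl)
    expect_equal(a, b, tolerance = 1e-9)
  }
})

test_that("multi oracle matches the pairwise oracle and hand traces", {
  fx <- fixture_e2()
  expect_equal(exhaustive_multi_optimum(fx$trees, fx$matrices), 1.6)

  # all-zero matrices
  trees <- list(chain_tree(2, "A"), chain_tree(2, "B"))
  cl0 <- closeness_matrix(data.frame(a = character(0), b = character(0),
                                     s = numeric(0)), trees[[1]], trees[[2]])
  expect_equal(exhaustive_multi_optimum(trees, list(cl0)), 0)

  # k = 2 reduces to the pairwise oracle
  for (seed in 1:10) {
    set.seed(seed)
    t1 <- random_tree(sample(2:4, 1), seed = NULL, id = "T1")
    t2 <- random_tree(sample(2:4, 1), seed = NULL, id = "T2")
    cl <- random_closeness(t1, t2, seed = NULL)
    expect_equal(exhaustive_multi_optimum(list(t1, t2), list(cl)),
                 exhaustive_pair_optimum(t1, t2, cl), tolerance = 1e-9)
  }

  expect_error(exhaustive_multi_optimum(
    list(random_tree(9, 1, "A"), random_tree(9, 2, "B"),
         random_tree(9, 3, "D")), list()), "size guard")
})

test_that("criterion-1 validator flags a wrong-branch merge", {
  # disease taxonomy style: two leaves whose true common ancestor is the
  # root are forced under the same deep branch in a corrupted integration
  src <- ontology_tree(data.frame(
    child = c("cancer", "infection", "thyroid_ca", "flu"),
    parent = c("disease", "disease", "cancer", "infection")), id = "S")
  other <- ontology_tree(data.frame(
    child = c("o_cancer", "o_thyroid"),
    parent = c("o_root", "o_cancer")), id = "O")
  # corrupt merged tree: infection placed below the cancer node, so
  # LCA(thyroid_ca, flu) lands in the cancer node, not the disease node
  merged_tree <- ontology_tree(data.frame(
    child = c("m_dis", "m_ca", "m_inf", "m_thy", "m_flu"),
    parent = c("m_root", "m_dis", "m_ca", "m_ca", "m_inf")), id = "bad")
  members <- tibble::tibble(
    node = c("m_dis", "m_ca", "m_ca", "m_inf", "m_thy", "m_thy", "m_flu",
             "m_root"),
    ontology = c("S", "S", "O", "S", "S", "O", "S", "O"),
    term = c("disease", "cancer", "o_cancer", "infection", "thyroid_ca",
             "o_thyroid", "flu", "o_root"))
  bad <- ontofuse:::new_integrated_ontology(
    tree = merged_tree, members = members,
    node_weight = stats::setNames(numeric(6), merged_tree$term),
    sources = c("O", "S"), total_cohesion = 0)
  rep <- validate_criterion1(bad, list(src, other))
  expect_gt(nrow(rep), 0)
  expect_true(any(rep$x == "thyroid_ca" | rep$y == "thyroid_ca"))

  # the two source trees intact under one root are always valid
  fx <- fixture_e1()
  cl0 <- closeness_matrix(data.frame(a = character(0), b = character(0),
                                     s = numeric(0)), fx$ta, fx$tb)
  clean <- integrate_pair(fx$ta, fx$tb, cl0)
  expect_equal(nrow(validate_criterion1(clean, list(fx$ta, fx$tb))), 0)

  # missing vertices are an error, not a silent pass
  expect_error(validate_criterion1(clean, list(chain_tree(5, "A"))),
               "missing vertex")
})

test_that("maximum spanning tree weight matches direct enumeration", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.9
  w[1, 3] <- w[3, 1] <- 0.2
  w[2, 3] <- w[3, 2] <- 0.5
  expect_equal(max_spanning_tree_weight(w), 1.4)
  w2 <- matrix(c(0, 3, 3, 0), 2, 2)
  expect_equal(max_spanning_tree_weight(w2), 3)
  k <- 5
  wu <- matrix(0.25, k, k); diag(wu) <- 0
  expect_equal(max_spanning_tree_weight(wu), (k - 1) * 0.25)
  expect_equal(max_spanning_tree_weight(matrix(0, 4, 4)), 0)
  expect_error(max_spanning_tree_weight(matrix(0, 1, 1)), "two nodes")
})
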