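test_that("three single-vertex ontologies merge into one weighted node", {
  fx <- fixture_e2()
  for (s in c("basic", "greedy", "fast")) {
    r <- integrate_multi(fx$trees, fx$matrices, strategy = s,
                         matcher = "optimal")
    expect_equal(r$total_cohesion, 1.6, tolerance = 1e-12)
    expect_equal(cohesion_of(r, fx$matrices), 1.6, tolerance = 1e-12)
    td <- tidy(r)
    expect_equal(max(td$n_members), 3) # x, y, z share one node
  }
  # fast contracts the 0.9 edge first; the surviving stale edge is
  # max(0.2, 0.5) and the spanning-tree bound is 0.9 + 0.5
  rf <- fast_multi_integrate(fx$trees, fx$matrices, matcher = "optimal")
  w0 <- attr(rf, "initial_pair_scores")
  expect_equal(sort(w0[upper.tri(w0)]), c(0.2, 0.5, 0.9))
  expect_equal(max_spanning_tree_weight(w0), 1.4)
  expect_gte(rf$total_cohesion, 1.4)
})

test_that("merged-node closeness sums member contributions", {
  fx <- fixture_e2()
  r12 <- integrate_pair(fx$trees$T1, fx$trees$T2,
                        fx$matrices[[1]], matcher = "optimal")
  mc <- merge_closeness(r12, fx$matrices, fx$trees$T3)
  # the {x,y} node relates to z with 0.2 + 0.5; singleton/virtual rows are 0
  expect_equal(sort(unname(mc$m[, "z"])), c(0, 0.7))
  expect_equal(sum(mc$m), 0.7)

  # a singleton node passes its single member's scores through
  t1 <- chain_tree(2, "A")
  t2 <- single_tree("y", "B")
  cl <- closeness_matrix(data.frame(a = c("a0", "a1"), b = c("y", "y"),
                                    s = c(0.3, 0)), t1, t2)
  mc2 <- merge_closeness(t1, list(cl), t2)
  expect_equal(unname(mc2$m[, "y"]), c(0.3, 0))
})

test_that("adjusted cohesion divides the weight increase by |X||Y|", {
  fx <- fixture_e2()
  # singleton ontologies: adjusted equals the raw pairwise score
  expect_equal(adjusted_cohesion(fx$trees$T1, fx$trees$T2, fx$matrices,
                                 matcher = "optimal"), 0.9)
  r12 <- integrate_pair(fx$trees$T1, fx$trees$T2, fx$matrices[[1]],
                        matcher = "optimal")
  # weight increase 0.7 with |X| = 2, |Y| = 1
  expect_equal(adjusted_cohesion(r12, fx$trees$T3, fx$matrices,
                                 matcher = "optimal"), 0.35)
  expect_error(adjusted_cohesion(r12, fx$trees$T1, fx$matrices), "overlap")
  # zero cross closeness
  ta <- single_tree("p", "P")
  tb <- single_tree("q", "Q")
  cl0 <- closeness_matrix(data.frame(a = character(0), b = character(0),
                                     s = numeric(0)), ta, tb)
  expect_equal(adjusted_cohesion(ta, tb, list(cl0)), 0)
})

test_that("k = 2 multi-integration reduces to pairwise integration", {
  for (seed in c(5, 23)) {
    set.seed(seed)
    t1 <- random_tree(6, seed = NULL, id = "T1")
    t2 <- random_tree(5, seed = NULL, id = "T2")
    cl <- random_closeness(t1, t2, seed = NULL)
    ref <- integrate_pair(t1, t2, cl, matcher = "greedy")
    for (s in c("basic", "greedy", "fast")) {
      r <- integrate_multi(list(t1, t2), list(cl), strategy = s)
      expect_equal(r$total_cohesion, ref$total_cohesion, tolerance = 1e-12)
      expect_equal(tidy(r)$members, tidy(ref)$members)
    }
  }
  expect_error(integrate_multi(list(chain_tree(2)), list()), "length")
})

test_that("all-zero matrices join the forest under one root at cohesion 0", {
  trees <- list(chain_tree(3, "A"), star_tree(2, "B"), chain_tree(2, "D"))
  mats <- list()
  combs <- utils::combn(3, 2)
  for (ci in seq_len(ncol(combs))) {
    i <- combs[1, ci]; j <- combs[2, ci]
    mats <- c(mats, list(closeness_matrix(
      data.frame(a = character(0), b = character(0), s = numeric(0)),
      trees[[i]], trees[[j]])))
  }
  for (s in c("basic", "greedy", "fast")) {
    r <- integrate_multi(trees, mats, strategy = s)
    expect_equal(r$total_cohesion, 0)
    expect_equal(sum(tidy(r)$n_members > 1), 0)
    expect_equal(nrow(validate_criterion1(r, trees)), 0)
  }
})

test_that("fast contraction starts from the dominant edge", {
  # star-shaped score graph: AB dominates, so A and B contract first
  ta <- single_tree("a", "A")
  tb <- single_tree("b", "B")
  tc <- single_tree("d", "D")
  mk <- function(t1, t2, w) {
    closeness_matrix(data.frame(x = t1$term, y = t2$term, s = w), t1, t2)
  }
  mats <- list(mk(ta, tb, 5), mk(ta, tc, 1), mk(tb, tc, 1))
  r <- fast_multi_integrate(list(ta, tb, tc), mats, matcher = "optimal")
  td <- tidy(r)
  merged2 <- td$members[td$n_members >= 2]
  expect_true(any(grepl("A:a", merged2) & grepl("B:b", merged2)))
  expect_equal(r$total_cohesion, 5 + 2) # d then joins the {a,b} node
})

test_that("multi-integration satisfies structural invariants at scale", {
  bs <- benchmark_suite(k = 4, n = 15, replicates = 2, seed = 77)
  for (inst in bs) {
    for (s in c("basic", "greedy", "fast")) {
      r <- integrate_multi(inst$trees, inst$matrices, strategy = s)
      expect_equal(nrow(validate_criterion1(r, inst$trees)), 0)
      expect_equal(cohesion_of(r, inst$matrices), r$total_cohesion,
                   tolerance = 1e-9)
      per <- table(r$members$node, r$members$ontology)
      expect_true(all(per <= 1))
    }
    # the fast result respects the spanning-tree lower bound
    rf <- fast_multi_integrate(inst$trees, inst$matrices)
    expect_gte(rf$total_cohesion,
               max_spanning_tree_weight(attr(rf, "initial_pair_scores")) - 1e-9)
  }
})
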