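shared_example <- data.frame(left = c("a1", "a1", "a2"),
                             right = c("b1", "b2", "b2"),
                             weight = c(2, 4, 3))

test_that("greedy maximal matching takes heaviest-first and blocks endpoints", {
  res <- greedy_maximal_matching(shared_example)
  expect_equal(res$total, 4) # (a1,b2) blocks both remaining edges
  expect_equal(nrow(res$pairs), 1)
  expect_equal(res$pairs$left, "a1")
  expect_equal(res$pairs$right, "b2")

  expect_equal(greedy_maximal_matching(shared_example[0, ])$total, 0)

  disjoint <- data.frame(left = c("a1", "a2"), right = c("b1", "b2"),
                         weight = c(3, 3))
  expect_equal(greedy_maximal_matching(disjoint)$total, 6)

  # zero-weight edges are never taken
  with_zero <- data.frame(left = "a1", right = "b1", weight = 0)
  expect_equal(nrow(greedy_maximal_matching(with_zero)$pairs), 0)

  expect_error(greedy_maximal_matching(
    data.frame(left = "a", right = "b", weight = -1)), "negative")
  expect_error(greedy_maximal_matching(
    data.frame(left = c("a", "a"), right = c("b", "b"), weight = c(1, 2))),
    "duplicate")
})

test_that("optimal matching attains the enumerated maximum", {
  expect_equal(optimal_matching(shared_example)$total, 5) # (a1,b1)+(a2,b2)
  expect_equal(optimal_matching(
    data.frame(left = "a", right = "b", weight = 7))$total, 7)
  square <- data.frame(left = c("a1", "a2", "a1", "a2"),
                       right = c("b1", "b2", "b2", "b1"),
                       weight = c(1, 1, 1, 1))
  expect_equal(optimal_matching(square)$total, 2) # any perfect matching
  ones3 <- expand.grid(left = c("a1", "a2", "a3"),
                       right = c("b1", "b2", "b3"))
  ones3$weight <- 1
  expect_equal(exhaustive_matching(ones3)$total, 3)
})

test_that("optimal and exhaustive totals agree on random edge sets", {
  for (seed in 1:150) {
    e <- random_edge_set(seed)
    expect_equal(optimal_matching(e)$total, exhaustive_matching(e)$total,
                 tolerance = 1e-12)
  }
})

test_that("greedy matching is a 1/2-approximation on every instance", {
  worst <- 1
  for (seed in 1:1000) {
    e <- random_edge_set(seed, la = 3L + seed %% 3L, lb = 3L + seed %% 4L)
    opt <- optimal_matching(e)$total
    if (opt == 0) next
    r <- greedy_maximal_matching(e)$total / opt
    worst <- min(worst, r)
    expect_gte(r, 0.5)
  }
  expect_lt(worst, 1) # the bound is actually exercised, not vacuous
})

test_that("adding an edge never decreases the optimal total", {
  for (seed in 1:40) {
    e <- random_edge_set(seed, la = 4L, lb = 4L)
    base <- optimal_matching(e)$total
    set.seed(seed + 5000)
    extra <- data.frame(left = "Lnew", right = "Rnew",
                        weight = stats::runif(1))
    expect_gte(optimal_matching(rbind(e, extra))$total, base)
  }
})

test_that("matching results are internally consistent", {
  for (seed in 1:30) {
    e <- random_edge_set(seed)
    for (f in list(greedy_maximal_matching, optimal_matching,
                   exhaustive_matching)) {
      res <- f(e)
      expect_equal(res$total, sum(res$pairs$weight))
      expect_false(anyDuplicated(res$pairs$left) > 0)
      expect_false(anyDuplicated(res$pairs$right) > 0)
      if (nrow(res$pairs)) {
        key_in <- paste(e$left, e$right)
        expect_true(all(paste(res$pairs$left, res$pairs$right) %in% key_in))
      }
    }
  }
})

test_that("the exhaustive matcher refuses oversized instances", {
  big <- expand.grid(left = sprintf("L%02d", 1:12),
                     right = sprintf("R%02d", 1:12))
  big$weight <- 1
  expect_error(exhaustive_matching(big), "size guard")
})
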