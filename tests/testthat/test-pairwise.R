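test_that("cohesion matrix entries match the hand-traced fixture", {
  fx <- fixture_e1()
  cm <- build_cohesion_matrix(fx$ta, fx$tb, fx$cl, matcher = "optimal")
  expect_equal(cm["a1", "b2"], 4)
  # merge case: M(a0,b0)=1 + optimal child matching (a1,b1)+(a2,b2)=5
  expect_equal(cm["a0", "b0"], 6)
  expect_equal(cm["<virtual>", "<virtual>"], 6)

  # greedy child matching keeps only (a1,b2)
  cmg <- build_cohesion_matrix(fx$ta, fx$tb, fx$cl, matcher = "greedy")
  expect_equal(cmg["a0", "b0"], 5)
  expect_equal(cmg["<virtual>", "<virtual>"], 5)

  # leaf base case: two single-vertex trees
  tx <- single_tree("x", "X")
  ty <- single_tree("y", "Y")
  clxy <- closeness_matrix(data.frame(a = "x", b = "y", s = 2.5), tx, ty)
  cm1 <- build_cohesion_matrix(tx, ty, clxy, matcher = "optimal")
  expect_equal(cm1["<virtual>", "<virtual>"], 2.5)
})

test_that("cohesion matrix dominance invariants hold on random instances", {
  for (seed in 1:20) {
    ins <- random_pair_instance(seed)
    for (m in c("greedy", "optimal")) {
      cm <- build_cohesion_matrix(ins$ta, ins$tb, ins$cl, matcher = m)
      M <- ins$cl$m
      na <- length(ins$ta$term)
      nb <- length(ins$tb$term)
      inner <- cm[-1, -1, drop = FALSE]
      expect_true(all(inner >= M - 1e-12)) # entry >= own closeness
      for (i in seq_len(na)) { # entry >= any child entry, either side
        for (ch in ins$ta$children[[i]]) {
          expect_true(all(cm[i + 1, ] >= cm[ch + 1, ] - 1e-12))
        }
      }
      expect_true(all(cm[1, 1] >= cm - 1e-12)) # whole problem dominates
    }
  }
})

test_that("compiled and reference DP agree for the greedy matcher", {
  for (seed in 1:25) {
    ins <- random_pair_instance(seed, nmin = 2L, nmax = 12L)
    cpp <- build_cohesion_matrix(ins$ta, ins$tb, ins$cl,
                                 matcher = "greedy", engine = "cpp")
    ref <- build_cohesion_matrix(ins$ta, ins$tb, ins$cl,
                                 matcher = "greedy", engine = "r")
    expect_equal(unclass(cpp), unclass(ref), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("reconstruction reproduces fixture integrations exactly", {
  fx <- fixture_e1()
  io <- integrate_pair(fx$ta, fx$tb, fx$cl, matcher = "optimal")
  expect_equal(io$total_cohesion, 6)
  td <- tidy(io)
  expect_equal(nrow(td), 4) # virtual root + three merged pairs
  expect_setequal(td$members,
                  c("", "A:a0,B:b0", "A:a1,B:b1", "A:a2,B:b2"))

  iog <- integrate_pair(fx$ta, fx$tb, fx$cl, matcher = "greedy")
  expect_equal(iog$total_cohesion, 5)
  tdg <- tidy(iog)
  expect_equal(nrow(tdg), 5) # a2 and b1 stay singletons
  expect_setequal(tdg$members,
                  c("", "A:a0,B:b0", "A:a1,B:b2", "A:a2", "B:b1"))

  # all-zero closeness: both trees hang intact under the virtual root
  cl0 <- closeness_matrix(data.frame(a = character(0), b = character(0),
                                     s = numeric(0)), fx$ta, fx$tb)
  io0 <- integrate_pair(fx$ta, fx$tb, cl0, matcher = "optimal")
  expect_equal(io0$total_cohesion, 0)
  expect_equal(sum(tidy(io0)$n_members > 1), 0)
  expect_equal(nrow(tidy(io0)), 7) # root + 3 + 3 singletons
})

test_that("reconstruction totals equal entry (0,0) for both matchers", {
  for (seed in 1:30) {
    ins <- random_pair_instance(seed)
    for (m in c("greedy", "optimal")) {
      cm <- build_cohesion_matrix(ins$ta, ins$tb, ins$cl, matcher = m,
                                  engine = "r")
      io <- build_integrated_ontology(cm, ins$ta, ins$tb, ins$cl)
      expect_equal(io$total_cohesion, cm[1, 1], tolerance = 1e-9)
      expect_equal(cohesion_of(io, list(ins$cl)), cm[1, 1], tolerance = 1e-9)
      expect_equal(nrow(validate_criterion1(io, list(ins$ta, ins$tb))), 0)
    }
  }
})

test_that("integrations cover every source vertex exactly once", {
  for (seed in c(3, 17, 42)) {
    ins <- random_pair_instance(seed, nmin = 5L, nmax = 12L)
    for (m in c("greedy", "optimal")) {
      io <- integrate_pair(ins$ta, ins$tb, ins$cl, matcher = m,
                           engine = if (m == "greedy") "auto" else "r")
      for (src in list(ins$ta, ins$tb)) {
        mem <- io$members[io$members$ontology == src$id, ]
        expect_setequal(mem$term, src$term)
        expect_equal(anyDuplicated(mem$term), 0)
      }
      # at most one member per source per node
      per <- table(io$members$node, io$members$ontology)
      expect_true(all(per <= 1))
    }
  }
})

test_that("raising one closeness entry never lowers the optimum", {
  for (seed in 1:15) {
    ins <- random_pair_instance(seed, nmin = 2L, nmax = 5L)
    base <- build_cohesion_matrix(ins$ta, ins$tb, ins$cl,
                                  matcher = "optimal")[1, 1]
    set.seed(seed)
    m2 <- ins$cl$m
    cell <- sample(length(m2), 1)
    m2[cell] <- m2[cell] + stats::runif(1)
    cl2 <- ontofuse:::new_closeness_matrix(m2, "A", "B")
    bumped <- build_cohesion_matrix(ins$ta, ins$tb, cl2,
                                    matcher = "optimal")[1, 1]
    expect_gte(bumped, base - 1e-12)
  }
})

test_that("the heuristic follows the depth-regularised greedy choice", {
  fx <- fixture_e1()
  hz <- heuristic_integrate(fx$ta, fx$tb, fx$cl, beta = 1)
  expect_equal(hz$total_cohesion, 5) # a0-b0 (1) then a1-b2 (4); a2 starves
  td <- tidy(hz)
  expect_setequal(td$members,
                  c("", "A:a0,B:b0", "A:a1,B:b2", "A:a2", "B:b1"))
  expect_equal(nrow(validate_criterion1(hz, list(fx$ta, fx$tb))), 0)

  # beta = Inf confines merges to the shallowest allowable candidates:
  # a1 must take b1 or b2 (depth 1 ties resolved to b1 by index) and a
  # deep-but-heavy candidate is ignored
  ta <- chain_tree(3, "A") # a0 -> a1 -> a2
  tb <- chain_tree(3, "B")
  cl <- closeness_matrix(
    data.frame(a = c("a0", "a1", "a1"), b = c("b0", "b2", "b1"),
               s = c(1, 100, 0.1)), ta, tb)
  hinf <- heuristic_integrate(ta, tb, cl, beta = Inf)
  tdinf <- tidy(hinf)
  expect_true("A:a1,B:b1" %in% tdinf$members) # shallow b1 despite b2's 100
  h1 <- heuristic_integrate(ta, tb, cl, beta = 1)
  expect_true("A:a1,B:b2" %in% tidy(h1)$members) # depth ignored: takes 100

  # all-zero closeness never merges
  cl0 <- closeness_matrix(data.frame(a = character(0), b = character(0),
                                     s = numeric(0)), ta, tb)
  h0 <- heuristic_integrate(ta, tb, cl0)
  expect_equal(h0$total_cohesion, 0)
  expect_equal(sum(tidy(h0)$n_members > 1), 0)

  expect_error(heuristic_integrate(ta, tb, cl, beta = 0.5), "beta")
})

test_that("heuristic results are LCA-preserving on random instances", {
  for (seed in 1:20) {
    ins <- random_pair_instance(seed, nmin = 3L, nmax = 10L)
    for (beta in c(1, 6, 100)) {
      hz <- heuristic_integrate(ins$ta, ins$tb, ins$cl, beta = beta)
      expect_equal(nrow(validate_criterion1(hz, list(ins$ta, ins$tb))), 0)
      expect_equal(cohesion_of(hz, list(ins$cl)), hz$total_cohesion,
                   tolerance = 1e-9)
      # the heuristic can never beat the optimal DP
      opt <- build_cohesion_matrix(ins$ta, ins$tb, ins$cl,
                                   matcher = "optimal")[1, 1]
      expect_lte(hz$total_cohesion, opt + 1e-9)
    }
  }
})
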