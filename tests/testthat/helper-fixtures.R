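# shared fixtures built in code

# two three-vertex stars with one dominant cross edge; the optimal
# integration merges all three pairs (total 6), the greedy matcher keeps
# only the heaviest child pair (total 5)
fixture_e1 <- function() {
  ta <- ontology_tree(data.frame(child = c("a1", "a2"),
                                 parent = c("a0", "a0")), id = "A")
  tb <- ontology_tree(data.frame(child = c("b1", "b2"),
                                 parent = c("b0", "b0")), id = "B")
  cl <- closeness_matrix(
    data.frame(term_a = c("a0", "a1", "a2", "a1"),
               term_b = c("b0", "b1", "b2", "b2"),
               score = c(1, 2, 3, 4)),
    ta, tb)
  list(ta = ta, tb = tb, cl = cl)
}

# three single-vertex ontologies whose best joint integration merges all
# three terms into one node of weight 0.9 + 0.2 + 0.5 = 1.6
fixture_e2 <- function() {
  tx <- single_tree("x", "T1")
  ty <- single_tree("y", "T2")
  tz <- single_tree("z", "T3")
  list(
    trees = list(T1 = tx, T2 = ty, T3 = tz),
    matrices = list(
      closeness_matrix(data.frame(a = "x", b = "y", s = 0.9), tx, ty),
      closeness_matrix(data.frame(a = "x", b = "z", s = 0.2), tx, tz),
      closeness_matrix(data.frame(a = "y", b = "z", s = 0.5), ty, tz)
    )
  )
}

single_tree <- function(term, id) {
  ontology_tree(data.frame(child = character(0), parent = character(0)),
                id = id, root = term)
}

chain_tree <- function(n, id = "C") {
  terms <- sprintf("%s%d", tolower(id), seq_len(n) - 1L)
  if (n == 1L) return(single_tree(terms, id))
  ontology_tree(data.frame(child = terms[-1L], parent = terms[-n]), id = id)
}

star_tree <- function(n_leaves, id = "S") {
  terms <- sprintf("%s%d", tolower(id), 0:n_leaves)
  ontology_tree(data.frame(child = terms[-1L], parent = terms[1L]), id = id)
}

# random pair instance with uniform closeness, sizes drawn from 2..7
random_pair_instance <- function(seed, nmin = 2L, nmax = 7L) {
  set.seed(seed)
  na <- sample(nmin:nmax, 1L)
  nb <- sample(nmin:nmax, 1L)
  ta <- random_tree(na, seed = NULL, id = "A")
  tb <- random_tree(nb, seed = NULL, id = "B")
  cl <- random_closeness(ta, tb, seed = NULL)
  list(ta = ta, tb = tb, cl = cl)
}

# random weighted bipartite edge set on la x lb items with some zero and
# duplicate-weight edges to exercise tie handling
random_edge_set <- function(seed, la = 4L, lb = 4L) {
  set.seed(seed)
  n_edges <- sample(0:(la * lb), 1L)
  if (n_edges == 0L) {
    return(data.frame(left = character(0), right = character(0),
                      weight = numeric(0)))
  }
  cells <- sample(la * lb, n_edges)
  w <- round(stats::runif(n_edges), 2) # rounding forces occasional ties
  data.frame(left = sprintf("L%d", ((cells - 1L) %% la) + 1L),
             right = sprintf("R%d", ((cells - 1L) %/% la) + 1L),
             weight = w)
}
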