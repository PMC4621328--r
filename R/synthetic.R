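#' Random ontology tree from a spanning tree of a random matrix
#'
#' Benchmark topology generator: draw a symmetric matrix of uniform(0, 1)
#' weights over `n` vertices, take its minimum spanning tree, root it at
#' the first vertex and orient all edges away from the root. With i.i.d.
#' uniform weights the minimum and maximum spanning tree are
#' distributionally identical, so the choice of minimum cannot bias any
#' benchmark. Term identifiers are `<id>_t0001` and so on, with `_t0001`
#' the root.
#'
#' @param n Number of vertices (`>= 1`).
#' @param seed Integer seed; the tree is fully determined by `(n, seed)`.
#'   `NULL` draws from the current RNG stream instead.
#' @param id Ontology identifier.
#' @return An [ontology_tree()] with `n` vertices.
#' @export
random_tree <- function(n, seed = NULL, id = "T") {
  stopifnot(n >= 1L)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(set_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  terms <- sprintf("%s_t%04d", id, seq_len(n))
  if (n == 1L) {
    stats::runif(1L) # keep the stream moving for derived generators
    return(ontology_tree(data.frame(child = character(0),
                                    parent = character(0)),
                         id = id, root = terms))
  }
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- stats::runif(n * (n - 1L) / 2L)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "upper", weighted = TRUE)
  mstree <- igraph::mst(g, weights = igraph::E(g)$weight)
  bfs <- igraph::bfs(mstree, root = 1L, father = TRUE)
  father <- as.integer(bfs$father)
  ord <- as.integer(bfs$order)
  child <- setdiff(ord, 1L)
  ontology_tree(data.frame(child = terms[child], parent = terms[father[child]]),
                id = id)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Random closeness matrix with uniform(0, 1) entries
#'
#' Every cross-ontology term pair receives an independent uniform(0, 1)
#' score; the matrix is fully determined by the two trees and the seed.
#'
#' @param tree_a,tree_b [ontology_tree()]s.
#' @inheritParams random_tree
#' @return A [closeness_matrix()].
#' @export
random_closeness <- function(tree_a, tree_b, seed = NULL) {
  stopifnot(inherits(tree_a, "ontology_tree"), inherits(tree_b, "ontology_tree"))
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(set_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  m <- matrix(stats::runif(n_vertices(tree_a) * n_vertices(tree_b)),
              n_vertices(tree_a), n_vertices(tree_b),
              dimnames = list(tree_a$term, tree_b$term))
  new_closeness_matrix(m, tree_a$id, tree_b$id)
}

#' Replicated multi-ontology benchmark instances
#'
#' Generates `replicates` independent instances, each with `k` random trees
#' of `n` vertices (ids `T01`, `T02`, ...) and all `k(k-1)/2` pairwise
#' random closeness matrices. Replicate `r` uses seed `seed + r - 1`, so
#' instances are reproducible individually and the whole suite has no
#' hidden global randomness.
#'
#' @param k Number of ontologies (`>= 2`).
#' @param n Vertices per ontology (`>= 1`).
#' @param replicates Number of instances (`>= 1`).
#' @param seed Base integer seed.
#' @return A list of class `benchmark_suite`; each element is a list with
#'   `trees` (named list) and `matrices` (named by pair key), plus a
#'   `spec` attribute recording `(k, n, replicates, seed)`.
#' @export
benchmark_suite <- function(k, n, replicates = 10L, seed = 1L) {
  stopifnot(k >= 2L, n >= 1L, replicates >= 1L)
  out <- lapply(seq_len(replicates), function(r) {
    old <- get_rng_state()
    on.exit(set_rng_state(old), add = TRUE)
    set.seed(seed + r - 1L)
    ids <- sprintf("T%02d", seq_len(k))
    trees <- lapply(ids, function(id) random_tree(n, seed = NULL, id = id))
    names(trees) <- ids
    matrices <- list()
    for (i in seq_len(k - 1L)) {
      for (j in seq(i + 1L, k)) {
        cl <- random_closeness(trees[[i]], trees[[j]], seed = NULL)
        matrices[[pair_key(ids[i], ids[j])]] <- cl
      }
    }
    list(trees = trees, matrices = matrices)
  })
  structure(out, class = "benchmark_suite",
            spec = list(k = k, n = n, replicates = replicates, seed = seed))
}

#' @export
print.benchmark_suite <- function(x, ...) {
  s <- attr(x, "spec")
  cat(sprintf(
    "<benchmark_suite: %d replicate(s) of k=%d ontologies, n=%d, seed=%d>\n",
    s$replicates, s$k, s$n, s$seed))
  invisible(x)
}
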