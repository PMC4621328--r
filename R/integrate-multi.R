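# node-level closeness between two integrations, summing the original
# term-level scores of all member pairs (rows follow X's node order)
cross_closeness <- function(X, Y, matrices) {
  nx <- n_vertices(X$tree)
  ny <- n_vertices(Y$tree)
  out <- matrix(0, nx, ny)
  row_of <- stats::setNames(match(X$members$node, X$tree$term), X$members$term)
  col_of <- stats::setNames(match(Y$members$node, Y$tree$term), Y$members$term)
  for (s in X$sources) {
    mem_s <- X$members[X$members$ontology == s, ]
    for (t in Y$sources) {
      mem_t <- Y$members[Y$members$ontology == t, ]
      m <- oriented_closeness(matrices, s, t)
      m <- m[mem_s$term, mem_t$term, drop = FALSE]
      rg <- unname(row_of[mem_s$term])
      cg <- unname(col_of[mem_t$term])
      tmp <- rowsum(m, group = rg)
      tmp <- t(rowsum(t(tmp), group = cg))
      out[as.integer(rownames(tmp)), as.integer(colnames(tmp))] <-
        out[as.integer(rownames(tmp)), as.integer(colnames(tmp))] + tmp
    }
  }
  out
}

#' Merge closeness matrices against a further ontology
#'
#' When an integration is itself integrated with another ontology, the
#' closeness between a merged node and an outside term is the sum of the
#' member terms' closenesses to it: a node holding `a` (from T1) and `b`
#' (from T2) relates to `c` in T3 with `M13(a, c) + M23(b, c)`.
#'
#' @param onto An [integrated_ontology] (or an [ontology_tree()]).
#' @param matrices List of [closeness_matrix()] objects covering every
#'   (member ontology, target) pair.
#' @param target The next [ontology_tree()] (or integration) to integrate
#'   against.
#' @return A [closeness_matrix()] between `onto`'s merged nodes and
#'   `target`'s vertices.
#' @export
merge_closeness <- function(onto, matrices, target) {
  X <- as_integration(onto)
  Y <- as_integration(target)
  matrices <- key_matrices(matrices)
  m <- cross_closeness(X, Y, matrices)
  dimnames(m) <- list(X$tree$term, Y$tree$term)
  new_closeness_matrix(m, X$tree$id, Y$tree$id)
}

#' Adjusted cohesion between two (possibly merged) ontologies
#'
#' The cross-ontology weight increase of integrating the two objects —
#' the optimal (or approximate) pairwise cohesion of their node-level
#' closeness — divided by `|X| * |Y|`, the product of their member-ontology
#' counts. Undivided cohesion grows with the number of member ontologies,
#' which biases greedy multi-integration towards repeatedly extending the
#' largest intermediate result; the division removes that size advantage.
#'
#' @param x,y [integrated_ontology] objects or [ontology_tree()]s with
#'   disjoint member-ontology sets.
#' @param matrices List of [closeness_matrix()] objects covering all cross
#'   pairs.
#' @inheritParams build_cohesion_matrix
#' @return A single non-negative number.
#' @export
adjusted_cohesion <- function(x, y, matrices, matcher = c("greedy", "optimal"),
                              engine = c("auto", "cpp", "r")) {
  matcher <- match.arg(matcher)
  engine <- match.arg(engine)
  X <- as_integration(x)
  Y <- as_integration(y)
  if (length(intersect(X$sources, Y$sources))) {
    stop("member ontology sets overlap", call. = FALSE)
  }
  matrices <- key_matrices(matrices)
  M <- cross_closeness(X, Y, matrices)
  cm00 <- if (matcher == "greedy" && engine != "r") {
    cohesion_dp_greedy_cpp(X$tree$parent, Y$tree$parent, M, FALSE)$g[1L, 1L]
  } else {
    dp_r(X$tree, Y$tree, M, kernel_for(matcher))[1L, 1L]
  }
  cm00 / (length(X$sources) * length(Y$sources))
}

# pairwise cohesion score g for two integrations (undivided weight increase)
pair_score <- function(X, Y, matrices, matcher, engine) {
  M <- cross_closeness(X, Y, matrices)
  if (matcher == "greedy" && engine != "r") {
    cohesion_dp_greedy_cpp(X$tree$parent, Y$tree$parent, M, FALSE)$g[1L, 1L]
  } else {
    dp_r(X$tree, Y$tree, M, kernel_for(matcher))[1L, 1L]
  }
}

# deterministic choice among active-pair candidates: maximum weight, ties by
# the lexicographically smallest (sorted) pair of smallest member ids
pick_pair <- function(W, actives) {
  k <- length(actives)
  best <- NULL
  best_w <- -Inf
  best_key <- NULL
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      key <- paste(sort(c(min(actives[[i]]$sources), min(actives[[j]]$sources))),
                   collapse = "\r")
      if (W[i, j] > best_w ||
          (W[i, j] == best_w && !is.null(best_key) && key < best_key)) {
        best <- c(i, j)
        best_w <- W[i, j]
        best_key <- key
      }
    }
  }
  best
}

#' Integrate more than two ontologies
#'
#' Three strategies, all built on the pairwise engine plus closeness-matrix
#' merging:
#'
#' * `"basic"` — fold the trees in input order: integrate the first two,
#'   merge closeness against the third, integrate, and so on. Fastest,
#'   ignores all cohesion information.
#' * `"greedy"` — maintain an inter-ontology score table of
#'   [adjusted_cohesion()] values over the active (possibly already-merged)
#'   ontologies; repeatedly integrate the highest-scoring pair and rescore
#'   the newcomer against the remaining actives.
#' * `"fast"` — compute all pairwise cohesion scores once, then perform
#'   k-1 contractions of the current maximum-weight edge; after each
#'   contraction, parallel edges collapse to the larger of the two stale
#'   weights (a merged ontology can only gain cohesion against an outsider,
#'   so the stale maximum is a valid lower bound). Never rescores, and its
#'   total cohesion is at least the maximum-spanning-tree weight of the
#'   initial score graph — hence at least 1/(k-1) of the optimum when the
#'   pairwise engine is exact.
#'
#' Ties are broken towards the pair with the smallest member-ontology ids;
#' a zero-weight maximum still contracts (the result must be one tree).
#'
#' @param trees List of [ontology_tree()]s (k >= 2) with distinct ids.
#' @param matrices List of [closeness_matrix()] objects, one per tree pair.
#' @param strategy `"fast"`, `"greedy"` or `"basic"`.
#' @inheritParams build_cohesion_matrix
#' @return An [integrated_ontology] over all k sources. For
#'   `strategy = "fast"` the initial pairwise score matrix is attached as
#'   attribute `initial_pair_scores` (used for the spanning-tree bound
#'   check).
#' @export
integrate_multi <- function(trees, matrices,
                            strategy = c("fast", "greedy", "basic"),
                            matcher = c("greedy", "optimal"),
                            engine = c("auto", "cpp", "r")) {
  strategy <- match.arg(strategy)
  matcher <- match.arg(matcher)
  engine <- match.arg(engine)
  stopifnot(length(trees) >= 2L)
  ids <- vapply(trees, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate ontology ids", call. = FALSE)
  matrices <- key_matrices(matrices)
  out <- switch(strategy,
                basic = multi_basic(trees, matrices, matcher, engine),
                greedy = multi_greedy(trees, matrices, matcher, engine),
                fast = multi_fast(trees, matrices, matcher, engine))
  out$strategy <- strategy
  out$matcher <- matcher
  out
}

#' @rdname integrate_multi
#' @export
basic_multi_integrate <- function(trees, matrices,
                                  matcher = c("greedy", "optimal"),
                                  engine = c("auto", "cpp", "r")) {
  integrate_multi(trees, matrices, strategy = "basic",
                  matcher = match.arg(matcher), engine = match.arg(engine))
}

#' @rdname integrate_multi
#' @export
greedy_multi_integrate <- function(trees, matrices,
                                   matcher = c("greedy", "optimal"),
                                   engine = c("auto", "cpp", "r")) {
  integrate_multi(trees, matrices, strategy = "greedy",
                  matcher = match.arg(matcher), engine = match.arg(engine))
}

#' @rdname integrate_multi
#' @export
fast_multi_integrate <- function(trees, matrices,
                                 matcher = c("greedy", "optimal"),
                                 engine = c("auto", "cpp", "r")) {
  integrate_multi(trees, matrices, strategy = "fast",
                  matcher = match.arg(matcher), engine = match.arg(engine))
}

multi_basic <- function(trees, matrices, matcher, engine) {
  X <- as_integration(trees[[1L]])
  for (i in seq_along(trees)[-1L]) {
    Y <- as_integration(trees[[i]])
    M <- cross_closeness(X, Y, matrices)
    X <- integrate_objects(X, Y, M, matcher, engine)
  }
  X
}

multi_greedy <- function(trees, matrices, matcher, engine) {
  actives <- lapply(trees, as_integration)
  k <- length(actives)
  W <- matrix(0, k, k)
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      W[i, j] <- pair_score(actives[[i]], actives[[j]], matrices,
                            matcher, engine) /
        (length(actives[[i]]$sources) * length(actives[[j]]$sources))
    }
  }
  while (length(actives) > 1L) {
    ij <- pick_pair(W, actives)
    X <- actives[[ij[1L]]]
    Y <- actives[[ij[2L]]]
    M <- cross_closeness(X, Y, matrices)
    Z <- integrate_objects(X, Y, M, matcher, engine)
    actives <- actives[-ij]
    W_old <- W[-ij, -ij, drop = FALSE]
    actives <- c(actives, list(Z))
    k <- length(actives)
    W <- matrix(0, k, k)
    W[seq_len(k - 1L), seq_len(k - 1L)] <- W_old
    for (i in seq_len(k - 1L)) {
      W[i, k] <- pair_score(actives[[i]], Z, matrices, matcher, engine) /
        (length(actives[[i]]$sources) * length(Z$sources))
    }
  }
  actives[[1L]]
}

multi_fast <- function(trees, matrices, matcher, engine) {
  actives <- lapply(trees, as_integration)
  k <- length(actives)
  W <- matrix(0, k, k)
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      W[i, j] <- pair_score(actives[[i]], actives[[j]], matrices,
                            matcher, engine)
    }
  }
  W0 <- W + t(W)
  dimnames(W0) <- list(vapply(actives, `[[`, character(1), "sources"),
                       vapply(actives, `[[`, character(1), "sources"))
  while (length(actives) > 1L) {
    ij <- pick_pair(W, actives)
    X <- actives[[ij[1L]]]
    Y <- actives[[ij[2L]]]
    M <- cross_closeness(X, Y, matrices)
    Z <- integrate_objects(X, Y, M, matcher, engine)
    # parallel edges collapse to the stale maximum; weights never recomputed
    Wfull <- W + t(W)
    stale <- pmax(Wfull[ij[1L], ], Wfull[ij[2L], ])[-ij]
    actives <- actives[-ij]
    W_old <- W[-ij, -ij, drop = FALSE]
    actives <- c(actives, list(Z))
    k <- length(actives)
    W <- matrix(0, k, k)
    W[seq_len(k - 1L), seq_len(k - 1L)] <- W_old
    if (k > 1L) W[seq_len(k - 1L), k] <- stale
  }
  out <- actives[[1L]]
  attr(out, "initial_pair_scores") <- W0
  out
}

#' Pairwise cohesion score graph
#'
#' The complete weighted graph over the input ontologies whose edge weights
#' are the pairwise maximum cohesion scores; this is the graph whose
#' maximum spanning tree lower-bounds the fast contraction strategy.
#'
#' @inheritParams integrate_multi
#' @return A symmetric k x k matrix with the ontology ids as dimnames.
#' @export
pairwise_cohesion_graph <- function(trees, matrices,
                                    matcher = c("greedy", "optimal"),
                                    engine = c("auto", "cpp", "r")) {
  matcher <- match.arg(matcher)
  engine <- match.arg(engine)
  matrices <- key_matrices(matrices)
  k <- length(trees)
  ids <- vapply(trees, `[[`, character(1), "id")
  W <- matrix(0, k, k, dimnames = list(ids, ids))
  objs <- lapply(trees, as_integration)
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      W[i, j] <- W[j, i] <- pair_score(objs[[i]], objs[[j]], matrices,
                                       matcher, engine)
    }
  }
  W
}
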