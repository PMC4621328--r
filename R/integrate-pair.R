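#' @useDynLib ontofuse, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

kernel_for <- function(matcher) {
  switch(matcher,
         greedy = greedy_maximal_matching,
         optimal = optimal_matching,
         exhaustive = exhaustive_matching,
         stop("unknown matcher: ", matcher, call. = FALSE))
}

# matching over two child forests using cohesion-matrix entries as weights;
# chi/chj are vertex indices, g is the (n+1)x(m+1) matrix (row/col 1 =
# virtual root). Returns matched index pairs and their total.
match_forest <- function(chi, chj, g, kernel) {
  w <- g[chi + 1L, chj + 1L, drop = FALSE]
  pos <- which(w > 0)
  if (!length(pos)) return(list(total = 0, li = integer(0), ri = integer(0)))
  ai <- ((pos - 1L) %% length(chi)) + 1L
  bj <- ((pos - 1L) %/% length(chi)) + 1L
  res <- kernel(data.frame(left = chi[ai], right = chj[bj], weight = w[pos]))
  list(total = res$total,
       li = as.integer(as.character(res$pairs$left)),
       ri = as.integer(as.character(res$pairs$right)))
}

# reference R implementation of the cohesion-matrix dynamic programme,
# parameterised by the matching kernel; the Rcpp path is used for the
# greedy kernel at scale
dp_r <- function(ta, tb, M, kernel) {
  na <- n_vertices(ta)
  nb <- n_vertices(tb)
  g <- matrix(0, na + 1L, nb + 1L)
  for (i in na:0) {
    chi <- children_idx(ta, i)
    for (j in nb:0) {
      chj <- children_idx(tb, j)
      score <- if (i > 0L && j > 0L) M[i, j] else 0
      if (length(chi) && length(chj)) {
        score <- score + match_forest(chi, chj, g, kernel)$total
      }
      sa <- if (length(chj)) max(g[i + 1L, chj + 1L]) else 0
      sb <- if (length(chi)) max(g[chi + 1L, j + 1L]) else 0
      g[i + 1L, j + 1L] <- max(score, sa, sb)
    }
  }
  g
}

# breadth-first reconstruction of the integrated tree from a filled cohesion
# matrix, replaying the deterministic matcher at every merged entry; the
# attaining case is re-derived in the fixed order merge > descend-right >
# descend-left
reconstruct_r <- function(g, ta, tb, M, kernel, tol = 1e-9) {
  na_v <- integer(0); nb_v <- integer(0); np_v <- integer(0)
  add <- function(a, b, p) {
    na_v[[length(na_v) + 1L]] <<- a
    nb_v[[length(nb_v) + 1L]] <<- b
    np_v[[length(np_v) + 1L]] <<- p
    length(na_v)
  }
  attach_sub <- function(root, parent, from_a) {
    tr <- if (from_a) ta else tb
    q <- list(c(root, parent))
    while (length(q)) {
      cur <- q[[1L]]; q <- q[-1L]
      id <- if (from_a) add(cur[1L], -1L, cur[2L]) else add(-1L, cur[1L], cur[2L])
      for (k in tr$children[[cur[1L]]]) q <- c(q, list(c(k, id)))
    }
  }
  queue <- list(list(0L, 0L, 0L))
  while (length(queue)) {
    tri <- queue[[1L]]; queue <- queue[-1L]
    a <- tri[[1L]]; b <- tri[[2L]]; par <- tri[[3L]]
    val <- g[a + 1L, b + 1L]
    chi <- children_idx(ta, a)
    chj <- children_idx(tb, b)
    base <- if (a > 0L && b > 0L) M[a, b] else 0
    mt <- if (length(chi) && length(chj)) match_forest(chi, chj, g, kernel)
          else list(total = 0, li = integer(0), ri = integer(0))
    if (abs(base + mt$total - val) <= tol) { # merge the two subtree roots
      id <- add(a, b, par)
      for (p in seq_along(mt$li)) {
        queue <- c(queue, list(list(mt$li[p], mt$ri[p], id)))
      }
      for (x in setdiff(chi, mt$li)) attach_sub(x, id, TRUE)
      for (y in setdiff(chj, mt$ri)) attach_sub(y, id, FALSE)
      next
    }
    handled <- FALSE
    for (y in chj) { # descend right: b stays singleton, a dives into T_y
      if (abs(g[a + 1L, y + 1L] - val) <= tol) {
        if (b == 0L) stop("matcher/matrix mismatch at the virtual root",
                          call. = FALSE)
        id <- add(-1L, b, par)
        queue <- c(queue, list(list(a, y, id)))
        for (y2 in setdiff(chj, y)) attach_sub(y2, id, FALSE)
        handled <- TRUE
        break
      }
    }
    if (handled) next
    for (x in chi) { # descend left
      if (abs(g[x + 1L, b + 1L] - val) <= tol) {
        if (a == 0L) stop("matcher/matrix mismatch at the virtual root",
                          call. = FALSE)
        id <- add(a, -1L, par)
        queue <- c(queue, list(list(x, b, id)))
        for (x2 in setdiff(chi, x)) attach_sub(x2, id, TRUE)
        handled <- TRUE
        break
      }
    }
    if (!handled) {
      stop("matcher/matrix mismatch: no case reproduces entry (", a, ", ", b,
           ")", call. = FALSE)
    }
  }
  list(node_a = unlist(na_v), node_b = unlist(nb_v), node_parent = unlist(np_v))
}

# assemble an integrated_ontology from reconstruction node arrays
integration_from_nodes <- function(rec, X, Y, M_cross, cm00,
                                   matcher = NA_character_,
                                   algorithm = NA_character_,
                                   strategy = NA_character_) {
  nn <- length(rec$node_a)
  labels <- sprintf("n%05d", seq_len(nn))
  edges <- data.frame(child = labels[-1L], parent = labels[rec$node_parent[-1L]])
  tr <- ontology_tree(edges, id = paste(sort(c(X$sources, Y$sources)),
                                        collapse = "+"))
  a_ok <- rec$node_a > 0L
  b_ok <- rec$node_b > 0L
  weight <- numeric(nn)
  weight[a_ok] <- weight[a_ok] + unname(X$node_weight[rec$node_a[a_ok]])
  weight[b_ok] <- weight[b_ok] + unname(Y$node_weight[rec$node_b[b_ok]])
  both <- a_ok & b_ok
  weight[both] <- weight[both] +
    M_cross[cbind(rec$node_a[both], rec$node_b[both])]
  amap <- stats::setNames(labels[a_ok], X$tree$term[rec$node_a[a_ok]])
  bmap <- stats::setNames(labels[b_ok], Y$tree$term[rec$node_b[b_ok]])
  mem_a <- X$members
  mem_a$node <- unname(amap[mem_a$node])
  mem_b <- Y$members
  mem_b$node <- unname(bmap[mem_b$node])
  members <- dplyr::bind_rows(mem_a, mem_b)
  nw <- stats::setNames(weight, labels)[tr$term]
  new_integrated_ontology(
    tree = tr, members = members, node_weight = nw,
    sources = sort(c(X$sources, Y$sources)),
    total_cohesion = X$total_cohesion + Y$total_cohesion + cm00,
    matcher = matcher, algorithm = algorithm, strategy = strategy
  )
}

# core pairwise engine shared by integrate_pair and the multi-ontology
# strategies; X and Y are integrations (or wrapped trees), M_cross the
# node-level closeness between them
integrate_objects <- function(X, Y, M_cross, matcher = "greedy",
                              engine = "auto", algorithm = "dp",
                              strategy = NA_character_) {
  ta <- X$tree
  tb <- Y$tree
  stopifnot(nrow(M_cross) == n_vertices(ta), ncol(M_cross) == n_vertices(tb))
  if (matcher == "greedy" && engine != "r") {
    res <- cohesion_dp_greedy_cpp(ta$parent, tb$parent, M_cross, TRUE)
    rec <- res[c("node_a", "node_b", "node_parent")]
    cm00 <- res$g[1L, 1L]
  } else {
    kernel <- kernel_for(matcher)
    g <- dp_r(ta, tb, M_cross, kernel)
    rec <- reconstruct_r(g, ta, tb, M_cross, kernel)
    cm00 <- g[1L, 1L]
  }
  integration_from_nodes(rec, X, Y, M_cross, cm00, matcher, algorithm, strategy)
}

#' Build the cohesion matrix for a pair of ontologies
#'
#' Fills the (n+1) x (m+1) table of optimal subtree-pair cohesion scores in
#' reverse topological order over both trees. Entry `(i, j)` (1-based row
#' `i+1`, column `j+1`; index 0 is the virtual root) is the best total
#' closeness attainable when integrating the subtree of `tree_a` rooted at
#' vertex `i` with the subtree of `tree_b` rooted at `j`: the maximum of
#' merging the two roots plus a weighted matching of their child forests,
#' or leaving one root unmerged and descending into one of its children.
#' Entry (0, 0) is the cohesion of the full integration; with the optimal
#' matcher it is the exact maximum, with the greedy matcher it is guaranteed
#' to be at least half of it.
#'
#' @param tree_a,tree_b [ontology_tree()]s to integrate.
#' @param closeness A [closeness_matrix()] between them (either side order).
#' @param matcher `"greedy"` (maximal matching, 1/2-approximation, default)
#'   or `"optimal"` (maximum weighted matching).
#' @param engine `"auto"` (compiled path for the greedy matcher), `"cpp"` or
#'   `"r"` (reference implementation).
#' @return A `cohesion_matrix`: a numeric matrix with dimnames
#'   `c("<virtual>", terms)` and attributes `matcher`, `side_a`, `side_b`.
#' @export
build_cohesion_matrix <- function(tree_a, tree_b, closeness,
                                  matcher = c("greedy", "optimal"),
                                  engine = c("auto", "cpp", "r")) {
  matcher <- match.arg(matcher)
  engine <- match.arg(engine)
  stopifnot(inherits(tree_a, "ontology_tree"), inherits(tree_b, "ontology_tree"))
  M <- oriented_closeness(key_matrices(list(closeness)), tree_a$id, tree_b$id)
  if (matcher == "optimal" && engine == "cpp") {
    stop("the compiled path implements the greedy matcher only", call. = FALSE)
  }
  g <- if (matcher == "greedy" && engine != "r") {
    cohesion_dp_greedy_cpp(tree_a$parent, tree_b$parent, M, FALSE)$g
  } else {
    dp_r(tree_a, tree_b, M, kernel_for(matcher))
  }
  dimnames(g) <- list(c("<virtual>", tree_a$term), c("<virtual>", tree_b$term))
  structure(g, class = c("cohesion_matrix", class(g)),
            matcher = matcher, side_a = tree_a$id, side_b = tree_b$id)
}

#' Reconstruct the integrated ontology from a cohesion matrix
#'
#' Rebuilds the integrated tree top-down from the filled cohesion matrix
#' without any stored integration details: a queue of subtree-pair triples
#' is processed breadth-first and, at each one, the case that attains the
#' stored entry value (merge the roots, or keep one root singleton and
#' descend into one of its children) is re-derived by replaying the same
#' deterministic matcher. The resulting tree's total cohesion equals entry
#' (0, 0).
#'
#' @param cm A `cohesion_matrix` from [build_cohesion_matrix()].
#' @param tree_a,tree_b,closeness The inputs `cm` was built from.
#' @param matcher Matching kernel; defaults to the one recorded in `cm`
#'   (a different one generally fails to reproduce the entries).
#' @return An [integrated_ontology].
#' @export
build_integrated_ontology <- function(cm, tree_a, tree_b, closeness,
                                      matcher = NULL) {
  if (is.null(matcher)) matcher <- attr(cm, "matcher")
  stopifnot(matcher %in% c("greedy", "optimal"))
  M <- oriented_closeness(key_matrices(list(closeness)), tree_a$id, tree_b$id)
  kernel <- kernel_for(matcher)
  g <- unclass(cm)
  attributes(g) <- list(dim = dim(cm))
  rec <- reconstruct_r(g, tree_a, tree_b, M, kernel)
  integration_from_nodes(rec, as_integration(tree_a), as_integration(tree_b),
                         M, g[1L, 1L], matcher, "dp")
}

#' Integrate a pair of ontologies
#'
#' One-call front end: builds the cohesion matrix and reconstructs the
#' integrated tree (`algorithm = "dp"`), or runs the top-down
#' depth-regularised heuristic (`algorithm = "heuristic"`). The result
#' always satisfies the LCA-preservation criterion for both sources.
#'
#' @inheritParams build_cohesion_matrix
#' @param algorithm `"dp"` (cohesion-matrix dynamic programme, default) or
#'   `"heuristic"` (greedy top-down).
#' @param beta Depth-regularisation base for the heuristic (`>= 1`; 1
#'   disables depth weighting, large values confine every merge to the
#'   shallowest allowable candidate).
#' @return An [integrated_ontology].
#' @examples
#' t_a <- ontology_tree(data.frame(child = c("a1", "a2"),
#'                                 parent = c("a0", "a0")), id = "A")
#' t_b <- ontology_tree(data.frame(child = c("b1", "b2"),
#'                                 parent = c("b0", "b0")), id = "B")
#' cl <- closeness_matrix(
#'   data.frame(a = c("a0", "a1", "a2", "a1"), b = c("b0", "b1", "b2", "b2"),
#'              s = c(1, 2, 3, 4)), t_a, t_b)
#' integrate_pair(t_a, t_b, cl, matcher = "optimal")$total_cohesion # 6
#' @export
integrate_pair <- function(tree_a, tree_b, closeness,
                           matcher = c("greedy", "optimal"),
                           algorithm = c("dp", "heuristic"), beta = 1,
                           engine = c("auto", "cpp", "r")) {
  matcher <- match.arg(matcher)
  algorithm <- match.arg(algorithm)
  engine <- match.arg(engine)
  if (algorithm == "heuristic") {
    return(heuristic_integrate(tree_a, tree_b, closeness, beta = beta))
  }
  M <- oriented_closeness(key_matrices(list(closeness)), tree_a$id, tree_b$id)
  integrate_objects(as_integration(tree_a), as_integration(tree_b), M,
                    matcher = matcher, engine = engine, algorithm = "dp")
}
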