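#' Validate LCA preservation of an integration
#'
#' The structural correctness criterion for every integration in this
#' package: for any two terms of one source ontology, their lowest common
#' ancestor in that source must be a member of the lowest common ancestor
#' node of the two terms in the merged tree. The check is exhaustive over
#' all within-ontology vertex pairs.
#'
#' @param onto An [integrated_ontology].
#' @param sources List of the source [ontology_tree()]s.
#' @return A tibble of violations (empty when the integration is valid):
#'   `ontology`, `x`, `y`, `source_lca` and `merged_lca_node` (the merged
#'   node that should, but does not, contain the source LCA).
#' @export
validate_criterion1 <- function(onto, sources) {
  stopifnot(inherits(onto, "integrated_ontology"))
  if (inherits(sources, "ontology_tree")) sources <- list(sources)
  tr <- onto$tree
  mem <- onto$members
  viol <- list()
  for (src in sources) {
    mem_s <- mem[mem$ontology == src$id, ]
    if (!setequal(mem_s$term, src$term)) {
      stop("missing vertex: integration does not cover all terms of '",
           src$id, "'", call. = FALSE)
    }
    node_idx <- stats::setNames(match(mem_s$node, tr$term), mem_s$term)
    nv <- stats::setNames(unname(node_idx[src$term]), NULL) # by source index
    n <- n_vertices(src)
    if (n < 2L) next
    for (x in seq_len(n - 1L)) {
      for (y in seq(x + 1L, n)) {
        l_src <- lca_idx(src$parent, src$depth, x, y)
        l_mrg <- lca_idx(tr$parent, tr$depth, nv[x], nv[y])
        if (nv[l_src] != l_mrg) {
          viol[[length(viol) + 1L]] <- tibble::tibble(
            ontology = src$id, x = src$term[x], y = src$term[y],
            source_lca = src$term[l_src], merged_lca_node = tr$term[l_mrg])
        }
      }
    }
  }
  if (!length(viol)) {
    return(tibble::tibble(ontology = character(0), x = character(0),
                          y = character(0), source_lca = character(0),
                          merged_lca_node = character(0)))
  }
  dplyr::bind_rows(viol)
}

#' Exhaustive optimum for integrating a pair of ontologies
#'
#' Independent brute-force oracle: the subtree-pair recursion evaluated with
#' an exhaustive enumeration of every forest matching at every level, so no
#' assignment-solver optimality is assumed anywhere. Guarded to tiny trees.
#'
#' @inheritParams build_cohesion_matrix
#' @param max_n Size guard per tree.
#' @return The maximum attainable total cohesion.
#' @export
exhaustive_pair_optimum <- function(tree_a, tree_b, closeness, max_n = 8L) {
  stopifnot(inherits(tree_a, "ontology_tree"), inherits(tree_b, "ontology_tree"))
  if (n_vertices(tree_a) > max_n || n_vertices(tree_b) > max_n) {
    stop("exhaustive_pair_optimum size guard exceeded", call. = FALSE)
  }
  M <- oriented_closeness(key_matrices(list(closeness)), tree_a$id, tree_b$id)
  memo <- new.env(parent = emptyenv())
  go <- function(i, j) {
    key <- paste0(i, ":", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    chi <- children_idx(tree_a, i)
    chj <- children_idx(tree_b, j)
    score <- if (i > 0L && j > 0L) M[i, j] else 0
    if (length(chi) && length(chj)) {
      e <- expand.grid(x = chi, y = chj)
      e$w <- vapply(seq_len(nrow(e)), function(r) go(e$x[r], e$y[r]), numeric(1))
      score <- score + exhaustive_matching(e[e$w > 0, ])$total
    }
    sa <- if (length(chj)) max(vapply(chj, function(y) go(i, y), numeric(1))) else 0
    sb <- if (length(chi)) max(vapply(chi, function(x) go(x, j), numeric(1))) else 0
    out <- max(score, sa, sb)
    memo[[key]] <- out
    out
  }
  go(0L, 0L)
}

# second, structurally different pair oracle: enumerate all partial
# injections between the two vertex sets that (a) preserve ancestor order
# and incomparability and (b) are closed under lowest common ancestors,
# and take the best total closeness. Used to cross-validate the recursion
# oracle; the two cannot share a systematic error.
mapping_pair_optimum <- function(tree_a, tree_b, closeness, max_n = 6L) {
  na <- n_vertices(tree_a)
  nb <- n_vertices(tree_b)
  if (na > max_n || nb > max_n) {
    stop("mapping_pair_optimum size guard exceeded", call. = FALSE)
  }
  M <- oriented_closeness(key_matrices(list(closeness)), tree_a$id, tree_b$id)
  pa <- tree_a$parent; da <- tree_a$depth
  pb <- tree_b$parent; db <- tree_b$depth
  rel <- function(p, d, x, y) {
    # 0 same, 1 x above y, -1 x below y, 2 incomparable
    if (x == y) return(0L)
    l <- lca_idx(p, d, x, y)
    if (l == x) return(1L)
    if (l == y) return(-1L)
    2L
  }
  best <- 0
  map <- rep(NA_integer_, na)
  consistent <- function(a) {
    for (a2 in seq_len(na)) {
      if (a2 == a || is.na(map[a2])) next
      if (rel(pa, da, a, a2) != rel(pb, db, map[a], map[a2])) return(FALSE)
    }
    TRUE
  }
  closed_and_score <- function() {
    dom <- which(!is.na(map))
    tot <- 0
    if (length(dom) > 1L) {
      for (u in seq_along(dom)[-length(dom)]) {
        for (v in seq(u + 1L, length(dom))) {
          x <- dom[u]; y <- dom[v]
          la <- lca_idx(pa, da, x, y)
          lb <- lca_idx(pb, db, map[x], map[y])
          if (is.na(map[la]) || map[la] != lb) return(-1)
        }
      }
    }
    sum(M[cbind(dom, map[dom])])
  }
  recurse <- function(a) {
    if (a > na) {
      sc <- closed_and_score()
      if (sc > best) best <<- sc
      return(invisible())
    }
    recurse(a + 1L) # leave a unmapped
    for (b in seq_len(nb)) {
      if (b %in% map) next
      map[a] <<- b
      if (consistent(a)) recurse(a + 1L)
      map[a] <<- NA_integer_
    }
  }
  recurse(1L)
  best
}

#' Exhaustive optimum for integrating several tiny ontologies
#'
#' Brute-force oracle for the multi-ontology problem: recursively enumerates
#' every way of partitioning forests into integration groups (at most one
#' subtree per source ontology in a group, the generalisation of the
#' pairwise matching argument) and every choice of which roots merge into a
#' group's top node. Guarded to k <= 3 ontologies of at most 4 vertices.
#'
#' @param trees List of [ontology_tree()]s.
#' @param matrices List of [closeness_matrix()] objects for every pair.
#' @param max_k,max_n Size guards.
#' @return The maximum attainable total cohesion over all LCA-preserving
#'   joint integrations.
#' @export
exhaustive_multi_optimum <- function(trees, matrices, max_k = 3L, max_n = 4L) {
  k <- length(trees)
  if (k < 2L) stop("need at least two ontologies", call. = FALSE)
  if (k > max_k || any(vapply(trees, n_vertices, integer(1)) > max_n)) {
    stop("exhaustive_multi_optimum size guard exceeded", call. = FALSE)
  }
  matrices <- key_matrices(matrices)
  ids <- vapply(trees, `[[`, character(1), "id")
  Ms <- list() # closeness by (s, t) index pair, rows = tree s
  for (s in seq_len(k - 1L)) {
    for (t in seq(s + 1L, k)) {
      Ms[[paste0(s, ":", t)]] <- oriented_closeness(matrices, ids[s], ids[t])
    }
  }
  score_pair <- function(s, rs, t, rt) {
    if (s < t) Ms[[paste0(s, ":", t)]][rs, rt] else Ms[[paste0(t, ":", s)]][rt, rs]
  }
  memo <- new.env(parent = emptyenv())

  # state: list of integer vectors, state[[s]] = roots of the forest from
  # tree s still to place (sorted)
  g_forest <- function(state) {
    items <- list() # (source, root)
    for (s in seq_len(k)) for (r in state[[s]]) items <- c(items, list(c(s, r)))
    if (length(items) == 0L) return(0)
    key <- paste(vapply(seq_len(k),
                        function(s) paste(state[[s]], collapse = ","),
                        character(1)), collapse = ";")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    # group the first item with at most one subtree from each other source
    first <- items[[1L]]
    s0 <- first[1L]; r0 <- first[2L]
    others <- setdiff(seq_len(k), s0)
    choices <- lapply(others, function(s) c(NA_integer_, state[[s]]))
    grid <- expand.grid(choices, KEEP.OUT.ATTRS = FALSE)
    best <- -Inf
    for (gi in seq_len(max(1L, nrow(grid)))) {
      group <- list(c(s0, r0))
      rest <- state
      rest[[s0]] <- setdiff(rest[[s0]], r0)
      if (nrow(grid)) {
        for (ci in seq_along(others)) {
          r <- grid[gi, ci]
          if (!is.na(r)) {
            group <- c(group, list(c(others[ci], r)))
            rest[[others[ci]]] <- setdiff(rest[[others[ci]]], r)
          }
        }
      }
      val <- g_group(group) + g_forest(rest)
      if (val > best) best <- val
    }
    memo[[key]] <- best
    best
  }

  # integrate one group of subtrees (<=1 per source) into a single tree:
  # choose the non-empty subset of roots merged into the top node
  g_group <- function(group) {
    if (length(group) == 1L) { # a lone source subtree contributes nothing
      return(0)
    }
    n <- length(group)
    best <- -Inf
    for (mask in seq_len(2^n - 1L)) {
      sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) > 0L)
      w <- 0
      for (u in seq_along(sel)[-length(sel)]) {
        for (v in seq(u + 1L, length(sel))) {
          gu <- group[[sel[u]]]; gv <- group[[sel[v]]]
          w <- w + score_pair(gu[1L], gu[2L], gv[1L], gv[2L])
        }
      }
      if (length(sel) == 1L) w <- 0
      sub <- lapply(seq_len(k), function(s) integer(0))
      for (gi in seq_len(n)) {
        s <- group[[gi]][1L]; r <- group[[gi]][2L]
        if (gi %in% sel) {
          sub[[s]] <- sort(c(sub[[s]], trees[[s]]$children[[r]]))
        } else {
          sub[[s]] <- sort(c(sub[[s]], r))
        }
      }
      val <- w + g_forest(sub)
      if (val > best) best <- val
    }
    best
  }

  init <- lapply(trees, function(tr) 1L) # each tree's real root
  g_forest(init)
}

#' Maximum spanning tree weight of a pairwise score graph
#'
#' @param w Symmetric non-negative weight matrix over k >= 2 ontologies
#'   (e.g. the `initial_pair_scores` attribute of a fast multi-integration,
#'   or [pairwise_cohesion_graph()] output).
#' @return The total weight of the maximum spanning tree.
#' @export
max_spanning_tree_weight <- function(w) {
  stopifnot(is.matrix(w), nrow(w) == ncol(w))
  k <- nrow(w)
  if (k < 2L) stop("need at least two nodes", call. = FALSE)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "upper", weighted = TRUE,
                                           diag = FALSE)
  miss <- which(upper.tri(w) & w == 0, arr.ind = TRUE)
  if (nrow(miss)) { # keep the graph complete: zero edges may enter the MST
    g <- igraph::add_edges(g, t(miss[, c(2L, 1L), drop = FALSE]), weight = 0)
  }
  mstree <- igraph::mst(g, weights = -igraph::E(g)$weight)
  sum(igraph::E(mstree)$weight)
}
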