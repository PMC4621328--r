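#' Top-down heuristic integration with depth regularisation
#'
#' Greedy alternative to the dynamic programme: after pairing the virtual
#' roots it visits the vertices of `tree_a` in breadth-first order and, for
#' each vertex `a`, picks a partner among the allowable candidates in
#' `tree_b` — the still-free descendants of the partner of `a`'s nearest
#' merged ancestor, excluding subtrees and intermediate ancestors already
#' claimed by other branches (claiming either would break LCA preservation).
#' The candidate maximising `closeness(a, b) / beta^rdepth(b)` is chosen,
#' where `rdepth(b)` is `b`'s depth below the shallowest allowable
#' candidate: deep merges discard many future integration opportunities, so
#' `beta > 1` penalises them. A merge happens only when the winning
#' closeness is strictly positive; otherwise `a` stays a singleton.
#'
#' @inheritParams build_cohesion_matrix
#' @param beta Depth-regularisation base, `>= 1` (may be `Inf`). `beta = 1`
#'   ignores depth; `beta = Inf` restricts every merge to a shallowest
#'   allowable candidate.
#' @return An [integrated_ontology] (LCA-preserving by construction).
#' @export
heuristic_integrate <- function(tree_a, tree_b, closeness, beta = 1) {
  stopifnot(inherits(tree_a, "ontology_tree"), inherits(tree_b, "ontology_tree"))
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta < 1) {
    stop("beta must be a single number >= 1", call. = FALSE)
  }
  M <- oriented_closeness(key_matrices(list(closeness)), tree_a$id, tree_b$id)
  na <- n_vertices(tree_a)
  nb <- n_vertices(tree_b)
  pa <- tree_a$parent
  pb <- tree_b$parent
  partner <- rep(NA_integer_, na)
  merged_b <- logical(nb)
  claimed_b <- logical(nb)

  # nearest strict ancestor of b-vertex v (0 = virtual root) that is merged
  anchor_of <- function(v) {
    p <- pb[v]
    while (p > 0L && !merged_b[p]) p <- pb[p]
    p
  }
  partner_above <- function(a) {
    p <- pa[a]
    while (p > 0L && is.na(partner[p])) p <- pa[p]
    if (p == 0L) 0L else partner[p]
  }

  for (a in seq_len(na)) {
    bstar <- partner_above(a)
    anchors <- vapply(seq_len(nb), anchor_of, integer(1))
    cand <- which(!merged_b & !claimed_b & anchors == bstar)
    if (!length(cand)) next
    rdepth <- tree_b$depth[cand] - min(tree_b$depth[cand])
    penalty <- beta^rdepth # beta = Inf gives 1 at rdepth 0, Inf below
    sc <- M[a, cand] / penalty
    pick <- cand[order(-sc, cand)[1L]]
    if (M[a, pick] > 0) {
      partner[a] <- pick
      merged_b[pick] <- TRUE
      # the whole branch of bstar leading to the pick is now claimed by a's
      # subtree: no other vertex anchored at bstar may enter it (only a's
      # own descendants continue below the pick, anchored at the pick)
      branch <- pick
      while (pb[branch] != bstar) branch <- pb[branch]
      claim <- setdiff(subtree_idx(tree_b, branch),
                       setdiff(subtree_idx(tree_b, pick), pick))
      claimed_b[claim] <- TRUE
    }
  }
  heuristic_result(tree_a, tree_b, M, partner, beta)
}

# assemble the merged tree for a consistent vertex mapping: each node's
# parent is the deeper of the nodes holding its members' source parents
heuristic_result <- function(ta, tb, M, partner, beta) {
  na <- n_vertices(ta)
  nb <- n_vertices(tb)
  # node table: 1 = virtual root; then one node per A vertex (merged or
  # singleton); then singleton nodes for unmerged B vertices
  free_b <- setdiff(seq_len(nb), partner[!is.na(partner)])
  n_nodes <- 1L + na + length(free_b)
  node_a <- c(0L, seq_len(na), rep(NA_integer_, length(free_b)))
  node_b <- c(0L, unname(partner), free_b)
  node_of_a <- 1L + seq_len(na)
  node_of_b <- integer(nb)
  node_of_b[partner[!is.na(partner)]] <- node_of_a[which(!is.na(partner))]
  node_of_b[free_b] <- 1L + na + seq_along(free_b)
  # each node hangs under the deeper of the nodes holding its members'
  # source parents; placement iterates until all depths are known (a node's
  # parent can itself depend on nodes of larger depth sum, so no single
  # static order works)
  parents_of <- function(i) {
    cand_par <- integer(0)
    if (!is.na(node_a[i]) && node_a[i] > 0L) {
      p <- ta$parent[node_a[i]]
      cand_par <- c(cand_par, if (p == 0L) 1L else node_of_a[p])
    }
    if (!is.na(node_b[i]) && node_b[i] > 0L) {
      p <- tb$parent[node_b[i]]
      cand_par <- c(cand_par, if (p == 0L) 1L else node_of_b[p])
    }
    unique(cand_par)
  }
  parent_node <- rep(NA_integer_, n_nodes)
  mdepth <- rep(NA_integer_, n_nodes)
  mdepth[1L] <- 0L
  pending <- seq_len(n_nodes)[-1L]
  while (length(pending)) {
    progress <- FALSE
    for (i in pending) {
      cand_par <- parents_of(i)
      if (!anyNA(mdepth[cand_par])) {
        parent_node[i] <- cand_par[order(-mdepth[cand_par])[1L]]
        mdepth[i] <- mdepth[parent_node[i]] + 1L
        progress <- TRUE
      }
    }
    pending <- which(is.na(mdepth))
    if (length(pending) && !progress) {
      stop("inconsistent heuristic mapping (cyclic placement)", call. = FALSE)
    }
  }
  # deterministic labels: breadth-first by merged depth, ties by node index
  ord <- order(mdepth, seq_len(n_nodes))
  labels <- character(n_nodes)
  labels[ord] <- sprintf("n%05d", seq_len(n_nodes))
  edges <- data.frame(child = labels[seq_len(n_nodes)[-1L]],
                      parent = labels[parent_node[-1L]])
  tr <- ontology_tree(edges, id = paste(sort(c(ta$id, tb$id)), collapse = "+"))
  weight <- numeric(n_nodes)
  merged <- which(!is.na(node_a) & node_a > 0L & !is.na(node_b) & node_b > 0L)
  weight[merged] <- M[cbind(node_a[merged], node_b[merged])]
  mem <- dplyr::bind_rows(
    tibble::tibble(node = labels[node_of_a], ontology = ta$id, term = ta$term),
    tibble::tibble(node = labels[node_of_b], ontology = tb$id, term = tb$term)
  )
  new_integrated_ontology(
    tree = tr, members = mem,
    node_weight = stats::setNames(weight, labels)[tr$term],
    sources = sort(c(ta$id, tb$id)),
    total_cohesion = sum(weight),
    algorithm = "heuristic"
  )
}
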