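# Internode attraction: the gravity-like score at the heart of the method.
#
# Attr(v, m) = P(v, m) * GIF(v) * GIF(m) / SL(v, m)^2
#   P(v, m)  = (Triangle(v, m) + 1) / Deg(v)   (directional)
#   SL(v, m) = shortest-path length, 1 or 2 within the candidate set
#
# Candidates for v are all nodes within distance <= 2 reachable through v's
# neighbours, plus the direct neighbours themselves.

# Compact internal view of a graph: integer adjacency lists plus the stable
# natural rank of each label (used for deterministic tie-breaking).
as_internal <- function(net) {
  adj <- lapply(igraph::as_adj_list(net, mode = "all"), as.integer)
  names <- igraph::V(net)$name
  if (is.null(names)) names <- as.character(seq_along(adj))
  nat_rank <- integer(length(names))
  nat_rank[natural_order(names)] <- seq_along(names)
  list(adj = adj, names = names, deg = unname(lengths(adj)),
       nat_rank = nat_rank)
}

vertex_index <- function(g, names, v) {
  i <- match(as.character(v), names)
  if (anyNA(i)) {
    stop("unknown node label(s): ",
         paste(as.character(v)[is.na(i)], collapse = ", "), call. = FALSE)
  }
  i
}

# Candidate indices for vertex vi: N(vi) united with neighbours of
# neighbours, excluding vi itself.
candidate_idx <- function(adj, vi) {
  nb <- adj[[vi]]
  cand <- unique(c(nb, unlist(adj[nb], use.names = FALSE)))
  cand[cand != vi]
}

#' Common-neighbour (triangle) count of a node pair
#'
#' `Triangle(v, m) = |N(v) intersect N(m)|`, the number of triangles the
#' edge or pair (v, m) participates in. Symmetric in its arguments; a large
#' count means the pair is embedded in a tightly knit neighbourhood.
#'
#' @param net An undirected `igraph` graph.
#' @param v,m Node labels; `v != m`.
#' @return A single non-negative integer.
#' @export
triangle_count <- function(net, v, m) {
  names <- igraph::V(net)$name
  i <- vertex_index(net, names, c(v, m))
  if (i[1L] == i[2L]) stop("triangle_count needs two distinct nodes",
                           call. = FALSE)
  adj <- igraph::as_adj_list(net, mode = "all")
  length(intersect(as.integer(adj[[i[1L]]]), as.integer(adj[[i[2L]]])))
}

#' Candidate attractor set of a node
#'
#' All nodes a node can be attracted to: its direct neighbours together with
#' its second-order neighbourhood (nodes reachable through a neighbour),
#' excluding the node itself. Every member lies at shortest-path distance 1
#' or 2. Including the direct neighbours guarantees a non-empty candidate
#' set for every non-isolated node (a pendant node attached by a
#' triangle-free edge would otherwise have none).
#'
#' @inheritParams triangle_count
#' @param v A node label.
#' @return Character vector of candidate node labels in natural order.
#' @export
candidate_set <- function(net, v) {
  int <- as_internal(net)
  vi <- vertex_index(net, int$names, v)
  natural_sort(int$names[candidate_idx(int$adj, vi)])
}

#' Attraction exerted on one node by another
#'
#' Computes the full attraction record for a candidate pair: the triangle
#' count, the attraction coefficient `p = (triangles + 1) / deg(v)`, the
#' shortest-path length `sl` (1 if adjacent, else 2), and the attraction
#' `attr = p * gif(v) * gif(m) / sl^2`. The score is directional —
#' `attraction(net, inf, v, m)` is the pull of `m` on `v` — but obeys the
#' exact reciprocity `deg(v) * attr(v, m) = deg(m) * attr(m, v)`.
#'
#' @inheritParams triangle_count
#' @param inf An influence table from [influence_table()] for `net`.
#' @param v,m Node labels with `m` in `candidate_set(net, v)`.
#' @return A list with fields `source`, `target`, `triangles`, `p`, `sl`,
#'   `attr`.
#' @examples
#' ex <- example_network()
#' inf <- influence_table(ex$network)
#' attraction(ex$network, inf, "1", "4")$attr  # 0.8
#' @export
attraction <- function(net, inf, v, m) {
  int <- as_internal(net)
  i <- vertex_index(net, int$names, c(v, m))
  vi <- i[1L]; mi <- i[2L]
  if (!(mi %in% candidate_idx(int$adj, vi))) {
    stop("node ", m, " is not in the candidate set of node ", v,
         call. = FALSE)
  }
  gif <- inf$gif[match(int$names, inf$node)]
  tri <- length(intersect(int$adj[[vi]], int$adj[[mi]]))
  sl <- if (mi %in% int$adj[[vi]]) 1L else 2L
  p <- (tri + 1) / int$deg[vi]
  list(source = int$names[vi], target = int$names[mi],
       triangles = tri, p = p, sl = sl,
       attr = p * gif[vi] * gif[mi] / sl^2)
}

# Selection core: for vertex vi return index of the strongest attractor.
# Rule: maximum attr, then minimum sl, then the tie policy. Attraction
# values are compared exactly (they are short rational expressions computed
# identically for every candidate; an epsilon would change tie semantics).
select_strongest <- function(int, gif, vi, tie_policy) {
  cand <- candidate_idx(int$adj, vi)
  if (length(cand) == 0L) return(NA_integer_)
  nb <- int$adj[[vi]]
  mask <- logical(length(int$adj))
  mask[nb] <- TRUE
  tri <- vapply(cand, function(mi) sum(mask[int$adj[[mi]]]) + 0, numeric(1))
  sl <- ifelse(mask[cand], 1, 2)
  a <- (tri + 1) / int$deg[vi] * gif[vi] * gif[cand] / sl^2
  idx <- which(a == max(a))
  if (length(idx) > 1L) idx <- idx[sl[idx] == min(sl[idx])]
  if (length(idx) > 1L) {
    idx <- if (identical(tie_policy, "random")) {
      idx[sample.int(length(idx), 1L)]
    } else {
      idx[which.min(int$nat_rank[cand[idx]])]
    }
  }
  cand[idx]
}

check_tie_policy <- function(tie_policy, seed) {
  tie_policy <- match.arg(tie_policy, c("lowest-label", "random"))
  if (identical(tie_policy, "random") && is.null(seed)) {
    stop("tie_policy = \"random\" requires a seed for reproducibility",
         call. = FALSE)
  }
  tie_policy
}

#' Strongest attractor of a node
#'
#' Applies the selection rule to a node's candidate set: take the candidate
#' with maximum attraction; among equals, the one at minimum shortest-path
#' length; any remaining tie is resolved by the tie policy —
#' `"lowest-label"` (default, deterministic) or `"random"` (seeded).
#'
#' @inheritParams attraction
#' @param v A node label with a non-empty candidate set.
#' @param tie_policy `"lowest-label"` or `"random"`.
#' @param seed Integer seed, required when `tie_policy = "random"`.
#' @return The label of the strongest attractor, or `NA_character_` for an
#'   isolated node (the caller assigns it a singleton community).
#' @export
max_strong <- function(net, inf, v, tie_policy = "lowest-label",
                       seed = NULL) {
  tie_policy <- check_tie_policy(tie_policy, seed)
  int <- as_internal(net)
  vi <- vertex_index(net, int$names, v)
  gif <- inf$gif[match(int$names, inf$node)]
  pick <- function() select_strongest(int, gif, vi, tie_policy)
  mi <- if (identical(tie_policy, "random")) with_local_seed(seed, pick())
        else pick()
  if (is.na(mi)) NA_character_ else int$names[mi]
}

#' Pair every node with its strongest attractor
#'
#' Runs the strongest-attractor selection for every non-isolated node and
#' returns the resulting pair table, the input to the community merge.
#'
#' @inheritParams max_strong
#' @return A data frame of class `"iacd_pairs"` with columns `node` and
#'   `strongest`, one row per non-isolated node in stable natural order;
#'   isolated node labels are carried in attribute `"isolated"`.
#' @examples
#' ex <- example_network()
#' pt <- build_pair_table(ex$network, influence_table(ex$network))
#' head(pt)
#' @export
build_pair_table <- function(net, inf = NULL, tie_policy = "lowest-label",
                             seed = NULL) {
  tie_policy <- check_tie_policy(tie_policy, seed)
  if (is.null(inf)) inf <- influence_table(net)
  int <- as_internal(net)
  gif <- inf$gif[match(int$names, inf$node)]
  vs <- natural_order(int$names)
  run <- function() {
    vapply(vs, function(vi) {
      if (int$deg[vi] == 0L) NA_integer_
      else select_strongest(int, gif, vi, tie_policy)
    }, integer(1))
  }
  pick <- if (identical(tie_policy, "random")) with_local_seed(seed, run())
          else run()
  isolated <- int$names[vs[is.na(pick)]]
  keep <- !is.na(pick)
  out <- data.frame(node = int$names[vs[keep]],
                    strongest = int$names[pick[keep]],
                    stringsAsFactors = FALSE)
  attr(out, "isolated") <- isolated
  attr(out, "tie_policy") <- tie_policy
  class(out) <- c("iacd_pairs", "data.frame")
  out
}
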