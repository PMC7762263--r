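#' Merge attractor pairs into communities
#'
#' Treats every (node, strongest-attractor) pair as an undirected edge of a
#' "pair graph" and returns its connected components as the community
#' partition. This is union-find semantics: the result is provably
#' independent of the order in which pairs are processed. Isolated nodes —
#' any node in `all_nodes` that appears in no pair — become singleton
#' communities. Community identifiers are canonical: the smallest member
#' label in natural order.
#'
#' @param pairs A pair table from [build_pair_table()], or any data frame
#'   with character columns `node` and `strongest`.
#' @param all_nodes Character vector of all node labels the partition must
#'   cover (defaults to the labels appearing in `pairs` plus its
#'   `"isolated"` attribute).
#' @return A named character vector of class `"iacd_partition"` mapping each
#'   node to its community identifier, in stable natural node order.
#' @export
merge_communities <- function(pairs, all_nodes = NULL) {
  stopifnot(is.data.frame(pairs), all(c("node", "strongest") %in%
                                        names(pairs)))
  if (is.null(all_nodes)) {
    all_nodes <- c(pairs$node, pairs$strongest,
                   attr(pairs, "isolated") %||% character(0))
  }
  all_nodes <- unique(as.character(all_nodes))
  unknown <- setdiff(unique(c(pairs$node, pairs$strongest)), all_nodes)
  if (length(unknown) > 0L) {
    stop("pair table references node(s) outside the network: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  pg <- igraph::graph_from_data_frame(
    pairs[, c("node", "strongest")], directed = FALSE,
    vertices = data.frame(name = natural_sort(all_nodes),
                          stringsAsFactors = FALSE))
  memb <- igraph::components(pg)$membership
  nodes <- igraph::V(pg)$name
  # canonical identifier: smallest member label (nodes are in natural order,
  # so the first node seen in each component is its smallest label)
  ids <- nodes[!duplicated(memb)][match(memb, unique(memb))]
  out <- stats::setNames(ids, nodes)
  class(out) <- "iacd_partition"
  out
}

#' Detect communities by internode attraction
#'
#' The full parameter-free pipeline: score node influence
#' ([influence_table()]), pair every node with its strongest attractor
#' ([build_pair_table()]), and merge pairs into communities
#' ([merge_communities()]). Deterministic under the default tie policy; with
#' `tie_policy = "random"` a seed is mandatory and runs with equal seeds are
#' identical.
#'
#' A multi-node edgeless network is not an error: every node becomes its own
#' singleton community (no attraction is defined, and none is needed).
#'
#' @param net An undirected `igraph` graph with at least one node.
#' @inheritParams max_strong
#' @return A named character vector of class `"iacd_partition"` mapping each
#'   node to its community identifier (the smallest member label).
#' @examples
#' ex <- example_network()
#' p <- iacd_detect(ex$network)
#' table(p)  # three communities of sizes 5, 7, 4
#' @export
iacd_detect <- function(net, tie_policy = "lowest-label", seed = NULL) {
  stopifnot(igraph::is_igraph(net))
  tie_policy <- check_tie_policy(tie_policy, seed)
  if (igraph::vcount(net) == 0L) {
    stop("cannot detect communities in an empty network", call. = FALSE)
  }
  nodes <- igraph::V(net)$name
  if (is.null(nodes)) {
    nodes <- as.character(seq_len(igraph::vcount(net)))
    igraph::V(net)$name <- nodes
  }
  if (igraph::ecount(net) == 0L) {
    out <- stats::setNames(nodes, nodes)[natural_order(nodes)]
    class(out) <- "iacd_partition"
    return(out)
  }
  inf <- influence_table(net)
  pairs <- build_pair_table(net, inf, tie_policy = tie_policy, seed = seed)
  merge_communities(pairs, all_nodes = nodes)
}

#' Group a partition into its communities
#'
#' @param p A partition: named character vector (node -> community id).
#' @return A named list of character vectors, one per community, in natural
#'   order of community identifier.
#' @export
partition_groups <- function(p) {
  grp <- split(names(p), as.character(p))
  grp[natural_order(names(grp))]
}

#' @export
print.iacd_partition <- function(x, ...) {
  grp <- partition_groups(x)
  cat("Partition of ", length(x), " nodes into ", length(grp),
      " communities\n", sep = "")
  sizes <- lengths(grp)
  for (i in seq_along(grp)) {
    cat("  [", names(grp)[i], "] n=", sizes[i], ": ",
        paste(natural_sort(grp[[i]]), collapse = " "), "\n", sep = "")
  }
  invisible(x)
}
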