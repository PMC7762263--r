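#' The 16-node worked-example network
#'
#' A small undirected network of 16 nodes and 30 edges with three planted
#' communities, \{1..5\}, \{6..12\} and \{13..16\}, used throughout the
#' documentation and tests to illustrate every stage of the method. Its
#' structural properties are over-determined by the influence and attraction
#' tables it was built to exhibit, so the constructor re-validates them on
#' every call: the degree sequence, the k-core indices, the candidate set
#' and attraction scores of node 1, the full strongest-attractor vector, and
#' the final three-community partition. Any mismatch is a fixture-integrity
#' error naming the violated constraint.
#'
#' @return A benchmark instance: a list with elements `network` (an
#'   undirected `igraph` graph), `truth` (named character vector of the
#'   three planted communities) and `config` (`NULL`; the instance is not
#'   generated).
#' @examples
#' ex <- example_network()
#' igraph::ecount(ex$network)  # 30
#' @export
example_network <- function() {
  edges <- matrix(c(
    1, 2,   1, 3,   1, 4,   1, 5,   1, 11,
    2, 3,   2, 4,   2, 5,
    3, 4,   3, 11,
    4, 5,   4, 6,
    6, 7,   6, 9,   6, 10,
    7, 8,   7, 9,   7, 12,
    8, 9,
    9, 10,  9, 11,
    10, 11, 10, 12,
    11, 12,
    12, 13,
    13, 14, 13, 15, 13, 16,
    14, 16,
    15, 16), ncol = 2L, byrow = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges[, 1L]),
               to = as.character(edges[, 2L]), stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = as.character(1:16),
                          stringsAsFactors = FALSE))
  truth <- stats::setNames(
    rep(c("1", "6", "13"), times = c(5L, 7L, 4L)), as.character(1:16))

  fail <- function(what) {
    stop("fixture integrity: worked-example network violates its ",
         "documented ", what, call. = FALSE)
  }
  deg <- as.integer(igraph::degree(g))[order(as.integer(igraph::V(g)$name))]
  if (!identical(deg, c(5L, 4L, 4L, 5L, 3L, 4L, 4L, 2L, 5L, 4L, 5L, 4L,
                        4L, 2L, 2L, 3L))) fail("degree sequence")
  ks <- unname(kcore_scores(g)[as.character(1:16)])
  if (!identical(ks, c(3L, 3L, 3L, 3L, 3L, 3L, 3L, 2L, 3L, 3L, 3L, 3L,
                       2L, 2L, 2L, 2L))) fail("k-core indices")
  if (!setequal(candidate_set(g, "1"),
                as.character(c(2:6, 9:12)))) fail("candidate set of node 1")
  inf <- influence_table(g)
  known_attr <- c(`2` = 0.64, `3` = 0.64, `4` = 0.8, `5` = 0.36, `6` = 0.08,
                  `9` = 0.1, `10` = 0.08, `11` = 0.4, `12` = 0.08)
  known_sl <- c(`2` = 1L, `3` = 1L, `4` = 1L, `5` = 1L, `6` = 2L,
                `9` = 2L, `10` = 2L, `11` = 1L, `12` = 2L)
  for (m in names(known_attr)) {
    rec <- attraction(g, inf, "1", m)
    if (rec$sl != known_sl[[m]]) fail("shortest-path lengths from node 1")
    if (abs(rec$attr - known_attr[[m]]) > 5e-3) {
      fail(paste0("attraction value for pair (1, ", m, ")"))
    }
  }
  pt <- build_pair_table(g, inf)
  expect_pairs <- as.character(c(4, 1, 1, 1, 1, 9, 9, 9, 6, 9, 10, 11,
                                 16, 13, 13, 13))
  if (!identical(pt$strongest[match(as.character(1:16), pt$node)],
                 expect_pairs)) fail("strongest-attractor vector")
  p <- merge_communities(pt, all_nodes = as.character(1:16))
  if (!isTRUE(all.equal(nmi(p, truth), 1))) fail("three-community partition")

  structure(list(network = g, truth = truth, config = NULL),
            class = "iacd_benchmark")
}
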