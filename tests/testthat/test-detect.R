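ex <- example_network()

test_that("merging the worked-example pairs yields the three communities", {
  pt <- build_pair_table(ex$network)
  p <- merge_communities(pt, all_nodes = as.character(1:16))
  grp <- partition_groups(p)
  expect_length(grp, 3L)
  expect_setequal(grp[["1"]], as.character(1:5))
  expect_setequal(grp[["6"]], as.character(6:12))
  expect_setequal(grp[["13"]], as.character(13:16))
})

test_that("merge result is independent of pair-table row order", {
  pairs <- data.frame(
    node = as.character(1:6),
    strongest = as.character(c(2, 1, 2, 5, 4, 5)),
    stringsAsFactors = FALSE)
  ref <- merge_communities(pairs, all_nodes = as.character(1:6))
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    }
    out
  }
  for (ord in perms(seq_len(nrow(pairs)))) {
    p <- merge_communities(pairs[ord, ], all_nodes = as.character(1:6))
    expect_identical(p, ref)
  }
})

test_that("merge handles chains, singletons and integrity violations", {
  chain <- data.frame(node = as.character(1:5),
                      strongest = as.character(c(2, 3, 4, 5, 1)))
  p <- merge_communities(chain)
  expect_length(partition_groups(p), 1L)

  pt <- data.frame(node = c("a", "b"), strongest = c("b", "a"))
  p2 <- merge_communities(pt, all_nodes = c("a", "b", "c"))
  expect_identical(unname(p2[["c"]]), "c")

  expect_error(merge_communities(pt, all_nodes = "a"), "outside the network")
})

test_that("detection recovers symmetric disconnected structures", {
  # two disjoint triangles: attraction cannot cross components
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("1", "2", "3", "4", "5", "6"),
               to   = c("2", "3", "1", "5", "6", "4")), directed = FALSE)
  p <- iacd_detect(g)
  grp <- partition_groups(p)
  expect_length(grp, 2L)
  expect_setequal(lengths(grp), c(3L, 3L))
})

test_that("degenerate networks yield singleton partitions, not errors", {
  g1 <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(g1)$name <- "solo"
  p1 <- iacd_detect(g1)
  expect_identical(unname(p1[["solo"]]), "solo")

  g3 <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(g3)$name <- as.character(1:3)
  p3 <- iacd_detect(g3)
  expect_length(partition_groups(p3), 3L)

  expect_error(iacd_detect(igraph::make_empty_graph(0, directed = FALSE)),
               "empty network")
})

test_that("every detected partition is a disjoint cover with no empty part", {
  for (seed in 1:10) {
    g <- random_graph(20L + seed, 0.05 + (seed %% 4) / 10, seed + 200L)
    p <- iacd_detect(g)
    expect_setequal(names(p), igraph::V(g)$name)
    expect_false(anyNA(p))
    expect_true(all(lengths(partition_groups(p)) >= 1L))
  }
})

test_that("detection is deterministic for both tie policies", {
  g <- random_graph(40L, 0.12, 321L)
  expect_identical(iacd_detect(g), iacd_detect(g))
  expect_identical(iacd_detect(g, tie_policy = "random", seed = 9L),
                   iacd_detect(g, tie_policy = "random", seed = 9L))
  expect_error(iacd_detect(g, tie_policy = "random"), "seed")
})

test_that("random tie policy does not disturb the caller's RNG stream", {
  set.seed(77)
  before <- .Random.seed
  invisible(iacd_detect(ex$network, tie_policy = "random", seed = 5L))
  expect_identical(.Random.seed, before)
})

test_that("communities are connected in the original network on fixtures", {
  check_connected <- function(net, p) {
    for (members in partition_groups(p)) {
      sub <- igraph::induced_subgraph(net, members)
      expect_true(igraph::is_connected(sub))
    }
  }
  check_connected(ex$network, iacd_detect(ex$network))
  inst <- generate_planted_partition(3, 15, 0.6, 0.02, seed = 4L)
  check_connected(inst$network, iacd_detect(inst$network))
})
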