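#' Read an undirected network from an edge-list file
#'
#' Parses a whitespace/tab-delimited edge list (two node labels per line,
#' lines starting with `#` ignored) into an undirected simple
#' [igraph][igraph::igraph-package] graph. Node labels are kept verbatim as
#' vertex names; vertices are stored in a stable natural order (numeric when
#' all labels are numbers, lexicographic otherwise) so repeated runs are
#' reproducible.
#'
#' Self-loops are dropped and duplicate edges collapsed, each with a warning:
#' the attraction model is defined only on simple graphs. Isolated nodes
#' cannot be represented in an edge list; supply `node_file` (one label per
#' line) to add them.
#'
#' @param path Path to the edge-list file.
#' @param node_file Optional path to a sidecar file listing all node labels,
#'   one per line, so that isolated nodes are included.
#' @return An undirected `igraph` graph with character vertex names.
#' @examples
#' f <- tempfile()
#' writeLines(c("# toy triangle", "1 2", "2 3", "3 1"), f)
#' g <- read_edge_list(f)
#' igraph::vcount(g)
#' @seealso [read_gml()], [write_partition()]
#' @export
read_edge_list <- function(path, node_file = NULL) {
  if (!file.exists(path)) {
    stop("edge-list file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    stop("empty network: no edges in ", path, call. = FALSE)
  }
  tokens <- strsplit(trimws(lines[idx]), "\\s+")
  bad <- which(lengths(tokens) < 2L)
  if (length(bad) > 0L) {
    stop("malformed edge-list line ", idx[bad[1L]], " in ", path,
         ": expected at least two tokens, got ",
         lengths(tokens)[bad[1L]], call. = FALSE)
  }
  from <- vapply(tokens, `[[`, character(1), 1L)
  to <- vapply(tokens, `[[`, character(1), 2L)

  loops <- from == to
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped", call. = FALSE)
    from <- from[!loops]
    to <- to[!loops]
  }
  if (length(from) == 0L) {
    stop("empty network: only self-loops in ", path, call. = FALSE)
  }
  key <- paste(pmin(from, to), pmax(from, to), sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicate edge(s) collapsed", call. = FALSE)
    from <- from[!dup]
    to <- to[!dup]
  }

  nodes <- unique(c(from, to))
  if (!is.null(node_file)) {
    extra <- trimws(readLines(node_file, warn = FALSE))
    extra <- extra[nzchar(extra) & !startsWith(extra, "#")]
    nodes <- unique(c(nodes, extra))
  }
  igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = natural_sort(nodes),
                          stringsAsFactors = FALSE)
  )
}

#' Read or write an undirected network in GML format
#'
#' Thin wrappers around igraph's GML support that enforce the package's
#' graph model: undirected simple graphs with stable character vertex names.
#' `read_gml()` refuses directed graphs; `write_gml()` refuses empty graphs.
#' A write/read round trip preserves node labels and the edge set.
#'
#' @param path Path to a GML file.
#' @param net An undirected `igraph` graph with vertex names.
#' @return `read_gml()` returns an undirected `igraph` graph;
#'   `write_gml()` invisibly returns `path`.
#' @export
read_gml <- function(path) {
  if (!file.exists(path)) {
    stop("GML file not found: ", path, call. = FALSE)
  }
  g <- igraph::read_graph(path, format = "gml")
  if (igraph::is_directed(g)) {
    stop("unsupported input: GML file ", path, " declares a directed graph",
         call. = FALSE)
  }
  va <- igraph::vertex_attr_names(g)
  name <- if ("name" %in% va) {
    as.character(igraph::V(g)$name)
  } else if ("label" %in% va) {
    as.character(igraph::V(g)$label)
  } else if ("id" %in% va) {
    as.character(igraph::V(g)$id)
  } else {
    as.character(seq_len(igraph::vcount(g)))
  }
  igraph::V(g)$name <- name
  if (igraph::any_loop(g) || igraph::any_multiple(g)) {
    warning("self-loops/duplicate edges in ", path, " simplified",
            call. = FALSE)
    g <- igraph::simplify(g)
  }
  g
}

#' @rdname read_gml
#' @export
write_gml <- function(net, path) {
  stopifnot(igraph::is_igraph(net))
  if (igraph::vcount(net) == 0L) {
    stop("refusing to write a GML file with zero nodes", call. = FALSE)
  }
  if (igraph::is_directed(net)) {
    stop("only undirected networks are supported", call. = FALSE)
  }
  igraph::write_graph(net, path, format = "gml")
  invisible(path)
}

#' Read a community-assignment file
#'
#' Reads ground-truth class labels or a previously written partition from a
#' file with one `node<TAB>label` record per line (any whitespace run is
#' accepted as the separator). Labels are preserved verbatim.
#'
#' @param path Path to the assignment file.
#' @return A named character vector mapping node label to community/class
#'   label, in stable natural node order.
#' @export
read_communities <- function(path) {
  if (!file.exists(path)) {
    stop("community file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    stop("empty community file: ", path, call. = FALSE)
  }
  tokens <- strsplit(trimws(lines[idx]), "\\s+")
  bad <- which(lengths(tokens) < 2L)
  if (length(bad) > 0L) {
    stop("malformed community line ", idx[bad[1L]], " in ", path,
         call. = FALSE)
  }
  node <- vapply(tokens, `[[`, character(1), 1L)
  label <- vapply(tokens, `[[`, character(1), 2L)
  first <- !duplicated(node)
  conflict <- !first & label != label[match(node, node)]
  if (any(conflict)) {
    stop("node ", node[which(conflict)[1L]],
         " listed with conflicting community labels in ", path,
         call. = FALSE)
  }
  node <- node[first]
  label <- label[first]
  out <- stats::setNames(label, node)
  out[natural_order(node)]
}

#' Write a partition or ground truth to a community-assignment file
#'
#' Writes one `node<TAB>community` line per node, in stable natural node
#' order, so that [read_communities()] round-trips the assignment exactly.
#'
#' @param p A named character vector (node -> community label), e.g. the
#'   result of [iacd_detect()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_partition <- function(p, path) {
  stopifnot(is.character(p) || is.factor(p), !is.null(names(p)))
  p <- p[natural_order(names(p))]
  writeLines(paste(names(p), as.character(p), sep = "\t"), path)
  invisible(path)
}
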