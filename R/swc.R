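#' Read a neuron skeleton from an SWC file
#'
#' Standard whitespace-delimited SWC morphology format
#' (`id type x y z radius parent`, comments starting with `#`). The type
#' field is used only to locate the soma (type 1, or the root when absent);
#' arbors are assumed planar and a nonzero z column triggers a warning
#' before z is dropped.
#'
#' @param path file path.
#' @return A [skeleton_graph()].
#' @export
read_swc <- function(path) {
  d <- utils::read.table(path, comment.char = "#",
                         col.names = c("id", "type", "x", "y", "z",
                                       "radius", "parent"))
  if (any(abs(d$z) > 1e-9))
    warning("nonzero z coordinates in SWC; arbor treated as 2-D (z dropped)")
  soma_id <- d$id[d$type == 1][1]
  if (is.na(soma_id)) soma_id <- d$id[d$parent == -1][1]
  edges <- d[d$parent != -1, c("id", "parent")]
  skeleton_graph(nodes = data.frame(id = d$id, x = d$x, y = d$y),
                 edges = as.matrix(edges),
                 soma = soma_id)
}

#' Write a skeleton to an SWC file
#'
#' @param g a [skeleton_graph()]; must be a tree rooted at the soma.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(g, path) {
  n <- g$nodes
  ig <- g$graph
  root <- as.character(g$soma)
  parent <- rep(-1L, nrow(n))
  ord <- as.integer(igraph::bfs(ig, root = root, unreachable = FALSE)$order)
  dj <- igraph::distances(ig, v = root)
  for (e in igraph::E(ig)) {
    ends <- igraph::ends(ig, e)
    a <- match(as.numeric(ends[1]), n$id)
    b <- match(as.numeric(ends[2]), n$id)
    if (dj[1, ends[1]] < dj[1, ends[2]]) parent[b] <- n$id[a]
    else parent[a] <- n$id[b]
  }
  out <- data.frame(id = n$id, type = ifelse(n$id == g$soma, 1L, 3L),
                    x = n$x, y = n$y, z = 0, radius = 0.5, parent = parent)
  utils::write.table(out, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Skeleton graph of a planar arbor
#'
#' Geometric graph representation of a skeletonized arbor: 2-D nodes,
#' undirected edges with Euclidean lengths, and a marked soma node.
#'
#' @param nodes data frame with columns `id`, `x`, `y`.
#' @param edges two-column matrix of node ids.
#' @param soma id of the soma node.
#' @return An object of class `skeleton_graph` wrapping an igraph object
#'   (`graph`), the node table (`nodes`), and `soma`.
#' @export
skeleton_graph <- function(nodes, edges, soma) {
  stopifnot(all(c("id", "x", "y") %in% names(nodes)), soma %in% nodes$id)
  ig <- igraph::graph_from_edgelist(
    cbind(as.character(edges[, 1]), as.character(edges[, 2])),
    directed = FALSE)
  missing <- setdiff(as.character(nodes$id), igraph::V(ig)$name)
  if (length(missing)) ig <- igraph::add_vertices(ig, length(missing),
                                                  name = missing)
  idx <- match(igraph::V(ig)$name, as.character(nodes$id))
  len <- apply(igraph::ends(ig, igraph::E(ig)), 1, function(e) {
    a <- match(e[1], as.character(nodes$id))
    b <- match(e[2], as.character(nodes$id))
    sqrt((nodes$x[a] - nodes$x[b])^2 + (nodes$y[a] - nodes$y[b])^2)
  })
  igraph::E(ig)$length <- if (length(len)) len else numeric(0)
  structure(list(graph = ig, nodes = nodes[idx, ], soma = soma),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("skeleton: %d nodes, %d edges, total length %.4g um\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              sum(igraph::E(x$graph)$length)))
  invisible(x)
}
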