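#' Nodes within a given distance of seed molecules
#'
#' Breadth-first neighborhood on the significant-edge graph: all nodes at
#' unweighted shortest-path distance at most `max_depth` from at least one
#' seed (seeds themselves are distance 0). Edge weights are ignored —
#' reachability counts hops only.
#'
#' Seed resolution is exact-match on node ids, with a case-insensitive
#' fallback that errors when ambiguous; an unknown seed errors with the
#' closest id matches to help typo hunting.
#'
#' @param network a `ggm_network`.
#' @param seeds character vector of node ids.
#' @param max_depth neighborhood radius in edges, default 2.
#' @return character vector of node ids (sorted; includes the seeds).
#' @export
neighborhood <- function(network, seeds, max_depth = 2) {
  stopifnot(inherits(network, "ggm_network"))
  if (max_depth < 0) stop("max_depth must be >= 0", call. = FALSE)
  ids <- network$nodes$id
  seeds <- vapply(seeds, resolve_seed, character(1), ids = ids)
  current <- unique(seeds)
  visited <- current
  adj <- split(c(network$edges$target, network$edges$source),
               c(network$edges$source, network$edges$target))
  depth <- 0
  while (depth < max_depth && length(current) > 0) {
    nxt <- unique(unlist(adj[current], use.names = FALSE))
    current <- setdiff(nxt, visited)
    visited <- c(visited, current)
    depth <- depth + 1
  }
  sort(visited)
}

resolve_seed <- function(seed, ids) {
  if (seed %in% ids) return(seed)
  ci <- ids[tolower(ids) == tolower(seed)]
  if (length(ci) == 1) return(ci)
  if (length(ci) > 1)
    stop("seed '", seed, "' is ambiguous under case-insensitive matching: ",
         paste(ci, collapse = ", "), call. = FALSE)
  near <- utils::head(ids[order(utils::adist(seed, ids))], 5)
  stop("unknown seed '", seed, "'; nearest node ids: ",
       paste(near, collapse = ", "), call. = FALSE)
}

#' Induced subgraph on a node subset
#'
#' Restricts the network to the given nodes, keeping exactly the edges with
#' both endpoints in the subset. Node annotations and edge statistics are
#' preserved.
#'
#' @param network a `ggm_network`.
#' @param nodes character vector of node ids (must exist in the network).
#' @return a `ggm_network` on the subset.
#' @export
induced_subgraph <- function(network, nodes) {
  stopifnot(inherits(network, "ggm_network"))
  unknown <- setdiff(nodes, network$nodes$id)
  if (length(unknown))
    stop("node(s) not in network: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  keep_n <- network$nodes$id %in% nodes
  keep_e <- network$edges$source %in% nodes & network$edges$target %in% nodes
  out <- network
  out$nodes <- network$nodes[keep_n, , drop = FALSE]
  out$edges <- network$edges[keep_e, , drop = FALSE]
  rownames(out$nodes) <- NULL
  rownames(out$edges) <- NULL
  out
}

#' Extract a seed-centered subnetwork
#'
#' [neighborhood()] followed by [induced_subgraph()]: the subnetwork around
#' the seeds containing every node within `max_depth` edges of a seed and
#' all significant edges among those nodes.
#'
#' @inheritParams neighborhood
#' @return a `ggm_network`.
#' @export
extract_subnetwork <- function(network, seeds, max_depth = 2) {
  induced_subgraph(network, neighborhood(network, seeds, max_depth))
}
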