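#' Construct a protein-protein interaction network
#'
#' Builds an undirected simple graph over protein identifiers from a
#' two-column edge table. Self-loops are dropped, duplicate pairs (in either
#' orientation) are collapsed, and nodes that appear only in self-loops are
#' removed entirely: an isolated node contributes nothing to any score.
#'
#' @param edges a two-column character matrix or data.frame of interacting
#'   protein identifier pairs. Orientation is ignored.
#' @return an object of class `ppi_network` with components:
#'   \describe{
#'     \item{nodes}{sorted character vector of protein identifiers}
#'     \item{edges}{integer matrix, two columns, indices into `nodes`, each
#'       unordered pair stored once with `edges[,1] < edges[,2]`}
#'     \item{adj}{adjacency list: for node `i`, the sorted integer indices of
#'       its neighbours}
#'     \item{n_self_removed, n_dup_removed}{cleaning counters}
#'   }
#' @examples
#' net <- ppi_network(data.frame(a = c("p1", "p2"), b = c("p2", "p3")))
#' network_degree(net)
#' @export
ppi_network <- function(edges) {
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop("edge table must have at least two columns")
  a <- as.character(edges[[1L]])
  b <- as.character(edges[[2L]])
  if (anyNA(a) || anyNA(b)) stop("missing identifiers in edge table")
  self <- a == b
  a <- a[!self]
  b <- b[!self]
  if (length(a) == 0L) stop("network has no edges after removing self-interactions")
  lo <- ifelse(a < b, a, b)
  hi <- ifelse(a < b, b, a)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  lo <- lo[!dup]
  hi <- hi[!dup]
  nodes <- sort(unique(c(lo, hi)))
  ui <- match(lo, nodes)
  vi <- match(hi, nodes)
  ord <- order(ui, vi) # canonical edge order: invariant to input permutation
  ui <- ui[ord]
  vi <- vi[ord]
  n <- length(nodes)
  ii <- c(ui, vi)
  jj <- c(vi, ui)
  o <- order(ii, jj)
  adj <- split(jj[o], factor(ii[o], levels = seq_len(n)))
  names(adj) <- NULL
  structure(
    list(
      nodes = nodes,
      edges = cbind(ui, vi, deparse.level = 0L),
      adj = adj,
      n_self_removed = sum(self),
      n_dup_removed = sum(dup)
    ),
    class = "ppi_network"
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("PPI network:", length(x$nodes), "proteins,", nrow(x$edges), "interactions\n")
  cat("  removed:", x$n_self_removed, "self-interaction(s),",
      x$n_dup_removed, "repeated interaction(s)\n")
  invisible(x)
}

#' Node degrees of a PPI network
#'
#' @param net a [ppi_network] object.
#' @return named integer vector of degrees, one per node.
#' @export
network_degree <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  d <- lengths(net$adj)
  names(d) <- net$nodes
  d
}

#' Test whether an unordered pair is an edge
#' @param net a [ppi_network] object.
#' @param u,v protein identifiers.
#' @return logical scalar.
#' @export
has_edge <- function(net, u, v) {
  iu <- match(u, net$nodes)
  iv <- match(v, net$nodes)
  if (is.na(iu) || is.na(iv)) return(FALSE)
  iv %in% net$adj[[iu]]
}

# igraph view of the network, vertex order identical to net$nodes
as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    d = data.frame(
      from = net$nodes[net$edges[, 1L]],
      to = net$nodes[net$edges[, 2L]],
      stringsAsFactors = FALSE
    ),
    directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE)
  )
}
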