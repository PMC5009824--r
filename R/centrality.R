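# Edge-clustering-coefficient centrality and classical baselines.
#
# The ECC of an edge (u,v) is the number of triangles containing the edge
# divided by min(k_u - 1, k_v - 1), the maximum number of triangles the edge
# could participate in given its endpoints' degrees. NC(i) sums ECC over the
# edges incident to i; NNC divides by the network-wide maximum NC.

# triangle count per edge: |adj(u) n adj(v)|, adjacency lists are sorted
edge_triangles <- function(net) {
  adj <- net$adj
  e <- net$edges
  vapply(seq_len(nrow(e)), function(k) {
    length(intersect(adj[[e[k, 1L]]], adj[[e[k, 2L]]]))
  }, integer(1L))
}

# per-edge ECC values aligned with net$edges rows
edge_ecc_values <- function(net) {
  z <- edge_triangles(net)
  deg <- lengths(net$adj)
  denom <- pmin(deg[net$edges[, 1L]], deg[net$edges[, 2L]]) - 1L
  ecc <- ifelse(denom > 0L, z / denom, 0)
  ecc
}

#' Edge clustering coefficient of a single edge
#'
#' `ECC(u,v) = Z(u,v) / min(k_u - 1, k_v - 1)`, where `Z(u,v)` is the number
#' of triangles built on the edge and the denominator is the maximal possible
#' number of such triangles. When the denominator is zero (a pendant edge) the
#' triangle count is necessarily zero too and the coefficient is defined as 0.
#'
#' @param net a [ppi_network].
#' @param u,v endpoints of an edge of `net`.
#' @return a ratio in \[0, 1\].
#' @examples
#' tri <- ppi_network(data.frame(a = c("a", "b", "c"), b = c("b", "c", "a")))
#' edge_clustering_coefficient(tri, "a", "b") # 1: the one possible triangle exists
#' @export
edge_clustering_coefficient <- function(net, u, v) {
  stopifnot(inherits(net, "ppi_network"))
  if (!has_edge(net, u, v)) stop("(", u, ", ", v, ") is not an edge of the network")
  iu <- match(u, net$nodes)
  iv <- match(v, net$nodes)
  z <- length(intersect(net$adj[[iu]], net$adj[[iv]]))
  denom <- min(length(net$adj[[iu]]), length(net$adj[[iv]])) - 1L
  if (denom <= 0L) 0 else z / denom
}

#' Edge clustering coefficients of all edges
#'
#' @param net a [ppi_network].
#' @return data.frame with columns `u`, `v` (identifiers), `triangles`, `ecc`,
#'   one row per edge.
#' @export
ecc_table <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  z <- edge_triangles(net)
  deg <- lengths(net$adj)
  denom <- pmin(deg[net$edges[, 1L]], deg[net$edges[, 2L]]) - 1L
  data.frame(
    u = net$nodes[net$edges[, 1L]],
    v = net$nodes[net$edges[, 2L]],
    triangles = z,
    ecc = ifelse(denom > 0L, z / denom, 0),
    stringsAsFactors = FALSE
  )
}

#' Edge-clustering-coefficient centrality NC
#'
#' `NC(i)` is the sum of the edge clustering coefficients of all edges
#' incident to protein `i`. Proteins on pendant edges or in triangle-free
#' regions score 0.
#'
#' @param net a [ppi_network].
#' @return named numeric vector over all network nodes.
#' @export
nc_scores <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  ecc <- edge_ecc_values(net)
  n <- length(net$nodes)
  nc <- numeric(n)
  ends <- c(net$edges[, 1L], net$edges[, 2L])
  contrib <- rowsum(c(ecc, ecc), group = ends)
  nc[as.integer(rownames(contrib))] <- contrib[, 1L]
  names(nc) <- net$nodes
  nc
}

#' Normalize a score map by its maximum
#'
#' Divides every value by the maximum over all nodes, mapping scores into
#' \[0, 1\]. If the maximum is 0 (e.g. a triangle-free network for NC) all
#' normalized values are 0.
#'
#' @param scores named numeric vector (e.g. from [nc_scores()]).
#' @return named numeric vector in \[0, 1\].
#' @export
normalize_max <- function(scores) {
  m <- max(scores, 0)
  if (m <= 0) return(scores * 0)
  scores / m
}

#' Normalized NC centrality (NNC)
#'
#' @param net a [ppi_network].
#' @return named numeric vector, `NC / max(NC)`, in \[0, 1\].
#' @export
nnc_scores <- function(net) normalize_max(nc_scores(net))

#' Classical baseline centralities
#'
#' Computes one of the six standard centrality measures used as comparison
#' baselines for essentiality ranking:
#' \describe{
#'   \item{DC}{degree centrality}
#'   \item{BC}{shortest-path betweenness (unnormalized pair counts)}
#'   \item{CC}{closeness; on disconnected graphs computed within each
#'     connected component and scaled by (component size - 1)/(n - 1)}
#'   \item{SC}{subgraph centrality, the diagonal of `expm(A)` via
#'     eigendecomposition of the adjacency matrix}
#'   \item{EC}{eigenvector centrality (principal eigenvector, max scaled to 1)}
#'   \item{IC}{Stephenson-Zelen information centrality, computed per connected
#'     component (the defining linear system is singular across components)}
#' }
#'
#' @param net a [ppi_network].
#' @param method one of `"DC"`, `"BC"`, `"CC"`, `"SC"`, `"EC"`, `"IC"`.
#' @return named numeric vector over all network nodes.
#' @export
baseline_centrality <- function(net, method = c("DC", "BC", "CC", "SC", "EC", "IC")) {
  stopifnot(inherits(net, "ppi_network"))
  method <- match.arg(method)
  n <- length(net$nodes)
  g <- as_igraph(net)
  out <- switch(method,
    DC = as.numeric(lengths(net$adj)),
    BC = as.numeric(igraph::betweenness(g, directed = FALSE)),
    CC = closeness_components(net, g),
    SC = subgraph_centrality_exact(net),
    EC = as.numeric(igraph::eigen_centrality(g)$vector),
    IC = information_centrality(net)
  )
  names(out) <- net$nodes
  out
}

# closeness within each component, scaled by (n_c - 1)/(n - 1)
closeness_components <- function(net, g = as_igraph(net)) {
  n <- length(net$nodes)
  comp <- igraph::components(g)$membership
  out <- numeric(n)
  for (c_id in unique(comp)) {
    idx <- which(comp == c_id)
    nc <- length(idx)
    if (nc < 2L) next
    d <- igraph::distances(g, v = idx, to = idx)
    out[idx] <- (nc - 1) / rowSums(d) * (nc - 1) / (n - 1)
  }
  out
}

# exact subgraph centrality: diag(expm(A)) = sum_j V_ij^2 exp(lambda_j)
subgraph_centrality_exact <- function(net) {
  n <- length(net$nodes)
  A <- matrix(0, n, n)
  A[net$edges] <- 1
  A[net$edges[, c(2L, 1L), drop = FALSE]] <- 1
  e <- eigen(A, symmetric = TRUE)
  as.numeric((e$vectors^2) %*% exp(e$values))
}

# Stephenson-Zelen information centrality per connected component:
# with C = (L + J)^{-1}, IC(i) = 1 / (C_ii + (trace(C) - 2 * rowsum_i(C)) / n_c)
information_centrality <- function(net) {
  n <- length(net$nodes)
  g <- as_igraph(net)
  comp <- igraph::components(g)$membership
  out <- numeric(n)
  for (c_id in unique(comp)) {
    idx <- which(comp == c_id)
    nc <- length(idx)
    if (nc < 2L) next
    A <- matrix(0, nc, nc)
    pos <- match(seq_len(n), idx)
    e <- net$edges
    keep <- !is.na(pos[e[, 1L]]) & !is.na(pos[e[, 2L]])
    ec <- cbind(pos[e[keep, 1L]], pos[e[keep, 2L]])
    A[ec] <- 1
    A[ec[, c(2L, 1L), drop = FALSE]] <- 1
    L <- diag(rowSums(A)) - A
    C <- solve(L + 1)
    out[idx] <- 1 / (diag(C) + (sum(diag(C)) - 2 * rowSums(C)) / nc)
  }
  out
}
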