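# Shared fixture builders. All fixtures are built in code; the brute-force
# triangle oracle below is kept independent of the package internals: it
# works on a raw pair list via a dense adjacency matrix.

net_from_pairs <- function(...) {
  pairs <- list(...)
  ppi_network(data.frame(
    a = vapply(pairs, `[[`, "", 1L),
    b = vapply(pairs, `[[`, "", 2L),
    stringsAsFactors = FALSE
  ))
}

triangle_net <- function() net_from_pairs(c("a", "b"), c("b", "c"), c("c", "a"))
path3_net <- function() net_from_pairs(c("a", "b"), c("b", "c"))
# edges {ab, ac, ad, bc, be}: one triangle (abc) hanging off pendant nodes
house_net <- function() {
  net_from_pairs(c("a", "b"), c("a", "c"), c("a", "d"), c("b", "c"), c("b", "e"))
}

write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# random simple graph as a raw (deduplicated) pair matrix over letter ids
random_pairs <- function(n, p) {
  ids <- sprintf("n%02d", seq_len(n))
  all_pairs <- t(utils::combn(ids, 2L))
  keep <- stats::runif(nrow(all_pairs)) < p
  if (!any(keep)) keep[sample(nrow(all_pairs), 1L)] <- TRUE
  all_pairs[keep, , drop = FALSE]
}

# independent oracle: dense adjacency matrix, triangles on an edge counted
# over all third vertices
oracle_adjacency <- function(pairs) {
  ids <- sort(unique(c(pairs)))
  M <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  M[pairs] <- TRUE
  M[pairs[, c(2L, 1L), drop = FALSE]] <- TRUE
  M
}

oracle_edge_scores <- function(pairs) {
  M <- oracle_adjacency(pairs)
  deg <- rowSums(M)
  z <- apply(pairs, 1L, function(e) sum(M[e[1L], ] & M[e[2L], ]))
  denom <- pmin(deg[pairs[, 1L]], deg[pairs[, 2L]]) - 1
  data.frame(
    u = pairs[, 1L], v = pairs[, 2L], triangles = as.integer(z),
    ecc = ifelse(denom > 0, z / denom, 0),
    stringsAsFactors = FALSE
  )
}

oracle_nc <- function(pairs) {
  es <- oracle_edge_scores(pairs)
  ids <- sort(unique(c(pairs)))
  nc <- stats::setNames(numeric(length(ids)), ids)
  for (k in seq_len(nrow(es))) {
    nc[es$u[k]] <- nc[es$u[k]] + es$ecc[k]
    nc[es$v[k]] <- nc[es$v[k]] + es$ecc[k]
  }
  nc
}
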