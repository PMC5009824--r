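# Orthology conservation score: OS(i) counts the reference species in which
# protein i has a (seed-pair) ortholog; NOS divides by the maximum over the
# network, so a protein conserved across the whole reference set scores 1 and
# a protein with no orthologs scores 0.

#' Orthologous score OS
#'
#' @param orth an `annotation_map` whose labels are reference species (from
#'   [read_annotation_pairs()] on a protein/species table).
#' @param nodes character vector of network node identifiers.
#' @return named integer vector: for each node, the number of reference
#'   species with an ortholog (0 for proteins absent from the table).
#' @export
compute_os <- function(orth, nodes) {
  stopifnot(inherits(orth, "annotation_map"))
  cnt <- lengths(orth$entries)
  os <- as.integer(cnt[nodes])
  os[is.na(os)] <- 0L
  names(os) <- nodes
  os
}

#' Normalized orthologous score NOS
#'
#' `NOS(i) = OS(i) / max_j OS(j)` over the network's nodes; identically 0 when
#' no protein has any ortholog.
#'
#' @param os named integer vector from [compute_os()].
#' @return named numeric vector in \[0, 1\].
#' @export
normalize_nos <- function(os) {
  x <- as.numeric(os)
  names(x) <- names(os)
  normalize_max(x)
}
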