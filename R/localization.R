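# Subcellular-localization correlation score.
#
# Proteins are ranked by NNC; the top k% and bottom k% define two contrast
# sets. For every subcellular location l, f_l counts top-set proteins
# annotated with l and h_l counts bottom-set proteins. The localization
# correlation coefficient is
#   LCC(l) = 1 - h_l/f_l   if f_l <  h_l   (negative association)
#   LCC(l) = f_l/h_l - 1   if f_l >= h_l   (positive association)
# with zero-denominator cases substituted from the finite values of the
# matching branch. A protein's SL is the sum of LCC over its locations; NSL
# shifts by the maximal |SL| and rescales to [0, 1].

#' Select the top and bottom k% proteins by a score
#'
#' Proteins are sorted by score descending with ties broken by identifier
#' ascending; the first and last `ceiling(k_percent/100 * N)` proteins form
#' the top and bottom sets. Both sets always have equal size.
#'
#' @param scores named numeric vector (typically NNC values over all nodes).
#' @param k_percent selection percentage, in (0, 50\].
#' @return list with character vectors `top` and `bottom`.
#' @export
select_extreme_sets <- function(scores, k_percent = 5) {
  if (length(scores) == 0L) stop("cannot select from an empty score map")
  stopifnot(k_percent > 0, k_percent <= 50)
  ids <- names(scores)
  ord <- order(-scores, ids)
  m <- as.integer(ceiling(k_percent * length(scores) / 100))
  list(
    top = ids[ord[seq_len(m)]],
    bottom = ids[ord[seq.int(length(scores) - m + 1L, length(scores))]]
  )
}

#' Location correlation coefficients from top/bottom contrast sets
#'
#' Counts, for every location in the annotation universe, the number of
#' top-set proteins (`f`) and bottom-set proteins (`h`) annotated with it and
#' applies the piecewise LCC formula (see the package vignette). Locations
#' observed in neither set get LCC = 0.
#'
#' Zero-denominator substitution (`lcc_zero_policy`):
#' \describe{
#'   \item{"literal"}{`f = 0` takes the maximum of `1 - h/f` over locations
#'     with `f != 0` in the negative branch; `h = 0` takes the maximum of
#'     `f/h - 1` over locations with `h != 0` in the positive branch. If the
#'     pool is empty the LCC is 0.}
#'   \item{"symmetric_extreme"}{as above, but `f = 0` takes the minimum (the
#'     most extreme negative value), mirroring the positive branch's maximum.}
#' }
#'
#' @param top,bottom character vectors of equal length (from
#'   [select_extreme_sets()]).
#' @param ann an `annotation_map` of subcellular locations.
#' @param lcc_zero_policy `"literal"` (default) or `"symmetric_extreme"`.
#' @return data.frame with columns `location`, `f`, `h`, `lcc`.
#' @export
compute_lcc_table <- function(top, bottom, ann,
                              lcc_zero_policy = c("literal", "symmetric_extreme")) {
  stopifnot(inherits(ann, "annotation_map"), length(top) == length(bottom))
  lcc_zero_policy <- match.arg(lcc_zero_policy)
  locs <- ann$labels
  count_in <- function(set) {
    labs <- unlist(ann$entries[intersect(set, names(ann$entries))],
                   use.names = FALSE)
    as.integer(table(factor(labs, levels = locs)))
  }
  f <- count_in(top)
  h <- count_in(bottom)
  data.frame(
    location = locs,
    f = f,
    h = h,
    lcc = lcc_values(f, h, lcc_zero_policy),
    stringsAsFactors = FALSE
  )
}

lcc_values <- function(f, h, lcc_zero_policy = "literal") {
  lcc <- numeric(length(f))
  neg <- f < h & f > 0L
  pos <- f >= h & h > 0L
  lcc[neg] <- 1 - h[neg] / f[neg]
  lcc[pos] <- f[pos] / h[pos] - 1
  # substitution pools: finite values of the matching branch
  f0 <- f == 0L & h > 0L
  if (any(f0)) {
    pool <- lcc[neg]
    if (length(pool) == 0L) {
      lcc[f0] <- 0
    } else if (lcc_zero_policy == "literal") {
      lcc[f0] <- max(pool)
    } else {
      lcc[f0] <- min(pool)
    }
  }
  h0 <- h == 0L & f > 0L
  if (any(h0)) {
    pool <- lcc[pos]
    lcc[h0] <- if (length(pool) == 0L) 0 else max(pool)
  }
  lcc
}

#' Per-protein subcellular localization score SL
#'
#' `SL(i)` is the sum of the LCC values of all locations in which protein `i`
#' appears; proteins without localization annotation score 0.
#'
#' @param ann an `annotation_map` of subcellular locations.
#' @param lcc an LCC table from [compute_lcc_table()].
#' @param nodes character vector of network node identifiers.
#' @return named numeric vector of SL values over `nodes`.
#' @export
compute_sl <- function(ann, lcc, nodes) {
  stopifnot(inherits(ann, "annotation_map"))
  lcc_by_loc <- stats::setNames(lcc$lcc, lcc$location)
  sl <- vapply(nodes, function(p) {
    labs <- ann$entries[[p]]
    if (is.null(labs)) 0 else sum(lcc_by_loc[labs], na.rm = TRUE)
  }, numeric(1L))
  names(sl) <- nodes
  sl
}

#' Normalized subcellular localization score NSL
#'
#' `NSL(i) = (SL(i) + M) / max_j(SL(j) + M)` with `M = max_j |SL(j)|`, which
#' maps SL into \[0, 1\] while preserving order. If the denominator is 0 (all
#' SL equal to a non-positive constant) all NSL are set to 0.
#'
#' @param sl named numeric vector of SL values.
#' @return named numeric vector in \[0, 1\].
#' @export
normalize_nsl <- function(sl) {
  if (length(sl) == 0L) return(sl)
  m <- max(abs(sl))
  denom <- max(sl) + m
  if (denom <= 1e-12) return(sl * 0)
  (sl + m) / denom
}
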