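# The SON essentiality ranking: a weighted linear combination of the three
# normalized per-protein scores,
#   pr(i) = (1 - alpha) * NOS(i) + alpha * [ (1 - beta) * NSL(i) + beta * NNC(i) ]
# so the effective weights are (1 - alpha) on orthology, alpha*(1 - beta) on
# localization and alpha*beta on network centrality. At the published optimum
# alpha = 0.7, beta = 0.3 these are 30%, 49% and 21%.

#' Combine component scores into the SON sorting score
#'
#' @param nos,nsl,nnc numeric vectors (recycled) of normalized orthology,
#'   localization and network-centrality scores, each expected in \[0, 1\].
#' @param alpha weight splitting orthology (`1 - alpha`) from the two
#'   network-derived scores (`alpha`); in \[0, 1\].
#' @param beta weight splitting, within the `alpha` share, localization
#'   (`1 - beta`) from network centrality (`beta`); in \[0, 1\].
#' @return numeric vector of sorting scores; in \[0, 1\] whenever all
#'   components are.
#' @examples
#' son_score(1, 0, 0, alpha = 0.7, beta = 0.3) # orthology weight: 0.30
#' son_score(0, 1, 0, alpha = 0.7, beta = 0.3) # localization weight: 0.49
#' son_score(0, 0, 1, alpha = 0.7, beta = 0.3) # centrality weight: 0.21
#' @export
son_score <- function(nos, nsl, nnc, alpha = 0.7, beta = 0.3) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    stop("alpha must be a single value in [0, 1]")
  }
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) ||
      beta < 0 || beta > 1) {
    stop("beta must be a single value in [0, 1]")
  }
  (1 - alpha) * nos + alpha * ((1 - beta) * nsl + beta * nnc)
}

#' Rank proteins by score, descending
#'
#' Stable descending sort with ties broken by identifier ascending; ranks are
#' the permutation 1..N (1 = best candidate).
#'
#' @param scores named numeric vector.
#' @return named integer vector of ranks aligned with `scores`.
#' @export
rank_proteins <- function(scores) {
  ord <- order(-scores, names(scores))
  r <- integer(length(scores))
  r[ord] <- seq_along(scores)
  names(r) <- names(scores)
  r
}

#' Size of a top-k% selection
#'
#' `ceiling(k_percent/100 * n)`, the convention under which the 5093-protein
#' yeast network yields top sets of 51, 255, 510, 764, 1019 and 1274 proteins
#' at 1, 5, 10, 15, 20 and 25 percent.
#'
#' @param n number of ranked proteins.
#' @param k_percent percentage cutoff in (0, 100\].
#' @return integer selection size.
#' @export
top_k_count <- function(n, k_percent) {
  stopifnot(n >= 1, k_percent > 0, k_percent <= 100)
  as.integer(ceiling(k_percent * n / 100))
}

# component scores shared by son() and son_grid(); localization/orthology may
# be NULL, in which case the corresponding normalized score is identically 0
son_components <- function(network, localization = NULL, orthologs = NULL,
                           k_percent = 5,
                           lcc_zero_policy = c("literal", "symmetric_extreme"),
                           warn_missing = TRUE) {
  stopifnot(inherits(network, "ppi_network"))
  lcc_zero_policy <- match.arg(lcc_zero_policy)
  nodes <- network$nodes
  nc <- nc_scores(network)
  nnc <- normalize_max(nc)
  zero <- stats::setNames(numeric(length(nodes)), nodes)
  if (is.null(localization)) {
    if (warn_missing) {
      warning("no localization annotations supplied: NSL treated as identically 0",
              call. = FALSE)
    }
    sl <- zero
    nsl <- zero
    lcc_table <- NULL
  } else {
    sets <- select_extreme_sets(nnc, k_percent)
    lcc_table <- compute_lcc_table(sets$top, sets$bottom, localization,
                                   lcc_zero_policy)
    sl <- compute_sl(localization, lcc_table, nodes)
    nsl <- normalize_nsl(sl)
  }
  if (is.null(orthologs)) {
    if (warn_missing) {
      warning("no orthology table supplied: NOS treated as identically 0",
              call. = FALSE)
    }
    os <- stats::setNames(integer(length(nodes)), nodes)
    nos <- zero
  } else {
    os <- compute_os(orthologs, nodes)
    nos <- normalize_nos(os)
  }
  list(nc = nc, nnc = nnc, sl = sl, nsl = nsl, os = os, nos = nos,
       lcc_table = lcc_table)
}

#' Fit the SON essentiality ranking on a PPI network
#'
#' Runs the full scoring pipeline: (1) NC and NNC from edge clustering
#' coefficients; (2) the localization correlation table from the top/bottom
#' `k_percent` NNC contrast and per-protein SL/NSL; (3) per-protein OS/NOS
#' from the orthology table; (4) the combined sorting score
#' `pr = (1-alpha)*NOS + alpha*[(1-beta)*NSL + beta*NNC]`; (5) a descending
#' stable sort into ranks. A missing localization or orthology source sets
#' the corresponding normalized score to 0 (with a warning), which permits
#' topology-only or orthology-only runs.
#'
#' @param network a [ppi_network].
#' @param localization optional `annotation_map` of subcellular locations.
#' @param orthologs optional `annotation_map` of reference species.
#' @param alpha,beta combination weights in \[0, 1\]; defaults 0.7 and 0.3,
#'   the published optimum.
#' @param k_percent top/bottom selection percentage for the localization
#'   contrast; default 5.
#' @param lcc_zero_policy zero-denominator policy for LCC, see
#'   [compute_lcc_table()].
#' @return an object of class `son`: a list with `scores` (data.frame in rank
#'   order with columns protein, degree, NC, NNC, SL, NSL, OS, NOS, pr, rank),
#'   `lcc_table`, `parameters`, `n_nodes`, `n_edges` and the matched call.
#' @examples
#' bench <- simulate_benchmark(n_proteins = 200, seed = 1)
#' fit <- son(bench$network, bench$localization, bench$orthologs)
#' head(fit$scores)
#' @export
son <- function(network, localization = NULL, orthologs = NULL,
                alpha = 0.7, beta = 0.3, k_percent = 5,
                lcc_zero_policy = c("literal", "symmetric_extreme")) {
  lcc_zero_policy <- match.arg(lcc_zero_policy)
  comp <- son_components(network, localization, orthologs, k_percent,
                         lcc_zero_policy)
  pr <- son_score(comp$nos, comp$nsl, comp$nnc, alpha, beta)
  rk <- rank_proteins(pr)
  scores <- data.frame(
    protein = network$nodes,
    degree = as.integer(lengths(network$adj)),
    NC = unname(comp$nc),
    NNC = unname(comp$nnc),
    SL = unname(comp$sl),
    NSL = unname(comp$nsl),
    OS = unname(comp$os),
    NOS = unname(comp$nos),
    pr = unname(pr),
    rank = unname(rk),
    stringsAsFactors = FALSE
  )
  scores <- scores[order(scores$rank), ]
  rownames(scores) <- NULL
  structure(
    list(
      scores = scores,
      lcc_table = comp$lcc_table,
      parameters = list(alpha = alpha, beta = beta, k_percent = k_percent,
                        lcc_zero_policy = lcc_zero_policy),
      n_nodes = length(network$nodes),
      n_edges = nrow(network$edges),
      call = match.call()
    ),
    class = "son"
  )
}

#' @export
print.son <- function(x, n = 6L, ...) {
  p <- x$parameters
  cat("SON essentiality ranking\n")
  cat(sprintf("  network: %d proteins, %d interactions\n", x$n_nodes, x$n_edges))
  cat(sprintf("  alpha = %.2f, beta = %.2f (weights: NOS %.0f%%, NSL %.0f%%, NNC %.0f%%)\n",
              p$alpha, p$beta, 100 * (1 - p$alpha),
              100 * p$alpha * (1 - p$beta), 100 * p$alpha * p$beta))
  cat("  top-ranked proteins:\n")
  print(utils::head(x$scores[, c("protein", "degree", "NNC", "NSL", "NOS", "pr", "rank")], n),
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.son <- function(object, percents = c(1, 5, 10, 15, 20, 25), ...) {
  s <- object$scores
  out <- list(
    parameters = object$parameters,
    n_nodes = object$n_nodes,
    n_edges = object$n_edges,
    top_sizes = stats::setNames(
      vapply(percents, function(p) top_k_count(object$n_nodes, p), integer(1L)),
      paste0(percents, "%")),
    score_summary = summary(s[, c("NNC", "NSL", "NOS", "pr")]),
    lcc_table = object$lcc_table
  )
  class(out) <- "summary.son"
  out
}

#' @export
print.summary.son <- function(x, ...) {
  cat("SON ranking over", x$n_nodes, "proteins /", x$n_edges, "interactions\n")
  cat("alpha =", x$parameters$alpha, " beta =", x$parameters$beta, "\n\n")
  cat("top-set sizes:\n")
  print(x$top_sizes)
  cat("\nscore distribution:\n")
  print(x$score_summary)
  if (!is.null(x$lcc_table)) {
    cat("\nlocation correlation coefficients:\n")
    print(x$lcc_table, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @export
coef.son <- function(object, ...) {
  stats::setNames(object$scores$pr, object$scores$protein)
}

#' @export
as.data.frame.son <- function(x, ...) x$scores

#' Extract the top-ranked candidate essential proteins
#'
#' @param object a fitted [son] object.
#' @param top_percent output cutoff K as a percentage; default 5.
#' @param ... unused.
#' @return character vector of the top `ceiling(K/100 * N)` protein
#'   identifiers, best first.
#' @export
predict.son <- function(object, top_percent = 5, ...) {
  m <- top_k_count(object$n_nodes, top_percent)
  object$scores$protein[seq_len(m)]
}

#' @export
plot.son <- function(x, ...) {
  s <- x$scores
  graphics::plot(s$rank, s$pr, type = "l", lwd = 2,
                 xlab = "rank", ylab = "score",
                 main = "SON sorting score by rank", ...)
  graphics::lines(s$rank, s$NNC, col = "grey55", lty = 2)
  graphics::lines(s$rank, s$NSL, col = "grey55", lty = 3)
  graphics::lines(s$rank, s$NOS, col = "grey55", lty = 4)
  graphics::legend("topright", c("pr", "NNC", "NSL", "NOS"),
                   col = c("black", "grey55", "grey55", "grey55"),
                   lty = 1:4, lwd = c(2, 1, 1, 1), bty = "n")
  invisible(x)
}

#' Parameter grid scan of essential-protein counts
#'
#' Recomputes the SON ranking over a grid of (alpha, beta) pairs — the
#' component scores are computed once — and counts gold-standard essential
#' proteins among the top cutoffs, one row per parameter pair.
#'
#' @inheritParams son
#' @param gold character vector of gold-standard essential proteins.
#' @param alphas,betas numeric grids in \[0, 1\]; default `seq(0, 1, 0.1)`.
#' @param percents top-percentage cutoffs to count at.
#' @return data.frame with columns `alpha`, `beta` and one `top_<p>` count
#'   column per percentage.
#' @export
son_grid <- function(network, localization = NULL, orthologs = NULL, gold,
                     alphas = seq(0, 1, by = 0.1), betas = seq(0, 1, by = 0.1),
                     percents = c(1, 5, 10, 15, 20, 25), k_percent = 5,
                     lcc_zero_policy = c("literal", "symmetric_extreme")) {
  if (length(alphas) == 0L || length(betas) == 0L) stop("empty parameter grid")
  if (length(gold) == 0L) stop("gold-standard list is empty")
  lcc_zero_policy <- match.arg(lcc_zero_policy)
  comp <- son_components(network, localization, orthologs, k_percent,
                         lcc_zero_policy)
  n <- length(network$nodes)
  is_gold <- network$nodes %in% gold
  sizes <- vapply(percents, function(p) top_k_count(n, p), integer(1L))
  grid <- expand.grid(beta = betas, alpha = alphas,
                      KEEP.OUT.ATTRS = FALSE)[, c("alpha", "beta")]
  counts <- matrix(0L, nrow(grid), length(percents))
  for (r in seq_len(nrow(grid))) {
    pr <- son_score(comp$nos, comp$nsl, comp$nnc, grid$alpha[r], grid$beta[r])
    ord <- order(-pr, network$nodes)
    cum <- cumsum(is_gold[ord])
    counts[r, ] <- as.integer(cum[sizes])
  }
  colnames(counts) <- paste0("top_", percents)
  cbind(grid, as.data.frame(counts))
}
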