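# Evaluation of an essentiality ranking against a gold standard: top-K%
# histogram counts, the precision-recall curve over all cutoffs K = 1..N,
# the jackknife cumulative-essential curve, and counts stratified by node
# connectivity. Gold-standard members absent from the ranking are excluded
# from numerator and denominator alike.

#' Ranked protein identifiers from a ranking-like object
#'
#' Normalizes the plug-in ranking interface used by the evaluation functions:
#' a fitted [son] object, a named numeric score vector (sorted descending,
#' ties broken by identifier ascending), or an already-ordered character
#' vector of identifiers.
#'
#' @param x a `son` object, named numeric vector, or character vector.
#' @return character vector of identifiers, best candidate first.
#' @export
ranked_proteins <- function(x) {
  if (inherits(x, "son")) return(x$scores$protein)
  if (is.character(x)) {
    if (anyDuplicated(x)) stop("ranking contains duplicate identifiers")
    return(x)
  }
  if (is.numeric(x) && !is.null(names(x))) {
    return(names(x)[order(-x, names(x))])
  }
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a ranking")
}

#' Gold-standard counts among the top k% of a ranking
#'
#' @param ranking a ranking-like object (see [ranked_proteins()]).
#' @param gold character vector of gold-standard essential proteins.
#' @param percents percentage cutoffs; default the conventional
#'   1, 5, 10, 15, 20, 25.
#' @return named integer vector of essential counts, one per percentage.
#' @export
topk_essential_counts <- function(ranking, gold,
                                  percents = c(1, 5, 10, 15, 20, 25)) {
  ids <- ranked_proteins(ranking)
  if (length(gold) == 0L) stop("gold-standard list is empty")
  cum <- cumsum(ids %in% gold)
  n <- length(ids)
  sizes <- vapply(percents, function(p) top_k_count(n, p), integer(1L))
  stats::setNames(as.integer(cum[sizes]), paste0(percents, "%"))
}

#' Precision-recall curve of a ranking
#'
#' For every cutoff K = 1..N the top K proteins are called candidate
#' essentials: `precision(K) = TP(K)/K`, `recall(K) = TP(K)/|gold in
#' ranking|`. The area under the curve is computed by trapezoidal
#' integration over recall.
#'
#' @inheritParams topk_essential_counts
#' @return list with `curve` (data.frame: K, tp, precision, recall) and
#'   `auc`.
#' @export
pr_curve <- function(ranking, gold) {
  ids <- ranked_proteins(ranking)
  is_ess <- ids %in% gold
  n_gold <- sum(is_ess)
  if (n_gold == 0L) stop("no gold-standard protein present in the ranking")
  if (n_gold == length(ids)) stop("no nonessential protein present in the ranking")
  tp <- cumsum(is_ess)
  k <- seq_along(ids)
  precision <- tp / k
  recall <- tp / n_gold
  auc <- sum(diff(c(0, recall)) * (precision + c(precision[1L], utils::head(precision, -1L))) / 2)
  list(curve = data.frame(K = k, tp = tp, precision = precision, recall = recall),
       auc = auc)
}

#' Jackknife cumulative-essential curve of a ranking
#'
#' The curve value at rank K is the cumulative count of gold-standard
#' essentials among the top K proteins. The normalized area,
#' `sum(curve) / (N * |gold in ranking|)`, is ~0.5 for a random ranking and
#' approaches 1 for a perfect one.
#'
#' @inheritParams topk_essential_counts
#' @return list with `curve` (integer vector of length N) and `area`.
#' @export
jackknife_curve <- function(ranking, gold) {
  ids <- ranked_proteins(ranking)
  is_ess <- ids %in% gold
  n_gold <- sum(is_ess)
  cum <- cumsum(is_ess)
  area <- if (n_gold == 0L) 0 else sum(cum) / (length(ids) * n_gold)
  list(curve = as.integer(cum), area = area)
}

#' Connectivity-stratified essential counts
#'
#' Splits the gold-standard essentials found in each top-k% set into a
#' low-connectivity stratum (degree at or below `threshold`) and a
#' high-connectivity stratum. The two strata always sum to the unstratified
#' count at the same cutoff.
#'
#' @inheritParams topk_essential_counts
#' @param net the [ppi_network] supplying node degrees.
#' @param threshold degree threshold separating strata; default 10.
#' @return data.frame with columns `percent`, `low`, `high`, `total`.
#' @export
connectivity_stratified_counts <- function(ranking, gold, net, threshold = 10,
                                           percents = c(1, 5, 10, 15, 20, 25)) {
  ids <- ranked_proteins(ranking)
  deg <- network_degree(net)[ids]
  if (anyNA(deg)) stop("ranking contains proteins absent from the network")
  is_ess <- ids %in% gold
  low_cum <- cumsum(is_ess & deg <= threshold)
  high_cum <- cumsum(is_ess & deg > threshold)
  n <- length(ids)
  sizes <- vapply(percents, function(p) top_k_count(n, p), integer(1L))
  data.frame(
    percent = percents,
    low = as.integer(low_cum[sizes]),
    high = as.integer(high_cum[sizes]),
    total = as.integer(low_cum[sizes] + high_cum[sizes])
  )
}

#' Full evaluation report for an essentiality ranking
#'
#' Bundles the three comparison methodologies (top-K% histogram counts,
#' precision-recall curve with AUC, jackknife curve with normalized area)
#' and, when a network is supplied, the connectivity-stratified counts.
#' Works identically for a [son] fit and for any baseline centrality score
#' vector.
#'
#' @inheritParams topk_essential_counts
#' @param network optional [ppi_network] for the degree stratification.
#' @param degree_threshold stratification threshold; default 10.
#' @param method label stored in the report (e.g. `"SON"`, `"DC"`).
#' @return object of class `son_evaluation`.
#' @export
evaluate_ranking <- function(ranking, gold, network = NULL,
                             percents = c(1, 5, 10, 15, 20, 25),
                             degree_threshold = 10, method = "SON") {
  ids <- ranked_proteins(ranking)
  gold_in <- intersect(gold, ids)
  pr <- pr_curve(ids, gold_in)
  jk <- jackknife_curve(ids, gold_in)
  out <- list(
    method = method,
    n = length(ids),
    n_gold = length(gold_in),
    topk = topk_essential_counts(ids, gold_in, percents),
    pr_curve = pr$curve,
    pr_auc = pr$auc,
    jackknife = jk$curve,
    jackknife_area = jk$area,
    stratified = if (!is.null(network)) {
      connectivity_stratified_counts(ids, gold_in, network, degree_threshold,
                                     percents)
    },
    degree_threshold = degree_threshold
  )
  class(out) <- "son_evaluation"
  out
}

#' @export
print.son_evaluation <- function(x, ...) {
  cat("Evaluation of", x$method, "ranking:", x$n, "proteins,",
      x$n_gold, "gold-standard essentials in ranking\n")
  cat("essential proteins in top-K%:\n")
  print(x$topk)
  cat(sprintf("PR AUC: %.4f   jackknife area: %.4f\n", x$pr_auc, x$jackknife_area))
  if (!is.null(x$stratified)) {
    cat("by connectivity (degree threshold", x$degree_threshold, "):\n")
    print(x$stratified, row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.son_evaluation <- function(x, type = c("pr", "jackknife"), ...) {
  type <- match.arg(type)
  if (type == "pr") {
    graphics::plot(x$pr_curve$recall, x$pr_curve$precision, type = "l", lwd = 2,
                   xlab = "recall", ylab = "precision", ylim = c(0, 1),
                   main = paste0("Precision-recall (", x$method,
                                 "), AUC = ", sprintf("%.3f", x$pr_auc)), ...)
  } else {
    graphics::plot(seq_along(x$jackknife), x$jackknife, type = "l", lwd = 2,
                   xlab = "rank", ylab = "cumulative essential proteins",
                   main = paste0("Jackknife curve (", x$method, ")"), ...)
    graphics::abline(a = 0, b = x$n_gold / x$n, col = "grey60", lty = 2)
  }
  invisible(x)
}
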