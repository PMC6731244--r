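# Pathway over-representation analysis: one-sided hypergeometric tests with
# Benjamini-Hochberg FDR, plus the PCA-loading quartile selection that feeds
# the compound sets.

#' Upper-tail hypergeometric probability
#'
#' P[X >= k] for X ~ Hypergeometric(N, K, n): drawing `n` items without
#' replacement from a universe of `N` of which `K` are "successes". Computed
#' as an exact log-space sum of point masses (log-sum-exp over
#' `dhyper(log = TRUE)` terms), so tiny tail probabilities are stable.
#'
#' @param k observed overlap (successes drawn), `0 <= k <= min(n, K)`.
#' @param K successes in the universe.
#' @param n draws.
#' @param N universe size.
#' @return probability in (0, 1]; exactly 1 when `k = 0`.
#' @examples
#' hypergeom_upper_tail(5, 5, 5, 20)  # 1 / choose(20, 5)
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  stopifnot(length(k) == 1, length(K) == 1, length(n) == 1, length(N) == 1)
  if (any(c(k, K, n, N) < 0) || k != round(k) || K != round(K) ||
      n != round(n) || N != round(N))
    stop("arguments must be non-negative integers")
  if (K > N || n > N) stop("K and n must not exceed N")
  if (k > min(n, K)) stop("k must not exceed min(n, K)")
  if (k == 0) return(1)
  kk <- k:min(n, K)
  lp <- stats::dhyper(kk, K, N - K, n, log = TRUE)
  mx <- max(lp)
  exp(mx + log(sum(exp(lp - mx))))
}

#' Pathway over-representation analysis
#'
#' Tests each pathway for enrichment of a selected compound set within a
#' measurement universe. Pathway memberships are intersected with the
#' universe before counting (so `K` is the pathway's in-universe size); only
#' pathways with `K >= 1` are tested. P-values are one-sided upper-tail
#' hypergeometric; q-values are Benjamini-Hochberg across the tested
#' pathways. Results are sorted by p ascending, ties broken by pathway id,
#' and are invariant to the input ordering of pathways and compounds.
#'
#' The universe should normally be the set of compounds actually measured in
#' the experiment (the conservative convention), not the whole database; it
#' is a required argument for that reason.
#'
#' @param selected character vector of selected compound ids (subset of
#'   `universe`).
#' @param pathways either a `metabolic_db` (its pathway table is used) or a
#'   data.frame with columns `id`, `name` and list-column `compound_ids`.
#' @param universe character vector of measured compound ids.
#' @return data.frame with columns `pathway_id`, `pathway_name`, `k`, `K`,
#'   `n`, `N`, `p`, `q`.
#' @export
enrich_pathways <- function(selected, pathways, universe) {
  if (inherits(pathways, "metabolic_db")) pathways <- pathways$pathways
  universe <- unique(as.character(universe))
  selected <- unique(as.character(selected))
  if (length(universe) == 0) stop("universe must be non-empty")
  if (length(selected) == 0) stop("selected set must be non-empty")
  stray <- setdiff(selected, universe)
  if (length(stray) > 0)
    stop("selected compounds outside the universe: ",
         paste(stray, collapse = ", "))

  N <- length(universe); n <- length(selected)
  rows <- list()
  for (i in seq_len(nrow(pathways))) {
    members <- intersect(pathways$compound_ids[[i]], universe)
    K <- length(members)
    if (K == 0) next
    k <- length(intersect(selected, members))
    rows[[length(rows) + 1L]] <- data.frame(
      pathway_id = pathways$id[i], pathway_name = pathways$name[i],
      k = k, K = K, n = n, N = N,
      p = hypergeom_upper_tail(k, K, n, N), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(pathway_id = character(0), pathway_name = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0), q = numeric(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$p, res$pathway_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Select top and bottom quartile of component loadings
#'
#' Splits compounds by their loading on one principal component: the positive
#' set holds those at or above the 75th percentile, the negative set those at
#' or below the 25th (percentiles by linear interpolation, the default
#' `quantile()` type). The two sets are disjoint by construction when the
#' loadings are not all equal.
#'
#' @param loadings named numeric vector of per-compound loadings for one
#'   component (names are compound ids); at least 4 finite values.
#' @return list with character vectors `positive` and `negative`.
#' @export
select_loading_quartiles <- function(loadings) {
  if (is.null(names(loadings)) || any(!nzchar(names(loadings))))
    stop("loadings must be a named vector (compound ids)")
  loadings <- loadings[is.finite(loadings)]
  if (length(loadings) < 4) stop("need at least 4 finite loadings")
  if (diff(range(loadings)) == 0)
    stop("all loadings equal; quartiles undefined")
  qs <- stats::quantile(loadings, c(0.25, 0.75), names = FALSE, type = 7)
  list(positive = sort(names(loadings)[loadings >= qs[2]]),
       negative = sort(names(loadings)[loadings <= qs[1]]))
}
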