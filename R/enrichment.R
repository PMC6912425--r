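# Gene-set over-representation analysis by exact 2x2 (hypergeometric) test.

#' Over-representation test for one gene set
#'
#' Builds the 2x2 table (DE vs not, in set vs not) over the universe and
#' computes the one-sided hypergeometric upper-tail p-value
#' `P[X >= k]` with `X ~ Hypergeom(N, m, K)`, where `k` is the overlap of
#' the DE list with the set, `m` the set size in the universe, `K` the DE
#' list size and `N` the universe size. The odds ratio uses a Haldane 0.5
#' correction when any cell is zero.
#'
#' @param de_genes character vector of differentially expressed gene ids
#'   (must be a subset of `universe`).
#' @param gene_set character vector of set members (intersected with the
#'   universe first).
#' @param universe character vector of all tested gene ids.
#' @return one-row data.frame: `k`, `m`, `K`, `N`, `odds_ratio`, `p`.
#' @export
ora_test <- function(de_genes, gene_set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  de_genes <- unique(de_genes)
  if (length(de_genes) == 0) stop("empty DE list")
  if (!all(de_genes %in% universe))
    stop("DE gene(s) outside the universe: ",
         setdiff(de_genes, universe)[1])
  set <- intersect(unique(gene_set), universe)
  k <- length(intersect(de_genes, set))
  m <- length(set)
  K <- length(de_genes)
  N <- length(universe)
  p <- stats::phyper(k - 1, m, N - m, K, lower.tail = FALSE)
  a <- k; b <- K - k; cc <- m - k; d <- N - m - K + k
  if (min(a, b, cc, d) == 0) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  data.frame(k = k, m = m, K = K, N = N,
             odds_ratio = (a * d) / (b * cc), p = p)
}

#' Over-representation of all sets across all contrasts
#'
#' Runs [ora_test()] for every set in every DE list and BH-adjusts p-values
#' across sets within each contrast.
#'
#' @param de_lists named list (one element per contrast) of DE gene-id
#'   vectors.
#' @param sets named list of gene sets (e.g. from [read_gmt()]).
#' @param universe all tested gene ids.
#' @return data.frame: `set_name`, `contrast`, `k`, `m`, `K`, `N`,
#'   `odds_ratio`, `p`, `fdr`.
#' @export
enrich_all <- function(de_lists, sets, universe) {
  out <- lapply(names(de_lists), function(ctr) {
    rows <- lapply(names(sets), function(nm) {
      r <- ora_test(de_lists[[ctr]], sets[[nm]], universe)
      cbind(data.frame(set_name = nm, contrast = ctr,
                       stringsAsFactors = FALSE), r)
    })
    tab <- do.call(rbind, rows)
    tab$fdr <- stats::p.adjust(tab$p, method = "BH")
    tab
  })
  do.call(rbind, out)
}
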