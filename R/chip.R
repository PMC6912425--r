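# Peak-to-gene annotation, promoter-window classification, occupancy
# aggregation and differential peak binding. All coordinates are 0-based
# half-open; peak membership in a region is decided by the peak midpoint.

peak_midpoint <- function(peaks) (peaks$start + peaks$end) %/% 2L

#' Assign each peak to the nearest gene by TSS distance
#'
#' The assigned gene minimizes the absolute distance between the peak
#' midpoint and the gene TSS on the same chromosome; ties are broken by the
#' lexicographically smaller gene id. The signed distance is strand-aware:
#' negative values lie upstream of the TSS.
#'
#' @param peaks peak table (as from [read_bed()]).
#' @param ann gene annotation (as from [read_gtf_minimal()]).
#' @return `peaks` with `assigned_gene` and `distance_to_tss` columns;
#'   peaks on chromosomes without genes are left unassigned (`NA`) with a
#'   notice.
#' @export
assign_nearest_gene <- function(peaks, ann) {
  mid <- peak_midpoint(peaks)
  gene <- rep(NA_character_, nrow(peaks))
  dist <- rep(NA_integer_, nrow(peaks))
  for (chr in unique(peaks$chrom)) {
    pj <- which(peaks$chrom == chr)
    aj <- which(ann$chrom == chr)
    if (!length(aj)) next
    # order by (tss, gene_id) so ties resolve to the smaller id
    aj <- aj[order(ann$tss[aj], ann$gene_id[aj])]
    tss <- ann$tss[aj]
    for (i in pj) {
      d <- abs(mid[i] - tss)
      cand <- aj[d == min(d)]
      # ties (equal distance on both sides) go to the smaller gene id
      best <- if (length(cand) > 1) cand[order(ann$gene_id[cand])][1] else
        cand
      gene[i] <- ann$gene_id[best]
      raw <- mid[i] - ann$tss[best]
      dist[i] <- if (ann$strand[best] == "+") raw else -raw
    }
  }
  if (anyNA(gene))
    message("assign_nearest_gene: ", sum(is.na(gene)),
            " peak(s) on chromosomes without genes left unassigned")
  peaks$assigned_gene <- gene
  peaks$distance_to_tss <- dist
  peaks
}

#' Classify peaks into Promoter / 5UTR / 3UTR / other
#'
#' The promoter window is +/- `promoter_halfwidth` bp around the assigned
#' gene's TSS (default 3 kb). Membership is decided by midpoint
#' containment, with precedence Promoter > 5UTR > 3UTR > other.
#'
#' @param peaks peak table with `assigned_gene` and `distance_to_tss` (from
#'   [assign_nearest_gene()]).
#' @param ann gene annotation with `utr5`/`utr3` list columns.
#' @param promoter_halfwidth promoter half-width in bp (default 3000).
#' @return `peaks` with a `region` column.
#' @export
classify_region <- function(peaks, ann, promoter_halfwidth = 3000) {
  if (is.null(peaks$assigned_gene))
    stop("peaks must be assigned first (assign_nearest_gene)")
  mid <- peak_midpoint(peaks)
  gi <- match(peaks$assigned_gene, ann$gene_id)
  in_utr <- function(i, col) {
    if (is.na(gi[i]) || is.null(ann[[col]])) return(FALSE)
    iv <- ann[[col]][[gi[i]]]
    nrow(iv) > 0 && any(mid[i] >= iv[, 1] & mid[i] < iv[, 2])
  }
  region <- vapply(seq_len(nrow(peaks)), function(i) {
    if (is.na(gi[i])) return(NA_character_)
    if (abs(peaks$distance_to_tss[i]) <= promoter_halfwidth) return("Promoter")
    if (in_utr(i, "utr5")) return("5UTR")
    if (in_utr(i, "utr3")) return("3UTR")
    "other"
  }, character(1))
  peaks$region <- region
  peaks
}

#' Aggregate normalized reads-in-peaks into a per-gene occupancy matrix
#'
#' Peak counts are normalized by median-of-ratios size factors computed
#' from the peak count matrix itself, then summed within each gene (or
#' gene x region) group. Region sums of a gene equal the gene total by
#' construction.
#'
#' @param peak_counts count matrix (peaks x ChIP samples).
#' @param peaks annotated peak table covering every counted peak.
#' @param group_by `"gene"` or `"gene_region"`.
#' @param sf size factors (computed from `peak_counts` if omitted).
#' @return numeric matrix of summed normalized counts; rows are gene ids or
#'   `gene|region` keys.
#' @export
occupancy_matrix <- function(peak_counts, peaks,
                             group_by = c("gene", "gene_region"),
                             sf = size_factors(peak_counts,
                                               method = "poscounts")) {
  group_by <- match.arg(group_by)
  idx <- match(rownames(peak_counts), peaks$peak_id)
  if (anyNA(idx))
    stop("peak id(s) missing from peak table: ",
         rownames(peak_counts)[is.na(idx)][1])
  if (is.null(peaks$assigned_gene) ||
      (group_by == "gene_region" && is.null(peaks$region)))
    stop("peaks must be annotated (assign_nearest_gene / classify_region)")
  norm <- sweep(peak_counts, 2, sf, "/")
  key <- if (group_by == "gene") peaks$assigned_gene[idx] else
    paste(peaks$assigned_gene[idx], peaks$region[idx], sep = "|")
  keep <- !is.na(peaks$assigned_gene[idx])
  rowsum(norm[keep, , drop = FALSE], key[keep])
}

#' Pairwise occupancy correlation between ChIP samples
#'
#' Pearson correlation of `log2(occupancy + 1)` across genes, for all
#' sample pairs. Zero-variance samples yield `NA` rows/columns with a
#' notice. The diagonal is 1.
#'
#' @param occ occupancy matrix (genes x samples).
#' @return symmetric correlation matrix.
#' @export
occupancy_correlation <- function(occ) {
  if (nrow(occ) < 3) stop("need >= 3 genes")
  lx <- log2(occ + 1)
  novar <- apply(lx, 2, stats::var) == 0
  if (any(novar))
    message("occupancy_correlation: zero-variance sample(s): ",
            paste(colnames(occ)[novar], collapse = ", "))
  r <- suppressWarnings(stats::cor(lx))
  diag(r)[!novar] <- 1
  r
}

#' Per-gene log2 occupancy change between two stages
#'
#' `log2((mean_B + c) / (mean_A + c))` with pseudocount `c = 1`, computed on
#' the occupancy matrix columns belonging to each stage.
#'
#' @param occ occupancy matrix.
#' @param samplesA,samplesB column ids of the two stages (>= 2 each).
#' @param pseudocount stabilizing constant (default 1).
#' @return named numeric vector of per-gene log2 changes (B vs A).
#' @export
occupancy_change <- function(occ, samplesA, samplesB, pseudocount = 1) {
  if (!all(c(samplesA, samplesB) %in% colnames(occ)))
    stop("missing stage sample(s) in occupancy matrix")
  if (length(samplesA) < 2 || length(samplesB) < 2)
    stop("need >= 2 samples per stage")
  mA <- rowMeans(occ[, samplesA, drop = FALSE])
  mB <- rowMeans(occ[, samplesB, drop = FALSE])
  log2((mB + pseudocount) / (mA + pseudocount))
}

#' Differential peak binding between stages
#'
#' Identical machinery to the gene-level NB Wald test, applied to the
#' reads-in-peaks count matrix, with the peak-level thresholds
#' (|log2FC| > 0.5, FDR < 0.2) for the regulation label.
#'
#' @param peak_counts count matrix (peaks x ChIP samples).
#' @param groups stage label per sample.
#' @param lfc_threshold,fdr_threshold label thresholds (defaults 0.5, 0.2).
#' @param contrasts list of `c(B, A)` pairs; defaults to the three stage
#'   contrasts.
#' @return data.frame of labelled results for all contrasts, joinable to a
#'   peak table on `feature_id` = `peak_id`.
#' @export
differential_binding <- function(peak_counts, groups, lfc_threshold = 0.5,
                                 fdr_threshold = 0.2,
                                 contrasts = list(c("early", "non"),
                                                  c("late", "non"),
                                                  c("late", "early"))) {
  sf <- size_factors(peak_counts, method = "poscounts")
  alpha <- estimate_dispersion(peak_counts, groups, sf)
  res <- lapply(contrasts, function(ctr)
    classify_de(nb_wald_test(peak_counts, groups, ctr, sf, alpha),
                lfc_threshold, fdr_threshold))
  do.call(rbind, res)
}
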