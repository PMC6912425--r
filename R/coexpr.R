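# Differential co-expression: per-stage Pearson correlation of a
# transcription factor with target genes, Fisher z transform, normal test
# on the z difference between stages, and permutation-based empirical p/q.

#' Variance-stabilizing transform of counts
#'
#' Shifted log of normalized counts: `log2(count / size_factor + 1)`.
#' Monotone in counts per sample and closed-form; it is not the fitted VST
#' of DESeq2, but is adequate for correlation analysis (documented
#' deviation).
#'
#' @param counts count matrix.
#' @param sf size factors (computed from `counts` if omitted; pass
#'   `rep(1, ncol(counts))` to skip normalization).
#' @return numeric matrix of transformed expression, same dimensions.
#' @export
vst <- function(counts, sf = size_factors(counts)) {
  validate_counts(counts)
  log2(sweep(counts, 2, sf, "/") + 1)
}

#' Per-stage Pearson co-expression of a factor with target genes
#'
#' @param expr transformed expression matrix (features x samples).
#' @param factor_id gene id of the transcription factor.
#' @param targets gene ids of candidate targets.
#' @param samples sample ids (columns of `expr`) belonging to the stage.
#' @param stage stage label to record.
#' @return data.frame: `factor`, `target`, `stage`, `r`, `n`. Zero-variance
#'   pairs are dropped with a notice.
#' @export
stage_pcc <- function(expr, factor_id, targets, samples, stage = NA) {
  if (!factor_id %in% rownames(expr)) stop("unknown factor: ", factor_id)
  miss <- setdiff(targets, rownames(expr))
  if (length(miss)) stop("unknown target(s): ", miss[1])
  if (length(samples) < 4) stop("need >= 4 samples in a stage")
  x <- expr[factor_id, samples]
  ym <- t(expr[targets, samples, drop = FALSE])
  if (stats::var(x) == 0) {
    message("stage_pcc: factor has zero variance; all pairs dropped")
    return(data.frame(factor = character(), target = character(),
                      stage = character(), r = numeric(), n = integer()))
  }
  r <- suppressWarnings(as.vector(stats::cor(x, ym)))
  drop <- is.na(r)
  if (any(drop))
    message("stage_pcc: dropped ", sum(drop), " zero-variance pair(s)")
  data.frame(factor = factor_id, target = targets[!drop], stage = stage,
             r = r[!drop], n = length(samples), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Fisher z transform of a correlation coefficient
#'
#' `z = atanh(r)` with sampling variance `1/(n - 3)`. Correlations at
#' exactly +/-1 are clamped to `1 - 1e-12` in absolute value, with a
#' warning.
#'
#' @param r correlation coefficient(s).
#' @param n number of samples used for each `r` (must exceed 3).
#' @return list with `z` and `var`.
#' @export
fisher_z <- function(r, n) {
  if (any(n <= 3)) stop("Fisher z requires n > 3")
  if (any(abs(r) > 1, na.rm = TRUE)) stop("|r| > 1")
  if (any(abs(r) == 1, na.rm = TRUE)) {
    warning("|r| = 1 clamped to 1 - 1e-12")
    r <- sign(r) * pmin(abs(r), 1 - 1e-12)
  }
  list(z = atanh(r), var = 1 / (n - 3))
}

#' Normal test for a difference in correlation between two conditions
#'
#' `z_diff = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' two-sided normal p-value.
#'
#' @param r1,n1 correlation and sample count in the first condition.
#' @param r2,n2 correlation and sample count in the second condition.
#' @return list with `z_diff` and `p_normal`.
#' @export
diff_coexpr_test <- function(r1, n1, r2, n2) {
  f1 <- fisher_z(r1, n1)
  f2 <- fisher_z(r2, n2)
  zd <- (f1$z - f2$z) / sqrt(f1$var + f2$var)
  list(z_diff = zd, p_normal = 2 * stats::pnorm(-abs(zd)))
}

# |z_diff| for one factor against a matrix of targets given a column split.
zdiff_abs <- function(x, ym, idxA, idxB) {
  rA <- suppressWarnings(as.vector(stats::cor(x[idxA], ym[idxA, ,
                                                          drop = FALSE])))
  rB <- suppressWarnings(as.vector(stats::cor(x[idxB], ym[idxB, ,
                                                          drop = FALSE])))
  clamp <- function(r) sign(r) * pmin(abs(r), 1 - 1e-12)
  abs((atanh(clamp(rA)) - atanh(clamp(rB))) /
        sqrt(1 / (length(idxA) - 3) + 1 / (length(idxB) - 3)))
}

#' Differential co-expression with permutation-based empirical p/q-values
#'
#' For each factor-target pair, the observed `|z_diff|` between two stages
#' is compared against a pooled null obtained by permuting stage labels
#' across the pooled samples `B` times and recomputing `|z_diff|` for all
#' pairs. The empirical p-value is
#' `(1 + #(null >= observed)) / (1 + B * pairs)`; q-values are BH-adjusted
#' empirical p-values, and pairs with `q < fdr_threshold` are labelled
#' `gain` (correlation stronger in stage A) or `loss`.
#'
#' @param expr transformed expression matrix.
#' @param factor_id factor gene id.
#' @param targets target gene ids.
#' @param samplesA,samplesB sample ids of the two stages.
#' @param B number of permutations (default 1000; must be >= 100).
#' @param seed RNG seed (mandatory for reproducibility).
#' @param stages length-2 labels used in the output.
#' @param fdr_threshold q-value cutoff for the pair label (default 0.2).
#' @return data.frame: `factor`, `target`, `stageA`, `stageB`, `rA`, `rB`,
#'   `nA`, `nB`, `z_diff`, `p_normal`, `p_empirical`, `q_empirical`,
#'   `pair_label`.
#' @export
permutation_qvalues <- function(expr, factor_id, targets, samplesA,
                                samplesB, B = 1000, seed,
                                stages = c("A", "B"), fdr_threshold = 0.2) {
  if (missing(seed)) stop("seed is mandatory")
  if (B < 100) stop("B must be >= 100")
  if (length(samplesA) < 4 || length(samplesB) < 4)
    stop("need >= 4 samples per stage")
  pooled <- c(samplesA, samplesB)
  nA <- length(samplesA); nB <- length(samplesB)
  x <- expr[factor_id, pooled]
  ym <- t(expr[targets, pooled, drop = FALSE])
  obs <- zdiff_abs(x, ym, seq_len(nA), nA + seq_len(nB))
  keep <- is.finite(obs)
  if (!all(keep))
    message("permutation_qvalues: dropped ", sum(!keep),
            " zero-variance pair(s)")
  null_pool <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      perm <- sample.int(nA + nB)
      zdiff_abs(x, ym, perm[seq_len(nA)], perm[nA + seq_len(nB)])
    }, numeric(length(targets)))
  })
  null_pool <- null_pool[is.finite(null_pool)]
  total <- length(null_pool)
  if (total < 100 * length(targets))
    warning("few usable permutation statistics; empirical p resolution low")
  p_emp <- vapply(obs, function(o)
    (1 + sum(null_pool >= o)) / (1 + total), 1.0)
  p_emp[!keep] <- NA_real_
  rA <- suppressWarnings(as.vector(stats::cor(x[seq_len(nA)],
                                              ym[seq_len(nA), ,
                                                 drop = FALSE])))
  rB <- suppressWarnings(as.vector(stats::cor(x[nA + seq_len(nB)],
                                              ym[nA + seq_len(nB), ,
                                                 drop = FALSE])))
  normal <- diff_coexpr_test(ifelse(keep, rA, 0), nA,
                             ifelse(keep, rB, 0), nB)
  q <- rep(NA_real_, length(p_emp))
  q[keep] <- stats::p.adjust(p_emp[keep], method = "BH")
  lab <- rep("none", length(q))
  sig <- !is.na(q) & q < fdr_threshold
  lab[sig & abs(rA) > abs(rB)] <- "gain"
  lab[sig & abs(rA) <= abs(rB)] <- "loss"
  data.frame(factor = factor_id, target = targets,
             stageA = stages[1], stageB = stages[2],
             rA = rA, rB = rB, nA = nA, nB = nB,
             z_diff = ifelse(keep, normal$z_diff, NA_real_),
             p_normal = ifelse(keep, normal$p_normal, NA_real_),
             p_empirical = p_emp, q_empirical = q, pair_label = lab,
             stringsAsFactors = FALSE, row.names = NULL)
}
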