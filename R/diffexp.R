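# Negative-binomial Wald differential expression, shared by the gene
# (diffexp) and peak (differential binding) analyses. The model family is
# the one DESeq2 assumes -- NB with var = mu + alpha * mu^2, log link,
# median-of-ratios normalization -- but deliberately simplified: no
# Cox-Reid dispersion adjustment, no LFC shrinkage, no outlier filtering.

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over features (restricted
#' to features with nonzero counts in every sample for `method = "ratio"`)
#' of the ratio of the sample's count to the feature's geometric mean.
#' Factors are rescaled to have geometric mean 1. `method = "poscounts"`
#' uses the geometric mean over positive counts only and all features with
#' at least one positive count, for matrices where no feature is positive
#' everywhere.
#'
#' @param counts count matrix (features x samples).
#' @param method `"ratio"` (default) or `"poscounts"`.
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts, method = c("ratio", "poscounts")) {
  method <- match.arg(method)
  validate_counts(counts)
  if (method == "ratio") {
    use <- rowSums(counts > 0) == ncol(counts)
    if (!any(use))
      stop("no feature has nonzero counts in all samples; ",
           "use size_factors(..., method = \"poscounts\")")
    lgeo <- rowMeans(log(counts[use, , drop = FALSE]))
    sf <- apply(counts[use, , drop = FALSE], 2,
                function(cnt) exp(stats::median(log(cnt) - lgeo)))
  } else {
    use <- rowSums(counts > 0) > 0
    if (!any(use)) stop("all-zero count matrix")
    cm <- counts[use, , drop = FALSE]
    lg <- log(cm)
    lg[!is.finite(lg)] <- NA
    lgeo <- rowMeans(lg, na.rm = TRUE)
    sf <- apply(cm, 2, function(cnt) {
      r <- log(cnt) - lgeo
      exp(stats::median(r[is.finite(r)]))
    })
  }
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Method-of-moments dispersion estimates with trend shrinkage
#'
#' Per feature, a raw dispersion is computed by pooling the within-group
#' variance of normalized counts across groups:
#' `alpha = max(0, (s2 - mu * mean(1/sf)) / mu^2)`, where the `mean(1/sf)`
#' term accounts for the extra Poisson variance introduced by dividing by
#' size factors. Raw values are then shrunk toward a mean-dispersion trend
#' `a0 + a1/mu` (fit by least squares with one outlier-trimming pass) with
#' a fixed weight, and floored at 1e-8.
#'
#' @param counts count matrix.
#' @param groups factor or character vector, one group label per sample.
#' @param sf size factors (computed from `counts` if omitted).
#' @param shrink_weight weight on the raw estimate (default 0.5; the
#'   remainder goes to the trend).
#' @return named numeric vector of dispersions, one per feature.
#' @export
estimate_dispersion <- function(counts, groups, sf = size_factors(counts),
                                shrink_weight = 0.5) {
  validate_counts(counts)
  groups <- as.character(groups)
  if (length(groups) != ncol(counts))
    stop("groups must have one label per sample")
  if (!any(table(groups) >= 2))
    stop("dispersion estimation requires replicates in at least one group")
  q <- sweep(counts, 2, sf, "/")
  mu <- rowMeans(q)
  ss <- 0; df <- 0
  for (g in unique(groups)) {
    j <- groups == g
    if (sum(j) < 2) next
    gm <- rowMeans(q[, j, drop = FALSE])
    ss <- ss + rowSums((q[, j, drop = FALSE] - gm)^2)
    df <- df + sum(j) - 1
  }
  s2 <- ss / df
  shot <- mean(1 / sf) # E[var(y/s)] = mu/s + alpha mu^2 per sample
  a_raw <- pmax(0, (s2 - mu * shot) / mu^2)
  a_raw[!is.finite(a_raw)] <- 0

  # parametric trend a0 + a1/mu, least squares with one trimming pass
  trend <- function(m) rep(stats::median(a_raw[a_raw > 0]), length(m))
  use <- a_raw > 1e-8 & mu > 0
  if (sum(use) >= 10) {
    x <- 1 / mu[use]; y <- a_raw[use]
    for (pass in 1:2) {
      fit <- stats::lm.fit(cbind(1, x), y)
      res <- fit$residuals
      keep <- abs(res) <= 4 * stats::mad(res) + 1e-12
      if (all(keep) || sum(keep) < 10) break
      x <- x[keep]; y <- y[keep]
    }
    a0 <- max(fit$coefficients[1], 1e-8)
    a1 <- max(fit$coefficients[2], 0)
    trend <- function(m) a0 + a1 / m
  } else if (!any(a_raw > 0)) {
    trend <- function(m) rep(1e-8, length(m))
  }
  alpha <- pmax(shrink_weight * a_raw + (1 - shrink_weight) * trend(mu),
                1e-8)
  stats::setNames(alpha, rownames(counts))
}

# Vectorized Newton solver for the NB group mean with fixed dispersion:
# solves sum_j (y_ij - s_j m_i) / (1 + alpha_i s_j m_i) = 0 per feature.
# Returns the normalized-scale mean and the Fisher information of log(m).
fit_nb_group_mean <- function(y, sf, alpha, max_iter = 100, tol = 1e-12) {
  m <- pmax(rowMeans(sweep(y, 2, sf, "/")), 1e-8)
  converged <- rep(FALSE, nrow(y))
  for (it in seq_len(max_iter)) {
    mu <- m %o% sf
    denom <- 1 + alpha * mu
    f <- rowSums((y - mu) / denom)
    fp <- -rowSums(sweep(denom^-2, 2, sf, "*") * (1 + alpha * y))
    step <- f / fp
    m_new <- m - step
    bad <- !is.finite(m_new) | m_new <= 0
    m_new[bad] <- m[bad] / 2
    converged <- abs(m_new - m) <= tol * pmax(m, 1e-8)
    m <- m_new
    if (all(converged)) break
  }
  mu <- m %o% sf
  info <- rowSums(mu / (1 + alpha * mu))
  list(mean = m, info = info, converged = converged)
}

#' Negative-binomial Wald test for one contrast
#'
#' Fits a group-mean NB GLM (log link) per feature with fixed per-feature
#' dispersion and size-factor offsets, then tests
#' `log2FC = log2(mu_B / mu_A)` with a two-sided normal Wald test; the
#' standard error comes from the observed information of the two group
#' log-means. P-values are BH-adjusted across features within the contrast.
#' Features that are all-zero in both groups get `log2FC = 0`, `p = NA` and
#' are excluded from the BH adjustment; non-converged fits are likewise
#' flagged with `p = NA`.
#'
#' @param counts count matrix.
#' @param groups group label per sample.
#' @param contrast character vector `c(B, A)`: log2FC is B relative to A.
#' @param sf size factors (computed from `counts` if omitted).
#' @param alpha per-feature dispersions (estimated if omitted).
#' @return data.frame: `feature_id`, `contrast`, `base_mean`, `log2FC`,
#'   `SE`, `stat`, `p`, `fdr`.
#' @export
nb_wald_test <- function(counts, groups, contrast,
                         sf = size_factors(counts),
                         alpha = estimate_dispersion(counts, groups, sf)) {
  validate_counts(counts)
  groups <- as.character(groups)
  stopifnot(length(contrast) == 2)
  if (!all(contrast %in% groups))
    stop("contrast group(s) not present: ",
         paste(setdiff(contrast, groups), collapse = ", "))
  jB <- which(groups == contrast[1])
  jA <- which(groups == contrast[2])
  if (length(jA) < 2 || length(jB) < 2)
    stop("each contrast group needs >= 2 samples")
  alpha <- pmax(alpha[rownames(counts)], 1e-8)
  fB <- fit_nb_group_mean(counts[, jB, drop = FALSE], sf[jB], alpha)
  fA <- fit_nb_group_mean(counts[, jA, drop = FALSE], sf[jA], alpha)
  mB <- pmax(fB$mean, 1e-8)
  mA <- pmax(fA$mean, 1e-8)
  lfc <- log2(mB / mA)
  se <- sqrt(1 / pmax(fA$info, 1e-12) + 1 / pmax(fB$info, 1e-12)) / log(2)
  stat <- lfc / se
  p <- 2 * stats::pnorm(-abs(stat))
  allzero <- rowSums(counts[, c(jA, jB), drop = FALSE]) == 0
  lfc[allzero] <- 0
  stat[allzero] <- NA_real_
  p[allzero] <- NA_real_
  notconv <- !(fA$converged & fB$converged) & !allzero
  if (any(notconv)) {
    message("nb_wald_test: ", sum(notconv),
            " feature(s) did not converge; p set to NA")
    p[notconv] <- NA_real_
  }
  fdr <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  fdr[ok] <- stats::p.adjust(p[ok], method = "BH")
  data.frame(
    feature_id = rownames(counts),
    contrast = paste0(contrast[1], "_vs_", contrast[2]),
    base_mean = (mA * length(jA) + mB * length(jB)) /
      (length(jA) + length(jB)),
    log2FC = lfc, SE = se, stat = stat, p = p, fdr = fdr,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Label differential features as up-, down-regulated or unchanged
#'
#' A feature is `up` when `log2FC > lfc_threshold` and
#' `fdr < fdr_threshold`; `down` symmetrically; otherwise `none`. The study
#' thresholds are |log2FC| > 1 with FDR < 0.2 for genes and |log2FC| > 0.5
#' with FDR < 0.2 for peaks; inequalities are strict.
#'
#' @param res result data.frame from [nb_wald_test()].
#' @param lfc_threshold log2 fold-change threshold (1.0 genes, 0.5 peaks).
#' @param fdr_threshold BH-FDR threshold (default 0.2).
#' @return `res` with a `label` column added.
#' @export
classify_de <- function(res, lfc_threshold = 1, fdr_threshold = 0.2) {
  stopifnot(lfc_threshold >= 0, fdr_threshold > 0)
  lab <- rep("none", nrow(res))
  sig <- !is.na(res$fdr) & res$fdr < fdr_threshold
  lab[sig & res$log2FC > lfc_threshold] <- "up"
  lab[sig & res$log2FC < -lfc_threshold] <- "down"
  res$label <- lab
  res
}

#' Run all stage contrasts on a count matrix
#'
#' Convenience driver: early vs non, late vs non and late vs early, with
#' shared size factors and dispersions, each labelled by [classify_de()].
#'
#' @param counts count matrix.
#' @param groups stage label per sample.
#' @param lfc_threshold,fdr_threshold thresholds passed to [classify_de()].
#' @param contrasts list of `c(B, A)` pairs; defaults to the three stage
#'   contrasts.
#' @return data.frame stacking all contrasts.
#' @export
stage_contrasts <- function(counts, groups, lfc_threshold = 1,
                            fdr_threshold = 0.2,
                            contrasts = list(c("early", "non"),
                                             c("late", "non"),
                                             c("late", "early"))) {
  sf <- size_factors(counts)
  alpha <- estimate_dispersion(counts, groups, sf)
  res <- lapply(contrasts, function(ctr)
    classify_de(nb_wald_test(counts, groups, ctr, sf, alpha),
                lfc_threshold, fdr_threshold))
  do.call(rbind, res)
}

#' Classical (Torgerson) multidimensional scaling of samples
#'
#' Computes Euclidean distances between samples on the (optionally
#' subsetted) transformed expression matrix and embeds them with classical
#' MDS (double centering + eigendecomposition, via `stats::cmdscale`).
#' Variance explained per dimension is the eigenvalue divided by the sum of
#' positive eigenvalues.
#'
#' @param expr transformed expression matrix (features x samples), e.g.
#'   from [vst()].
#' @param subset optional feature ids to restrict to.
#' @param k number of dimensions (reduced, with a warning, if fewer
#'   positive eigenvalues exist).
#' @return list with `points` (samples x k), `eig`, and
#'   `variance_explained` (length k).
#' @export
classical_mds <- function(expr, subset = NULL, k = 2) {
  if (!is.null(subset)) {
    miss <- setdiff(subset, rownames(expr))
    if (length(miss)) stop("subset feature(s) not in matrix: ", miss[1])
    expr <- expr[subset, , drop = FALSE]
  }
  if (ncol(expr) < k + 1) stop("need at least k + 1 samples")
  d <- stats::dist(t(expr))
  fit <- stats::cmdscale(d, k = min(k, ncol(expr) - 1), eig = TRUE)
  pos <- fit$eig[fit$eig > 1e-9]
  npos <- length(pos)
  if (npos < k) {
    warning("only ", npos, " positive eigenvalue(s); k reduced")
    k <- npos
  }
  pts <- fit$points[, seq_len(k), drop = FALSE]
  list(points = pts, eig = fit$eig,
       variance_explained = fit$eig[seq_len(k)] / sum(pos))
}
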