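# Integration of expression, binding and co-expression evidence into
# classified regulatory links. The study narrative never states a formal
# link-calling rule; this module formalizes it as the conjunction of
# (i) a promoter-window peak of the factor on the target gene,
# (ii) significant binding or stage change of that peak, and
# (iii) stage co-expression of factor and target beyond a reporting
# threshold, with the link suppressed in stages where the factor gene is
# not expressed ("availability of the factor in each stage").

contrast_stage <- function(contrast) {
  c(early_vs_non = "early", late_vs_non = "late",
    late_vs_early = "late")[contrast]
}

#' Call direct regulatory links from promoter binding plus co-expression
#'
#' For every annotated promoter peak of a factor on a gene, each stage
#' contrast where the peak's differential binding is significant nominates
#' a candidate stage (the later stage of the contrast). A link is emitted
#' for that stage when the factor is expressed there and the absolute
#' stage co-expression between factor and target exceeds `r_threshold`.
#' Links with factor == target are labelled `auto`.
#'
#' @param peaks annotated peak table with `peak_id`, `assigned_gene`,
#'   `region` and a `factor` column naming the ChIP factor each peak
#'   belongs to.
#' @param binding differential-binding results (from
#'   [differential_binding()]) with a `factor` column; one row per peak and
#'   contrast, labelled.
#' @param coexpr per-stage correlations: data.frame `factor`, `target`,
#'   `stage`, `r` (from [stage_pcc()]).
#' @param de optional labelled gene-level DE results used to fill the
#'   target's DE stratum (contrast `<stage>_vs_non`).
#' @param factor_expr optional data.frame `factor`, `stage`, `mean_count`
#'   (normalized): links in stages where `mean_count < min_factor_expr` are
#'   suppressed. When `NULL` the factor counts as always available.
#' @param r_threshold co-expression reporting threshold (default 0.25).
#' @param min_factor_expr availability floor on the factor's normalized
#'   mean count (default 10).
#' @return data.frame of links: `factor`, `target`, `mode`, `stage`,
#'   `sign`, `promoter_peak`, `peak_id`, `binding_change`, `coexpr_r`,
#'   `target_de_label`, `kd_consistent` (initialized to "untested").
#' @export
direct_targets <- function(peaks, binding, coexpr, de = NULL,
                           factor_expr = NULL, r_threshold = 0.25,
                           min_factor_expr = 10) {
  if (is.null(peaks$region) || is.null(peaks$assigned_gene))
    stop("peaks must be annotated")
  if (is.null(peaks$factor) || is.null(binding$factor))
    stop("peaks and binding need a 'factor' column")
  prom <- peaks[!is.na(peaks$region) & peaks$region == "Promoter", ,
                drop = FALSE]
  sig <- binding[binding$label != "none", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(prom))) {
    f <- prom$factor[i]; g <- prom$assigned_gene[i]
    b <- sig[sig$feature_id == prom$peak_id[i] & sig$factor == f, ,
             drop = FALSE]
    if (!nrow(b)) next
    b$stage <- contrast_stage(b$contrast)
    for (s in unique(b$stage)) {
      if (!is.null(factor_expr)) {
        fe <- factor_expr$mean_count[factor_expr$factor == f &
                                       factor_expr$stage == s]
        if (!length(fe) || fe < min_factor_expr) next
      }
      r <- coexpr$r[coexpr$factor == f & coexpr$target == g &
                      coexpr$stage == s]
      if (!length(r) || is.na(r[1]) || abs(r[1]) <= r_threshold) next
      bs <- b[b$stage == s, , drop = FALSE]
      lab <- NA_character_
      if (!is.null(de)) {
        lab0 <- de$label[de$feature_id == g &
                           de$contrast == paste0(s, "_vs_non")]
        if (length(lab0)) lab <- lab0[1]
      }
      out[[length(out) + 1]] <- data.frame(
        factor = f, target = g,
        mode = if (f == g) "auto" else "direct", stage = s,
        promoter_peak = TRUE, peak_id = prom$peak_id[i],
        binding_change = bs$log2FC[which.max(abs(bs$log2FC))],
        coexpr_r = r[1], target_de_label = lab,
        kd_consistent = "untested", stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    links <- data.frame(factor = character(), target = character(),
                        mode = character(), stage = character(),
                        promoter_peak = logical(), peak_id = character(),
                        binding_change = numeric(), coexpr_r = numeric(),
                        target_de_label = character(),
                        kd_consistent = character(),
                        stringsAsFactors = FALSE)
  } else {
    links <- do.call(rbind, out)
    # one link per (factor, target, stage): keep the strongest peak
    o <- order(links$factor, links$target, links$stage,
               -abs(links$binding_change))
    links <- links[o, ]
    links <- links[!duplicated(links[c("factor", "target", "stage")]), ]
    rownames(links) <- NULL
  }
  links$sign <- infer_sign(links, theta = r_threshold)
  links[c("factor", "target", "mode", "stage", "sign", "promoter_peak",
          "peak_id", "binding_change", "coexpr_r", "target_de_label",
          "kd_consistent")]
}

#' Infer the regulation sign of links from stage co-expression
#'
#' `induction` when `r > theta`, `repression` when `r < -theta`,
#' `ambiguous` otherwise.
#'
#' @param links link data.frame with a `coexpr_r` column.
#' @param theta threshold on |r| (default 0.25).
#' @return character vector of signs.
#' @export
infer_sign <- function(links, theta = 0.25) {
  r <- links$coexpr_r
  ifelse(is.na(r), "ambiguous",
         ifelse(r > theta, "induction",
                ifelse(r < -theta, "repression", "ambiguous")))
}

#' Expand direct links on autophagy TFs into indirect links
#'
#' For each direct link F -> t where t is an autophagy transcription
#' factor, emits F -> g (mode `indirect_via_tf`) for every annotated target
#' g of t. Regulons are supplied, not inferred: `tf_targets` comes from the
#' synthetic truth or a user file. TFs without annotation produce no links,
#' with a notice.
#'
#' @param direct_links output of [direct_targets()].
#' @param tf_genes gene ids of the autophagy transcription factors.
#' @param tf_targets data.frame `tf`, `target` (optionally `sign`).
#' @return data.frame of indirect links with a `via_tf` column.
#' @export
indirect_targets <- function(direct_links, tf_genes, tf_targets) {
  hits <- direct_links[direct_links$target %in% tf_genes &
                         direct_links$mode %in% c("direct", "auto"), ,
                       drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(hits))) {
    t <- hits$target[i]
    dn <- tf_targets[tf_targets$tf == t, , drop = FALSE]
    if (!nrow(dn)) {
      message("indirect_targets: no annotated targets for TF ", t)
      next
    }
    out[[length(out) + 1]] <- data.frame(
      factor = hits$factor[i], target = dn$target,
      mode = "indirect_via_tf", stage = hits$stage[i],
      sign = "ambiguous", via_tf = t, promoter_peak = FALSE,
      peak_id = NA_character_, binding_change = NA_real_,
      coexpr_r = NA_real_, target_de_label = NA_character_,
      kd_consistent = "untested", stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(factor = character(), target = character(),
                      mode = character(), stage = character(),
                      sign = character(), via_tf = character(),
                      stringsAsFactors = FALSE))
  links <- do.call(rbind, out)
  links[!duplicated(links[c("factor", "target", "stage")]), ]
}

#' Detect feedback pairs (2-cycles of direct links)
#'
#' F -> G and G -> F (both direct, F != G) are reported as one feedback
#' pair.
#'
#' @param links direct link data.frame.
#' @return data.frame `factor_a`, `factor_b`, one row per unordered pair.
#' @export
detect_feedback <- function(links) {
  d <- unique(links[links$mode == "direct",
                    c("factor", "target")])
  d <- d[d$factor != d$target, , drop = FALSE]
  key <- paste(d$factor, d$target)
  rev_key <- paste(d$target, d$factor)
  cyc <- d[key %in% rev_key, , drop = FALSE]
  if (!nrow(cyc))
    return(data.frame(factor_a = character(), factor_b = character(),
                      stringsAsFactors = FALSE))
  a <- pmin(cyc$factor, cyc$target)
  b <- pmax(cyc$factor, cyc$target)
  unique(data.frame(factor_a = a, factor_b = b, stringsAsFactors = FALSE))
}

#' Check links against knockdown differential expression
#'
#' A link is `kd_consistent = "yes"` when its sign is induction and the
#' target is down-regulated under knockdown of the factor (or repression
#' and up-regulated) at any tested time point; `"no"` when the target was
#' tested and never matched; `"untested"` when the factor has no knockdown
#' data or the target is absent from it.
#'
#' @param links link data.frame.
#' @param kd_de labelled knockdown DE results: data.frame `factor`,
#'   `feature_id`, `time_h`, `log2FC`, `fdr`, `label`.
#' @return `links` with `kd_consistent` filled in.
#' @export
knockdown_consistency <- function(links, kd_de) {
  for (i in seq_len(nrow(links))) {
    rows <- kd_de[kd_de$factor == links$factor[i] &
                    kd_de$feature_id == links$target[i], , drop = FALSE]
    if (!nrow(rows)) next # stays untested
    want <- switch(links$sign[i], induction = "down", repression = "up",
                   NA_character_)
    if (is.na(want)) next
    links$kd_consistent[i] <- if (any(rows$label == want)) "yes" else "no"
  }
  links
}

#' Score called links against a planted truth table
#'
#' Precision and recall are computed on unique (factor, target) pairs of
#' direct/auto links; feedback recovery and the fraction of recovered true
#' links marked knockdown-consistent are also reported.
#'
#' @param links called links (direct/auto modes are evaluated).
#' @param truth truth table (see [make_truth()]).
#' @return list: `precision`, `recall`, `n_true`, `n_called`,
#'   `feedback_detected`, `kd_consistent_frac`.
#' @export
evaluate_links <- function(links, truth) {
  called <- unique(links[links$mode %in% c("direct", "auto"),
                         c("factor", "target")])
  truth_pairs <- unique(truth$links[c("factor", "target")])
  key <- function(d) paste(d$factor, d$target)
  tp <- sum(key(called) %in% key(truth_pairs))
  fb <- detect_feedback(links)
  tl <- truth$links
  tkey <- key(tl)
  planted_fb <- tl[paste(tl$target, tl$factor) %in% tkey &
                     tl$factor != tl$target, , drop = FALSE]
  fb_truth <- unique(data.frame(
    factor_a = pmin(planted_fb$factor, planted_fb$target),
    factor_b = pmax(planted_fb$factor, planted_fb$target)))
  fb_found <- if (nrow(fb_truth) == 0) NA else
    all(paste(fb_truth$factor_a, fb_truth$factor_b) %in%
          paste(fb$factor_a, fb$factor_b))
  true_called <- links[links$mode %in% c("direct", "auto") &
                         paste(links$factor, links$target) %in% tkey, ,
                       drop = FALSE]
  kd_frac <- if (!nrow(true_called)) NA_real_ else {
    tested <- true_called$kd_consistent != "untested"
    if (!any(tested)) NA_real_ else
      mean(true_called$kd_consistent == "yes")
  }
  list(precision = if (nrow(called)) tp / nrow(called) else NA_real_,
       recall = if (nrow(truth_pairs)) tp / nrow(truth_pairs) else
         NA_real_,
       n_true = nrow(truth_pairs), n_called = nrow(called),
       feedback_detected = fb_found, kd_consistent_frac = kd_frac)
}
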