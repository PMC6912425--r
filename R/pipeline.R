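# End-to-end driver: simulate -> filter/stage -> diffexp/MDS -> coexpr ->
# enrichment -> peak annotation/occupancy/differential binding -> knockdown
# contrasts -> link integration -> report directory with manifest.

#' Pipeline configuration
#'
#' Bundles a simulation scenario with every analysis threshold. Serializes
#' to and from a single human-readable JSON file.
#'
#' @param sim a [sim_config()] describing the synthetic scenario.
#' @param lfc_gene,lfc_peak regulation-label log2FC thresholds (1.0 genes,
#'   0.5 peaks).
#' @param fdr FDR threshold (0.2).
#' @param coexpr_theta co-expression reporting threshold on |r| (0.25).
#' @param min_count,min_samples expression filter (10 reads in 3 samples).
#' @param min_factor_expr factor availability floor (normalized counts).
#' @param permutations permutations B for empirical co-expression p-values.
#' @param kd_time_points_h time points profiled in the knockdown arms.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), lfc_gene = 1,
                            lfc_peak = 0.5, fdr = 0.2,
                            coexpr_theta = 0.25, min_count = 10,
                            min_samples = 3, min_factor_expr = 10,
                            permutations = 1000,
                            kd_time_points_h = c(0, 48)) {
  stopifnot(lfc_gene >= 0, lfc_peak >= 0, fdr > 0, fdr <= 1,
            coexpr_theta >= 0, coexpr_theta < 1, permutations >= 100)
  structure(list(sim = validate_sim_config(sim), lfc_gene = lfc_gene,
                 lfc_peak = lfc_peak, fdr = fdr,
                 coexpr_theta = coexpr_theta, min_count = min_count,
                 min_samples = min_samples,
                 min_factor_expr = min_factor_expr,
                 permutations = permutations,
                 kd_time_points_h = kd_time_points_h),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as JSON
#'
#' @param cfg a [pipeline_config()].
#' @param path file path.
#' @return the configuration (read) or `path` invisibly (write).
#' @export
write_pipeline_config <- function(cfg, path) {
  x <- write_pipeline_config_obj(cfg)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$sim$effect_table <- as.data.frame(x$sim$effect_table,
                                      stringsAsFactors = FALSE)
  x$sim$time_points_h <- lapply(x$sim$time_points_h, as.numeric)
  x$sim$group_sizes <- unlist(x$sim$group_sizes)
  sim <- do.call(sim_config, x$sim)
  x$sim <- NULL
  do.call(pipeline_config, c(list(sim = sim), x))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes simulate -> filter -> stage contrasts -> MDS -> differential
#' co-expression -> over-representation -> peak annotation, occupancy and
#' differential binding -> knockdown contrasts -> regulatory-link
#' integration, writing every table plus a manifest (config, seed, file
#' checksums) and a text summary to `out_dir`. Deterministic given the
#' configuration (all randomness derives from `cfg$sim$seed`).
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir report directory (created if missing); `NULL` skips all
#'   file output.
#' @return (invisibly) a list with every intermediate result, the planted
#'   truth and the truth-recovery evaluation.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  sim <- cfg$sim
  step <- function(...) message("[adiporeg] ", ...)

  step("simulating dataset (", sim$n_genes, " genes, seed ", sim$seed, ")")
  truth <- make_truth(sim)
  rna <- generate_timecourse_counts(sim, truth)
  ann <- generate_annotation(sim$n_genes, seed = sim$seed,
                             gene_ids = truth$genes$gene_id)
  chip <- generate_peak_counts(sim, ann, truth)
  factors <- unique(chip$samples$target)
  sets <- generate_gene_sets(truth, seed = sim$seed)
  kd <- lapply(stats::setNames(factors, factors), function(f)
    generate_knockdown_counts(sim, truth, f,
                              time_points_h = cfg$kd_time_points_h))

  step("filtering low-quality samples / low-expression genes")
  counts <- filter_low_quality(rna$counts, rna$samples, cfg$min_count,
                               cfg$min_samples)
  st <- rna$samples[match(colnames(counts), rna$samples$sample_id), ]

  step("stage differential expression")
  de <- stage_contrasts(counts, st$stage, cfg$lfc_gene, cfg$fdr)

  step("multidimensional scaling")
  sf <- size_factors(counts)
  expr <- vst(counts, sf)
  mds_all <- classical_mds(expr, k = 2)
  atg <- intersect(
    truth$genes$gene_id[truth$genes$group %in% c("autophagy",
                                                 "autophagy_tf")],
    rownames(expr))
  mds_atg <- if (length(atg) >= 3) classical_mds(expr, atg, k = 2) else
    NULL

  step("differential co-expression (B = ", cfg$permutations, ")")
  targets <- intersect(
    truth$genes$gene_id[truth$genes$group != "background"],
    rownames(expr))
  stage_samples <- split(st$sample_id, st$stage)[STAGES]
  pcc <- do.call(rbind, lapply(factors, function(f) {
    if (!f %in% rownames(expr)) return(NULL)
    do.call(rbind, lapply(STAGES, function(s)
      stage_pcc(expr, f, setdiff(targets, f), stage_samples[[s]], s)))
  }))
  pairs <- list(c("early", "non"), c("late", "non"), c("late", "early"))
  dc <- do.call(rbind, lapply(factors, function(f) {
    if (!f %in% rownames(expr)) return(NULL)
    do.call(rbind, lapply(seq_along(pairs), function(pi) {
      pr <- pairs[[pi]]
      permutation_qvalues(expr, f, setdiff(targets, f),
                          stage_samples[[pr[1]]], stage_samples[[pr[2]]],
                          B = cfg$permutations,
                          seed = sim$seed + 100L + pi, stages = pr,
                          fdr_threshold = cfg$fdr)
    }))
  }))

  step("gene-set over-representation")
  de_lists <- lapply(split(de, de$contrast), function(d)
    d$feature_id[d$label != "none"])
  de_lists <- de_lists[vapply(de_lists, length, 1L) > 0]
  ora <- if (length(de_lists))
    enrich_all(de_lists, sets, rownames(counts)) else NULL

  step("peak annotation, occupancy and differential binding")
  peaks <- classify_region(assign_nearest_gene(chip$peaks, ann), ann,
                           sim$promoter_halfwidth_bp)
  chip_st <- chip$samples
  binding <- do.call(rbind, lapply(factors, function(f) {
    j <- chip_st$sample_id[chip_st$target == f]
    b <- differential_binding(chip$counts[, j, drop = FALSE],
                              chip_st$stage[chip_st$target == f],
                              cfg$lfc_peak, cfg$fdr)
    b$factor <- f
    b
  }))
  occ_gene <- occupancy_matrix(chip$counts, peaks, "gene")
  occ_region <- occupancy_matrix(chip$counts, peaks, "gene_region")
  occ_cor <- occupancy_correlation(occ_gene)
  occ_change <- do.call(rbind, lapply(factors, function(f) {
    sel <- chip_st$target == f
    do.call(rbind, lapply(c("early", "late"), function(s) {
      data.frame(factor = f, contrast = paste0(s, "_vs_non"),
                 gene = rownames(occ_gene),
                 log2_change = occupancy_change(
                   occ_gene,
                   chip_st$sample_id[sel & chip_st$stage == "non"],
                   chip_st$sample_id[sel & chip_st$stage == s]),
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
  }))

  step("knockdown contrasts")
  kd_de <- do.call(rbind, lapply(factors, function(f) {
    x <- kd[[f]]
    do.call(rbind, lapply(unique(x$samples$time_h), function(t) {
      j <- x$samples$time_h == t
      res <- nb_wald_test(x$counts[, j, drop = FALSE],
                          x$samples$arm[j], c("knockdown", "control"))
      res <- classify_de(res, cfg$lfc_gene, cfg$fdr)
      res$factor <- f
      res$time_h <- t
      res
    }))
  }))

  step("integrating evidence into regulatory links")
  q <- sweep(counts, 2, sf, "/")
  factor_expr <- do.call(rbind, lapply(factors, function(f) {
    if (!f %in% rownames(q)) return(NULL)
    data.frame(factor = f, stage = STAGES,
               mean_count = vapply(STAGES, function(s)
                 mean(q[f, st$stage == s]), 1.0),
               stringsAsFactors = FALSE)
  }))
  links <- direct_targets(peaks, binding, pcc, de, factor_expr,
                          r_threshold = cfg$coexpr_theta,
                          min_factor_expr = cfg$min_factor_expr)
  links <- knockdown_consistency(links, kd_de)
  tf_genes <- truth$genes$gene_id[truth$genes$group == "autophagy_tf"]
  indirect <- indirect_targets(links, tf_genes, truth$tf_targets)
  feedback <- detect_feedback(links)
  evaluation <- evaluate_links(links, truth)
  step(sprintf("links: %d direct/auto, %d indirect; precision %.2f, recall %.2f",
               nrow(links), nrow(indirect), evaluation$precision,
               evaluation$recall))

  res <- list(config = cfg, truth = truth, ann = ann, counts = counts,
              samples = st, de = de, mds_all = mds_all, mds_atg = mds_atg,
              pcc = pcc, diff_coexpr = dc, ora = ora, peaks = peaks,
              binding = binding, occ_gene = occ_gene,
              occ_region = occ_region, occ_cor = occ_cor,
              occ_change = occ_change, kd_de = kd_de, links = links,
              indirect = indirect, feedback = feedback,
              evaluation = evaluation)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(out_dir, f)
    files <- c(
      write_counts(rna$counts, p("counts.tsv")),
      write_sample_table(rna$samples, p("samples.csv")),
      write_annotation(ann, p("annotation.gtf")),
      write_bed(peaks, p("peaks_annotated.bed")),
      write_counts(chip$counts, p("peak_counts.tsv")),
      write_sample_table(chip$samples, p("chip_samples.csv")),
      write_gmt(sets, p("gene_sets.gmt")),
      write_tsv(de, p("diffexp.tsv")),
      write_tsv(data.frame(sample_id = rownames(mds_all$points),
                           mds_all$points,
                           check.names = FALSE), p("mds_all.tsv")),
      write_tsv(pcc, p("coexpr_pcc.tsv")),
      write_tsv(dc, p("diff_coexpr.tsv")),
      if (!is.null(ora)) write_tsv(ora, p("enrichment.tsv")),
      write_tsv(peaks[!vapply(peaks, is.list, TRUE)],
                p("peaks_annotated.tsv")),
      write_tsv(binding, p("diffbind.tsv")),
      write_tsv(data.frame(key = rownames(occ_gene), occ_gene,
                           check.names = FALSE), p("occupancy_gene.tsv")),
      write_tsv(data.frame(key = rownames(occ_region), occ_region,
                           check.names = FALSE),
                p("occupancy_gene_region.tsv")),
      write_tsv(data.frame(sample = rownames(occ_cor), occ_cor,
                           check.names = FALSE),
                p("occupancy_correlation.tsv")),
      write_tsv(occ_change, p("occupancy_change.tsv")),
      write_tsv(kd_de, p("knockdown_de.tsv")),
      write_tsv(links, p("links.tsv")),
      write_tsv(indirect, p("links_indirect.tsv")),
      write_tsv(feedback, p("feedback_pairs.tsv"))
    )
    manifest <- list(
      package = "adiporeg",
      version = as.character(utils::packageVersion("adiporeg")),
      r_version = R.version.string,
      seed = sim$seed,
      config = jsonlite::fromJSON(jsonlite::toJSON(
        write_pipeline_config_obj(cfg), auto_unbox = TRUE, digits = NA)),
      files = as.list(tools::md5sum(files))
    )
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    ev <- evaluation
    writeLines(c(
      "adiporeg pipeline summary",
      sprintf("genes analyzed: %d (of %d simulated)", nrow(counts),
              sim$n_genes),
      sprintf("DE calls: %d up, %d down across %d contrasts",
              sum(de$label == "up"), sum(de$label == "down"),
              length(unique(de$contrast))),
      sprintf("direct/auto links called: %d; indirect: %d; feedback pairs: %d",
              nrow(links), nrow(indirect), nrow(feedback)),
      sprintf("truth recovery: precision %.3f, recall %.3f (n_true %d)",
              ev$precision, ev$recall, ev$n_true),
      sprintf("knockdown-consistent fraction of true links: %.3f",
              ev$kd_consistent_frac)
    ), p("summary.txt"))
  }
  invisible(res)
}

# config as a plain list for JSON embedding (named vectors to objects)
write_pipeline_config_obj <- function(cfg) {
  x <- unclass(cfg)
  x$sim <- unclass(x$sim)
  x$sim$effect_table <- as.list(x$sim$effect_table)
  x$sim$group_sizes <- as.list(x$sim$group_sizes)
  x
}
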