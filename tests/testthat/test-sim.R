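test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(samples_per_stage = 3))
  expect_error(sim_config(dispersion = -1))
  expect_error(sim_config(frac_null = 1.5))
  expect_error(sim_config(time_points_h = list(non = c(0), early = c(24),
                                               late = c(10))),
               "staging rule")
  expect_error(make_truth(sim_config(n_genes = 10)), "group_sizes")
})

test_that("annotation generator: single gene, determinism, capacity", {
  one <- generate_annotation(1, chrom_length = 10000, seed = 1,
                             pitch = 10000, gene_length = 2000)
  expect_equal(nrow(one), 1L)
  expect_gte(one$tss, 0)
  expect_lt(one$tss, 10000)

  a <- generate_annotation(100, seed = 7)
  b <- generate_annotation(100, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, generate_annotation(100, seed = 8)))

  expect_error(generate_annotation(5, chrom_length = 1000), "cannot fit")
})

test_that("truth table: closed vocabulary, uniqueness, pure-null config", {
  truth <- make_truth(sim_config(n_genes = 400, frac_null = 0.5,
                                 group_sizes = c(adipogenic_tf = 5,
                                                 autophagy_tf = 6,
                                                 autophagy = 40,
                                                 lipogenic = 10),
                                 seed = 3))
  expect_equal(anyDuplicated(truth$genes$gene_id), 0L)
  expect_true(all(truth$genes$group %in%
                    c("adipogenic_tf", "autophagy_tf", "autophagy",
                      "lipogenic", "background")))
  expect_gt(nrow(truth$links), 0)
  # feedback 2-cycle and auto-regulation are planted
  expect_true(any(truth$links$factor == truth$links$target))
  k <- paste(truth$links$factor, truth$links$target)
  expect_true(any(paste(truth$links$target, truth$links$factor) %in%
                    k[truth$links$factor != truth$links$target]))

  null_truth <- make_truth(sim_config(n_genes = 400, frac_null = 1,
                                      group_sizes = c(adipogenic_tf = 5,
                                                      autophagy_tf = 6,
                                                      autophagy = 40,
                                                      lipogenic = 10)))
  expect_equal(null_truth$genes$lfc_early_vs_non, rep(0, 400))
  expect_equal(null_truth$genes$lfc_late_vs_non, rep(0, 400))
  expect_equal(nrow(null_truth$links), 0L)
})

test_that("timecourse counts: determinism and stage structure", {
  cfg <- sim_config(n_genes = 300, seed = 5)
  a <- generate_timecourse_counts(cfg)
  b <- generate_timecourse_counts(cfg)
  expect_identical(a$counts, b$counts)
  expect_equal(assign_stage(a$samples$time_h), a$samples$stage)
  expect_equal(sum(a$samples$stage == "early"), cfg$samples_per_stage)
  expect_true(all(a$counts >= 0))
})

test_that("planted log2FC=2 shifts the NB mean ratio into [3, 5.3]", {
  # across replicate seeds, the empirical early/non mean ratio of a gene
  # planted at log2FC = 2 concentrates near 2^2 = 4
  ratios <- vapply(1:100, function(s) {
    truth <- hand_truth(n_bg = 0, lfc_early = 2)
    cfg <- sim_config(n_genes = 1, seed = s, sf_range = c(1, 1))
    rna <- generate_timecourse_counts(cfg, truth)
    mean(rna$counts[1, rna$samples$stage == "early"]) /
      mean(rna$counts[1, rna$samples$stage == "non"])
  }, 1.0)
  expect_gte(mean(ratios), 3)
  expect_lte(mean(ratios), 5.3)
})

test_that("NB mean/variance law holds across replicate simulations", {
  # pooled within-stage sample variance ~ mu + alpha mu^2
  alpha <- 0.15
  mu <- 100
  stats <- vapply(1:100, function(s) {
    truth <- hand_truth(n_bg = 19)
    cfg <- sim_config(n_genes = 20, baseline_mean = mu, dispersion = alpha,
                      seed = s, sf_range = c(1, 1))
    rna <- generate_timecourse_counts(cfg, truth)
    non <- rna$counts[, rna$samples$stage == "non"]
    mean(apply(non, 1, var))
  }, 1.0)
  expected <- mu + alpha * mu^2
  expect_equal(mean(stats), expected, tolerance = 0.1)
})

test_that("peak generator plants promoter peaks and distal decoys", {
  cfg <- sim_config(n_genes = 400, n_peaks = 150,
                    group_sizes = c(adipogenic_tf = 5, autophagy_tf = 6,
                                    autophagy = 40, lipogenic = 10),
                    seed = 6)
  truth <- make_truth(cfg)
  ann <- generate_annotation(400, seed = 6,
                             gene_ids = truth$genes$gene_id)
  pk <- generate_peak_counts(cfg, ann, truth)
  expect_identical(pk$counts,
                   generate_peak_counts(cfg, ann, truth)$counts)
  # every planted direct target has >= 1 peak inside its promoter window
  for (i in seq_len(nrow(truth$links))) {
    g <- truth$links$target[i]
    tss <- ann$tss[ann$gene_id == g]
    own <- pk$peaks[!is.na(pk$peaks$target_gene) &
                      pk$peaks$target_gene == g, ]
    mid <- (own$start + own$end) %/% 2
    expect_true(any(abs(mid - tss) <= cfg$promoter_halfwidth_bp))
  }
  # decoys without planted change carry zero occupancy truth
  expect_true(all(pk$peaks$occ_lfc[is.na(pk$peaks$target_gene)] == 0))
})

test_that("knockdown arms: null at zero strength, deterministic, errors", {
  cfg <- sim_config(n_genes = 200, seed = 4,
                    group_sizes = c(adipogenic_tf = 2, autophagy_tf = 3,
                                    autophagy = 20, lipogenic = 5))
  truth <- make_truth(cfg)
  kd <- generate_knockdown_counts(cfg, truth, "Cebpb")
  expect_identical(kd$counts,
                   generate_knockdown_counts(cfg, truth, "Cebpb")$counts)
  expect_error(generate_knockdown_counts(cfg, truth, "nope"), "unknown")
  expect_error(generate_knockdown_counts(cfg, truth, "Becn1"),
               "non-adipogenic")

  # kd_strength = kd_effect = 0: arms are exchangeable, so arm-vs-arm DE
  # behaves like a null comparison
  kd0 <- generate_knockdown_counts(cfg, truth, "Cebpb", kd_strength = 0,
                                   kd_effect = 0, time_points_h = 0)
  res0 <- nb_wald_test(kd0$counts, kd0$samples$arm,
                       c("knockdown", "control"))
  expect_lte(mean(res0$p < 0.05, na.rm = TRUE), 0.12)
  expect_equal(mean(res0$log2FC), 0, tolerance = 0.1)

  # planted kd_strength = 2 on the factor's own gene is recovered by DE
  lfcs <- vapply(1:20, function(s) {
    cfg2 <- sim_config(n_genes = 200, seed = s,
                       group_sizes = c(adipogenic_tf = 2,
                                       autophagy_tf = 3, autophagy = 20,
                                       lipogenic = 5))
    truth2 <- make_truth(cfg2)
    k <- generate_knockdown_counts(cfg2, truth2, "Cebpb",
                                   time_points_h = 0, kd_strength = 2)
    res <- nb_wald_test(k$counts, k$samples$arm,
                        c("knockdown", "control"))
    res$log2FC[res$feature_id == "Cebpb"]
  }, 1.0)
  expect_gte(mean(lfcs), -2.6)
  expect_lte(mean(lfcs), -1.4)
})

test_that("gene sets: label conservation, composites, empty groups", {
  cfg <- sim_config(n_genes = 2000, seed = 2)
  truth <- make_truth(cfg)
  sets <- generate_gene_sets(truth, seed = 2)
  # the autophagy set size equals the planted label count (default 158)
  expect_equal(length(sets$autophagy), 158L)
  expect_setequal(intersect(sets$autophagy_all, sets$tf_all),
                  sets$autophagy_tf)
  expect_true(any(grepl("^decoy", names(sets))))

  empty <- make_truth(sim_config(n_genes = 100,
                                 group_sizes = c(adipogenic_tf = 2,
                                                 autophagy_tf = 2,
                                                 autophagy = 10,
                                                 lipogenic = 0)))
  expect_warning(s2 <- generate_gene_sets(empty, seed = 1), "lipogenic")
  expect_false("lipogenic" %in% names(s2))
})
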