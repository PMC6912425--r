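# Link-calling logic on hand-constructed evidence tables.

mk_peaks <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(peak_id = r[[1]], chrom = "chr1", start = 0L, end = 100L,
               factor = r[[2]], assigned_gene = r[[3]], region = r[[4]],
               stringsAsFactors = FALSE)))
}

mk_binding <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(feature_id = r[[1]], factor = r[[2]], contrast = r[[3]],
               log2FC = r[[4]], label = r[[5]], stringsAsFactors = FALSE)))
}

mk_coexpr <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(factor = r[[1]], target = r[[2]], stage = r[[3]],
               r = r[[4]], stringsAsFactors = FALSE)))
}

test_that("direct links require promoter peak + binding + co-expression", {
  peaks <- mk_peaks(list("p1", "F", "gT", "Promoter"),
                    list("p2", "F", "gD", "other"),
                    list("p3", "F", "gN", "Promoter"))
  binding <- mk_binding(list("p1", "F", "early_vs_non", 1.4, "up"),
                        list("p2", "F", "early_vs_non", 2.0, "up"),
                        list("p3", "F", "early_vs_non", 0.1, "none"))
  coexpr <- mk_coexpr(list("F", "gT", "early", 0.9),
                      list("F", "gD", "early", 0.9),
                      list("F", "gN", "early", 0.9))
  links <- direct_targets(peaks, binding, coexpr)
  # gD fails (no promoter), gN fails (no significant binding)
  expect_equal(links$target, "gT")
  expect_equal(links$mode, "direct")
  expect_equal(links$stage, "early")
  expect_equal(links$sign, "induction")
  expect_true(links$promoter_peak)

  # weak co-expression suppresses the link (threshold is strict)
  weak <- mk_coexpr(list("F", "gT", "early", 0.25))
  expect_equal(nrow(direct_targets(peaks, binding, weak)), 0L)

  # r = -0.3 with theta 0.25 -> repression
  neg <- mk_coexpr(list("F", "gT", "early", -0.3))
  expect_equal(direct_targets(peaks, binding, neg)$sign, "repression")

  # factor not expressed in the stage -> link suppressed
  fe <- data.frame(factor = "F", stage = "early", mean_count = 1)
  expect_equal(nrow(direct_targets(peaks, binding, coexpr,
                                   factor_expr = fe)), 0L)

  # factor binding its own promoter -> mode auto
  auto <- direct_targets(mk_peaks(list("p1", "F", "F", "Promoter")),
                         binding, mk_coexpr(list("F", "F", "early", 1)))
  expect_equal(auto$mode, "auto")
})

test_that("contrasts nominate the later stage; no promoter peaks, no links", {
  peaks <- mk_peaks(list("p1", "F", "gT", "Promoter"))
  binding <- mk_binding(list("p1", "F", "late_vs_early", -0.9, "down"))
  coexpr <- mk_coexpr(list("F", "gT", "late", 0.5),
                      list("F", "gT", "early", 0.5))
  links <- direct_targets(peaks, binding, coexpr)
  expect_equal(links$stage, "late")

  none <- mk_peaks(list("p1", "F", "gT", "other"))
  expect_equal(nrow(direct_targets(none, binding, coexpr)), 0L)
})

test_that("infer_sign thresholds and ambiguity", {
  links <- data.frame(coexpr_r = c(0.9, -0.3, 0.1, NA))
  expect_equal(infer_sign(links, theta = 0.25),
               c("induction", "repression", "ambiguous", "ambiguous"))
})

test_that("indirect links expand through annotated TF regulons only", {
  direct <- data.frame(factor = "F", target = c("Tf1", "gX"),
                       mode = "direct", stage = "early",
                       stringsAsFactors = FALSE)
  tf_targets <- data.frame(tf = "Tf1", target = c("gA", "gB"),
                           sign = c(1, -1), stringsAsFactors = FALSE)
  ind <- indirect_targets(direct, tf_genes = "Tf1", tf_targets)
  expect_setequal(ind$target, c("gA", "gB"))
  expect_equal(unique(ind$mode), "indirect_via_tf")
  expect_equal(unique(ind$via_tf), "Tf1")

  # no direct link to any TF gene -> empty set
  expect_equal(nrow(indirect_targets(direct[2, , drop = FALSE], "Tf1",
                                     tf_targets)), 0L)
  # TF without regulon annotation -> notice, no links
  expect_message(
    out <- indirect_targets(direct, "Tf1",
                            tf_targets[0, , drop = FALSE]),
    "no annotated targets")
  expect_equal(nrow(out), 0L)

  # a gene reachable directly and via a TF keeps both modes
  tf2 <- data.frame(tf = "Tf1", target = "gX", sign = 1)
  both <- indirect_targets(direct, "Tf1", tf2)
  expect_equal(both$target, "gX") # plus the direct link kept elsewhere
})

test_that("feedback pairs are exactly the planted 2-cycles", {
  links <- data.frame(factor = c("F1", "F2", "F1", "F1"),
                      target = c("F2", "F1", "g3", "F1"),
                      mode = c("direct", "direct", "direct", "auto"),
                      stringsAsFactors = FALSE)
  fb <- detect_feedback(links)
  expect_equal(nrow(fb), 1L)
  expect_equal(c(fb$factor_a, fb$factor_b), c("F1", "F2"))
  expect_equal(nrow(detect_feedback(links[3, , drop = FALSE])), 0L)
})

test_that("knockdown consistency follows the sign-matching rule", {
  links <- data.frame(factor = "F", target = c("g1", "g2", "g3", "g4"),
                      mode = "direct", stage = "early",
                      sign = c("induction", "induction", "repression",
                               "induction"),
                      kd_consistent = "untested",
                      stringsAsFactors = FALSE)
  kd_de <- data.frame(factor = "F",
                      feature_id = c("g1", "g2", "g3"),
                      time_h = 0, log2FC = c(-2, 0.1, 1.5),
                      fdr = c(0.01, 0.9, 0.01),
                      label = c("down", "none", "up"),
                      stringsAsFactors = FALSE)
  got <- knockdown_consistency(links, kd_de)
  # induction + down = yes; induction + unchanged = no;
  # repression + up = yes; absent from KD data = untested
  expect_equal(got$kd_consistent, c("yes", "no", "yes", "untested"))
})

test_that("evaluate_links scores precision, recall and feedback", {
  truth <- hand_truth(
    n_bg = 5,
    links = data.frame(factor = "Cebpb", target = c("g001", "g002"),
                       stage = "early", sign = 1, occ_lfc = 1.5,
                       stringsAsFactors = FALSE))
  links <- data.frame(factor = "Cebpb", target = c("g001", "g003"),
                      mode = "direct", stage = "early", sign = "induction",
                      kd_consistent = c("yes", "no"),
                      stringsAsFactors = FALSE)
  ev <- evaluate_links(links, truth)
  expect_equal(ev$precision, 0.5)
  expect_equal(ev$recall, 0.5)
  expect_equal(ev$kd_consistent_frac, 1) # among recovered true links
})
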