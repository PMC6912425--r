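test_that("nearest-gene assignment: conventions and brute-force oracle", {
  ann <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                    strand = c("+", "-"),
                    start = c(10000L, 50000L), end = c(12000L, 52000L),
                    tss = c(10000L, 52000L), stringsAsFactors = FALSE)
  peaks <- data.frame(peak_id = c("p1", "p2", "p3"), chrom = "chr1",
                      start = c(9900L, 8900L, 52900L),
                      end = c(10100L, 9100L, 53100L),
                      stringsAsFactors = FALSE)
  got <- assign_nearest_gene(peaks, ann)
  # midpoint exactly at the TSS -> that gene, distance 0
  expect_equal(got$assigned_gene[1], "gA")
  expect_equal(got$distance_to_tss[1], 0)
  # 1000 bp 5' of a + strand TSS -> -1000 (upstream is negative)
  expect_equal(got$distance_to_tss[2], -1000)
  # 1000 bp past a - strand TSS in genomic coordinates is also upstream
  expect_equal(got$assigned_gene[3], "gB")
  expect_equal(got$distance_to_tss[3], -1000)

  # equidistant peak resolves to the lexicographically smaller gene id
  mid_tss <- (10000 + 52000) / 2
  tie <- data.frame(peak_id = "t", chrom = "chr1",
                    start = mid_tss - 100L, end = mid_tss + 100L)
  expect_equal(assign_nearest_gene(tie, ann)$assigned_gene, "gA")

  # peak on a gene-less chromosome is left unassigned, with a notice
  lost <- data.frame(peak_id = "x", chrom = "chrX", start = 1L, end = 5L)
  expect_message(res <- assign_nearest_gene(lost, ann), "unassigned")
  expect_true(is.na(res$assigned_gene))
})

test_that("assignments equal exhaustive nearest-TSS search on 100 toy annotations", {
  for (s in 1:100) {
    n <- 5 + s %% 20
    ann <- generate_annotation(n, seed = s)
    withr::with_seed(s, {
      gsel <- sample.int(n, 10, replace = TRUE)
      mid <- ann$tss[gsel] + sample(-8000:8000, 10, replace = TRUE)
      mid <- pmax(mid, 200L)
    })
    peaks <- data.frame(peak_id = paste0("p", 1:10),
                        chrom = ann$chrom[gsel],
                        start = mid - 50L, end = mid + 50L,
                        stringsAsFactors = FALSE)
    got <- assign_nearest_gene(peaks, ann)
    expect_identical(got$assigned_gene, brute_nearest(peaks, ann))
  }
})

test_that("region classification: 3 kb boundary, UTRs, precedence", {
  ann <- generate_annotation(4, seed = 11)
  tss <- ann$tss[1] # + strand gene; utr5 = [start, start+200)
  peak_at <- function(mid, id) data.frame(peak_id = id,
                                          chrom = ann$chrom[1],
                                          start = mid - 10L,
                                          end = mid + 10L,
                                          stringsAsFactors = FALSE)
  p <- do.call(rbind, list(
    peak_at(tss + 2999L, "in_prom"),   # 2999 bp -> Promoter
    peak_at(tss + 3000L, "boundary"),  # exactly 3000 -> still Promoter
    peak_at(tss - 3001L, "out_prom"),  # 3001 bp, outside UTRs -> other
    peak_at(tss + 100L, "in_utr5")))   # inside both promoter and 5'UTR
  got <- classify_region(assign_nearest_gene(p, ann), ann)
  expect_equal(got$region,
               c("Promoter", "Promoter", "other", "Promoter"))
  # promoter classification is symmetric in distance sign
  sym <- rbind(peak_at(tss - 2000L, "a"), peak_at(tss + 2000L, "b"))
  expect_equal(unique(classify_region(assign_nearest_gene(sym, ann),
                                      ann)$region), "Promoter")
  # a peak in the 3' UTR of the gene, > 3 kb from the TSS
  utr3 <- ann$utr3[[1]]
  p3 <- peak_at(as.integer(mean(utr3[1, ])), "in_utr3")
  got3 <- classify_region(assign_nearest_gene(p3, ann), ann)
  expect_equal(got3$region,
               if (abs(got3$distance_to_tss) <= 3000) "Promoter" else
                 "3UTR")
  expect_error(classify_region(p, ann), "assigned first")
})

test_that("occupancy matrix: conservation, manual oracle, errors", {
  # toy: 4 peaks over 2 genes, hand-aggregated
  peaks <- data.frame(peak_id = paste0("p", 1:4), chrom = "chr1",
                      start = c(0L, 100L, 200L, 300L),
                      end = c(50L, 150L, 250L, 350L),
                      assigned_gene = c("gA", "gA", "gB", "gB"),
                      region = c("Promoter", "other", "Promoter", "3UTR"),
                      stringsAsFactors = FALSE)
  cm <- matrix(c(10L, 20L, 5L, 15L,
                 8L, 16L, 4L, 12L), 4, 2,
               dimnames = list(paste0("p", 1:4), c("s1", "s2")))
  occ <- occupancy_matrix(cm, peaks, "gene", sf = c(1, 2))
  expect_equal(occ["gA", ], c(s1 = 30, s2 = 12)) # (10+20), (8+16)/2
  expect_equal(occ["gB", ], c(s1 = 20, s2 = 8))
  occ_r <- occupancy_matrix(cm, peaks, "gene_region", sf = c(1, 2))
  # conservation: region sums equal gene totals exactly
  gene_of <- sub("\\|.*", "", rownames(occ_r))
  expect_equal(rowsum(occ_r, gene_of), occ[sort(rownames(occ)), ],
               ignore_attr = TRUE)

  bad <- cm
  rownames(bad)[1] <- "missing_peak"
  expect_error(occupancy_matrix(bad, peaks), "missing from peak table")

  # one peak per gene: occupancy equals the normalized count
  one <- occupancy_matrix(cm[1:2, ],
                          peaks[1:2, ][, c("peak_id", "chrom", "start",
                                           "end", "assigned_gene",
                                           "region")] |>
                            transform(assigned_gene = c("gA", "gB")),
                          "gene", sf = c(1, 2))
  expect_equal(one["gA", ], c(s1 = 10, s2 = 4))
})

test_that("occupancy correlation and stage change behave as documented", {
  withr::with_seed(3, {
    occ <- matrix(rpois(60, 40), 10, 6,
                  dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  })
  r <- occupancy_correlation(occ)
  expect_equal(diag(r), rep(1, 6), ignore_attr = TRUE)
  expect_equal(r, t(r))
  # doubling raw occupancy is affine in log space only approximately;
  # exact PCC = 1 holds for scaling in log space:
  occ2 <- occ
  occ2[, 2] <- occ[, 1]
  expect_equal(occupancy_correlation(occ2)["s1", "s2"], 1)

  expect_equal(unname(occupancy_change(occ, c("s1", "s2"), c("s1", "s2"))),
               rep(0, 10))
  dbl <- cbind(occ, d1 = 2 * occ[, 1] + 1, d2 = 2 * occ[, 2] + 1)
  ch <- occupancy_change(dbl, c("s1", "s2"), c("d1", "d2"))
  expect_equal(unname(ch), rep(1, 10), tolerance = 0.15)
  expect_error(occupancy_change(occ, "s1", c("s2", "s3")), ">= 2")
})

test_that("differential binding recovers a planted -2.75 promoter change", {
  lfcs <- vapply(1:20, function(s) {
    links <- data.frame(factor = "Cebpb", target = "g001",
                        stage = "early", sign = 1, occ_lfc = -2.75,
                        stringsAsFactors = FALSE)
    truth <- hand_truth(n_bg = 60, links = links)
    cfg <- sim_config(n_genes = 61, n_peaks = 30, seed = s)
    ann <- generate_annotation(61, seed = s,
                               gene_ids = truth$genes$gene_id)
    pk <- generate_peak_counts(cfg, ann, truth, n_static = 10)
    j <- pk$samples$target == "Cebpb"
    db <- differential_binding(pk$counts[, j], pk$samples$stage[j],
                               contrasts = list(c("early", "non")))
    db$log2FC[db$feature_id == "peak_0001"]
  }, 1.0)
  expect_lt(abs(mean(lfcs) - (-2.75)), 0.5)
})
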