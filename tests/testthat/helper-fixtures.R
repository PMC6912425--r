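# Small fixture builders shared across test files.

toy_counts <- function(nr = 5, nc = 4, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rpois(nr * nc, 50), nr, nc,
                dimnames = list(sprintf("g%02d", seq_len(nr)),
                                sprintf("s%02d", seq_len(nc))))
  })
  m
}

toy_samples <- function(counts, stage = NULL) {
  n <- ncol(counts)
  if (is.null(stage)) stage <- rep(c("non", "early"), length.out = n)
  time_h <- c(non = 0, early = 24, late = 240)[stage]
  data.frame(sample_id = colnames(counts), time_h = time_h, stage = stage,
             assay = "rnaseq", target = "none", arm = "none",
             quality_flag = TRUE, stringsAsFactors = FALSE)
}

# hand-built truth table around a single factor
hand_truth <- function(n_bg = 100, links = NULL, lfc_early = NULL,
                       lfc_late = NULL) {
  genes <- data.frame(
    gene_id = c("Cebpb", sprintf("g%03d", seq_len(n_bg))),
    group = c("adipogenic_tf", rep("background", n_bg)),
    lfc_early_vs_non = 0, lfc_late_vs_non = 0,
    stringsAsFactors = FALSE)
  if (!is.null(lfc_early)) genes$lfc_early_vs_non <- lfc_early
  if (!is.null(lfc_late)) genes$lfc_late_vs_non <- lfc_late
  if (is.null(links))
    links <- data.frame(factor = character(), target = character(),
                        stage = character(), sign = numeric(),
                        occ_lfc = numeric(), stringsAsFactors = FALSE)
  structure(list(genes = genes, links = links,
                 tf_targets = data.frame(tf = character(),
                                         target = character(),
                                         sign = numeric(),
                                         stringsAsFactors = FALSE)),
            class = "truth_table")
}

# brute-force nearest-TSS search, the oracle for assign_nearest_gene
brute_nearest <- function(peaks, ann) {
  mid <- (peaks$start + peaks$end) %/% 2L
  vapply(seq_len(nrow(peaks)), function(i) {
    cand <- ann[ann$chrom == peaks$chrom[i], ]
    if (!nrow(cand)) return(NA_character_)
    d <- abs(mid[i] - cand$tss)
    hit <- cand$gene_id[d == min(d)]
    sort(hit)[1]
  }, character(1))
}
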