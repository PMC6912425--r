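# Synthetic staged time-course generator with planted ground truth. The
# generator emulates the statistical structure of the curated 3T3-L1
# datasets: three differentiation stages with NB-distributed gene counts,
# stage-specific log2 fold-changes for designated gene groups (adipogenic
# TFs, autophagy TFs, autophagy genes, lipogenic genes), factor-specific
# promoter peak occupancy changing by stage, latent-activity coupling that
# creates stage-restricted co-expression between factors and their direct
# targets, and knockdown arms that invert or abolish planted effects.

GENE_GROUPS <- c("adipogenic_tf", "autophagy_tf", "autophagy", "lipogenic",
                 "background")

#' Simulation configuration
#'
#' Default values define the package's reference synthetic scenario. Sample
#' sizes, time points, the three-stage design, the 158-gene autophagy set
#' and the six autophagy transcription factors mirror the real study's
#' structure; effect sizes and noise levels are calibration choices
#' documented in the methods vignette.
#'
#' @param n_genes number of genes (must cover `group_sizes`).
#' @param n_peaks total number of ChIP peaks (planted + decoys).
#' @param samples_per_stage RNA/ChIP samples per stage (>= 4).
#' @param time_points_h named list (non/early/late) of hours assigned to
#'   each stage's samples.
#' @param baseline_mean NB baseline mean count.
#' @param dispersion NB dispersion alpha (var = mu + alpha mu^2).
#' @param frac_null fraction of genes with no planted effect.
#' @param effect_table data.frame with columns `group`,
#'   `lfc_early_vs_non`, `lfc_late_vs_non`: planted per-group magnitudes.
#' @param group_sizes named counts of planted gene groups.
#' @param n_factors number of simulated ChIP factors (first genes of the
#'   adipogenic_tf group).
#' @param promoter_halfwidth_bp promoter half-width (default 3000).
#' @param coupling_sd standard deviation (log2 units) of the latent factor
#'   activity shared between a factor and its direct targets.
#' @param kd_strength log2 reduction of the factor's own mean under
#'   knockdown.
#' @param kd_effect log2 magnitude of the knockdown effect propagated to
#'   direct targets.
#' @param sf_range range of per-sample library-size factors (log-uniform).
#' @param seed RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000, n_peaks = 300,
                       samples_per_stage = 8,
                       time_points_h = list(non = c(-48, 0),
                                            early = c(4, 24, 48),
                                            late = c(96, 240)),
                       baseline_mean = 100, dispersion = 0.1,
                       frac_null = 0.8,
                       effect_table = default_effect_table(),
                       group_sizes = c(adipogenic_tf = 5, autophagy_tf = 6,
                                       autophagy = 158, lipogenic = 10),
                       n_factors = 2, promoter_halfwidth_bp = 3000,
                       coupling_sd = 0.8, kd_strength = 2, kd_effect = 1.5,
                       sf_range = c(0.5, 2), seed = 1) {
  cfg <- list(n_genes = n_genes, n_peaks = n_peaks,
              samples_per_stage = samples_per_stage,
              time_points_h = time_points_h,
              baseline_mean = baseline_mean, dispersion = dispersion,
              frac_null = frac_null, effect_table = effect_table,
              group_sizes = group_sizes, n_factors = n_factors,
              promoter_halfwidth_bp = promoter_halfwidth_bp,
              coupling_sd = coupling_sd, kd_strength = kd_strength,
              kd_effect = kd_effect, sf_range = sf_range, seed = seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param cfg configuration to validate.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 1, cfg$samples_per_stage >= 4,
            cfg$baseline_mean > 0, cfg$dispersion >= 0,
            cfg$frac_null >= 0, cfg$frac_null <= 1,
            cfg$n_factors >= 1, cfg$promoter_halfwidth_bp > 0)
  if (!identical(sort(names(cfg$time_points_h)), sort(STAGES)))
    stop("time_points_h must name exactly the stages non/early/late")
  for (s in STAGES) {
    if (!all(assign_stage(cfg$time_points_h[[s]]) == s))
      stop("time point(s) of stage '", s,
           "' do not map to it under the staging rule")
  }
  if (cfg$n_factors > cfg$group_sizes[["adipogenic_tf"]])
    stop("n_factors exceeds the adipogenic_tf group size")
  cfg
}

#' Default planted effect magnitudes per gene group
#'
#' Magnitudes (log2 units) of the stage contrasts vs non; autophagy and
#' background effects receive a random per-gene sign in [make_truth()],
#' adipogenic trajectories are monotone increasing.
#'
#' @return data.frame with columns `group`, `lfc_early_vs_non`,
#'   `lfc_late_vs_non`.
#' @export
default_effect_table <- function() {
  data.frame(
    group = c("adipogenic_tf", "autophagy_tf", "autophagy", "lipogenic",
              "background"),
    lfc_early_vs_non = c(1.5, 1.0, 1.5, 0.5, 1.5),
    lfc_late_vs_non  = c(2.5, 2.0, 1.0, 2.0, 1.5),
    stringsAsFactors = FALSE
  )
}

# Canonical gene names used for flavor; the remainder are synthetic ids.
group_gene_ids <- function(group_sizes) {
  pad <- function(prefix, k, seed_names) {
    n_extra <- max(0, k - length(seed_names))
    c(seed_names[seq_len(min(k, length(seed_names)))],
      if (n_extra) sprintf("%s%03d", prefix, seq_len(n_extra)))
  }
  list(
    adipogenic_tf = pad("Adtf", group_sizes[["adipogenic_tf"]],
                        c("Cebpb", "Pparg", "Med1", "Rxrg", "Ep300")),
    autophagy_tf = pad("Autf", group_sizes[["autophagy_tf"]],
                       c("Foxo1", "Tfeb", "Xbp1", "Irf8", "Trp53",
                         "Zkscan3")),
    autophagy = pad("Atg", group_sizes[["autophagy"]],
                    c("Becn1", "Map1lc3b", "Sqstm1")),
    lipogenic = pad("Lip", group_sizes[["lipogenic"]],
                    c("Acly", "Lpl", "Fasn"))
  )
}

#' Construct a truth table (planted ground truth)
#'
#' Lays out gene groups, planted per-gene stage log2 fold-changes, direct
#' regulatory links from the simulated factors (including one feedback pair
#' and one auto-regulation link when at least two factors are simulated),
#' TF-to-target annotations for the autophagy transcription factors, and
#' planted peak occupancy changes. With `frac_null = 1` all effects are
#' zero and no links are planted.
#'
#' @param cfg a [sim_config()].
#' @return a `truth_table` list: `genes` (gene_id, group, baseline,
#'   lfc_early_vs_non, lfc_late_vs_non), `links` (factor, target, stage,
#'   sign, occ_lfc), `tf_targets` (tf, target, sign).
#' @export
make_truth <- function(cfg) {
  validate_sim_config(cfg)
  gs <- cfg$group_sizes
  if (sum(gs) > cfg$n_genes)
    stop("n_genes must be >= sum(group_sizes) = ", sum(gs))
  ids <- group_gene_ids(gs)
  n_bg <- cfg$n_genes - sum(gs)
  gene_id <- c(unlist(ids, use.names = FALSE),
               sprintf("g%05d", seq_len(n_bg)))
  group <- rep(c(names(ids), "background"),
               c(lengths(ids), n_bg))
  withr::with_seed(cfg$seed, {
    baseline <- stats::rlnorm(cfg$n_genes, log(cfg$baseline_mean), 1)
    et <- cfg$effect_table
    ei <- match(group, et$group)
    sign_gene <- ifelse(group %in% c("autophagy", "background"),
                        sample(c(-1, 1), cfg$n_genes, replace = TRUE), 1)
    lfc_e <- et$lfc_early_vs_non[ei] * sign_gene
    lfc_l <- et$lfc_late_vs_non[ei] * sign_gene

    # null mask: background genes first, then (if needed) group genes
    n_null <- round(cfg$frac_null * cfg$n_genes)
    bg_idx <- which(group == "background")
    null_idx <- bg_idx[sample.int(length(bg_idx),
                                  min(n_null, length(bg_idx)))]
    if (n_null > length(bg_idx)) {
      extra <- sample(which(group != "background"),
                      n_null - length(bg_idx))
      null_idx <- c(null_idx, extra)
    }
    lfc_e[null_idx] <- 0
    lfc_l[null_idx] <- 0

    genes <- data.frame(gene_id = gene_id, group = group,
                        baseline = baseline,
                        lfc_early_vs_non = lfc_e, lfc_late_vs_non = lfc_l,
                        stringsAsFactors = FALSE)

    links <- data.frame(factor = character(), target = character(),
                        stage = character(), sign = numeric(),
                        occ_lfc = numeric(), stringsAsFactors = FALSE)
    tf_targets <- data.frame(tf = character(), target = character(),
                             sign = numeric(), stringsAsFactors = FALSE)
    if (cfg$frac_null < 1) {
      factors <- ids$adipogenic_tf[seq_len(cfg$n_factors)]
      non_null_atg <- setdiff(ids$autophagy, gene_id[null_idx])
      pick <- function(k, exclude) {
        avail <- setdiff(non_null_atg, exclude)
        sample(avail, min(k, length(avail)))
      }
      add <- function(links, factor, target, stage) {
        sgn <- sample(c(1, -1), length(target), replace = TRUE,
                      prob = c(0.7, 0.3))
        occ <- sample(c(1.5, 2, 2.75), length(target), replace = TRUE) *
          sample(c(1, -1), length(target), replace = TRUE)
        rbind(links, data.frame(factor = factor, target = target,
                                stage = stage, sign = sgn, occ_lfc = occ,
                                stringsAsFactors = FALSE))
      }
      # named targets echo the biology: early-acting factor 1, late factor 2
      t1 <- unique(c(intersect(c("Becn1", "Map1lc3b"), non_null_atg),
                     pick(7, c("Becn1", "Map1lc3b"))))
      links <- add(links, factors[1], c(t1, intersect("Xbp1",
                                                      ids$autophagy_tf)),
                   "early")
      if (cfg$n_factors >= 2) {
        t2 <- unique(c(intersect(c("Becn1", "Sqstm1"), non_null_atg),
                       pick(7, c("Becn1", "Sqstm1"))))
        links <- add(links, factors[2],
                     c(t2, intersect(c("Tfeb", "Foxo1"),
                                     ids$autophagy_tf)), "late")
        # feedback 2-cycle between the two factors + one auto-regulation
        links <- add(links, factors[1], factors[2], "early")
        links <- add(links, factors[2], factors[1], "late")
        links <- add(links, factors[1], factors[1], "early")
      }
      if (cfg$n_factors > 2) {
        for (f in factors[-(1:2)])
          links <- add(links, f, pick(10, character()), sample(STAGES[-1],
                                                               1))
      }
      links <- links[!duplicated(links[c("factor", "target")]), ]
      # regulons of the autophagy TFs (for indirect-target truth)
      for (tf in intersect(c("Foxo1", "Tfeb", "Xbp1"), ids$autophagy_tf)) {
        tg <- pick(5, links$target)
        if (!length(tg)) next
        tf_targets <- rbind(tf_targets,
                            data.frame(tf = tf, target = tg,
                                       sign = sample(c(1, -1), length(tg),
                                                     replace = TRUE),
                                       stringsAsFactors = FALSE))
      }
    }
    structure(list(genes = genes, links = links, tf_targets = tf_targets),
              class = "truth_table")
  })
}

#' Validate a truth table
#'
#' @param truth a `truth_table` list (see [make_truth()]).
#' @return the truth table, after validation.
#' @export
validate_truth <- function(truth) {
  g <- truth$genes
  if (anyDuplicated(g$gene_id))
    stop("duplicate gene in truth: ", g$gene_id[duplicated(g$gene_id)][1])
  if (!all(g$group %in% GENE_GROUPS))
    stop("unknown group label: ", setdiff(g$group, GENE_GROUPS)[1])
  if (nrow(truth$links) &&
      !all(c(truth$links$factor, truth$links$target) %in% g$gene_id))
    stop("link references unknown gene")
  truth
}

#' Generate a toy gene annotation
#'
#' Genes are laid out on toy chromosomes at a fixed pitch with seeded
#' jitter, alternating strands. The TSS is the gene start on + and the gene
#' end on -; a 200 bp 5' UTR sits at the TSS end and a 200 bp 3' UTR at the
#' opposite end. Deterministic given the seed.
#'
#' @param n_genes number of genes (>= 1).
#' @param chrom_length length of each toy chromosome in bp (default fits
#'   500 genes per chromosome).
#' @param seed RNG seed.
#' @param gene_ids optional gene ids (defaults to `gene0001`...).
#' @param gene_length,pitch gene body length and slot pitch in bp.
#' @return gene annotation data.frame (see [read_gtf_minimal()]).
#' @export
generate_annotation <- function(n_genes, chrom_length = 500 * 16000,
                                seed = 1, gene_ids = NULL,
                                gene_length = 2000, pitch = 16000) {
  stopifnot(n_genes >= 1)
  per_chrom <- chrom_length %/% pitch
  if (per_chrom < 1)
    stop("chrom_length ", chrom_length, " cannot fit a gene slot of ",
         pitch, " bp")
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  stopifnot(length(gene_ids) == n_genes)
  i <- seq_len(n_genes) - 1L
  chrom <- paste0("chr", i %/% per_chrom + 1L)
  slot0 <- (i %% per_chrom) * pitch
  withr::with_seed(seed, {
    # jitter keeps the gene (plus promoter margin) inside its slot
    margin <- (pitch - gene_length) %/% 2
    jitter <- sample.int(max(1, margin %/% 2), n_genes, replace = TRUE)
  })
  start <- as.integer(slot0 + margin %/% 2 + jitter)
  end <- as.integer(start + gene_length)
  strand <- rep(c("+", "-"), length.out = n_genes)
  tss <- ifelse(strand == "+", start, end)
  utr5 <- vector("list", n_genes)
  utr3 <- vector("list", n_genes)
  for (k in seq_len(n_genes)) {
    if (strand[k] == "+") {
      utr5[[k]] <- matrix(c(start[k], start[k] + 200L), 1)
      utr3[[k]] <- matrix(c(end[k] - 200L, end[k]), 1)
    } else {
      utr5[[k]] <- matrix(c(end[k] - 200L, end[k]), 1)
      utr3[[k]] <- matrix(c(start[k], start[k] + 200L), 1)
    }
  }
  ann <- data.frame(gene_id = gene_ids, chrom = chrom, strand = strand,
                    start = start, end = end, tss = as.integer(tss),
                    stringsAsFactors = FALSE)
  ann$utr5 <- utr5
  ann$utr3 <- utr3
  attr(ann, "chrom_length") <- chrom_length
  attr(ann, "pitch") <- pitch
  validate_annotation(ann)
}

# NB sampler that degrades to Poisson at dispersion zero
rnb <- function(n, mu, dispersion) {
  if (dispersion == 0) stats::rpois(n, mu) else
    stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

# build the RNA-seq sample table for a config
timecourse_samples <- function(cfg) {
  rows <- lapply(STAGES, function(s) {
    tp <- rep(cfg$time_points_h[[s]],
              length.out = cfg$samples_per_stage)
    data.frame(
      sample_id = sprintf("rna_%s_%02d", s, seq_len(cfg$samples_per_stage)),
      time_h = tp, stage = s, assay = "rnaseq", target = "none",
      arm = "none", quality_flag = TRUE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# per-gene log2 mean offsets for a vector of stages, given truth genes
stage_lfc_matrix <- function(genes, stages) {
  lfc <- cbind(non = 0, early = genes$lfc_early_vs_non,
               late = genes$lfc_late_vs_non)
  lfc[, stages, drop = FALSE]
}

#' Generate staged time-course RNA-seq counts
#'
#' Counts are NB-distributed with mean
#' `size_factor * baseline * 2^(planted log2FC for the sample's stage)`.
#' Direct-target co-expression is planted through a latent per-sample
#' factor activity (SD `coupling_sd` log2 units) added to the factor's own
#' gene in all stages and, scaled by the link sign, to each direct target
#' in the link's stage only.
#'
#' @param cfg a [sim_config()].
#' @param truth a truth table (defaults to [make_truth()] on `cfg`).
#' @return list with `counts` (genes x samples), `samples` (sample table)
#'   and `truth`.
#' @export
generate_timecourse_counts <- function(cfg, truth = make_truth(cfg)) {
  validate_sim_config(cfg)
  validate_truth(truth)
  genes <- truth$genes
  st <- timecourse_samples(cfg)
  baseline <- if (is.null(genes$baseline))
    rep(cfg$baseline_mean, nrow(genes)) else genes$baseline
  withr::with_seed(cfg$seed + 1L, {
    sf <- exp(stats::runif(nrow(st), log(cfg$sf_range[1]),
                           log(cfg$sf_range[2])))
    lmu <- log2(baseline) + stage_lfc_matrix(genes, st$stage)
    if (nrow(truth$links)) {
      factors <- unique(truth$links$factor)
      act <- matrix(stats::rnorm(length(factors) * nrow(st),
                                 sd = cfg$coupling_sd),
                    length(factors), nrow(st),
                    dimnames = list(factors, st$sample_id))
      for (f in factors)
        lmu[match(f, genes$gene_id), ] <-
          lmu[match(f, genes$gene_id), ] + act[f, ]
      for (k in seq_len(nrow(truth$links))) {
        lk <- truth$links[k, ]
        if (lk$target == lk$factor) next # auto-link: correlation is trivial
        j <- st$stage == lk$stage
        gi <- match(lk$target, genes$gene_id)
        lmu[gi, j] <- lmu[gi, j] + lk$sign * act[lk$factor, j]
      }
    }
    mu <- sweep(2^lmu, 2, sf, "*")
    counts <- matrix(rnb(length(mu), mu, cfg$dispersion), nrow(mu),
                     dimnames = list(genes$gene_id, st$sample_id))
  })
  list(counts = counts, samples = st, truth = truth)
}

#' Generate a peak table and reads-in-peaks counts
#'
#' Every planted direct link gets one peak whose midpoint lies inside the
#' promoter window of the target gene; additional "static" promoter peaks
#' (no occupancy change) on background genes and distal decoy peaks between
#' genes fill the table up to `cfg$n_peaks`. Counts are NB-distributed; in
#' samples of the peak's own factor the mean follows the planted stage
#' occupancy log2FC (applied from the link's stage onward), in other
#' factors' samples the peak shows background signal only.
#'
#' @param cfg a [sim_config()].
#' @param ann gene annotation covering the truth's genes.
#' @param truth truth table.
#' @param n_static number of unchanged promoter decoy peaks (default 50).
#' @return list with `peaks` (peak table incl. owner `factor` and planted
#'   `occ_lfc`), `counts` (peaks x ChIP samples), `samples` and `truth`.
#' @export
generate_peak_counts <- function(cfg, ann, truth, n_static = 50) {
  validate_sim_config(cfg)
  validate_truth(truth)
  hw <- cfg$promoter_halfwidth_bp
  links <- truth$links
  factors <- if (nrow(links)) unique(links$factor) else
    group_gene_ids(cfg$group_sizes)$adipogenic_tf[seq_len(cfg$n_factors)]
  withr::with_seed(cfg$seed + 2L, {
    rows <- list()
    if (nrow(links)) {
      gi <- match(links$target, ann$gene_id)
      off <- round(stats::runif(nrow(links), -(hw - 500), hw - 500))
      mid <- pmax(200L, ann$tss[gi] + as.integer(off))
      rows[[1]] <- data.frame(
        chrom = ann$chrom[gi], start = mid - 150L, end = mid + 150L,
        factor = links$factor, target_gene = links$target,
        occ_lfc = links$occ_lfc, occ_stage = links$stage,
        stringsAsFactors = FALSE)
    }
    bg <- truth$genes$gene_id[truth$genes$group == "background"]
    n_static <- min(n_static, length(bg))
    if (n_static) {
      gsel <- match(sample(bg, n_static), ann$gene_id)
      off <- round(stats::runif(n_static, -(hw - 500), hw - 500))
      mid <- pmax(200L, ann$tss[gsel] + as.integer(off))
      rows[[2]] <- data.frame(
        chrom = ann$chrom[gsel], start = mid - 150L, end = mid + 150L,
        factor = rep(factors, length.out = n_static),
        target_gene = NA_character_, occ_lfc = 0, occ_stage = NA_character_,
        stringsAsFactors = FALSE)
    }
    n_so_far <- sum(vapply(rows, nrow, 1L))
    n_decoy <- max(0L, cfg$n_peaks - n_so_far)
    if (n_decoy) {
      pitch <- attr(ann, "pitch")
      if (is.null(pitch)) pitch <- 16000
      gsel <- sample.int(nrow(ann), n_decoy, replace = TRUE)
      # midway between gene slots: far from every TSS, outside UTRs
      mid <- (ann$start[gsel] %/% pitch) * pitch + pitch - 500L
      rows[[3]] <- data.frame(
        chrom = ann$chrom[gsel], start = mid - 150L, end = mid + 150L,
        factor = rep(factors, length.out = n_decoy),
        target_gene = NA_character_, occ_lfc = 0, occ_stage = NA_character_,
        stringsAsFactors = FALSE)
    }
    peaks <- do.call(rbind, rows)
    peaks <- cbind(peak_id = sprintf("peak_%04d", seq_len(nrow(peaks))),
                   peaks, score = 0, strand = ".",
                   stringsAsFactors = FALSE)

    # ChIP sample table: per factor, samples_per_stage per stage
    st <- do.call(rbind, lapply(factors, function(f) {
      s <- timecourse_samples(cfg)
      s$sample_id <- sprintf("chip_%s_%s", f, s$sample_id)
      s$assay <- "chipseq"
      s$target <- f
      s
    }))
    sf <- exp(stats::runif(nrow(st), log(cfg$sf_range[1]),
                           log(cfg$sf_range[2])))
    base_p <- stats::rlnorm(nrow(peaks), log(50), 0.5)
    stage_num <- match(st$stage, STAGES)
    lmu <- matrix(log2(base_p), nrow(peaks), nrow(st))
    own <- outer(peaks$factor, st$target, "==")
    lmu[!own] <- lmu[!own] - 2 # background signal in other factors' samples
    for (k in which(peaks$occ_lfc != 0)) {
      on <- own[k, ] & stage_num >= match(peaks$occ_stage[k], STAGES)
      lmu[k, on] <- lmu[k, on] + peaks$occ_lfc[k]
    }
    mu <- sweep(2^lmu, 2, sf, "*")
    counts <- matrix(rnb(length(mu), mu, cfg$dispersion), nrow(mu),
                     dimnames = list(peaks$peak_id, st$sample_id))
  })
  list(peaks = peaks, counts = counts, samples = st, truth = truth)
}

#' Generate knockdown-vs-control counts for one factor
#'
#' The knockdown arm multiplies the factor's own mean by
#' `2^(-kd_strength)` and each planted direct target's mean by
#' `2^(-sign * kd_effect)` (first-order propagation only), at every
#' requested time point. The control arm is untouched. With
#' `kd_strength = 0` and `kd_effect = 0` the two arms are drawn from
#' identical distributions.
#'
#' @param cfg a [sim_config()].
#' @param truth truth table.
#' @param factor gene id of a planted adipogenic TF.
#' @param time_points_h time points profiled (default 0 and 48 h).
#' @param kd_strength,kd_effect see [sim_config()]; default from `cfg`.
#' @return list with `counts` and `samples` (arm in `arm`, factor in
#'   `target`).
#' @export
generate_knockdown_counts <- function(cfg, truth, factor,
                                      time_points_h = c(0, 48),
                                      kd_strength = cfg$kd_strength,
                                      kd_effect = cfg$kd_effect) {
  validate_sim_config(cfg)
  validate_truth(truth)
  genes <- truth$genes
  fi <- match(factor, genes$gene_id)
  if (is.na(fi) || genes$group[fi] != "adipogenic_tf")
    stop("unknown or non-adipogenic factor: ", factor)
  grid <- expand.grid(arm = c("control", "knockdown"),
                      time_h = time_points_h,
                      rep = seq_len(cfg$samples_per_stage),
                      stringsAsFactors = FALSE)
  st <- data.frame(
    sample_id = sprintf("kd_%s_%s_t%g_%02d", factor, grid$arm, grid$time_h,
                        grid$rep),
    time_h = grid$time_h, stage = assign_stage(grid$time_h),
    assay = "rnaseq", target = factor, arm = grid$arm,
    quality_flag = TRUE, stringsAsFactors = FALSE)
  baseline <- if (is.null(genes$baseline))
    rep(cfg$baseline_mean, nrow(genes)) else genes$baseline
  tg <- truth$links[truth$links$factor == factor &
                      truth$links$target != factor, ]
  withr::with_seed(cfg$seed + 10L + fi, {
    sf <- exp(stats::runif(nrow(st), log(cfg$sf_range[1]),
                           log(cfg$sf_range[2])))
    lmu <- log2(baseline) + stage_lfc_matrix(genes, st$stage)
    kd <- st$arm == "knockdown"
    lmu[fi, kd] <- lmu[fi, kd] - kd_strength
    if (nrow(tg)) {
      ti <- match(tg$target, genes$gene_id)
      lmu[ti, kd] <- lmu[ti, kd] - tg$sign * kd_effect
    }
    mu <- sweep(2^lmu, 2, sf, "*")
    counts <- matrix(rnb(length(mu), mu, cfg$dispersion), nrow(mu),
                     dimnames = list(genes$gene_id, st$sample_id))
  })
  list(counts = counts, samples = st)
}

#' Build GMT-style gene sets from a truth table
#'
#' One set per non-empty planted group (empty groups are omitted with a
#' warning), the composite sets `autophagy_all` (autophagy plus autophagy
#' TFs) and `tf_all` (all TFs) whose intersection is exactly the autophagy
#' TF set, and uniform random decoy sets.
#'
#' @param truth truth table.
#' @param n_decoys number of decoy sets (default 20).
#' @param decoy_size members per decoy set (default 50).
#' @param seed RNG seed for the decoys.
#' @return named list of gene-id vectors with a `description` attribute.
#' @export
generate_gene_sets <- function(truth, n_decoys = 20, decoy_size = 50,
                               seed = 1) {
  validate_truth(truth)
  g <- truth$genes
  sets <- list()
  desc <- character()
  for (grp in setdiff(GENE_GROUPS, "background")) {
    members <- g$gene_id[g$group == grp]
    if (!length(members)) {
      warning("group '", grp, "' is empty; set omitted")
      next
    }
    sets[[grp]] <- members
    desc <- c(desc, paste("planted", grp, "group"))
  }
  sets$autophagy_all <- g$gene_id[g$group %in% c("autophagy",
                                                 "autophagy_tf")]
  sets$tf_all <- g$gene_id[g$group %in% c("adipogenic_tf", "autophagy_tf")]
  desc <- c(desc, "autophagy genes incl. autophagy TFs",
            "all transcription factor genes")
  withr::with_seed(seed, {
    for (d in seq_len(n_decoys)) {
      sets[[sprintf("decoy%02d", d)]] <-
        sample(g$gene_id, min(decoy_size, nrow(g)))
      desc <- c(desc, "uniform random decoy set")
    }
  })
  attr(sets, "description") <- desc
  sets
}
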