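# Readers and writers for the plain-text formats the pipeline consumes:
# counts TSV, sample table CSV, BED/narrowPeak, minimal GTF, and GMT.
# Coordinates are 0-based half-open everywhere in memory; GTF (1-based
# inclusive) is converted at the boundary.

#' Validate a count matrix
#'
#' A count matrix is an integer-valued matrix with unique feature row names
#' and unique sample column names, and no negative entries.
#'
#' @param counts matrix to validate.
#' @return the matrix, invisibly, after validation.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have feature row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature id: ",
         rownames(counts)[duplicated(rownames(counts))][1])
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample id: ",
         colnames(counts)[duplicated(colnames(counts))][1])
  if (anyNA(counts)) stop("counts contain missing values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop("negative count for feature '", rownames(counts)[bad[1]], "'")
  }
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    stop("non-integer count for feature '", rownames(counts)[bad[1]], "'")
  }
  invisible(counts)
}

#' Read a count matrix from a tab-separated file
#'
#' The file must have a header row of sample ids and feature ids in the
#' first column. Entries must be non-negative integers.
#'
#' @param path path to a TSV file.
#' @return integer matrix (features x samples) with dimnames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", fill = FALSE,
                          check.names = FALSE, colClasses = NA)
  if (ncol(df) < 2) stop("counts file needs a feature column plus >=1 sample")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    line <- which(duplicated(ids))[1] + 1L # header is line 1
    stop("duplicate feature id '", ids[duplicated(ids)][1],
         "' at line ", line, " of ", path)
  }
  num <- df[, -1, drop = FALSE]
  for (j in seq_along(num)) {
    v <- suppressWarnings(as.numeric(num[[j]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad)) {
      stop("invalid count '", num[[j]][bad[1]], "' at line ", bad[1] + 1L,
           ", column '", names(num)[j], "' of ", path)
    }
    num[[j]] <- as.integer(v)
  }
  m <- as.matrix(num)
  rownames(m) <- ids
  validate_counts(m)
  m
}

#' Write a count matrix to a tab-separated file
#'
#' @param counts validated count matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  validate_counts(counts)
  df <- data.frame(feature_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample table from a CSV file
#'
#' Expected columns: `sample_id`, `time_h`, `stage`, `assay`, `target`,
#' `arm`, `quality_flag`. The stage column is checked for consistency with
#' [assign_stage()].
#'
#' @param path path to a CSV file.
#' @return data.frame with one row per sample.
#' @export
read_sample_table <- function(path) {
  st <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_table(st)
}

#' @rdname read_sample_table
#' @param st sample table data.frame to validate.
#' @export
validate_sample_table <- function(st) {
  need <- c("sample_id", "time_h", "stage", "assay", "target", "arm",
            "quality_flag")
  miss <- setdiff(need, names(st))
  if (length(miss)) stop("sample table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(st$sample_id))
    stop("duplicate sample id: ", st$sample_id[duplicated(st$sample_id)][1])
  expected <- assign_stage(st$time_h)
  off <- which(st$stage != expected)
  if (length(off))
    stop("stage inconsistent with time_h for sample '",
         st$sample_id[off[1]], "' (", st$time_h[off[1]], " h should be ",
         expected[off[1]], ")")
  st$quality_flag <- as.logical(st$quality_flag)
  st
}

#' Write a sample table to CSV
#'
#' @param st sample table data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(st, path) {
  utils::write.csv(validate_sample_table(st), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a BED or narrowPeak file as a peak table
#'
#' Standard BED semantics: 0-based half-open intervals. narrowPeak files
#' (BED6+4) are accepted; extra columns are ignored. Fewer than six columns
#' are tolerated down to three (name, score and strand filled with
#' defaults).
#'
#' @param path path to a BED/narrowPeak file.
#' @return data.frame with columns `peak_id`, `chrom`, `start`, `end`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t", fill = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 3) stop("BED file needs >=3 columns: ", path)
  out <- data.frame(
    peak_id = if (ncol(df) >= 4) as.character(df[[4]]) else
      paste0("peak_", seq_len(nrow(df))),
    chrom  = as.character(df[[1]]),
    start  = as.integer(df[[2]]),
    end    = as.integer(df[[3]]),
    score  = if (ncol(df) >= 5) as.numeric(df[[5]]) else 0,
    strand = if (ncol(df) >= 6) as.character(df[[6]]) else ".",
    stringsAsFactors = FALSE
  )
  bad <- which(out$end <= out$start)
  if (length(bad))
    stop("interval end <= start at line ", bad[1], " of ", path)
  bads <- which(!out$strand %in% c("+", "-", "."))
  if (length(bads))
    stop("unknown strand symbol '", out$strand[bads[1]], "' at line ",
         bads[1], " of ", path)
  if (anyDuplicated(out$peak_id))
    stop("duplicate peak id: ", out$peak_id[duplicated(out$peak_id)][1])
  out
}

#' Write a peak table as 6-column BED
#'
#' @param peaks peak table data.frame (as from [read_bed()]); if a `region`
#'   column is present it is appended to the name field.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  name <- peaks$peak_id
  if (!is.null(peaks$region)) name <- paste(name, peaks$region, sep = "|")
  df <- data.frame(peaks$chrom, peaks$start, peaks$end, name,
                   if (is.null(peaks$score)) 0 else peaks$score,
                   if (is.null(peaks$strand)) "." else peaks$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Each line is: set name, description, then tab-separated member ids.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors, with a `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3)
  if (length(short))
    stop("GMT line ", short[1], " has fewer than 3 fields in ", path)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(names(sets)))
    stop("duplicate set name: ", names(sets)[duplicated(names(sets))][1])
  attr(sets, "description") <- vapply(fields, `[[`, "", 2)
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description optional character vector of descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(description)) {
    description <- attr(sets, "description")
    if (is.null(description)) description <- rep("na", length(sets))
  }
  lines <- mapply(function(nm, desc, members)
    paste(c(nm, desc, members), collapse = "\t"),
    names(sets), description, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read a minimal GTF into a gene annotation table
#'
#' Recognizes `gene`, `five_prime_utr` and `three_prime_utr` features and
#' the `gene_id` attribute. GTF coordinates (1-based inclusive) are
#' converted to 0-based half-open by shifting start by -1.
#'
#' @param path path to a GTF file.
#' @return gene annotation data.frame: `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `tss`, plus list columns `utr5` and `utr3` holding
#'   two-column interval matrices.
#' @export
read_gtf_minimal <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t", fill = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          quote = "")
  if (ncol(df) != 9) stop("GTF requires 9 tab-separated columns: ", path)
  names(df) <- c("chrom", "source", "feature", "start", "end", "score",
                 "strand", "frame", "attributes")
  bad <- which(df$end < df$start)
  if (length(bad)) stop("GTF end < start at line ", bad[1], " of ", path)
  if (any(!df$strand %in% c("+", "-")))
    stop("unknown strand symbol in GTF: ", path)
  gid <- sub('.*gene_id "([^"]+)".*', "\\1", df$attributes)
  if (any(gid == df$attributes))
    stop("missing gene_id attribute at line ",
         which(gid == df$attributes)[1], " of ", path)
  df$start <- df$start - 1L # to 0-based half-open
  genes <- df[df$feature == "gene", ]
  ann <- data.frame(
    gene_id = gid[df$feature == "gene"],
    chrom = genes$chrom, strand = genes$strand,
    start = genes$start, end = genes$end,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(ann$gene_id))
    stop("duplicate gene id: ", ann$gene_id[duplicated(ann$gene_id)][1])
  ann$tss <- ifelse(ann$strand == "+", ann$start, ann$end)
  grab <- function(feature) {
    sel <- df$feature == feature
    ivs <- split.data.frame(df[sel, c("start", "end")], gid[sel])
    lapply(stats::setNames(ann$gene_id, ann$gene_id), function(g) {
      if (is.null(ivs[[g]])) matrix(integer(), 0, 2) else
        unname(as.matrix(ivs[[g]]))
    })
  }
  ann$utr5 <- unname(grab("five_prime_utr"))
  ann$utr3 <- unname(grab("three_prime_utr"))
  validate_annotation(ann)
}

#' Validate a gene annotation table
#'
#' @param ann annotation data.frame as documented in [read_gtf_minimal()].
#' @return the annotation, after validation.
#' @export
validate_annotation <- function(ann) {
  need <- c("gene_id", "chrom", "strand", "start", "end", "tss")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(ann$gene_id))
    stop("duplicate gene id: ", ann$gene_id[duplicated(ann$gene_id)][1])
  if (any(ann$start >= ann$end)) stop("gene start must be < end")
  tss_ok <- ifelse(ann$strand == "+", ann$tss == ann$start,
                   ann$tss == ann$end)
  if (!all(tss_ok)) stop("tss must be the strand-appropriate gene boundary")
  for (col in intersect(c("utr5", "utr3"), names(ann))) {
    for (i in seq_len(nrow(ann))) {
      iv <- ann[[col]][[i]]
      if (nrow(iv) && (any(iv[, 1] < ann$start[i]) ||
                       any(iv[, 2] > ann$end[i])))
        stop(col, " interval outside gene span for ", ann$gene_id[i])
    }
  }
  ann
}

#' Write a gene annotation as GTF (gene + UTR features) or flat TSV
#'
#' @param ann annotation data.frame.
#' @param path output path.
#' @param format `"gtf"` or `"tsv"` (TSV drops UTR intervals).
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path, format = c("gtf", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(ann[c("gene_id", "chrom", "strand", "start", "end",
                             "tss")],
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  row <- function(chrom, feature, s0, e0, strand, gid)
    paste(chrom, "adiporeg", feature, s0 + 1L, e0, ".", strand, ".",
          sprintf('gene_id "%s";', gid), sep = "\t")
  lines <- character()
  for (i in seq_len(nrow(ann))) {
    lines <- c(lines, row(ann$chrom[i], "gene", ann$start[i], ann$end[i],
                          ann$strand[i], ann$gene_id[i]))
    for (nm in c("utr5", "utr3")) {
      feat <- if (nm == "utr5") "five_prime_utr" else "three_prime_utr"
      iv <- ann[[nm]][[i]]
      if (!is.null(iv) && nrow(iv))
        for (k in seq_len(nrow(iv)))
          lines <- c(lines, row(ann$chrom[i], feat, iv[k, 1], iv[k, 2],
                                ann$strand[i], ann$gene_id[i]))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Drop low-quality samples and low-expression features
#'
#' Removes samples whose `quality_flag` is `FALSE`, then keeps features with
#' at least `min_count` reads in at least `min_samples` of the remaining
#' samples. The exact filter the original study applied to "low expressed"
#' genes is not published; the defaults (10 reads in 3 samples) are this
#' package's choice and are exposed.
#'
#' @param counts count matrix (features x samples).
#' @param samples sample table with `sample_id` and `quality_flag`.
#' @param min_count minimum read count (default 10).
#' @param min_samples minimum number of samples reaching `min_count`
#'   (default 3).
#' @return filtered count matrix.
#' @export
filter_low_quality <- function(counts, samples, min_count = 10,
                               min_samples = 3) {
  stopifnot(min_count >= 0, min_samples >= 0)
  validate_counts(counts)
  idx <- match(colnames(counts), samples$sample_id)
  if (anyNA(idx)) stop("sample(s) missing from sample table: ",
                       colnames(counts)[is.na(idx)][1])
  keep_s <- samples$quality_flag[idx]
  cm <- counts[, keep_s, drop = FALSE]
  keep_f <- rowSums(cm >= min_count) >= min_samples
  message("filter_low_quality: removed ", sum(!keep_s), " sample(s), ",
          sum(!keep_f), " feature(s)")
  out <- cm[keep_f, , drop = FALSE]
  if (nrow(out) == 0 || ncol(out) == 0)
    stop("filtering removed all ", if (ncol(out) == 0) "samples" else
      "features")
  out
}
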