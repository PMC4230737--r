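#' methaberr: DNA methylation aberration analysis for reprogrammed cells
#'
#' Tools to detect and classify DNA methylation aberrations in induced
#' pluripotent stem cells (iPSCs) relative to parental fibroblasts and
#' reference embryonic stem cells (ESCs), and to interpret them through
#' permutation-based enrichment at transcription-factor binding regions,
#' genomic-context profiling, sequencing-array concordance, and
#' tumour-versus-normal delta-beta comparison. A synthetic-data module
#' generates beta-value matrices with planted ground truth so the whole
#' pipeline can be exercised and validated without external downloads.
#'
#' @keywords internal
"_PACKAGE"

## Recognised sample group labels.
GROUP_LEVELS <- c("FIB", "ESC", "Y_IPSC", "T_IPSC", "TUMOR", "NORMAL")

## CpG island context strata of the 450K annotation.
ISLAND_CONTEXTS <- c("island", "shore", "shelf", "open_sea")

#' Compute a beta value from methylated/unmethylated signal intensities
#'
#' The beta value is the fraction of methylated signal, `M / (M + U)`,
#' the standard per-CpG methylation estimate on Infinium arrays. The
#' function is vectorised and scale-invariant in the two intensities.
#'
#' @param methylated_signal Non-negative methylated channel intensity `M`.
#' @param unmethylated_signal Non-negative unmethylated channel intensity `U`.
#' @return Numeric vector of beta values in `[0, 1]`.
#' @examples
#' compute_beta(75, 25)   # 0.75
#' compute_beta(0, 100)   # 0
#' @export
compute_beta <- function(methylated_signal, unmethylated_signal) {
  m <- as.numeric(methylated_signal)
  u <- as.numeric(unmethylated_signal)
  if (any(is.na(m)) || any(is.na(u))) {
    stop("signal intensities must be non-missing")
  }
  if (any(m < 0) || any(u < 0)) {
    stop("signal intensities must be non-negative")
  }
  tot <- m + u
  if (any(tot == 0)) {
    stop("undefined beta: M + U = 0 (failed probe)")
  }
  m / tot
}

#' Construct and validate a beta-value matrix
#'
#' A beta matrix is a plain numeric matrix, probes in rows and samples in
#' columns, with unique dimnames and all non-missing values in `[0, 1]`.
#' `NA` marks failed probes and is propagated by downstream statistics.
#'
#' @param values Numeric matrix with probe rownames and sample colnames.
#' @return The validated matrix (invisibly unchanged).
#' @export
beta_matrix <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("beta matrix needs probe rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate probe ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample ids")
  }
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("beta value out of [0,1] at probe '%s', sample '%s'",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]))
  }
  values
}

#' Read a beta-value matrix from a tab-separated file
#'
#' Expects a header row; first column holds probe ids, remaining columns
#' one sample each. Empty cells and `NA` become missing values.
#'
#' @param path Path to the TSV file.
#' @return A validated beta matrix (probes x samples).
#' @export
read_beta_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("beta matrix file needs a probe column plus samples")
  probes <- as.character(df[[1]])
  if (anyDuplicated(probes)) {
    stop("duplicate probe id in ", path, ": ",
         probes[duplicated(probes)][1])
  }
  values <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- probes
  beta_matrix(values)
}

#' Write a beta-value matrix to a tab-separated file
#'
#' @param matrix Beta matrix as from [beta_matrix()].
#' @param path Output path.
#' @export
write_beta_matrix <- function(matrix, path) {
  df <- data.frame(probe_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a sample sheet mapping sample ids to groups
#'
#' Two tab-separated columns, `sample_id` and `group`; groups must be one
#' of FIB, ESC, Y_IPSC, T_IPSC, TUMOR, NORMAL.
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns `sample_id`, `group`.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample sheet missing columns: ",
                         paste(miss, collapse = ", "))
  sample_sheet(df$sample_id, df$group)
}

#' Construct and validate a sample sheet
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param group Character vector of group labels, same length.
#' @return data.frame with columns `sample_id`, `group`.
#' @export
sample_sheet <- function(sample_id, group) {
  sample_id <- as.character(sample_id)
  group <- as.character(group)
  if (length(sample_id) != length(group)) {
    stop("sample_id and group lengths differ")
  }
  if (anyDuplicated(sample_id)) stop("duplicate sample ids in sample sheet")
  bad <- setdiff(unique(group), GROUP_LEVELS)
  if (length(bad)) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(GROUP_LEVELS, collapse = ", "), ")")
  }
  data.frame(sample_id = sample_id, group = group,
             stringsAsFactors = FALSE)
}

#' Samples belonging to one or more groups
#'
#' @param sheet Sample sheet data.frame.
#' @param groups Character vector of group labels.
#' @return Character vector of sample ids.
#' @export
samples_in_group <- function(sheet, groups) {
  sheet$sample_id[sheet$group %in% groups]
}

#' Read probe annotation
#'
#' Tab-separated with columns `probe_id`, `chrom`, `pos` (1-based bp),
#' `island_context` (island/shore/shelf/open_sea, case-insensitive),
#' `nearest_gene`, `tss_distance` (signed bp; negative = upstream).
#' Empty gene fields become `NA`.
#'
#' @param path Path to the TSV file.
#' @return Validated annotation data.frame.
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("probe_id", "chrom", "pos", "island_context",
            "nearest_gene", "tss_distance")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("probe annotation missing columns: ",
                         paste(miss, collapse = ", "))
  probe_annotation(df$probe_id, df$chrom, df$pos, df$island_context,
                   df$nearest_gene, df$tss_distance)
}

#' Construct and validate a probe annotation table
#'
#' @param probe_id,chrom,pos,island_context,nearest_gene,tss_distance
#'   Parallel vectors; see [read_probe_annotation()] for semantics.
#' @return data.frame with normalised `island_context`.
#' @export
probe_annotation <- function(probe_id, chrom, pos, island_context,
                             nearest_gene = NA, tss_distance = NA) {
  probe_id <- as.character(probe_id)
  if (anyDuplicated(probe_id)) stop("duplicate probe ids in annotation")
  ctx <- tolower(as.character(island_context))
  ctx[ctx %in% c("opensea", "open sea")] <- "open_sea"
  bad <- setdiff(unique(ctx[!is.na(ctx)]), ISLAND_CONTEXTS)
  if (length(bad)) stop("unknown island_context value(s): ",
                        paste(bad, collapse = ", "))
  gene <- as.character(nearest_gene)
  tssd <- as.numeric(tss_distance)
  if (any(!is.na(gene) & is.na(tssd))) {
    stop("tss_distance must be defined wherever nearest_gene is")
  }
  data.frame(probe_id = probe_id, chrom = as.character(chrom),
             pos = as.integer(pos), island_context = ctx,
             nearest_gene = gene, tss_distance = tssd,
             stringsAsFactors = FALSE)
}

#' Read transcription-factor binding peaks from a BED file
#'
#' BED3+ input; intervals are stored exactly as read, in the 0-based
#' half-open BED convention. An array probe at 1-based position p overlaps
#' the interval (s, e) iff s <= p - 1 < e; the conversion happens only at
#' the point of comparison (see [overlap_count()]).
#'
#' @param path Path to the BED file (no header).
#' @param factor_name Name of the transcription factor the peaks belong to.
#' @return A `peak_set`: data.frame (chrom, start, end) with a
#'   `factor_name` attribute.
#' @export
read_bed_peaks <- function(path, factor_name) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(peak_set(character(0), integer(0), integer(0), factor_name))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(parts, length, integer(1))
  if (any(nf < 3)) {
    stop("BED line ", which(nf < 3)[1], " has fewer than 3 fields")
  }
  chrom <- vapply(parts, `[[`, character(1), 1)
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 2)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 3)))
  if (any(is.na(start)) || any(is.na(end))) {
    stop("BED line ", which(is.na(start) | is.na(end))[1],
         ": non-numeric start/end")
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stop("BED line ", bad[1], ": start >= end (", start[bad[1]], " >= ",
         end[bad[1]], ")")
  }
  peak_set(chrom, start, end, factor_name)
}

#' Construct a peak set
#'
#' @param chrom,start,end Interval columns in BED (0-based half-open)
#'   convention.
#' @param factor_name Non-empty factor name.
#' @return A `peak_set` data.frame.
#' @export
peak_set <- function(chrom, start, end, factor_name) {
  if (!is.character(factor_name) || length(factor_name) != 1 ||
      !nzchar(factor_name)) {
    stop("factor_name must be a non-empty string")
  }
  if (length(start) && any(start >= end)) stop("peak with start >= end")
  ps <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), stringsAsFactors = FALSE)
  attr(ps, "factor_name") <- factor_name
  class(ps) <- c("peak_set", "data.frame")
  ps
}

#' Write a peak set back to BED
#'
#' @param peaks A `peak_set`.
#' @param path Output path.
#' @export
write_bed_peaks <- function(peaks, path) {
  utils::write.table(as.data.frame(peaks)[, c("chrom", "start", "end")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read an RRBS per-CpG count table
#'
#' Tab-separated with columns `chrom`, `pos` (1-based), `meth_count`,
#' `total_count`; counts must satisfy 0 <= meth <= total, total >= 1.
#'
#' @param path Path to the TSV file.
#' @return data.frame of RRBS records.
#' @export
read_rrbs_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "meth_count", "total_count")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("RRBS table missing columns: ",
                         paste(miss, collapse = ", "))
  rrbs_profile(df$chrom, df$pos, df$meth_count, df$total_count)
}

#' Construct and validate an RRBS profile
#'
#' @param chrom,pos,meth_count,total_count Parallel record vectors.
#' @return data.frame of RRBS records.
#' @export
rrbs_profile <- function(chrom, pos, meth_count, total_count) {
  meth_count <- as.integer(meth_count)
  total_count <- as.integer(total_count)
  if (any(total_count < 1)) stop("RRBS total_count must be >= 1")
  if (any(meth_count < 0) || any(meth_count > total_count)) {
    stop("RRBS meth_count must satisfy 0 <= meth <= total")
  }
  data.frame(chrom = as.character(chrom), pos = as.integer(pos),
             meth_count = meth_count, total_count = total_count,
             stringsAsFactors = FALSE)
}

#' Write a results table as TSV
#'
#' UTF-8, tab-separated, header row, no quoting; the standard output
#' format of every pipeline stage. Reading back with
#' [utils::read.delim()] round-trips values within text precision.
#'
#' @param results A data.frame.
#' @param path Output path.
#' @export
write_results_table <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}
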