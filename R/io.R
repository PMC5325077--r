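#' Write a cohort's expression matrix and embryo metadata as TSV
#'
#' The expression table has one `gene_id` column followed by one contiguous
#' column block per embryo, labelled `EMBRYOID_sliceNN` with `NN` 1-based
#' anterior-to-posterior.  FPKM values are written with 6 significant
#' digits.  The metadata table maps each embryo id to genotype, time point,
#' slice count, and the comma-separated list of QC-failed slice numbers.
#'
#' @param embryos list of `embryo_sample` objects (or a `cohort`).
#' @param path output path for the expression TSV.
#' @param metadata_path output path for the metadata TSV.
#' @return invisibly, the two paths.
#' @export
write_expression_table <- function(embryos, path, metadata_path) {
  if (inherits(embryos, "cohort")) embryos <- embryos$embryos
  stopifnot(length(embryos) > 0)
  gene_ids <- rownames(embryos[[1]]$expr)
  cols <- list(gene_id = gene_ids)
  meta <- list()
  for (e in embryos) {
    stopifnot(identical(rownames(e$expr), gene_ids))
    n <- ncol(e$expr)
    labs <- sprintf("%s_slice%02d", e$embryo_id, seq_len(n))
    for (j in seq_len(n)) cols[[labs[j]]] <- signif(e$expr[, j], 6)
    meta[[length(meta) + 1L]] <- data.frame(
      embryo_id = e$embryo_id, genotype = e$genotype,
      timepoint = e$timepoint, n_slices = n,
      qc_failed = paste(which(!e$qc_mask), collapse = ","),
      stringsAsFactors = FALSE)
  }
  data.table::fwrite(cols, path, sep = "\t", quote = FALSE)
  data.table::fwrite(do.call(rbind, meta), metadata_path, sep = "\t",
                     quote = FALSE)
  invisible(c(path, metadata_path))
}

#' Read an expression table and its embryo metadata
#'
#' Inverse of [write_expression_table()]; round-trips matrices to within
#' float-formatting precision (6 significant digits).  Column labels must
#' follow the `EMBRYOID_sliceNN` dialect with dense 1-based slice numbering
#' per embryo; values must be finite and non-negative.
#'
#' @param path expression TSV path.
#' @param metadata_path metadata TSV path.
#' @return A list of class `expression_table`: `gene_ids`, `embryos`
#'   (named list of `embryo_sample` objects with QC masks populated from
#'   the metadata).
#' @export
read_expression_table <- function(path, metadata_path) {
  dt <- tryCatch(
    data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE),
    error = function(e) stop("malformed expression table '", path, "': ",
                             conditionMessage(e)))
  if (colnames(dt)[1] != "gene_id") {
    stop("expression table must start with a 'gene_id' column")
  }
  gene_ids <- as.character(dt[[1]])
  labs <- colnames(dt)[-1]
  m <- regmatches(labs, regexec("^(.*)_slice([0-9]+)$", labs))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop("column label(s) not in EMBRYOID_sliceNN form: ",
         paste(labs[bad], collapse = ", "))
  }
  emb_of <- vapply(m, `[[`, character(1), 2)
  slice_of <- as.integer(vapply(m, `[[`, character(1), 3))
  vals <- as.matrix(dt[, -1, drop = FALSE])
  if (any(!is.finite(vals))) stop("non-finite expression values in ", path)
  if (any(vals < 0)) stop("negative expression values in ", path)

  meta <- read.delim(metadata_path, stringsAsFactors = FALSE,
                     colClasses = "character")
  need <- c("embryo_id", "genotype", "timepoint", "n_slices", "qc_failed")
  if (!all(need %in% colnames(meta))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  }
  if (!setequal(unique(emb_of), meta$embryo_id)) {
    stop("embryo ids in metadata and expression table do not match: ",
         paste(setdiff(union(emb_of, meta$embryo_id),
                       intersect(emb_of, meta$embryo_id)), collapse = ", "))
  }

  embryos <- list()
  for (i in seq_len(nrow(meta))) {
    id <- meta$embryo_id[i]
    sel <- which(emb_of == id)
    if (!identical(slice_of[sel], seq_along(sel))) {
      stop("slice numbering for embryo '", id,
           "' is not dense 1..N in order")
    }
    expr <- vals[, sel, drop = FALSE]
    rownames(expr) <- gene_ids
    colnames(expr) <- NULL
    qc <- rep(TRUE, length(sel))
    if (nzchar(meta$qc_failed[i])) {
      failed <- as.integer(strsplit(meta$qc_failed[i], ",")[[1]])
      if (any(failed < 1 | failed > length(sel))) {
        stop("QC-failed slice index out of range for embryo '", id, "'")
      }
      qc[failed] <- FALSE
    }
    embryos[[id]] <- structure(
      list(embryo_id = id, genotype = meta$genotype[i],
           timepoint = meta$timepoint[i], expr = expr, qc_mask = qc),
      class = "embryo_sample")
  }
  structure(list(gene_ids = gene_ids, embryos = embryos),
            class = "expression_table")
}

#' Read ChIP peaks from a BED file
#'
#' Minimal 4+ column BED reader: `chrom start end name [score]`, 0-based
#' half-open coordinates preserved as given.  Column 4 is interpreted as
#' the TF name.  Comment (`#`), `track` and `browser` lines are skipped.
#'
#' @param path BED file path.
#' @return A data.frame of class `peak_set` with columns `chrom`, `start`,
#'   `end`, `tf`, `score`.
#' @export
read_peaks <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  if (!any(keep)) {
    return(structure(data.frame(chrom = character(), start = integer(),
                                end = integer(), tf = character(),
                                score = numeric()),
                     class = c("peak_set", "data.frame")))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- vapply(fields, length, integer(1))
  if (any(nf < 4L)) {
    stop("BED line ", which(keep)[which(nf < 4L)[1]],
         ": need at least 4 columns (chrom, start, end, name)")
  }
  out <- data.frame(
    chrom = vapply(fields, `[[`, character(1), 1),
    start = as.integer(vapply(fields, `[[`, character(1), 2)),
    end = as.integer(vapply(fields, `[[`, character(1), 3)),
    tf = vapply(fields, `[[`, character(1), 4),
    score = vapply(fields, function(f) {
      if (length(f) >= 5) suppressWarnings(as.numeric(f[5])) else NA_real_
    }, numeric(1)),
    stringsAsFactors = FALSE)
  bad <- which(!(out$start < out$end))
  if (length(bad)) {
    stop("BED line ", which(keep)[bad[1]], ": start >= end (",
         out$start[bad[1]], " >= ", out$end[bad[1]], ")")
  }
  if (any(!nzchar(out$tf))) stop("empty name field in BED file ", path)
  structure(out, class = c("peak_set", "data.frame"))
}

#' Read enhancer intervals from BED and compute their centers
#'
#' Enhancer (CRM) center = `floor((start + end) / 2)` in 0-based
#' coordinates.
#'
#' @param path BED file path (column 4 = enhancer name).
#' @return A `peak_set` data.frame with an additional `center` column.
#' @export
read_enhancers <- function(path) {
  p <- read_peaks(path)
  p$center <- floor((p$start + p$end) / 2)
  p
}

#' Read a transcription start site table
#'
#' TSV with header columns `gene_id`, `chrom`, `position` (1-based TSS
#' coordinate), `strand` (`+`/`-`); one primary TSS per gene.
#'
#' @param path TSV path.
#' @return A data.frame of class `tss_table`.
#' @export
read_tss <- function(path) {
  tss <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "position", "strand")
  miss <- setdiff(need, colnames(tss))
  if (length(miss)) {
    stop("TSS table is missing column(s): ", paste(miss, collapse = ", "))
  }
  dup <- unique(tss$gene_id[duplicated(tss$gene_id)])
  if (length(dup)) {
    stop("duplicate gene_id in TSS table: ", paste(dup, collapse = ", "))
  }
  if (!all(tss$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  tss$position <- as.integer(tss$position)
  structure(tss[, need], class = c("tss_table", "data.frame"))
}

#' Write a peak set as BED
#' @param peaks a `peak_set` data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_peaks <- function(peaks, path) {
  df <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$tf,
                   ifelse(is.na(peaks$score), 0, peaks$score))
  data.table::fwrite(df, path, sep = "\t", quote = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a TSS table as TSV
#' @param tss a `tss_table` data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_tss <- function(tss, path) {
  data.table::fwrite(tss, path, sep = "\t", quote = FALSE)
  invisible(path)
}
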