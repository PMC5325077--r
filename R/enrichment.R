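# Pearson chi-squared (1 df, no continuity correction) on a 2x2 table
# given as counts; returns c(chi2, p).  Degenerate margins give chi2 = 0.
.chi2_2x2 <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  if (denom == 0) return(c(chi2 = 0, p = 1))
  chi2 <- n * (a * d - b * c)^2 / denom
  c(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

# odds ratio with Haldane-Anscombe 0.5 correction only when a zero cell
# occurs; second element reports whether the correction was applied
.odds_ratio <- function(a, b, c, d) {
  zero <- any(c(a, b, c, d) == 0)
  if (zero) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  list(or = (a * d) / (b * c), corrected = zero)
}

#' Assign ChIP peaks to genes by TSS proximity
#'
#' A gene is called bound by a TF iff at least one of that TF's peaks
#' overlaps the window `[TSS - window, TSS + window]` (any-overlap rule,
#' strand-agnostic).  Peaks on chromosomes absent from the TSS table are
#' skipped with a warning.  The bound set grows monotonically with
#' `window`.
#'
#' @param peaks a `peak_set` (see [read_peaks()]), 0-based half-open.
#' @param tss a `tss_table` (see [read_tss()]), 1-based TSS positions.
#' @param window half-width of the window around the TSS, bp.
#' @param tfs TF panel defining the matrix columns; defaults to the TFs
#'   present in `peaks`.
#' @return logical genes x TFs matrix (`binding_matrix`).
#' @export
assign_peaks_to_genes <- function(peaks, tss, window = 10000,
                                  tfs = NULL) {
  if (is.null(tfs)) tfs <- sort(unique(peaks$tf))
  bm <- matrix(FALSE, nrow(tss), length(tfs),
               dimnames = list(tss$gene_id, tfs))
  unknown <- setdiff(unique(peaks$chrom), unique(tss$chrom))
  if (length(unknown)) {
    warning("skipping peaks on chromosome(s) absent from the TSS table: ",
            paste(unknown, collapse = ", "))
    peaks <- peaks[!peaks$chrom %in% unknown, , drop = FALSE]
  }
  if (nrow(peaks) == 0) return(bm)
  # 1-based closed coordinates for both intervals
  win <- GenomicRanges::GRanges(
    tss$chrom,
    IRanges::IRanges(pmax(tss$position - window, 1), tss$position + window))
  pk <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$start + 1L, peaks$end))
  hits <- GenomicRanges::findOverlaps(win, pk)
  if (length(hits)) {
    gi <- S4Vectors::queryHits(hits)
    ti <- match(peaks$tf[S4Vectors::subjectHits(hits)], tfs)
    ok <- !is.na(ti)
    bm[cbind(gi[ok], ti[ok])] <- TRUE
  }
  bm
}

#' Map enhancers to their nearest gene within a window of the center
#'
#' For each enhancer the TSS closest (in either direction) to the enhancer
#' center is reported, provided it lies within `window` bp; exact distance
#' ties report all tied genes.
#'
#' @param enhancers a `peak_set` with a `center` column (see
#'   [read_enhancers()]).
#' @param tss a `tss_table`.
#' @param window maximum center-to-TSS distance, bp.
#' @return data.frame with one row per (enhancer, assigned gene):
#'   `enhancer`, `chrom`, `center`, `gene_id` (NA if no TSS within the
#'   window), `distance`.
#' @export
nearest_gene_for_enhancer <- function(enhancers, tss, window = 10000) {
  if (nrow(tss) == 0) stop("empty TSS table")
  out <- list()
  for (i in seq_len(nrow(enhancers))) {
    center_1b <- enhancers$center[i] + 1L  # 0-based center -> 1-based
    cand <- tss[tss$chrom == enhancers$chrom[i], , drop = FALSE]
    d <- abs(cand$position - center_1b)
    sel <- which(d == min(d) & d <= window)
    if (nrow(cand) == 0 || length(sel) == 0) {
      out[[i]] <- data.frame(enhancer = enhancers$tf[i],
                             chrom = enhancers$chrom[i],
                             center = enhancers$center[i],
                             gene_id = NA_character_,
                             distance = NA_integer_,
                             stringsAsFactors = FALSE)
    } else {
      out[[i]] <- data.frame(enhancer = enhancers$tf[i],
                             chrom = enhancers$chrom[i],
                             center = enhancers$center[i],
                             gene_id = cand$gene_id[sel],
                             distance = d[sel],
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# shared core: per-TF 2x2 chi-squared of binding in set A vs set B
.tf_2x2_tests <- function(genes_a, genes_b, binding, base_universe, alpha) {
  tfs <- colnames(binding)
  res <- lapply(tfs, function(tf) {
    ba <- binding[genes_a, tf]
    bb <- binding[genes_b, tf]
    a <- sum(ba); b <- sum(!ba); c <- sum(bb); d <- sum(!bb)
    ct <- .chi2_2x2(a, b, c, d)
    or <- .odds_ratio(a, b, c, d)
    data.frame(tf = tf, odds_ratio = or$or,
               or_corrected = or$corrected,
               base_frequency = mean(binding[base_universe, tf]),
               chi2 = unname(ct["chi2"]), p = unname(ct["p"]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_bonferroni <- pmin(res$p * length(tfs), 1)
  res$significant_after_bonferroni <- res$p_bonferroni < alpha
  res
}

#' TF-binding enrichment in a gene category versus background
#'
#' For each TF, a Pearson chi-squared test (no continuity correction) of
#' the 2x2 table binding x (category vs background), Bonferroni-corrected
#' over the TF panel.  `base_frequency` is the binding rate over the whole
#' universe (category plus background).
#'
#' @param category_genes gene ids in the category (e.g. one pattern-change
#'   class); non-empty.
#' @param background_genes expressed genes not in the category.
#' @param binding logical genes x TFs matrix.
#' @param alpha family-wise significance level.
#' @return data.frame: `tf`, `odds_ratio`, `or_corrected` (TRUE when the
#'   Haldane-Anscombe 0.5 correction was applied), `base_frequency`,
#'   `chi2`, `p`, `p_bonferroni`, `significant_after_bonferroni`.
#' @export
tf_enrichment_by_category <- function(category_genes, background_genes,
                                      binding, alpha = 0.05) {
  if (length(category_genes) == 0) stop("empty gene category")
  stopifnot(all(category_genes %in% rownames(binding)),
            all(background_genes %in% rownames(binding)))
  .tf_2x2_tests(category_genes, background_genes, binding,
                base_universe = union(category_genes, background_genes),
                alpha = alpha)
}

#' TF-binding enrichment among top delta-D genes
#'
#' Compares the `top_n` genes by delta-D with a control set of the
#' `control_n` genes whose delta-D lies closest to the median of the
#' eligible universe (genes flagged as changing in both mutants), per TF,
#' with Pearson chi-squared and Bonferroni correction.  `base_frequency`
#' is the binding rate over all expressed genes.
#'
#' @param delta_d_values named numeric vector of delta-D, restricted to
#'   genes changing in both mutants.
#' @param binding logical genes x TFs matrix.
#' @param top_n,control_n sizes of the test and control sets.
#' @param expressed_genes universe for `base_frequency`; defaults to all
#'   rows of `binding`.
#' @param alpha family-wise significance level.
#' @return data.frame as in [tf_enrichment_by_category()].
#' @export
delta_d_enrichment <- function(delta_d_values, binding, top_n = 50,
                               control_n = 200, expressed_genes = NULL,
                               alpha = 0.05) {
  delta_d_values <- delta_d_values[!is.na(delta_d_values)]
  if (length(delta_d_values) < top_n + control_n) {
    stop("need at least ", top_n + control_n, " eligible genes, have ",
         length(delta_d_values))
  }
  if (is.null(expressed_genes)) expressed_genes <- rownames(binding)
  top <- top_changed_genes(delta_d_values, top_n)
  med <- median(delta_d_values)
  rest <- delta_d_values[setdiff(names(delta_d_values), top)]
  ord <- order(abs(rest - med), names(rest))
  control <- names(rest)[ord][seq_len(control_n)]
  .tf_2x2_tests(top, control, binding, base_universe = expressed_genes,
                alpha = alpha)
}

#' Combinatorial binding as a function of delta-D rank
#'
#' Genes are sorted by delta-D and grouped into non-overlapping windows of
#' `window` consecutive genes (remainder dropped).  For each threshold `k`
#' the fraction of genes in each window bound by at least `k` of the TFs
#' is computed, and an ordinary least-squares line is fitted to
#' (window mean delta-D, fraction).
#'
#' @param delta_d_values named numeric vector of delta-D.
#' @param binding logical genes x TFs matrix.
#' @param window genes per window.
#' @param k_values thresholds on the number of bound TFs.
#' @return list with `windows` (data.frame: `window`, `mean_delta_d`, one
#'   `frac_ge_k` column per k) and `fits` (data.frame: `k`, `slope`,
#'   `intercept`).
#' @export
combinatorial_binding_curve <- function(delta_d_values, binding,
                                        window = 50, k_values = 3:9) {
  delta_d_values <- delta_d_values[!is.na(delta_d_values)]
  if (window > length(delta_d_values)) {
    stop("window (", window, ") exceeds gene count (",
         length(delta_d_values), ")")
  }
  n_win <- length(delta_d_values) %/% window
  if (n_win < 2) stop("need at least 2 windows of ", window, " genes")
  ord <- order(delta_d_values, names(delta_d_values))
  genes <- names(delta_d_values)[ord][seq_len(n_win * window)]
  dd <- delta_d_values[genes]
  n_bound <- rowSums(binding[genes, , drop = FALSE])
  win_of <- rep(seq_len(n_win), each = window)
  wins <- data.frame(window = seq_len(n_win),
                     mean_delta_d = as.numeric(tapply(dd, win_of, mean)))
  fits <- list()
  for (k in k_values) {
    frac <- as.numeric(tapply(n_bound >= k, win_of, mean))
    wins[[sprintf("frac_ge_%d", k)]] <- frac
    fit <- lm(frac ~ wins$mean_delta_d)
    fits[[length(fits) + 1L]] <- data.frame(
      k = k, slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]))
  }
  list(windows = wins, fits = do.call(rbind, fits))
}

#' Test binding-signature groups for atypical pattern-change distributions
#'
#' Groups genes by their exact binary TF-binding signature; every group
#' with at least `min_group` genes is compared to the distribution over
#' all expressed genes with a two-sample Kolmogorov-Smirnov test on the
#' summed EMD scores, Bonferroni-corrected over the tested groups.
#'
#' @param binding logical genes x TFs matrix over the expressed universe.
#' @param summed_emd named numeric vector (e.g. summed EMD to wild type
#'   over several mutants) for the same genes.
#' @param min_group minimum group size to test.
#' @param alpha family-wise significance level.
#' @return data.frame: `signature` (e.g. `"bcd+cad"` or `"(none)"`), `n`,
#'   `ks_d`, `p`, `p_bonferroni`, `significant_after_bonferroni`.  Empty
#'   (with a warning) if no group reaches `min_group`.
#' @export
binding_group_tests <- function(binding, summed_emd, min_group = 30,
                                alpha = 0.05) {
  genes <- intersect(rownames(binding), names(summed_emd))
  genes <- genes[!is.na(summed_emd[genes])]
  bm <- binding[genes, , drop = FALSE]
  sig <- apply(bm, 1, function(r) {
    if (!any(r)) "(none)" else paste(colnames(bm)[r], collapse = "+")
  })
  counts <- table(sig)
  test_sigs <- names(counts)[counts >= min_group]
  if (length(test_sigs) == 0) {
    warning("no binding signature reaches min_group = ", min_group)
    return(data.frame(signature = character(), n = integer(),
                      ks_d = numeric(), p = numeric(),
                      p_bonferroni = numeric(),
                      significant_after_bonferroni = logical()))
  }
  all_scores <- summed_emd[genes]
  res <- lapply(test_sigs, function(s) {
    grp <- all_scores[sig == s]
    kt <- suppressWarnings(ks.test(grp, all_scores))
    data.frame(signature = s, n = length(grp),
               ks_d = unname(kt$statistic), p = kt$p.value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_bonferroni <- pmin(res$p * nrow(res), 1)
  res$significant_after_bonferroni <- res$p_bonferroni < alpha
  res <- res[order(res$p, res$signature), ]
  rownames(res) <- NULL
  res
}
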