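PATTERN_CLASSES <- c("low_expression", "uniform", "ambiguous", "patterned")

# one gene's imputed slice values in one embryo
.gene_values <- function(embryo, gene) {
  if (!gene %in% rownames(embryo$expr)) {
    stop("gene '", gene, "' not present in embryo '", embryo$embryo_id, "'")
  }
  p <- slice_profile(gene, embryo$embryo_id, embryo$expr[gene, ],
                     qc_mask = embryo$qc_mask)
  impute_bad_slices(p)$values
}

# imputed expression matrix of a whole embryo (genes x slices)
.imputed_expr <- function(embryo) {
  expr <- embryo$expr
  ok <- embryo$qc_mask
  if (all(ok)) return(expr)
  if (!any(ok)) stop("all slices failed QC in embryo ", embryo$embryo_id)
  idx_ok <- which(ok)
  for (i in which(!ok)) {
    left <- idx_ok[idx_ok < i]
    right <- idx_ok[idx_ok > i]
    expr[, i] <- if (length(left) && length(right)) {
      (expr[, max(left)] + expr[, min(right)]) / 2
    } else if (length(left)) expr[, max(left)] else expr[, min(right)]
  }
  expr
}

#' Classify expression patterns of all genes in one genotype
#'
#' A gene is `low_expression` if it never reaches `expressed_fpkm` (default
#' 15 FPKM) in any slice of any replicate embryo.  Otherwise its EMD to a
#' uniform distribution is computed per embryo (on QC-imputed profiles) and
#' averaged across replicates: `uniform` below `uniform_emd` (default
#' 0.04), `patterned` above `patterned_emd` (default 0.08), `ambiguous` in
#' between.
#'
#' @param embryos list of `embryo_sample` replicates of one genotype at one
#'   stage.
#' @param expressed_fpkm,uniform_emd,patterned_emd thresholds.
#' @return data.frame with columns `gene_id`, `label`, `emd_to_uniform`
#'   (NA for low-expression genes), `max_fpkm`.
#' @export
classify_patterns <- function(embryos, expressed_fpkm = 15,
                              uniform_emd = 0.04, patterned_emd = 0.08) {
  stopifnot(length(embryos) >= 1)
  genes <- rownames(embryos[[1]]$expr)
  mats <- lapply(embryos, .imputed_expr)
  max_fpkm <- do.call(pmax, lapply(mats, function(m) {
    apply(m, 1, max)
  }))
  emds <- vapply(mats, function(m) {
    n <- ncol(m)
    vapply(seq_len(nrow(m)), function(i) {
      if (sum(m[i, ]) == 0) NA_real_ else emd_to_uniform(m[i, ])
    }, numeric(1))
  }, numeric(length(genes)))
  mean_emd <- rowMeans(as.matrix(emds), na.rm = TRUE)
  mean_emd[is.nan(mean_emd)] <- NA_real_
  label <- ifelse(max_fpkm < expressed_fpkm, "low_expression",
           ifelse(is.na(mean_emd), "low_expression",
           ifelse(mean_emd < uniform_emd, "uniform",
           ifelse(mean_emd > patterned_emd, "patterned", "ambiguous"))))
  data.frame(gene_id = genes, label = label,
             emd_to_uniform = ifelse(label == "low_expression", NA_real_,
                                     mean_emd),
             max_fpkm = max_fpkm, stringsAsFactors = FALSE)
}

#' Classify one gene's pattern
#'
#' Single-gene convenience wrapper around [classify_patterns()].
#'
#' @param gene gene id.
#' @param embryos replicate embryos of one genotype.
#' @param ... thresholds passed on.
#' @return one-row data.frame as in [classify_patterns()].
#' @export
classify_pattern <- function(gene, embryos, ...) {
  if (length(embryos) == 0) stop("no embryos supplied")
  cls <- classify_patterns(embryos, ...)
  row <- cls[cls$gene_id == gene, , drop = FALSE]
  if (nrow(row) == 0) stop("gene '", gene, "' not found")
  row
}

TRANSITIONS <- c("low_expression_to_patterned", "patterned_to_uniform",
                 "patterned_to_low_expression", "uniform_to_patterned")

#' Tabulate pattern-class transitions between wild type and a mutant
#'
#' Counts the four canonical transitions (low-expression to patterned,
#' patterned to uniform, patterned to low-expression, uniform to
#' patterned).  Genes that are `ambiguous` in either genotype are excluded;
#' everything else (unchanged, or other combinations) lands in the
#' `remainder` cell.  The universe is restricted to genes expressed (not
#' `low_expression`) in at least one of the two genotypes.
#'
#' @param wt_classes,mut_classes data.frames from [classify_patterns()] (or
#'   named character vectors of labels) over the same gene universe.
#' @return A named integer vector: the four transitions, `remainder`, and
#'   `total`.
#' @export
transition_table <- function(wt_classes, mut_classes) {
  as_labels <- function(x) {
    if (is.data.frame(x)) setNames(x$label, x$gene_id) else x
  }
  wt <- as_labels(wt_classes)
  mut <- as_labels(mut_classes)
  if (!setequal(names(wt), names(mut))) {
    stop("wild-type and mutant class vectors cover different gene sets")
  }
  mut <- mut[names(wt)]
  keep <- (wt != "low_expression" | mut != "low_expression") &
    wt != "ambiguous" & mut != "ambiguous"
  wt <- wt[keep]; mut <- mut[keep]
  key <- paste(wt, mut, sep = "_to_")
  counts <- setNames(integer(length(TRANSITIONS)), TRANSITIONS)
  for (tr in TRANSITIONS) counts[tr] <- sum(key == tr)
  c(counts, remainder = sum(!key %in% TRANSITIONS), total = length(key))
}

# unit-mass distribution of a gene in an embryo, or NULL if all-zero
.gene_distribution <- function(embryo, gene) {
  v <- .gene_values(embryo, gene)
  d <- to_distribution(v)
  if (d$all_zero) NULL else d
}

#' Pattern change of one gene between two genotypes
#'
#' Mean EMD over all cross pairs (each replicate of genotype A against each
#' replicate of genotype B).  With `aggregate = "min"` or `"median"` the
#' cross-pair EMDs are combined differently.  Returns `NA` when the gene is
#' below the expression floor in both genotypes (such genes are excluded
#' from change distributions), or when no valid replicate pair exists.
#'
#' @param gene gene id.
#' @param embryos_a,embryos_b replicate embryos of the two genotypes at the
#'   same stage.
#' @param expressed_fpkm expression floor (default 15 FPKM).
#' @param aggregate how to combine cross-pair EMDs: `"mean"` (default),
#'   `"min"`, or `"median"`.
#' @return numeric EMD, or `NA`.
#' @export
pattern_change <- function(gene, embryos_a, embryos_b, expressed_fpkm = 15,
                           aggregate = c("mean", "min", "median")) {
  aggregate <- match.arg(aggregate)
  va <- lapply(embryos_a, .gene_values, gene = gene)
  vb <- lapply(embryos_b, .gene_values, gene = gene)
  if (max(vapply(c(va, vb), max, numeric(1))) < expressed_fpkm) {
    return(NA_real_)
  }
  da <- lapply(va, function(v) { d <- to_distribution(v)
                                 if (d$all_zero) NULL else d })
  db <- lapply(vb, function(v) { d <- to_distribution(v)
                                 if (d$all_zero) NULL else d })
  da <- Filter(Negate(is.null), da)
  db <- Filter(Negate(is.null), db)
  if (length(da) == 0 || length(db) == 0) return(NA_real_)
  vals <- unlist(lapply(da, function(a) {
    vapply(db, function(b) emd(a, b), numeric(1))
  }))
  switch(aggregate, mean = mean(vals), min = min(vals),
         median = median(vals))
}

#' Pattern change of every gene between two genotypes
#'
#' Vectorized form of [pattern_change()]: the replicate-cross-pair mean
#' EMD for every gene shared by the two embryo sets.  Genes below the
#' expression floor in both genotypes (or with no valid replicate pair)
#' get `NA`.
#'
#' @inheritParams pattern_change
#' @return named numeric vector over all genes.
#' @export
pattern_change_table <- function(embryos_a, embryos_b,
                                 expressed_fpkm = 15,
                                 aggregate = c("mean", "min", "median")) {
  aggregate <- match.arg(aggregate)
  genes <- rownames(embryos_a[[1]]$expr)
  prep <- function(e) {
    m <- .imputed_expr(e)[genes, , drop = FALSE]
    n <- ncol(m)
    tot <- rowSums(m)
    list(pos = (seq_len(n) - 0.5) / n, mass = m / ifelse(tot > 0, tot, 1),
         tot = tot, max = apply(m, 1, max))
  }
  pa <- lapply(embryos_a, prep)
  pb <- lapply(embryos_b, prep)
  max_all <- do.call(pmax, c(lapply(pa, `[[`, "max"),
                             lapply(pb, `[[`, "max")))
  agg_fun <- switch(aggregate, mean = mean, min = min, median = median)
  out <- setNames(rep(NA_real_, length(genes)), genes)
  for (g in seq_along(genes)) {
    if (max_all[g] < expressed_fpkm) next
    vals <- c()
    for (a in pa) {
      if (a$tot[g] == 0) next
      for (b in pb) {
        if (b$tot[g] == 0) next
        vals <- c(vals, .emd_vec(a$pos, a$mass[g, ], b$pos, b$mass[g, ]))
      }
    }
    if (length(vals)) out[g] <- agg_fun(vals)
  }
  out
}

#' Differential-response statistic delta-D for one gene
#'
#' Quantifies whether two mutants perturb a gene's pattern in *different*
#' ways, rather than both moving it away from wild type similarly:
#' \deqn{\Delta D = EMD(M1, M2) - |EMD(M1, WT) - EMD(M2, WT)|}
#' where each EMD is the replicate-averaged [pattern_change()].  Because
#' EMD is a metric, the reverse triangle inequality gives
#' \eqn{0 \le \Delta D \le EMD(M1, M2)}: a gene that responds identically
#' to both mutants (M1 = M2) scores 0, as does a gene unperturbed in one
#' mutant (M1 = WT).
#'
#' @param gene gene id.
#' @param wt_embryos,m1_embryos,m2_embryos replicate embryos of the three
#'   genotypes at the same stage.
#' @param expressed_fpkm expression floor.
#' @return A one-row data.frame: `gene_id`, `d_m1_m2`, `d_m1_wt`,
#'   `d_m2_wt`, `delta_d` (all `NA` if the gene fails the expression filter
#'   in any pairing).
#' @export
delta_d <- function(gene, wt_embryos, m1_embryos, m2_embryos,
                    expressed_fpkm = 15) {
  if (length(wt_embryos) == 0 || length(m1_embryos) == 0 ||
      length(m2_embryos) == 0) {
    stop("all three genotypes need at least one embryo")
  }
  d12 <- pattern_change(gene, m1_embryos, m2_embryos, expressed_fpkm)
  d1w <- pattern_change(gene, m1_embryos, wt_embryos, expressed_fpkm)
  d2w <- pattern_change(gene, m2_embryos, wt_embryos, expressed_fpkm)
  dd <- if (anyNA(c(d12, d1w, d2w))) NA_real_ else d12 - abs(d1w - d2w)
  data.frame(gene_id = gene, d_m1_m2 = d12, d_m1_wt = d1w, d_m2_wt = d2w,
             delta_d = dd, stringsAsFactors = FALSE)
}

#' Delta-D records for every gene
#'
#' Vectorized form of [delta_d()] over all genes shared by the three
#' embryo sets.
#'
#' @inheritParams delta_d
#' @return data.frame with columns `gene_id`, `d_m1_m2`, `d_m1_wt`,
#'   `d_m2_wt`, `delta_d`.
#' @export
delta_d_table <- function(wt_embryos, m1_embryos, m2_embryos,
                          expressed_fpkm = 15) {
  if (length(wt_embryos) == 0 || length(m1_embryos) == 0 ||
      length(m2_embryos) == 0) {
    stop("all three genotypes need at least one embryo")
  }
  d12 <- pattern_change_table(m1_embryos, m2_embryos, expressed_fpkm)
  d1w <- pattern_change_table(m1_embryos, wt_embryos, expressed_fpkm)
  d2w <- pattern_change_table(m2_embryos, wt_embryos, expressed_fpkm)
  dd <- d12 - abs(d1w - d2w)
  data.frame(gene_id = names(d12), d_m1_m2 = unname(d12),
             d_m1_wt = unname(d1w), d_m2_wt = unname(d2w),
             delta_d = unname(dd), stringsAsFactors = FALSE)
}

#' Flag genes in the top tail of a change distribution
#'
#' A gene is flagged when its distance is at least the `k`-th largest
#' value, `k = floor(n * (1 - quantile))` — i.e. the top 20% by default,
#' inclusive of ties at the boundary value.  If all distances are equal no
#' gene is flagged (with a warning).
#'
#' @param distances named numeric vector (NA values are never flagged).
#' @param quantile quantile defining the tail (default 0.80 = top 20%).
#' @return named logical vector aligned with `distances`.
#' @export
change_flags <- function(distances, quantile = 0.80) {
  ok <- !is.na(distances)
  if (sum(ok) < 5) stop("need at least 5 genes with distances")
  x <- distances[ok]
  flags <- setNames(rep(FALSE, length(distances)), names(distances))
  if (max(x) == min(x)) {
    warning("all distances equal; no genes flagged")
    return(flags)
  }
  k <- floor(sum(ok) * (1 - quantile) + 1e-9)
  cutoff <- sort(x, decreasing = TRUE)[k]
  flags[ok] <- x >= cutoff
  flags
}

#' Test independence of change between two genotypes
#'
#' Pearson chi-squared test (1 df, no continuity correction) on the 2x2
#' table of change flags, plus the observed/expected ratio for the
#' both-changed cell; ratios above 1 mean genes tend to change in both
#' mutants together.
#'
#' @param flags_a,flags_b logical vectors over the same gene universe.
#' @return list with `chi2`, `p`, `ratio`, `table`.
#' @export
co_change_test <- function(flags_a, flags_b) {
  stopifnot(length(flags_a) == length(flags_b))
  keep <- !is.na(flags_a) & !is.na(flags_b)
  a <- flags_a[keep]; b <- flags_b[keep]
  tab <- table(factor(a, c(FALSE, TRUE)), factor(b, c(FALSE, TRUE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate 2x2 table: a margin is zero")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    warning("expected cell count below 5; chi-squared approximation weak")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  n <- sum(tab)
  ratio <- tab["TRUE", "TRUE"] / (n * mean(a) * mean(b))
  list(chi2 = unname(ct$statistic), p = ct$p.value, ratio = unname(ratio),
       table = tab)
}

#' Top changed genes
#'
#' Genes ordered by descending distance, ties broken lexicographically by
#' gene id for reproducibility.
#'
#' @param distances named numeric vector.
#' @param n number of genes to return.
#' @return character vector of `n` gene ids.
#' @export
top_changed_genes <- function(distances, n = 100) {
  distances <- distances[!is.na(distances)]
  if (n > length(distances)) {
    stop("asked for ", n, " genes but only ", length(distances),
         " have distances")
  }
  ord <- order(-distances, names(distances))
  names(distances)[ord][seq_len(n)]
}

#' Average max-normalized pattern of a gene set in one embryo
#'
#' Slice-wise mean of the max-normalized, QC-imputed profiles; used to
#' visualize what the most-changed genes do on average in each genotype.
#'
#' @param genes character vector of gene ids (non-empty).
#' @param embryo an `embryo_sample`.
#' @param floor FPKM normalization floor (see [max_normalize()]).
#' @return numeric vector, one value in `[0, 1]` per slice.
#' @export
average_pattern <- function(genes, embryo, floor = 10) {
  if (length(genes) == 0) stop("empty gene list")
  m <- .imputed_expr(embryo)[genes, , drop = FALSE]
  norm <- t(apply(m, 1, max_normalize, floor = floor))
  colMeans(norm)
}

#' Hierarchically cluster genes by their spatial patterns
#'
#' Gene-gene distance is the mean EMD between the two genes' unit-mass
#' profiles over all embryos in which both genes are expressed (reach
#' `expressed_fpkm` in some slice); pairs sharing no embryo get the
#' maximal distance 1.  Agglomeration uses average linkage.  Genes are
#' sorted by id before clustering, so the merges are invariant to input
#' order.
#'
#' @param embryos list of `embryo_sample` objects.
#' @param genes gene ids to cluster (>= 2).
#' @param expressed_fpkm expression floor per embryo.
#' @return list with `hclust` (the tree), `order` (leaf gene ids), and
#'   `dist` (the distance matrix as a `dist`).
#' @export
cluster_genes <- function(embryos, genes, expressed_fpkm = 15) {
  genes <- sort(unique(genes))
  if (length(genes) < 2) stop("need at least 2 genes to cluster")
  ng <- length(genes)
  sum_d <- matrix(0, ng, ng)
  cnt <- matrix(0L, ng, ng)
  for (e in embryos) {
    m <- .imputed_expr(e)[genes, , drop = FALSE]
    expressed <- apply(m, 1, max) >= expressed_fpkm
    tot <- rowSums(m)
    use <- expressed & tot > 0
    if (sum(use) < 2) next
    n <- ncol(m)
    cdf <- t(apply(m[use, , drop = FALSE] / tot[use], 1, cumsum))
    # EMD between genes sharing slice positions = scaled L1 on CDFs
    d_e <- as.matrix(stats::dist(cdf[, -n, drop = FALSE],
                                 method = "manhattan")) / n
    idx <- which(use)
    sum_d[idx, idx] <- sum_d[idx, idx] + d_e
    cnt[idx, idx] <- cnt[idx, idx] + 1L
  }
  mean_d <- ifelse(cnt > 0, sum_d / pmax(cnt, 1L), 1)
  diag(mean_d) <- 0
  rownames(mean_d) <- colnames(mean_d) <- genes
  d <- as.dist(mean_d)
  hc <- hclust(d, method = "average")
  list(hclust = hc, order = genes[hc$order], dist = d)
}

#' Count coherent level responses to opposite dosage perturbations
#'
#' Among (typically uniformly expressed) genes, counts those whose
#' embryo-wide mean expression rises at least `fold`-fold relative to wild
#' type in *both* perturbed conditions, and those that drop at least
#' `fold`-fold in both (boundary inclusive).  Such genes appear tuned to
#' the wild-type dose of the factor rather than responding monotonically.
#'
#' @param wt_mean,m1_mean,m2_mean named per-gene mean FPKM vectors over the
#'   same genes.
#' @param fold fold-change threshold (> 1).
#' @return list with counts `n_up`, `n_down` and id vectors `up_genes`,
#'   `down_genes`.
#' @export
level_response <- function(wt_mean, m1_mean, m2_mean, fold = 1.5) {
  if (fold <= 1) stop("fold threshold must exceed 1")
  stopifnot(length(wt_mean) == length(m1_mean),
            length(wt_mean) == length(m2_mean))
  up <- m1_mean >= fold * wt_mean & m2_mean >= fold * wt_mean
  down <- m1_mean <= wt_mean / fold & m2_mean <= wt_mean / fold
  up[is.na(up)] <- FALSE; down[is.na(down)] <- FALSE
  list(n_up = sum(up), n_down = sum(down),
       up_genes = names(wt_mean)[up], down_genes = names(wt_mean)[down])
}
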