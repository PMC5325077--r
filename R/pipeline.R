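PIPELINE_STAGES <- c("simulate", "distances", "classify", "deltad",
                     "enrich", "cluster", "report")

#' Pipeline configuration
#'
#' Collects every numeric convention of the analysis in one place:
#' expression floor (15 FPKM), heatmap normalization floor (10 FPKM),
#' uniform/patterned EMD thresholds (0.04 / 0.08), the top-20% change
#' quantile, the delta-D call-out level, the 1.5-fold level-response
#' threshold, the 10 kb TSS window, and the enrichment design sizes
#' (top 50 vs 200 near-median; binding groups of >= 30; delta-D windows
#' of 50).
#'
#' @param outdir output directory; created if missing.
#' @param expression,metadata,peaks,tss,enhancers input file paths.  When
#'   `NULL` and the `simulate` stage runs, synthetic files are generated
#'   under `outdir`.
#' @param cohort a [cohort_config()] used by the `simulate` stage.
#' @param expressed_fpkm,heatmap_floor_fpkm,uniform_emd,patterned_emd,change_quantile,delta_d_callout,fold,tss_window,top_n,enrich_top_n,enrich_control_n,group_min,fig9_window
#'   analysis thresholds (see Details above).
#' @param cluster_max_genes cap on genes entering hierarchical clustering.
#' @param stage time point used for all comparisons (latest stage by
#'   default).
#' @param roles named list selecting genotypes: `wt`, `m1`, `m2` (the
#'   delta-D pair), and `level_up` / `level_down` (the dosage pair for the
#'   level-response count).
#' @param seed integer seed controlling all pipeline randomness.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir,
                            expression = NULL, metadata = NULL,
                            peaks = NULL, tss = NULL, enhancers = NULL,
                            cohort = cohort_config(),
                            expressed_fpkm = 15, heatmap_floor_fpkm = 10,
                            uniform_emd = 0.04, patterned_emd = 0.08,
                            change_quantile = 0.8, delta_d_callout = 0.2,
                            fold = 1.5, tss_window = 10000,
                            top_n = 100, enrich_top_n = 50,
                            enrich_control_n = 200, group_min = 30,
                            fig9_window = 50, cluster_max_genes = 120,
                            stage = "c14D",
                            roles = list(wt = "wt", m1 = "bcd_minus",
                                         m2 = "zld_minus",
                                         level_up = "bcd_2.4x",
                                         level_down = "bcd_minus"),
                            seed = 1L) {
  stopifnot(expressed_fpkm > 0, heatmap_floor_fpkm > 0, uniform_emd > 0,
            patterned_emd > 0, uniform_emd < patterned_emd,
            change_quantile > 0, change_quantile < 1, fold > 1,
            tss_window > 0, top_n > 0, enrich_top_n > 0,
            enrich_control_n > 0, group_min > 0, fig9_window > 0)
  structure(list(
    outdir = outdir, expression = expression, metadata = metadata,
    peaks = peaks, tss = tss, enhancers = enhancers, cohort = cohort,
    expressed_fpkm = expressed_fpkm,
    heatmap_floor_fpkm = heatmap_floor_fpkm,
    uniform_emd = uniform_emd, patterned_emd = patterned_emd,
    change_quantile = change_quantile, delta_d_callout = delta_d_callout,
    fold = fold, tss_window = tss_window, top_n = top_n,
    enrich_top_n = enrich_top_n, enrich_control_n = enrich_control_n,
    group_min = group_min, fig9_window = fig9_window,
    cluster_max_genes = cluster_max_genes, stage = stage, roles = roles,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$cohort <- unclass(x$cohort)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$cohort <- do.call(cohort_config, x$cohort)
  do.call(pipeline_config, x)
}

.log <- function(...) message("[slicepattern] ", sprintf(...))

.fwrite_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
  path
}

# synthetic genome scaffold: TSS spaced far enough apart that each peak
# can only fall in its own gene's 10 kb window
.synthetic_genome <- function(gene_ids) {
  chroms <- c("chr2L", "chr2R", "chr3L", "chr3R", "chrX")
  n <- length(gene_ids)
  data.frame(
    gene_id = gene_ids,
    chrom = rep(chroms, length.out = n),
    position = 50000L + 25000L * (seq_len(n) - 1L) %/% length(chroms),
    strand = rep(c("+", "-"), length.out = n),
    stringsAsFactors = FALSE)
}

# one BED peak per TRUE cell of a binding matrix, near each gene's TSS
.peaks_from_binding <- function(bm, tss) {
  rows <- which(bm, arr.ind = TRUE)
  if (nrow(rows) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), tf = character(),
                      score = numeric()))
  }
  g <- rownames(bm)[rows[, 1]]
  idx <- match(g, tss$gene_id)
  offset <- round(runif(nrow(rows), -8000, 8000))
  half <- round(runif(nrow(rows), 100, 250))
  center <- tss$position[idx] + offset
  df <- data.frame(chrom = tss$chrom[idx],
                   start = pmax(center - half, 0L),
                   end = center + half,
                   tf = colnames(bm)[rows[, 2]],
                   score = 1000,
                   stringsAsFactors = FALSE)
  df[order(df$chrom, df$start, df$tf), ]
}

#' Run the full sliced-embryo analysis pipeline
#'
#' Orchestrates simulate, distances, classify, delta-D, enrichment,
#' clustering and reporting.  Every stage writes flat TSV outputs under
#' `config$outdir` so each intermediate is diffable; a run manifest
#' records the seed, thresholds and MD5 checksums of all outputs.
#' Re-running with an identical configuration reproduces byte-identical
#' files.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of stages to execute (all by default); later
#'   stages recompute what they need in memory, but input files must
#'   exist if `"simulate"` is not among the stages.
#' @return invisibly, a list with the manifest and the main in-memory
#'   results.
#' @export
run_pipeline <- function(config, stages = PIPELINE_STAGES) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  outputs <- character()
  path_in <- function(name, given) {
    if (!is.null(given)) given else file.path(config$outdir, name)
  }
  expr_path <- path_in("expression.tsv", config$expression)
  meta_path <- path_in("metadata.tsv", config$metadata)
  peaks_path <- path_in("peaks.bed", config$peaks)
  tss_path <- path_in("tss.tsv", config$tss)
  enh_path <- path_in("enhancers.bed", config$enhancers)

  truth <- NULL
  if ("simulate" %in% stages) {
    .log("simulate: generating cohort of %d genes (seed %d)",
         config$cohort$n_genes, config$cohort$seed)
    cohort <- generate_cohort(config$cohort)
    write_expression_table(cohort, expr_path, meta_path)
    truth <- cohort$truth
    .fwrite_tsv(truth, file.path(config$outdir, "truth.tsv"))

    gene_ids <- rownames(cohort$embryos[[1]]$expr)
    tss <- .synthetic_genome(gene_ids)
    roles <- config$roles
    eff <- truth[truth$genotype %in% c(roles$m1, roles$m2), ]
    affected <- gene_ids %in% eff$gene_id[eff$effect != "none"]
    bm_true <- simulate_binding_matrix(gene_ids, affected,
                                       enriched_tf = "bcd")
    peaks <- .peaks_from_binding(bm_true, tss)
    write_tss(structure(tss, class = c("tss_table", "data.frame")),
              tss_path)
    write_peaks(peaks, peaks_path)
    # enhancers: one interval near the TSS of a sample of patterned genes
    wt_truth <- truth[truth$genotype == "wt", ]
    pat <- wt_truth$gene_id[wt_truth$true_class == "patterned"]
    pat <- head(sort(pat), 40)
    idx <- match(pat, tss$gene_id)
    ecenter <- tss$position[idx] + round(runif(length(idx), -5000, 5000))
    enh <- data.frame(chrom = tss$chrom[idx], start = ecenter - 500,
                      end = ecenter + 500,
                      tf = sprintf("CRM_%s", pat), score = 0)
    write_peaks(structure(enh, class = c("peak_set", "data.frame")),
                enh_path)
    outputs <- c(outputs, expr_path, meta_path,
                 file.path(config$outdir, "truth.tsv"),
                 tss_path, peaks_path, enh_path)
  }
  if (all(stages == "simulate")) {
    .log("done: %d output files", length(unique(outputs)))
    return(invisible(list(outputs = sort(unique(outputs)),
                          truth = truth)))
  }
  for (p in c(expr_path, meta_path)) {
    if (!file.exists(p)) stop("required input file missing: ", p)
  }

  tab <- read_expression_table(expr_path, meta_path)
  genotypes <- unique(vapply(tab$embryos, `[[`, character(1), "genotype"))
  stage_embryos <- function(g) {
    Filter(function(e) e$genotype == g && e$timepoint == config$stage,
           tab$embryos)
  }
  roles <- config$roles
  wt_emb <- stage_embryos(roles$wt)
  if (length(wt_emb) == 0) {
    stop("no wild-type embryos at stage ", config$stage)
  }
  mutants <- setdiff(genotypes, roles$wt)

  # ---- distances: per-gene change of every mutant vs wild type --------
  .log("distances: %d mutants vs %s", length(mutants), roles$wt)
  dist_to_wt <- lapply(mutants, function(g) {
    pattern_change_table(stage_embryos(g), wt_emb, config$expressed_fpkm)
  })
  names(dist_to_wt) <- mutants
  if ("distances" %in% stages) {
    long <- do.call(rbind, lapply(mutants, function(g) {
      d <- dist_to_wt[[g]]
      data.frame(gene_id = names(d), genotype = g,
                 emd_to_wt = signif(unname(d), 6))
    }))
    outputs <- c(outputs,
                 .fwrite_tsv(long, file.path(config$outdir,
                                             "distances.tsv")))
  }

  # ---- classify + transitions ----------------------------------------
  classes <- lapply(setNames(genotypes, genotypes), function(g) {
    classify_patterns(stage_embryos(g), config$expressed_fpkm,
                      config$uniform_emd, config$patterned_emd)
  })
  if ("classify" %in% stages) {
    cls_long <- do.call(rbind, lapply(genotypes, function(g) {
      cbind(genotype = g, classes[[g]])
    }))
    cls_long$emd_to_uniform <- signif(cls_long$emd_to_uniform, 6)
    cls_long$max_fpkm <- signif(cls_long$max_fpkm, 6)
    outputs <- c(outputs,
                 .fwrite_tsv(cls_long, file.path(config$outdir,
                                                 "classes.tsv")))
    trans <- do.call(rbind, lapply(mutants, function(g) {
      tt <- transition_table(classes[[roles$wt]], classes[[g]])
      data.frame(genotype = g, transition = names(tt),
                 count = unname(tt))
    }))
    outputs <- c(outputs,
                 .fwrite_tsv(trans, file.path(config$outdir,
                                              "transitions.tsv")))
    .log("classify: %d genotypes; %d expressed genes in %s",
         length(genotypes),
         sum(classes[[roles$wt]]$label != "low_expression"), roles$wt)
  }

  # change flags (top tail per genotype) and co-change across mutants
  flags <- lapply(dist_to_wt, change_flags,
                  quantile = config$change_quantile)
  if ("classify" %in% stages && length(mutants) >= 2) {
    pairs <- utils::combn(mutants, 2, simplify = FALSE)
    cc <- do.call(rbind, lapply(pairs, function(pr) {
      r <- co_change_test(flags[[pr[1]]], flags[[pr[2]]])
      data.frame(genotype_a = pr[1], genotype_b = pr[2],
                 chi2 = signif(r$chi2, 6), p = signif(r$p, 6),
                 obs_exp_ratio = signif(r$ratio, 6))
    }))
    outputs <- c(outputs,
                 .fwrite_tsv(cc, file.path(config$outdir,
                                           "co_change.tsv")))
  }

  # ---- delta-D --------------------------------------------------------
  m1_emb <- stage_embryos(roles$m1)
  m2_emb <- stage_embryos(roles$m2)
  dd <- delta_d_table(wt_emb, m1_emb, m2_emb, config$expressed_fpkm)
  if ("deltad" %in% stages) {
    out <- dd
    for (cn in c("d_m1_m2", "d_m1_wt", "d_m2_wt", "delta_d")) {
      out[[cn]] <- signif(out[[cn]], 6)
    }
    outputs <- c(outputs,
                 .fwrite_tsv(out, file.path(config$outdir, "deltad.tsv")))
    n_callout <- sum(dd$delta_d > config$delta_d_callout, na.rm = TRUE)
    .log("deltad: %d genes with delta-D > %.2f", n_callout,
         config$delta_d_callout)
  }

  # ---- level response (dosage pair) ----------------------------------
  if ("deltad" %in% stages &&
      all(c(roles$level_up, roles$level_down) %in% genotypes)) {
    uniform_wt <- classes[[roles$wt]]$gene_id[
      classes[[roles$wt]]$label == "uniform"]
    mean_fpkm <- function(g) {
      embs <- stage_embryos(g)
      rowMeans(vapply(embs, function(e) rowMeans(.imputed_expr(e)),
                      numeric(length(tab$gene_ids))))[uniform_wt]
    }
    lr <- level_response(mean_fpkm(roles$wt), mean_fpkm(roles$level_up),
                         mean_fpkm(roles$level_down), config$fold)
    outputs <- c(outputs, .fwrite_tsv(
      data.frame(direction = c("up_in_both", "down_in_both"),
                 count = c(lr$n_up, lr$n_down),
                 n_uniform_genes = length(uniform_wt)),
      file.path(config$outdir, "level_response.tsv")))
  }

  # ---- enrichment ----------------------------------------------------
  if ("enrich" %in% stages) {
    for (p in c(peaks_path, tss_path)) {
      if (!file.exists(p)) stop("enrichment input missing: ", p)
    }
    peaks <- read_peaks(peaks_path)
    tss <- read_tss(tss_path)
    binding <- assign_peaks_to_genes(peaks, tss,
                                     window = config$tss_window,
                                     tfs = DEFAULT_TFS)
    expressed <- classes[[roles$wt]]$gene_id[
      classes[[roles$wt]]$label != "low_expression"]

    # Table-2 style: TF enrichment per transition category, per mutant
    cat_rows <- list()
    for (g in mutants) {
      wt_lab <- setNames(classes[[roles$wt]]$label,
                         classes[[roles$wt]]$gene_id)
      mut_lab <- setNames(classes[[g]]$label, classes[[g]]$gene_id)
      key <- paste(wt_lab, mut_lab, sep = "_to_")
      for (tr in TRANSITIONS) {
        cat_genes <- names(wt_lab)[key == tr]
        bg <- setdiff(expressed, cat_genes)
        if (length(cat_genes) < 5 || length(bg) < 5) next
        r <- tf_enrichment_by_category(cat_genes, bg, binding)
        cat_rows[[length(cat_rows) + 1L]] <-
          cbind(genotype = g, transition = tr, n_category =
                  length(cat_genes), r)
      }
    }
    if (length(cat_rows)) {
      ce <- do.call(rbind, cat_rows)
      for (cn in c("odds_ratio", "base_frequency", "chi2", "p",
                   "p_bonferroni")) ce[[cn]] <- signif(ce[[cn]], 6)
      outputs <- c(outputs, .fwrite_tsv(
        ce, file.path(config$outdir, "enrichment_category.tsv")))
    }

    # Table-3 style: top delta-D vs near-median controls, among genes
    # changing in both mutants
    both <- flags[[roles$m1]] & flags[[roles$m2]]
    dd_vec <- setNames(dd$delta_d, dd$gene_id)
    eligible <- dd_vec[names(both)[both & !is.na(dd_vec[names(both)])]]
    ctrl_n <- config$enrich_control_n
    if (length(eligible) < config$enrich_top_n + ctrl_n) {
      ctrl_n <- length(eligible) - config$enrich_top_n
      .log("enrich: only %d genes change in both mutants; control set reduced to %d",
           length(eligible), ctrl_n)
    }
    if (ctrl_n >= 10) {
      de <- delta_d_enrichment(eligible, binding,
                               top_n = config$enrich_top_n,
                               control_n = ctrl_n,
                               expressed_genes = expressed)
      for (cn in c("odds_ratio", "base_frequency", "chi2", "p",
                   "p_bonferroni")) de[[cn]] <- signif(de[[cn]], 6)
      outputs <- c(outputs, .fwrite_tsv(
        de, file.path(config$outdir, "enrichment_deltad.tsv")))
    } else {
      .log("enrich: too few co-changing genes for the delta-D design; skipped")
    }

    # combinatorial binding vs delta-D windows
    cb <- combinatorial_binding_curve(dd_vec[expressed], binding,
                                      window = config$fig9_window)
    outputs <- c(outputs, .fwrite_tsv(
      cb$windows, file.path(config$outdir, "binding_windows.tsv")))
    outputs <- c(outputs, .fwrite_tsv(
      cb$fits, file.path(config$outdir, "binding_window_fits.tsv")))

    # binding-signature groups vs summed EMD across the mutant panel
    summed <- Reduce(`+`, lapply(dist_to_wt, function(d) {
      d2 <- d; d2[is.na(d2)] <- 0; d2
    }))
    gt <- binding_group_tests(binding[expressed, , drop = FALSE],
                              summed[expressed],
                              min_group = config$group_min)
    if (nrow(gt)) {
      gt$ks_d <- signif(gt$ks_d, 6)
      gt$p <- signif(gt$p, 6)
      gt$p_bonferroni <- signif(gt$p_bonferroni, 6)
    }
    outputs <- c(outputs, .fwrite_tsv(
      gt, file.path(config$outdir, "binding_groups.tsv")))

    # enhancer -> nearest gene map
    if (file.exists(enh_path)) {
      enh <- read_enhancers(enh_path)
      ng <- nearest_gene_for_enhancer(enh, tss,
                                      window = config$tss_window)
      outputs <- c(outputs, .fwrite_tsv(
        ng, file.path(config$outdir, "enhancer_genes.tsv")))
    }
    .log("enrich: %d TFs x %d genes", ncol(binding), nrow(binding))
  }

  # ---- clustering ----------------------------------------------------
  if ("cluster" %in% stages) {
    pooled <- Reduce(pmax, lapply(dist_to_wt, function(d) {
      d2 <- d; d2[is.na(d2)] <- 0; d2
    }))
    n_cl <- min(config$cluster_max_genes, sum(pooled > 0))
    sel <- top_changed_genes(pooled, n_cl)
    cl <- cluster_genes(tab$embryos[vapply(tab$embryos, `[[`,
                                           character(1),
                                           "timepoint") == config$stage],
                        sel, config$expressed_fpkm)
    merges <- data.frame(step = seq_len(nrow(cl$hclust$merge)),
                         left = cl$hclust$merge[, 1],
                         right = cl$hclust$merge[, 2],
                         height = signif(cl$hclust$height, 6))
    outputs <- c(outputs, .fwrite_tsv(
      merges, file.path(config$outdir, "cluster_merges.tsv")))
    outputs <- c(outputs, .fwrite_tsv(
      data.frame(position = seq_along(cl$order), gene_id = cl$order),
      file.path(config$outdir, "cluster_order.tsv")))
    .log("cluster: %d genes", n_cl)
  }

  # ---- report: heatmap matrices, average patterns, similarity --------
  if ("report" %in% stages) {
    pooled <- Reduce(pmax, lapply(dist_to_wt, function(d) {
      d2 <- d; d2[is.na(d2)] <- 0; d2
    }))
    top <- top_changed_genes(pooled, min(config$top_n,
                                         sum(pooled > 0)))
    hm <- render_heatmaps(tab$embryos, top, config$outdir,
                          floor = config$heatmap_floor_fpkm)
    outputs <- c(outputs, hm)

    avg <- list()
    for (g in genotypes) {
      for (e in stage_embryos(g)) {
        ap <- average_pattern(top, e, floor = config$heatmap_floor_fpkm)
        avg[[length(avg) + 1L]] <- data.frame(
          genotype = g, embryo_id = e$embryo_id,
          slice = seq_along(ap), mean_intensity = signif(ap, 6))
      }
    }
    outputs <- c(outputs, .fwrite_tsv(
      do.call(rbind, avg),
      file.path(config$outdir, "average_patterns.tsv")))

    sim <- do.call(rbind, lapply(wt_emb, function(e) {
      s <- adjacent_slice_similarity(.imputed_expr(e))
      if (nrow(s)) cbind(embryo_id = e$embryo_id, s) else NULL
    }))
    if (is.null(sim)) {
      sim <- data.frame(embryo_id = character(), offset = integer(),
                        similarity = numeric(), n_pairs = integer())
    } else {
      sim$similarity <- signif(sim$similarity, 6)
    }
    outputs <- c(outputs, .fwrite_tsv(
      sim, file.path(config$outdir, "slice_similarity.tsv")))

    cfg_path <- file.path(config$outdir, "config.yaml")
    write_pipeline_config(config, cfg_path)
    manifest <- list(
      package = "slicepattern",
      version = as.character(utils::packageVersion("slicepattern")),
      seed = config$seed,
      stage = config$stage,
      roles = config$roles,
      n_genes = length(tab$gene_ids),
      n_embryos = length(tab$embryos),
      outputs = as.list(setNames(
        unname(tools::md5sum(sort(unique(outputs)))),
        basename(sort(unique(outputs)))))
    )
    jsonlite::write_json(manifest,
                         file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    outputs <- c(outputs, cfg_path,
                 file.path(config$outdir, "manifest.json"))
  }
  .log("done: %d output files", length(unique(outputs)))
  invisible(list(outputs = sort(unique(outputs)),
                 classes = classes, delta_d = dd, truth = truth))
}

#' Write heatmap matrices (and optional images) for a gene selection
#'
#' For each genotype, writes a genes x slices TSV of per-gene,
#' per-embryo max-normalized intensities (linear scale, anterior left;
#' the normalization divides by the embryo maximum for the gene or by
#' `floor` FPKM, whichever is greater) with column blocks per embryo,
#' plus a parallel 0/1 mask marking slices whose values were imputed
#' from neighbors after QC failure.  Images are optional so the output
#' stays plain text.
#'
#' @param embryos list of `embryo_sample` objects.
#' @param genes non-empty gene selection (row order preserved).
#' @param outdir output directory.
#' @param floor heatmap normalization floor, FPKM.
#' @param images if TRUE and the pheatmap package is available, also
#'   writes PNG heatmaps.
#' @return character vector of written file paths.
#' @export
render_heatmaps <- function(embryos, genes, outdir, floor = 10,
                            images = FALSE) {
  if (length(genes) == 0) stop("empty gene selection for heatmaps")
  genotypes <- unique(vapply(embryos, `[[`, character(1), "genotype"))
  paths <- character()
  for (g in genotypes) {
    embs <- Filter(function(e) e$genotype == g, embryos)
    blocks <- lapply(embs, function(e) {
      m <- .imputed_expr(e)[genes, , drop = FALSE]
      norm <- t(apply(m, 1, max_normalize, floor = floor))
      colnames(norm) <- sprintf("%s_slice%02d", e$embryo_id,
                                seq_len(ncol(norm)))
      norm
    })
    mat <- do.call(cbind, blocks)
    mask <- do.call(cbind, lapply(embs, function(e) {
      mk <- matrix(as.integer(!e$qc_mask), nrow = length(genes),
                   ncol = length(e$qc_mask), byrow = TRUE)
      colnames(mk) <- sprintf("%s_slice%02d", e$embryo_id,
                              seq_len(ncol(mk)))
      mk
    }))
    mp <- file.path(outdir, sprintf("heatmap_%s.tsv", g))
    kp <- file.path(outdir, sprintf("heatmap_mask_%s.tsv", g))
    .fwrite_tsv(data.frame(gene_id = genes, signif(mat, 6),
                           check.names = FALSE), mp)
    .fwrite_tsv(data.frame(gene_id = genes, mask, check.names = FALSE),
                kp)
    paths <- c(paths, mp, kp)
    if (images && requireNamespace("pheatmap", quietly = TRUE)) {
      png_path <- file.path(outdir, sprintf("heatmap_%s.png", g))
      grDevices::png(png_path, width = 1200, height = 900)
      pheatmap::pheatmap(mat, cluster_rows = FALSE, cluster_cols = FALSE,
                         color = grDevices::colorRampPalette(
                           c("white", "darkblue"))(100))
      grDevices::dev.off()
      paths <- c(paths, png_path)
    }
  }
  paths
}
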