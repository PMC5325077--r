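#' Default transcription factor panel
#'
#' Ten early anteroposterior regulators with genome-wide ChIP binding data:
#' nine non-pair-rule AP factors plus the pioneer factor Zelda.
#' @export
DEFAULT_TFS <- c("bcd", "cad", "D", "gt", "hb", "hkb", "kni", "kr", "tll",
                 "zld")

#' Configuration of a synthetic sliced-embryo cohort
#'
#' Captures the study design being emulated: 5 genotypes (wild-type plus
#' four maternal-factor perturbations), 2 time points with 2 replicate
#' embryos each, 25-30 slices per embryo with counts differing between
#' embryos, FPKM-scale expression with multiplicative lognormal noise, and
#' occasional QC-failed slices.
#'
#' @param n_genes number of genes to simulate.
#' @param genotypes character vector of genotypes (must include `"wt"`).
#' @param timepoints labels of the developmental stages sampled.
#' @param replicates_per_timepoint embryos per genotype per time point.
#' @param slice_count_range inclusive integer range slice counts are drawn
#'   from, per embryo (min >= 5).
#' @param noise_sigma sigma of the per-gene, per-slice multiplicative
#'   lognormal noise (>= 0).
#' @param qc_fail_rate independent per-slice QC failure probability.
#' @param frac_low fraction of genes simulated below the 15 FPKM floor.
#' @param frac_responsive fraction of genes eligible for mutant effects;
#'   responsiveness is shared across genotypes, which makes changes
#'   correlated between mutants as observed in real data.
#' @param effect_prob_responsive,effect_prob_background probability that a
#'   responsive / non-responsive gene receives an effect in a given mutant.
#' @param seed integer RNG seed; fully determines the cohort.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_genes = 1000,
                          genotypes = GENOTYPES,
                          timepoints = c("c13", "c14D"),
                          replicates_per_timepoint = 2,
                          slice_count_range = c(25L, 30L),
                          noise_sigma = 0.15,
                          qc_fail_rate = 0.03,
                          frac_low = 0.10,
                          frac_responsive = 0.20,
                          effect_prob_responsive = 0.7,
                          effect_prob_background = 0.02,
                          seed = 1L) {
  genotypes <- unlist(genotypes)
  timepoints <- unlist(timepoints)
  slice_count_range <- as.integer(unlist(slice_count_range))
  stopifnot(n_genes > 0, length(genotypes) > 0, "wt" %in% genotypes,
            replicates_per_timepoint >= 1, length(slice_count_range) == 2,
            slice_count_range[1] >= 5,
            slice_count_range[1] <= slice_count_range[2],
            noise_sigma >= 0, qc_fail_rate >= 0, qc_fail_rate <= 1)
  structure(list(
    n_genes = as.integer(n_genes), genotypes = genotypes,
    timepoints = timepoints,
    replicates_per_timepoint = as.integer(replicates_per_timepoint),
    slice_count_range = as.integer(slice_count_range),
    noise_sigma = noise_sigma, qc_fail_rate = qc_fail_rate,
    frac_low = frac_low, frac_responsive = frac_responsive,
    effect_prob_responsive = effect_prob_responsive,
    effect_prob_background = effect_prob_background,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Slice a virtual embryo
#'
#' Cuts the unit AP axis into `n_slices` equal-width slices (slice `i`
#' covers `[(i-1)/N, i/N)`); each gene's stored FPKM is the mean of its
#' continuous pattern over the slice interval (midpoint rule, 32
#' sub-samples) multiplied by lognormal noise drawn independently per gene
#' and slice.  Each slice independently fails QC with probability
#' `qc_fail_rate`; terminal slices may fail.
#'
#' @param specs list of [pattern_spec()] objects (one per gene).
#' @param n_slices number of slices (>= 5).
#' @param noise_sigma multiplicative lognormal sigma (>= 0).
#' @param qc_fail_rate per-slice failure probability.
#' @param embryo_id,genotype,timepoint metadata carried on the sample.
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used (as within [generate_cohort()]).
#' @return An object of class `embryo_sample`: fields `embryo_id`,
#'   `genotype`, `timepoint`, `expr` (genes x slices FPKM matrix with
#'   gene ids as rownames), `qc_mask` (`TRUE` = usable slice).
#' @export
slice_embryo <- function(specs, n_slices, noise_sigma = 0,
                         qc_fail_rate = 0, embryo_id = "embryo",
                         genotype = "wt", timepoint = "c14D", seed = NULL) {
  if (n_slices < 5L) stop("need at least 5 slices")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n_sub <- 32L
  # midpoints of n_sub sub-intervals within each slice
  xs <- (rep(seq_len(n_slices) - 1L, each = n_sub) +
           (seq_len(n_sub) - 0.5) / n_sub) / n_slices
  expr <- t(vapply(specs, function(sp) {
    colMeans(matrix(evaluate_pattern(sp, xs), nrow = n_sub))
  }, numeric(n_slices)))
  rownames(expr) <- unname(vapply(specs, `[[`, character(1), "gene_id"))
  if (noise_sigma > 0) {
    expr <- expr * exp(matrix(rnorm(length(expr), 0, noise_sigma),
                              nrow = nrow(expr)))
  }
  qc_mask <- runif(n_slices) >= qc_fail_rate
  structure(list(embryo_id = embryo_id, genotype = genotype,
                 timepoint = timepoint, expr = expr, qc_mask = qc_mask),
            class = "embryo_sample")
}

# noise-free pattern class of a spec, at a reference slice count
.true_class <- function(spec, n_slices = 27L,
                        expressed_fpkm = 15, uniform_emd = 0.04,
                        patterned_emd = 0.08) {
  centers <- (seq_len(n_slices) - 0.5) / n_slices
  v <- evaluate_pattern(spec, centers)
  if (max(v) < expressed_fpkm) return("low_expression")
  e <- emd_to_uniform(v)
  if (e < uniform_emd) "uniform"
  else if (e > patterned_emd) "patterned"
  else "ambiguous"
}

# draw one wild-type pattern; ~frac_low genes stay under the expressed floor
.random_pattern <- function(gene_id, frac_low) {
  fam <- sample(PATTERN_FAMILIES, 1, prob = c(
    uniform = 0.45, anterior_gradient = 0.10, posterior_gradient = 0.10,
    anterior_domain = 0.10, posterior_domain = 0.08, central_domain = 0.07,
    stripes = 0.10
  ))
  low <- runif(1) < frac_low
  amp <- if (low) runif(1, 1, 10) else exp(rnorm(1, log(60), 0.5))
  base <- if (fam == "uniform" || low) 0 else runif(1, 0, 0.05) * amp
  switch(fam,
    uniform = pattern_spec(gene_id, fam, amplitude = amp),
    anterior_gradient = ,
    posterior_gradient = pattern_spec(gene_id, fam, amplitude = amp,
                                      baseline = base,
                                      decay = runif(1, 0.08, 0.25)),
    anterior_domain = pattern_spec(gene_id, fam, amplitude = amp,
                                   baseline = base,
                                   center = runif(1, 0.05, 0.30),
                                   width = runif(1, 0.05, 0.12)),
    posterior_domain = pattern_spec(gene_id, fam, amplitude = amp,
                                    baseline = base,
                                    center = runif(1, 0.70, 0.95),
                                    width = runif(1, 0.05, 0.12)),
    central_domain = pattern_spec(gene_id, fam, amplitude = amp,
                                  baseline = base,
                                  center = runif(1, 0.40, 0.60),
                                  width = runif(1, 0.05, 0.12)),
    stripes = pattern_spec(gene_id, fam, amplitude = amp, baseline = base,
                           n_stripes = sample(3:7, 1),
                           phase = runif(1, 0, 1))
  )
}

# draw a mutant effect appropriate for the gene's wild-type class
.random_effect <- function(gene_id, genotype, wt_class) {
  if (wt_class == "patterned") {
    eff <- sample(c("uniformize", "loss_to_low", "shift", "ectopic_gain"),
                  1, prob = c(0.35, 0.30, 0.25, 0.10))
    if (eff == "shift") {
      return(genotype_effect(gene_id, genotype, "shift",
                             shift = sample(c(-1, 1), 1) *
                               runif(1, 0.08, 0.20)))
    }
    genotype_effect(gene_id, genotype, eff)
  } else if (wt_class == "uniform") {
    if (runif(1) < 0.5) {
      genotype_effect(gene_id, genotype, "ectopic_gain",
                      gain_amplitude = runif(1, 60, 150))
    } else {
      genotype_effect(gene_id, genotype, "level_scale",
                      scale = sample(c(runif(1, 1.6, 3),
                                       1 / runif(1, 1.6, 3)), 1))
    }
  } else {
    # low-expression (or ambiguous) gene gains a de-novo domain
    genotype_effect(gene_id, genotype, "ectopic_gain",
                    gain_amplitude = runif(1, 60, 150))
  }
}

#' Generate a synthetic sliced-embryo cohort with ground truth
#'
#' Draws one wild-type pattern per gene, assigns genotype effects (with a
#' shared "responsive" gene set so that changes are correlated between
#' mutants), and slices one virtual embryo per genotype x time point x
#' replicate.  Slice counts are drawn per embryo from
#' `slice_count_range`, so embryos differ in slice number as real
#' cryosliced embryos do.
#'
#' @param config a [cohort_config()].
#' @return A list of class `cohort` with elements:
#'   \describe{
#'     \item{embryos}{list of [slice_embryo()] samples.}
#'     \item{truth}{data.frame, one row per gene x genotype: `gene_id`,
#'       `genotype`, `family`, `effect`, `true_class` (noise-free pattern
#'       class), `params` (JSON-encoded pattern parameters).}
#'     \item{specs}{list (genotype -> list of `pattern_spec`).}
#'     \item{config}{the input configuration.}
#'   }
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (length(config$genotypes) == 0) stop("empty genotype list")
  set.seed(config$seed)
  gene_ids <- sprintf("gene_%04d", seq_len(config$n_genes))

  wt_specs <- lapply(gene_ids, .random_pattern, frac_low = config$frac_low)
  names(wt_specs) <- gene_ids
  wt_class <- vapply(wt_specs, .true_class, character(1))
  responsive <- runif(config$n_genes) < config$frac_responsive

  specs_by_genotype <- list(wt = wt_specs)
  truth <- list(data.frame(
    gene_id = gene_ids, genotype = "wt",
    family = vapply(wt_specs, `[[`, character(1), "family"),
    effect = "none", true_class = wt_class,
    params = vapply(wt_specs, function(s) {
      as.character(jsonlite::toJSON(c(s$params, baseline = s$baseline),
                                    auto_unbox = TRUE, digits = NA))
    }, character(1)),
    stringsAsFactors = FALSE
  ))

  for (g in setdiff(config$genotypes, "wt")) {
    p_eff <- ifelse(responsive, config$effect_prob_responsive,
                    config$effect_prob_background)
    hit <- runif(config$n_genes) < p_eff
    specs_g <- wt_specs
    effects <- rep("none", config$n_genes)
    for (k in which(hit)) {
      eff <- .random_effect(gene_ids[k], g, wt_class[k])
      specs_g[[k]] <- apply_effect(wt_specs[[k]], eff)
      effects[k] <- eff$effect
    }
    specs_by_genotype[[g]] <- specs_g
    truth[[length(truth) + 1L]] <- data.frame(
      gene_id = gene_ids, genotype = g,
      family = vapply(specs_g, `[[`, character(1), "family"),
      effect = effects,
      true_class = vapply(specs_g, .true_class, character(1)),
      params = vapply(specs_g, function(s) {
        as.character(jsonlite::toJSON(c(s$params, baseline = s$baseline),
                                      auto_unbox = TRUE, digits = NA))
      }, character(1)),
      stringsAsFactors = FALSE
    )
  }

  embryos <- list()
  for (g in config$genotypes) {
    for (tp in config$timepoints) {
      for (r in seq_len(config$replicates_per_timepoint)) {
        n_slices <- config$slice_count_range[1] +
          sample.int(diff(config$slice_count_range) + 1L, 1L) - 1L
        id <- sprintf("%s_%s_r%d", g, tp, r)
        embryos[[id]] <- slice_embryo(
          specs_by_genotype[[g]], n_slices,
          noise_sigma = config$noise_sigma,
          qc_fail_rate = config$qc_fail_rate,
          embryo_id = id, genotype = g, timepoint = tp)
      }
    }
  }

  structure(list(embryos = embryos, truth = do.call(rbind, truth),
                 specs = specs_by_genotype, config = config),
            class = "cohort")
}

#' Simulate a TF binding matrix with optional planted enrichment
#'
#' Draws a boolean genes x TFs matrix.  When `enriched_tf` is given, that
#' factor is bound at rate `p_affected` among `affected` genes and
#' `p_background` elsewhere; all other factors bind independently at
#' `p_background` (or per-TF rates supplied via `base_rates`).
#'
#' @param gene_ids character vector of genes.
#' @param affected logical (or gene-id subset) marking genes carrying a
#'   mutant effect.
#' @param tfs TF names (default [DEFAULT_TFS]).
#' @param enriched_tf TF to plant enrichment on, or `NULL` for fully
#'   independent binding.
#' @param p_affected,p_background binding rates.
#' @param base_rates optional named per-TF background rates.
#' @return logical matrix, genes x TFs.
#' @export
simulate_binding_matrix <- function(gene_ids, affected = NULL,
                                    tfs = DEFAULT_TFS,
                                    enriched_tf = NULL,
                                    p_affected = 0.6, p_background = 0.15,
                                    base_rates = NULL) {
  n <- length(gene_ids)
  if (is.character(affected)) affected <- gene_ids %in% affected
  if (is.null(affected)) affected <- rep(FALSE, n)
  stopifnot(length(affected) == n)
  if (is.null(base_rates)) base_rates <- setNames(rep(p_background,
                                                      length(tfs)), tfs)
  bm <- vapply(tfs, function(tf) {
    p <- rep(base_rates[[tf]], n)
    if (!is.null(enriched_tf) && tf == enriched_tf) p[affected] <- p_affected
    runif(n) < p
  }, logical(n))
  rownames(bm) <- gene_ids
  bm
}
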