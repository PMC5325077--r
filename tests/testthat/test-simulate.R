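test_that("slice values are interval means of the continuous pattern", {
  u <- pattern_spec("g1", "uniform", amplitude = 50)
  e <- slice_embryo(list(u), n_slices = 10, noise_sigma = 0, seed = 1)
  expect_equal(unname(e$expr["g1", ]), rep(50, 10))

  g <- pattern_spec("g1", "anterior_gradient", amplitude = 80, decay = 0.2)
  e2 <- slice_embryo(list(g), n_slices = 20, noise_sigma = 0, seed = 1)
  # monotone integrand implies strictly decreasing interval means
  expect_true(all(diff(e2$expr["g1", ]) < 0))
  # interval mean of exp(-x/lambda) over [0, 1/N] in closed form
  lam <- 0.2; n <- 20
  expect_equal(unname(e2$expr["g1", 1]),
               80 * lam * n * (1 - exp(-1 / (lam * n))),
               tolerance = 1e-4)
})

test_that("slicing is reproducible and validates its inputs", {
  specs <- list(pattern_spec("a", "uniform", amplitude = 30),
                pattern_spec("b", "central_domain", amplitude = 90,
                             center = 0.5, width = 0.1))
  e1 <- slice_embryo(specs, 12, noise_sigma = 0.3, qc_fail_rate = 0.2,
                     seed = 99)
  e2 <- slice_embryo(specs, 12, noise_sigma = 0.3, qc_fail_rate = 0.2,
                     seed = 99)
  expect_identical(e1, e2)
  expect_error(slice_embryo(specs, 4), "at least 5")
  expect_error(slice_embryo(specs, 10, noise_sigma = -0.1), ">= 0")
})

test_that("generate_cohort honors the study design", {
  cfg <- cohort_config(n_genes = 40, seed = 3)
  cohort <- generate_cohort(cfg)
  # 5 genotypes x 2 time points x 2 replicates
  expect_length(cohort$embryos, 20)
  counts <- vapply(cohort$embryos, function(e) ncol(e$expr), integer(1))
  expect_true(all(counts >= 25 & counts <= 30))
  expect_gt(length(unique(counts)), 1)  # embryos differ in slice count
  # truth table: one row per gene x genotype
  expect_equal(nrow(cohort$truth), 40 * 5)
  expect_true(all(cohort$truth$effect[cohort$truth$genotype == "wt"] ==
                    "none"))

  # determinism of the whole cohort
  cohort2 <- generate_cohort(cohort_config(n_genes = 40, seed = 3))
  expect_identical(cohort$embryos, cohort2$embryos)
  expect_identical(cohort$truth, cohort2$truth)

  expect_error(generate_cohort(cohort_config(n_genes = 10,
                                             genotypes = character(0))),
               "genotype")
})

test_that("truth classes are consistent with the generating family", {
  cfg <- tiny_cohort(n_genes = 150, sigma = 0, seed = 5, qc_fail_rate = 0)
  cohort <- generate_cohort(cfg)
  wt <- cohort$truth[cohort$truth$genotype == "wt", ]
  uni <- wt[wt$family == "uniform" & wt$true_class != "low_expression", ]
  expect_true(all(uni$true_class == "uniform"))
  # at sigma = 0 the uniform-family genes have EMD-to-uniform exactly 0
  e <- cohort$embryos[["wt_c14D_r1"]]
  for (g in head(uni$gene_id, 5)) {
    expect_equal(emd_to_uniform(e$expr[g, ]), 0, tolerance = 1e-12)
  }
  # narrow single domains are strongly patterned
  dom <- wt[grepl("domain", wt$family) & wt$true_class != "low_expression", ]
  params <- lapply(dom$params, jsonlite::fromJSON)
  narrow <- dom$gene_id[vapply(params, function(p) p$width <= 0.1,
                               logical(1))]
  for (g in narrow) {
    expect_gt(emd_to_uniform(e$expr[g, ]), 0.08)
  }
})

test_that("binding simulation plants enrichment where asked", {
  set.seed(8)
  genes <- sprintf("g%03d", 1:500)
  affected <- seq_along(genes) <= 100
  bm <- simulate_binding_matrix(genes, affected, enriched_tf = "bcd")
  expect_identical(dim(bm), c(500L, 10L))
  expect_gt(mean(bm[affected, "bcd"]), mean(bm[!affected, "bcd"]))
  # other factors independent of the affected set
  expect_lt(abs(mean(bm[affected, "kr"]) - mean(bm[!affected, "kr"])),
            0.15)
})
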