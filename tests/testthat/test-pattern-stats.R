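# two replicate embryos of one genotype built from pattern specs
embryos_from_specs <- function(specs, n_slices = 27, genotype = "wt",
                               ids = c("r1", "r2")) {
  lapply(ids, function(id) {
    slice_embryo(specs, n_slices, noise_sigma = 0, embryo_id = id,
                 genotype = genotype)
  })
}

test_that("classification applies the 15 FPKM floor and EMD thresholds", {
  specs <- list(
    pattern_spec("flat", "uniform", amplitude = 50),
    pattern_spec("dim", "uniform", amplitude = 8),
    pattern_spec("spike", "anterior_domain", amplitude = 400,
                 center = 0.5, width = 0.015))
  embs <- embryos_from_specs(specs)
  cls <- classify_patterns(embs)
  lab <- setNames(cls$label, cls$gene_id)
  expect_identical(lab[["flat"]], "uniform")
  expect_identical(lab[["dim"]], "low_expression")
  expect_identical(lab[["spike"]], "patterned")
  expect_equal(cls$emd_to_uniform[cls$gene_id == "flat"], 0)
  # near-single-slice spike: EMD to uniform checked against the oracle
  v <- embs[[1]]$expr["spike", ]
  expect_gt(emd_lp_oracle(to_distribution(v),
                          to_distribution(rep(1, 27))), 0.08)

  one <- classify_pattern("spike", embs)
  expect_identical(one$label, "patterned")
  expect_error(classify_pattern("spike", list()), "no embryos")
})

test_that("transition table counts the four named transitions", {
  wt <- c(a = "patterned", b = "uniform", c = "patterned")
  mut <- c(a = "uniform", b = "patterned", c = "patterned")
  trans_names <- c(
    "low_expression_to_patterned", "patterned_to_uniform",
    "patterned_to_low_expression", "uniform_to_patterned")
  tt <- transition_table(wt, mut)
  expect_equal(unname(tt[trans_names]), c(0, 1, 0, 1))
  expect_equal(unname(tt["remainder"]), 1)
  expect_equal(unname(tt["total"]), 3)

  same <- transition_table(wt, wt)
  expect_true(all(same[1:4] == 0))

  # ambiguous genes are excluded from the universe
  wt2 <- c(wt, d = "ambiguous")
  mut2 <- c(mut, d = "patterned")
  expect_equal(unname(transition_table(wt2, mut2)["total"]), 3)

  expect_error(transition_table(wt, mut[1:2]), "different gene sets")
})

test_that("pattern change is zero for identical inputs and tracks shifts", {
  specs <- list(pattern_spec("g", "anterior_domain", amplitude = 100,
                             center = 0.3, width = 0.06))
  wt <- embryos_from_specs(specs, n_slices = 30)
  expect_equal(pattern_change("g", wt, wt), 0)

  # a +0.1 shift with 30 slices is an exact 3-slice translation
  shifted <- lapply(specs, apply_effect,
                    effect = genotype_effect("g", "hb_minus", "shift",
                                             shift = 0.1))
  mut <- embryos_from_specs(shifted, n_slices = 30, genotype = "hb_minus")
  # exact up to the ~1e-7 Gaussian tail clipped at the anterior pole
  expect_equal(pattern_change("g", wt, mut), 0.1, tolerance = 1e-5)

  # unexpressed in both genotypes: excluded as NA
  lo <- list(pattern_spec("g", "uniform", amplitude = 5))
  expect_true(is.na(pattern_change("g", embryos_from_specs(lo),
                                   embryos_from_specs(lo))))

  # vectorized table agrees with the per-gene form
  many <- list(pattern_spec("g1", "uniform", amplitude = 40),
               pattern_spec("g2", "posterior_gradient", amplitude = 70,
                            decay = 0.15))
  ea <- embryos_from_specs(many, 26)
  eb <- embryos_from_specs(many, 29)
  tabbed <- pattern_change_table(ea, eb)
  expect_equal(tabbed[["g1"]], pattern_change("g1", ea, eb))
  expect_equal(tabbed[["g2"]], pattern_change("g2", ea, eb))
})

test_that("delta-D collapses to zero when mutants agree or match WT", {
  specs_wt <- list(pattern_spec("g", "anterior_gradient", amplitude = 90,
                                decay = 0.2))
  specs_m <- list(pattern_spec("g", "posterior_gradient", amplitude = 90,
                               decay = 0.2))
  wt <- embryos_from_specs(specs_wt, 27)
  m <- embryos_from_specs(specs_m, 27, genotype = "bcd_minus")
  # M1 = M2
  rec <- delta_d("g", wt, m, m)
  expect_equal(rec$d_m1_m2, 0)
  expect_equal(rec$delta_d, 0)
  # M1 = WT: EMD(M1,M2) = EMD(WT,M2) exactly
  rec2 <- delta_d("g", wt, wt, m)
  expect_equal(rec2$delta_d, 0, tolerance = 1e-12)
  expect_error(delta_d("g", wt, list(), m), "at least one embryo")

  # batch form matches
  dt <- delta_d_table(wt, m, m)
  expect_equal(dt$delta_d[dt$gene_id == "g"], 0)
})

test_that("change flags take the top tail, inclusive of boundary ties", {
  d <- setNames(as.numeric(1:10), paste0("g", 1:10))
  f <- change_flags(d, 0.8)
  expect_identical(names(d)[f], c("g9", "g10"))
  # ties at the cutoff are all flagged
  d2 <- setNames(c(1, 2, 3, 4, 5, 6, 7, 9, 9, 9), paste0("g", 1:10))
  expect_equal(sum(change_flags(d2, 0.8)), 3)
  expect_warning(f3 <- change_flags(setNames(rep(2, 6), letters[1:6])),
                 "no genes flagged")
  expect_false(any(f3))
  # approximately the right fraction for continuous distances
  set.seed(30)
  d4 <- setNames(runif(500), sprintf("g%03d", 1:500))
  expect_equal(sum(change_flags(d4, 0.8)), 100)
})

test_that("co-change chi-squared matches hand computation", {
  # balanced table: no association
  fa <- rep(c(TRUE, FALSE), each = 100)
  fb <- rep(c(TRUE, FALSE, TRUE, FALSE), each = 50)
  r <- co_change_test(fa, fb)
  expect_equal(r$chi2, 0)
  expect_equal(r$ratio, 1)
  # [[90,10],[10,90]]: chi2 = n(ad-bc)^2 / prod(margins) = 128
  fa2 <- rep(c(TRUE, FALSE), each = 100)
  fb2 <- c(rep(TRUE, 90), rep(FALSE, 10), rep(TRUE, 10), rep(FALSE, 90))
  r2 <- co_change_test(fa2, fb2)
  expect_equal(r2$chi2, 128)
  expect_lt(r2$p, 1e-28)
  expect_error(co_change_test(rep(TRUE, 10), rep(c(TRUE, FALSE), 5)),
               "margin")
})

test_that("top_changed_genes orders by distance with stable ties", {
  d <- c(g_1 = 3, g_2 = 1, g_3 = 2)
  expect_identical(top_changed_genes(d, 2), c("g_1", "g_3"))
  ties <- c(b = 5, a = 5, c = 1)
  expect_identical(top_changed_genes(ties, 2), c("a", "b"))
  expect_error(top_changed_genes(d, 7), "only 3")
})

test_that("average_pattern is the slice-wise mean of normalized rows", {
  m <- rbind(g1 = c(0, 10, 20, 30, 40), g2 = c(40, 30, 20, 10, 0))
  e <- make_embryo(m)
  expect_equal(average_pattern("g1", e), m["g1", ] / 40)
  # mirror-image patterns average to a flat profile
  expect_equal(unname(average_pattern(c("g1", "g2"), e)), rep(0.5, 5))
  expect_error(average_pattern(character(0), e), "empty")
})

test_that("EMD clustering separates pattern classes deterministically", {
  specs <- list(
    pattern_spec("ant1", "anterior_domain", amplitude = 80, center = 0.15,
                 width = 0.07),
    pattern_spec("ant2", "anterior_domain", amplitude = 60, center = 0.22,
                 width = 0.08),
    pattern_spec("ant2_dup", "anterior_domain", amplitude = 60,
                 center = 0.22, width = 0.08),
    pattern_spec("post1", "posterior_domain", amplitude = 80,
                 center = 0.85, width = 0.07),
    pattern_spec("post2", "posterior_domain", amplitude = 60,
                 center = 0.78, width = 0.08))
  embs <- embryos_from_specs(specs, 27)
  cl <- cluster_genes(embs, vapply(specs, `[[`, character(1), "gene_id"))
  dm <- as.matrix(cl$dist)
  # duplicate rows at distance zero, merged first
  expect_equal(dm["ant2", "ant2_dup"], 0)
  expect_equal(cl$hclust$height[1], 0)
  k2 <- stats::cutree(cl$hclust, 2)
  expect_equal(length(unique(k2[c("ant1", "ant2", "ant2_dup")])), 1)
  expect_equal(length(unique(k2[c("post1", "post2")])), 1)
  expect_false(k2[["ant1"]] == k2[["post1"]])
  # invariance to input order: same merges, same leaf order
  cl2 <- cluster_genes(embs, rev(vapply(specs, `[[`, character(1),
                                        "gene_id")))
  expect_identical(cl$order, cl2$order)
  expect_equal(cl$hclust$merge, cl2$hclust$merge)
  expect_error(cluster_genes(embs, "ant1"), "at least 2")
})

test_that("level response counts coherent fold changes in both mutants", {
  wt <- c(a = 10, b = 10, c = 10, d = 10)
  up <- c(a = 20, b = 15, c = 5, d = 10)    # a, b up >= 1.5x
  dn <- c(a = 30, b = 16, c = 6, d = 4)
  r <- level_response(wt, up, dn)
  expect_equal(r$n_up, 2)                    # boundary 15 = 1.5x counted
  expect_identical(r$up_genes, c("a", "b"))
  expect_identical(r$down_genes, "c")        # 5 and 6 both <= 10/1.5
  r2 <- level_response(wt, c(a = 5, b = 6, c = 11, d = 10),
                       c(a = 6, b = 6.6, c = 2, d = 10))
  expect_identical(r2$down_genes, c("a", "b"))
  expect_error(level_response(wt, up, dn, fold = 1), "exceed 1")
})
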