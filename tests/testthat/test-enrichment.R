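# small genome: 6 genes, 25 kb apart on one chromosome
toy_tss <- function() {
  structure(data.frame(
    gene_id = sprintf("g%d", 1:6), chrom = "chr2L",
    position = 50000L + 25000L * 0:5, strand = rep(c("+", "-"), 3)),
    class = c("tss_table", "data.frame"))
}

peak_df <- function(chrom, start, end, tf) {
  structure(data.frame(chrom = chrom, start = start, end = end, tf = tf,
                       score = NA_real_, stringsAsFactors = FALSE),
            class = c("peak_set", "data.frame"))
}

test_that("peak-to-gene assignment uses any overlap with the 10kb window", {
  tss <- toy_tss()
  peaks <- peak_df("chr2L",
                   start = c(44800, 70000, 64500, 100100),
                   end = c(45200, 70400, 64900, 100500),
                   tf = c("bcd", "bcd", "zld", "kni"))
  bm <- assign_peaks_to_genes(peaks, tss)
  # peak centered 5 kb upstream of g1 (TSS 50000): bound
  expect_true(bm["g1", "bcd"])
  # peak >10 kb from every TSS: g1 at 50000, g2 at 75000; 64500-64900 is
  # 10.1 kb beyond g2's window start? no -- it overlaps g2's window
  # [65000, 85000] not at all and g1's [40000, 60000] not at all
  expect_false(any(bm[, "zld"]))
  # straddling the window edge of g2 ([65000,85000]): 70000 peak inside
  expect_true(bm["g2", "bcd"])
  # peak overlapping g3's window boundary (window [75000+10000] for g3
  # TSS 100000: [90000, 110000]) - inside
  expect_true(bm["g3", "kni"])
  # monotone in window size
  bm_small <- assign_peaks_to_genes(peaks, tss, window = 2000)
  expect_true(all(bm[bm_small]))   # bound set grows with the window
  expect_lte(sum(bm_small), sum(bm))
  # unknown chromosome: warn and skip
  expect_warning(
    bm2 <- assign_peaks_to_genes(peak_df("chrU", 1, 100, "bcd"), tss),
    "chrU")
  expect_false(any(bm2))
})

test_that("enhancers map to the nearest TSS within the window", {
  tss <- toy_tss()
  # center 53000: distances 3000 (g1) and 22000 (g2) -> g1
  e1 <- peak_df("chr2L", 52500, 53500, "CRM_a")
  e1$center <- 53000
  r1 <- nearest_gene_for_enhancer(e1, tss)
  expect_identical(r1$gene_id, "g1")
  # nearest TSS 12 kb away -> none
  e2 <- peak_df("chr2L", 61500, 62500, "CRM_b")
  e2$center <- 62000
  expect_true(is.na(nearest_gene_for_enhancer(e2, tss)$gene_id))
  # exact tie: both genes reported
  e3 <- peak_df("chr2L", 62000, 63000, "CRM_c")
  e3$center <- 62500  # 12500 from both? no: 62501-50000 vs 75000-62501
  e3$center <- 62499  # 1-based center 62500: 12500 from g1, 12500 from g2
  r3 <- nearest_gene_for_enhancer(e3, tss, window = 15000)
  expect_setequal(r3$gene_id, c("g1", "g2"))
  expect_error(nearest_gene_for_enhancer(e1, tss[0, ]), "empty")
})

test_that("category enrichment recovers a hand-computed chi-squared", {
  genes <- sprintf("g%03d", 1:200)
  binding <- matrix(FALSE, 200, 2, dimnames = list(genes, c("bcd", "kr")))
  cat_genes <- genes[1:100]
  bg <- genes[101:200]
  binding[genes[1:40], "bcd"] <- TRUE       # 40/100 in category
  binding[genes[101:110], "bcd"] <- TRUE    # 10/100 in background
  binding[, "kr"] <- rep(c(TRUE, FALSE), 100)  # identical rates
  res <- tf_enrichment_by_category(cat_genes, bg, binding)
  # Pearson chi2 of [[40,60],[10,90]] = 200*(40*90-60*10)^2/(100*100*50*150)
  expect_equal(res$chi2[res$tf == "bcd"],
               200 * (40 * 90 - 60 * 10)^2 / (100 * 100 * 50 * 150))
  expect_true(res$significant_after_bonferroni[res$tf == "bcd"])
  expect_false(res$significant_after_bonferroni[res$tf == "kr"])
  expect_equal(res$base_frequency[res$tf == "kr"], 0.5)
  expect_error(tf_enrichment_by_category(character(0), bg, binding),
               "empty")
})

test_that("delta-D enrichment flags degenerate separation with Haldane OR", {
  set.seed(17)
  n <- 300
  genes <- sprintf("g%03d", 1:n)
  dd <- setNames(sort(runif(n)), genes)  # ranks = order in genes
  binding <- matrix(FALSE, n, 2, dimnames = list(genes, c("bcd", "kr")))
  top <- top_changed_genes(dd, 50)
  binding[top, "bcd"] <- TRUE             # all top bound, controls unbound
  binding[, "kr"] <- runif(n) < 0.3
  res <- delta_d_enrichment(dd, binding, top_n = 50, control_n = 200)
  bcd <- res[res$tf == "bcd", ]
  expect_true(bcd$or_corrected)           # zero cell -> 0.5 correction
  expect_gt(bcd$odds_ratio, 100)
  # chi2 of [[50,0],[0,200]] = 250
  expect_equal(bcd$chi2, 250)
  expect_true(bcd$significant_after_bonferroni)
  # base frequency over all genes
  expect_equal(res$base_frequency[res$tf == "bcd"], 50 / 300)
  expect_error(delta_d_enrichment(dd[1:100], binding), "eligible")
})

test_that("combinatorial binding curve bins genes and fits lines", {
  n <- 120
  genes <- sprintf("g%03d", 1:n)
  dd <- setNames(seq(0, 1, length.out = n), genes)
  all_bound <- matrix(TRUE, n, 10,
                      dimnames = list(genes, DEFAULT_TFS))
  r <- combinatorial_binding_curve(dd, all_bound, window = 50)
  expect_equal(nrow(r$windows), 2)  # remainder of 20 genes dropped
  expect_true(all(r$windows$frac_ge_3 == 1))
  expect_equal(r$fits$slope, rep(0, 7))

  # binding count increasing deterministically with delta-D rank
  inc <- matrix(FALSE, n, 10, dimnames = list(genes, DEFAULT_TFS))
  for (i in seq_len(n)) inc[i, seq_len(ceiling(10 * i / n))] <- TRUE
  r2 <- combinatorial_binding_curve(dd, inc, window = 40)
  expect_true(all(r2$fits$slope > 0))
  expect_error(combinatorial_binding_curve(dd[1:30], inc[1:30, ],
                                           window = 50), "window")
})

test_that("binding-group KS tests detect shifted groups", {
  set.seed(23)
  n <- 400
  genes <- sprintf("g%03d", 1:n)
  binding <- matrix(FALSE, n, 3,
                    dimnames = list(genes, c("bcd", "cad", "gt")))
  binding[1:40, c("bcd", "cad")] <- TRUE   # signature bcd+cad, n = 40
  binding[41:80, "gt"] <- TRUE             # signature gt, n = 40
  scores <- setNames(runif(n), genes)
  scores[1:40] <- scores[1:40] + 0.5       # bcd+cad group shifted up
  res <- binding_group_tests(binding, scores, min_group = 30)
  shifted <- res[res$signature == "bcd+cad", ]
  expect_true(shifted$significant_after_bonferroni)
  null_grp <- res[res$signature == "gt", ]
  expect_false(null_grp$significant_after_bonferroni)
  # no group large enough: empty result with warning
  expect_warning(r0 <- binding_group_tests(binding, scores,
                                           min_group = 500),
                 "min_group")
  expect_equal(nrow(r0), 0)
})
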