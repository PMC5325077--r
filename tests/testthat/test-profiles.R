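test_that("imputation averages interior neighbors and copies at edges", {
  p <- slice_profile("g", "e", c(4, 7, 8, 2, 1),
                     qc_mask = c(TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(impute_bad_slices(p)$values, c(4, 6, 8, 2, 1))

  # failed run in the interior: each slice averages its nearest usable
  # neighbor on each side
  p2 <- slice_profile("g", "e", c(4, 0, 0, 8, 1),
                      qc_mask = c(TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(impute_bad_slices(p2)$values, c(4, 6, 6, 8, 1))

  # terminal slice copies the nearest usable value
  p3 <- slice_profile("g", "e", c(99, 10, 3, 4, 5),
                      qc_mask = c(FALSE, TRUE, TRUE, TRUE, TRUE))
  expect_equal(impute_bad_slices(p3)$values, c(10, 10, 3, 4, 5))

  # identity on fully usable profiles; error when nothing is usable
  p4 <- slice_profile("g", "e", 1:5)
  expect_equal(impute_bad_slices(p4)$values, 1:5)
  p5 <- slice_profile("g", "e", 1:5, qc_mask = rep(FALSE, 5))
  expect_error(impute_bad_slices(p5), "all slices failed")
})

test_that("max_normalize uses the larger of profile max and the floor", {
  expect_equal(max_normalize(c(10, 25, 50)), c(0.2, 0.5, 1))
  expect_equal(max_normalize(c(1, 2, 4)), c(0.1, 0.2, 0.4))  # floor 10
  expect_equal(max_normalize(rep(0, 4)), rep(0, 4))
  expect_error(max_normalize(c(-1, 2)), "negative")
})

test_that("to_distribution places unit mass at slice centers", {
  d <- to_distribution(c(1, 1, 1, 1))
  expect_equal(d$positions, c(0.125, 0.375, 0.625, 0.875))
  expect_equal(d$masses, rep(0.25, 4))
  expect_false(d$all_zero)

  d2 <- to_distribution(c(0, 2, 0, 0))
  expect_equal(sum(d2$masses), 1)
  expect_equal(d2$masses[2], 1)

  z <- to_distribution(rep(0, 5))
  expect_true(z$all_zero)
  expect_error(emd(z, d), "low_expression")
  expect_error(to_distribution(c(-1, 1)), "negative")
})

test_that("EMD matches hand-computable transports", {
  n <- 10
  a <- to_distribution(c(rep(0, 0), 1, rep(0, n - 1)))
  b <- to_distribution(c(rep(0, n - 1), 1))
  # single atom moved across the embryo: distance (N-1)/N
  expect_equal(emd(a, b), (n - 1) / n)
  expect_equal(emd(a, a), 0)
  expect_equal(emd(a, b), emd(b, a))
})

test_that("CDF-integral EMD agrees with the transportation oracle", {
  set.seed(101)
  worst <- 0
  for (i in 1:300) {
    a <- random_distribution(sample(5:30, 1))
    b <- random_distribution(sample(5:30, 1))
    worst <- max(worst, abs(emd(a, b) - emd_lp_oracle(a, b)))
  }
  expect_lt(worst, 1e-9)
  # reflection symmetry: a reversed profile is equidistant from uniform
  v <- runif(12)
  expect_equal(emd_to_uniform(v), emd_to_uniform(rev(v)), tolerance = 1e-12)
  # infeasible masses rejected by the oracle
  bad <- to_distribution(c(1, 1))
  bad$masses <- c(0.2, 0.2)
  expect_error(emd_lp_oracle(bad, bad), "infeasible")
})

test_that("EMD is scale-invariant and stable under slice refinement", {
  set.seed(7)
  v <- runif(20) * 100
  w <- runif(20) * 100
  d1 <- emd(to_distribution(v), to_distribution(w))
  d2 <- emd(to_distribution(3.7 * v), to_distribution(0.2 * w))
  expect_equal(d1, d2, tolerance = 1e-12)

  # splitting every slice in two moves each atom by < 1/(2N) on average
  split2 <- function(x) rep(x, each = 2)
  d3 <- emd(to_distribution(split2(v)), to_distribution(split2(w)))
  expect_lt(abs(d3 - d1), 1 / (2 * 20))
})

test_that("emd_to_uniform scores flatness and is reduced by flattening", {
  expect_equal(emd_to_uniform(rep(7, 9)), 0)
  n <- 27
  spike <- c(rep(0, 13), 1, rep(0, 13))
  e_spike <- emd_to_uniform(spike)
  o <- emd_lp_oracle(to_distribution(spike),
                     to_distribution(rep(1, n)))
  expect_equal(e_spike, o, tolerance = 1e-12)
  expect_gt(e_spike, 0.08)

  grad <- exp(-(0:26) / 8)
  flat50 <- 0.5 * grad + 0.5 * mean(grad)
  expect_gt(emd_to_uniform(grad), emd_to_uniform(flat50))
})

test_that("adjacent slices are more similar than distant ones", {
  cfg <- tiny_cohort(n_genes = 80, sigma = 0.1, seed = 11,
                     genotypes = "wt", qc_fail_rate = 0)
  emb <- generate_cohort(cfg)$embryos[[1]]
  s <- adjacent_slice_similarity(emb$expr)
  expect_gt(s$similarity[s$offset == 1],
            s$similarity[s$offset == 10])
  expect_true(all(diff(s$similarity[s$offset <= 10]) < 0.05))

  # duplicated columns are perfectly correlated at offset 1
  m <- matrix(runif(30), 10, 3)[, c(1, 1, 1)]
  expect_equal(adjacent_slice_similarity(m)$similarity[1], 1)

  # constant embryo: correlations undefined, all offsets omitted
  flat <- matrix(5, 10, 6)
  expect_equal(nrow(adjacent_slice_similarity(flat)), 0)
})
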