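test_that("NB log mass matches the closed form and dnbinom at integers", {
  # k=2, n=5, q=0.5: C(6,2) * 0.5^7 = 15/128
  expect_equal(nb_log_pmf(2, 5, p_guide = 0.5), log(15 / 128),
               tolerance = 1e-12)
  # single-success case
  expect_equal(nb_log_pmf(0, 1, p_guide = 0.1), log(0.9), tolerance = 1e-12)
  # agreement with dnbinom on a grid of integer counts
  k <- 0:50
  expect_equal(nb_log_pmf(k, 7, 0.03),
               dnbinom(k, size = 7, prob = 0.97, log = TRUE),
               tolerance = 1e-10)
})

test_that("NB mass normalises to 1 and guards degenerate fractions", {
  for (case in list(c(n = 5, p = 0.5), c(n = 1, p = 0.1),
                    c(n = 20, p = 0.02))) {
    total <- sum(exp(nb_log_pmf(0:5000, case["n"], case["p"])))
    expect_equal(total, 1, tolerance = 1e-8)
  }
  expect_identical(nb_log_pmf(3, 10, 0), -Inf)
  expect_identical(nb_log_pmf(3, 10, 1), -Inf)
})

test_that("expected read fraction scales the library fraction by enrichment", {
  b <- sorting_bins(c("bot", "top"), c(0, 0.9), c(0.1, 1))
  # at mu = 0 the expected fraction is the library fraction, any bin
  expect_equal(expected_read_fraction(0.001, b, 0), c(0.001, 0.001))
  # enrichment in the top bin under an upshift
  expect_equal(expected_read_fraction(0.001, b[2, ], 0.5),
               0.001 * (1 - pnorm(qnorm(0.9) - 0.5)) / 0.1,
               tolerance = 1e-12)
  # absent guide: zero everywhere
  expect_equal(expected_read_fraction(0, b, 0.7), c(0, 0))
})

test_that("library fractions at mu = 0 are conserved across every bin", {
  set.seed(7)
  b <- default_bins()
  lf <- runif(50); lf <- lf / sum(lf)
  for (j in seq_len(nrow(b))) {
    tot <- sum(vapply(lf, function(f)
      expected_read_fraction(f, b[j, ], 0), numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("mu estimation recovers the null and mirrors under bin symmetry", {
  b <- default_bins()
  counts <- setNames(1000 * b$fraction, b$bin_id)
  totals <- setNames(rep(2e5, 6), b$bin_id)
  est <- estimate_guide_mu(counts, totals, lib_fraction = 0.001, bins = b)
  expect_lt(abs(est$mu_hat), 1e-3)
  expect_false(est$unquantifiable)

  # enrich the top tail: positive shift; mirrored counts negate it
  shifted <- setNames(c(40, 70, 90, 110, 130, 160), b$bin_id)
  up <- estimate_guide_mu(shifted, totals, 0.001, b)
  down <- estimate_guide_mu(setNames(rev(shifted), b$bin_id), totals,
                            0.001, b)
  expect_gt(up$mu_hat, 0.05)
  expect_equal(up$mu_hat, -down$mu_hat, tolerance = 1e-3)
  expect_equal(up$ll_ratio, down$ll_ratio, tolerance = 1e-6)
  expect_gte(up$ll_ratio, 0)
})

test_that("zero unsorted reads makes a guide unquantifiable, not an error", {
  b <- default_bins()
  est <- estimate_guide_mu(setNames(rep(10, 6), b$bin_id),
                           setNames(rep(1e5, 6), b$bin_id),
                           lib_fraction = 0, bins = b)
  expect_true(est$unquantifiable)
  expect_identical(est$mu_hat, 0)
  expect_identical(est$ll_ratio, 0)
})

test_that("optimiser agrees with a 201-point grid-search oracle", {
  set.seed(11)
  b <- default_bins()
  grid <- seq(-1, 1, length.out = 201)
  totals <- setNames(round(runif(6, 5e4, 2e5)), b$bin_id)
  for (i in 1:10) {
    lf <- runif(1, 1e-4, 2e-3)
    mu_true <- runif(1, -0.9, 0.9)
    counts <- setNames(rpois(6, totals * pmin(0.99,
      lf * bin_occupancy(b, mu_true) / b$fraction)), b$bin_id)
    est <- estimate_guide_mu(counts, totals, lf, b)
    # oracle: full NB log-mass summed per grid point, pseudocounted the
    # same way, maximised by enumeration
    k <- counts + 10 * totals / 1e6
    ll <- vapply(grid, function(m)
      sum(nb_log_pmf(k, totals,
                     lf * bin_occupancy(b, m) / b$fraction)), numeric(1))
    oracle_mu <- grid[which.max(ll)]
    expect_lt(abs(est$mu_hat - oracle_mu), diff(grid)[1] + 1e-9)
  }
})

test_that("simulated guides at mu = 0.5 are recovered within 0.1 on average", {
  b <- default_bins()
  set.seed(21)
  # guide of interest at mu = 0.5 with ~1000 cells and 10x reads, embedded
  # in a 200-guide screen that supplies the bin read totals
  A <- rep(1000, 200)
  eff <- c(0.5, rep(0, 199))
  ests <- replicate(100, {
    cells <- simulate_sorted_cells(A, b, mu = eff)
    rd <- simulate_reads(cells, A, 10)
    totals <- setNames(colSums(rd$reads), b$bin_id)
    estimate_guide_mu(setNames(rd$reads[1, ], b$bin_id), totals,
                      lib_fraction = rd$unsorted[1] / sum(rd$unsorted),
                      bins = b)$mu_hat
  })
  expect_lt(abs(mean(ests) - 0.5), 0.1)
})

test_that("shifting reads from bottom to top bin never decreases mu_hat", {
  b <- default_bins()
  totals <- setNames(rep(1e5, 6), b$bin_id)
  base <- setNames(rep(100, 6), b$bin_id)
  prev <- -Inf
  for (d in seq(0, 90, by = 10)) {
    counts <- base
    counts["A"] <- base["A"] - d
    counts["F"] <- base["F"] + d
    est <- estimate_guide_mu(counts, totals, 0.001, b)
    expect_gte(est$mu_hat, prev - 1e-6)
    prev <- est$mu_hat
  }
})
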