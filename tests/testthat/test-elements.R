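test_that("Stouffer combination is sum over root-n", {
  expect_equal(stouffer_combine(c(2, 2, 2, 2)), 4)
  expect_equal(stouffer_combine(3.1), 3.1)
  expect_equal(stouffer_combine(c(1, -1)), 0)
  expect_error(stouffer_combine(numeric(0)), "empty")
})

test_that("resampled control null has unit SD for standard-normal controls", {
  set.seed(100)
  ctrl <- rnorm(500)
  null <- build_null_model(ctrl, k_values = c(4, 5), n_draws = 10000,
                           seed = 1)
  # Stouffer of k iid standard normals is standard normal
  expect_equal(unname(null$sd[["4"]]), 1, tolerance = 0.05)
  expect_equal(unname(null$sd[["5"]]), 1, tolerance = 0.05)
})

test_that("degenerate or exhausted control pools are rejected", {
  expect_error(build_null_model(rep(0.7, 20), k_values = 3, seed = 1),
               "degenerate|zero variance")
  expect_error(build_null_model(rnorm(5), k_values = 100, seed = 1),
               "pool")
  # resample_factor 1 with k = pool size: every draw is the whole pool
  expect_error(build_null_model(rnorm(4), k_values = 4, resample_factor = 1,
                                n_draws = 100, seed = 1),
               "degenerate|zero variance")
  expect_error(build_null_model(0.5, k_values = 2), "at least 2")
})

test_that("element significance scales by the null SD and converts to tails", {
  null <- structure(list(sd = c(`4` = 1, `2` = 1.5)), class = "control_null")
  r <- element_significance(c(0.5, 0.5, 0.5, 0.5), null)  # stouffer = 1
  expect_equal(r$stouffer_z, 1)
  expect_equal(r$significance_z, 1)
  expect_equal(r$p_up, pnorm(1, lower.tail = FALSE))
  null2 <- structure(list(sd = c(`1` = 1)), class = "control_null")
  r3 <- element_significance(2, null2)
  expect_equal(r3$significance_z, 2)
  expect_equal(r3$p_up, 0.02275013, tolerance = 1e-6)
  r4 <- element_significance(0, null2)
  expect_equal(r4$p_up, 0.5)
  expect_equal(r4$p_down, 0.5)
  null3 <- structure(list(sd = c(`3` = 1.5)), class = "control_null")
  r5 <- element_significance(c(-3, -3, -3) / sqrt(3), null3)
  expect_equal(r5$significance_z, -2)
  expect_equal(r5$p_down, 0.02275013, tolerance = 1e-6)
  expect_equal(r5$p_either, 2 * r5$p_down)
  expect_error(element_significance(c(1, 1), null2), "no entry")
})

test_that("annotated elements group by label and respect min_guides", {
  g <- rbind(guide_results(rep(1, 5), element_label = "E1"),
             guide_results(rep(-0.5, 4), element_label = "E2"),
             guide_results(rnorm(30, sd = 0.3), is_negative_control = TRUE))
  g$guide_id <- sprintf("g%03d", seq_len(nrow(g)))
  expect_warning(
    el <- element_stats(g, by = "annotation", min_guides = 5,
                        n_draws = 2000, seed = 5),
    "fewer than 5")
  expect_equal(el$element_id, "E1")
  expect_equal(el$n_guides, 5)
  expect_equal(el$effect_z, 1)
  expect_equal(el$stouffer_z, sqrt(5) * 1)
  expect_true(all(c("fdr_up", "fdr_down", "fdr_either") %in% names(el)))
})

test_that("an element measured in two experiments yields two results", {
  g1 <- rbind(guide_results(rep(0.8, 5), element_label = "E1",
                            experiment_id = "r1"),
              guide_results(rnorm(20, sd = 0.2), is_negative_control = TRUE,
                            experiment_id = "r1"))
  g2 <- g1
  g2$experiment_id <- "r2"
  g <- rbind(g1, g2)
  g$guide_id <- paste0(g$guide_id, "_", g$experiment_id)
  el <- element_stats(g, by = "annotation", n_draws = 2000, seed = 5)
  expect_equal(nrow(el), 2)
  expect_setequal(el$experiment_id, c("r1", "r2"))
})

test_that("sliding windows match the brute-force enumeration oracle", {
  # spec'd small cases first
  g <- guide_results(rnorm(5), chrom = "chr1", pos = c(100, 200, 300, 400, 500))
  ws <- sortshift:::window_guide_sets(g, 500, 5)
  expect_length(ws$rows, 1)
  expect_equal(ws$meta$start, 100)
  expect_equal(ws$meta$end, 500)

  g2 <- guide_results(rnorm(2), chrom = "chr1", pos = c(100, 10000))
  expect_length(sortshift:::window_guide_sets(g2, 500, 2)$rows, 0)

  g3 <- guide_results(rnorm(6), chrom = "chr1", pos = seq(0, 500, 100))
  ws3 <- sortshift:::window_guide_sets(g3, 500, 5)
  expect_length(ws3$rows, 2)
  expect_true(all(lengths(ws3$rows) >= 5))

  # property: random instances up to 50 guides, several widths
  set.seed(77)
  for (i in 1:8) {
    n <- sample(10:50, 1)
    g <- guide_results(rnorm(n),
                       chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                       pos = sample(1:3000, n))
    w <- sample(c(200, 500, 1000), 1)
    k <- sample(2:5, 1)
    ws <- sortshift:::window_guide_sets(g, w, k)
    got <- sort(vapply(ws$rows, function(idx)
      paste(sort(g$guide_id[idx]), collapse = "|"), character(1)))
    expect_identical(got, brute_force_windows(g, w, k))
  }
})

test_that("window mode demands positions; annotation mode demands labels", {
  g <- guide_results(rnorm(10))
  expect_error(element_stats(g, by = "window"), "chrom/pos")
  g2 <- guide_results(rnorm(10))
  g2$element_label <- NULL
  expect_error(element_stats(g2, by = "annotation"), "element_label")
})

test_that("element results are invariant to guide input order", {
  set.seed(12)
  g <- rbind(guide_results(rnorm(25, 0.5), chrom = "chr1",
                           pos = sort(sample(1:2000, 25)),
                           element_label = rep(paste0("E", 1:5), each = 5)),
             guide_results(rnorm(40, sd = 0.4), is_negative_control = TRUE))
  g$guide_id <- sprintf("g%03d", seq_len(nrow(g)))
  perm <- sample(nrow(g))
  for (mode in c("annotation", "window")) {
    a <- element_stats(g, by = mode, n_draws = 1000, seed = 9)
    b <- element_stats(g[perm, ], by = mode, n_draws = 1000, seed = 9)
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a, b)
  }
})

test_that("scaled control-only pseudo-elements have unit SD null", {
  set.seed(55)
  ctrl_z <- rnorm(300, sd = 0.7)  # over/under-dispersion is the point
  null <- build_null_model(ctrl_z, k_values = c(3, 5, 8), n_draws = 10000,
                           seed = 2)
  pool <- rep(ctrl_z, each = 10)
  for (k in c(3, 5, 8)) {
    draws <- replicate(10000, sum(sample(pool, k)) / sqrt(k))
    scaled <- draws / null$sd[[as.character(k)]]
    expect_equal(sd(scaled), 1, tolerance = 0.05)
  }
})

test_that("per-experiment BH adjustment matches the textbook step-up", {
  expect_equal(bh_stepup(c(0.01, 0.02, 0.03, 0.5)),
               c(0.04, 0.04, 0.04, 0.5))
  set.seed(31)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), bh_stepup(p), tolerance = 1e-12)
  }
  # grouping: two experiments adjusted independently
  g <- rbind(guide_results(rep(2, 5), element_label = "E1",
                           experiment_id = "r1"),
             guide_results(rnorm(30, sd = 0.5), is_negative_control = TRUE,
                           experiment_id = "r1"),
             guide_results(rep(0.1, 5), element_label = "E1",
                           experiment_id = "r2"),
             guide_results(rnorm(30, sd = 0.5), is_negative_control = TRUE,
                           experiment_id = "r2"))
  g$guide_id <- sprintf("g%03d", seq_len(nrow(g)))
  el <- element_stats(g, by = "annotation", n_draws = 2000, seed = 4)
  for (ex in c("r1", "r2")) {
    sub <- el[el$experiment_id == ex, ]
    expect_equal(sub$fdr_either, bh_stepup(sub$p_either))
  }
})

test_that("replicate combination enforces FDR in all and consistent sign", {
  base <- data.frame(element_id = c("E1", "E2", "E3"),
                     effect_z = c(0.3, 0.3, 0.3),
                     stringsAsFactors = FALSE)
  make <- function(ex, fdr, eff) {
    d <- base
    d$experiment_id <- ex
    d$fdr_either <- fdr
    d$effect_z <- eff
    d
  }
  el <- rbind(make("r1", c(0.005, 0.005, 0.005), c(0.3, 0.3, 0.3)),
              make("r2", c(0.005, 0.5, 0.005), c(0.2, 0.2, -0.2)))
  called <- combine_replicates(el, fdr_threshold = 0.01)
  expect_equal(called$element_id, "E1")
  expect_equal(called$direction, "up")
  # sign conflict tolerated when not required
  loose <- combine_replicates(el, fdr_threshold = 0.01,
                              require_consistent_sign = FALSE)
  expect_setequal(loose$element_id, c("E1", "E3"))
  expect_error(combine_replicates(el[el$experiment_id == "r1", ]), ">= 2")
})
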