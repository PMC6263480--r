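# Accuracy metrics, optimal-percentile search and derived statistics.

test_that("rmse, bias and r_squared follow their definitions", {
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(1, 3), c(2, 2)), 1.0)
  expect_equal(rmse(c(2, 3), c(1, 2)), 1.0)   # constant offset c -> |c|
  expect_equal(bias(c(1, 3), c(2, 2)), 0)     # errors cancel
  expect_equal(bias(c(1, 2) - 0.07, c(1, 2)), -0.07)
  expect_error(rmse(1:3, 1:2), "length mismatch")

  ref <- c(1, 2, 4)
  expect_equal(r_squared(ref, ref), 1)
  expect_equal(r_squared(2 * ref + 5, ref), 1)  # affine invariance
  est <- c(1, 2, 3)
  cov_form <- (sum((est - mean(est)) * (ref - mean(ref))) / 2)^2 /
    (stats::var(est) * stats::var(ref))
  expect_equal(r_squared(est, ref), cov_form, tolerance = 1e-12)
  expect_error(r_squared(c(1, 1, 1), ref), "constant")
  # identity-line convention penalizes offset fits
  expect_lt(r_squared(ref + 1, ref, convention = "identity"), 1)
})

test_that("the rmse decomposition identity holds", {
  for (s in 1:20) {
    e <- canopyscan:::with_seed(s, stats::rnorm(50))
    r <- canopyscan:::with_seed(s + 100, stats::rnorm(50))
    n <- length(e)
    expect_equal(rmse(e, r)^2,
                 bias(e, r)^2 + mean((e - r - mean(e - r))^2),
                 tolerance = 1e-12)
  }
})

test_that("campaigns map to manual methods per the trial design", {
  expect_identical(campaign_method(1:5), c("A", "A", "B", "B", "B"))
  expect_error(campaign_method(6), "1..5")
})

test_that("optimal_percentile scans the grid, breaks ties low, reports both optima", {
  # single plot whose ladder contains the reference exactly at 82%
  grid <- 1:100
  heights <- 0.5 + grid / 200
  ladders <- data.frame(plot_id = 1, percentile = grid, height = heights)
  ref <- data.frame(plot_id = 1, height_m = heights[82])
  opt <- optimal_percentile(ladders, ref)
  expect_identical(opt$percentile, 82L)
  expect_equal(opt$rmse, 0)

  # two percentiles with equal RMSE: the lower one wins
  lad2 <- data.frame(plot_id = 1, percentile = c(1, 2, 3),
                     height = c(0.4, 0.4, 0.6))
  ref2 <- data.frame(plot_id = 1, height_m = 0.4)
  expect_identical(optimal_percentile(lad2, ref2)$percentile, 1)

  # reported minimum equals a brute-force scan over the grid
  seeds <- 1:6
  lads <- do.call(rbind, lapply(seeds, function(i) {
    h <- canopyscan:::with_seed(i, sort(stats::runif(10, 0.2, 1)))
    data.frame(plot_id = i, percentile = seq(10, 100, by = 10), height = h)
  }))
  refs <- data.frame(plot_id = seeds,
                     height_m = canopyscan:::with_seed(99, stats::runif(6, 0.4, 0.9)))
  opt3 <- optimal_percentile(lads, refs)
  brute <- vapply(seq(10, 100, by = 10), function(p) {
    est <- lads$height[lads$percentile == p][match(refs$plot_id,
                                                   lads$plot_id[lads$percentile == p])]
    rmse(est, refs$height_m)
  }, numeric(1))
  expect_equal(opt3$rmse, min(brute), tolerance = 1e-12)
  expect_equal(opt3$percentile, seq(10, 100, by = 10)[which.min(brute)])
  expect_true(!is.null(opt3$r2_percentile))

  expect_error(optimal_percentile(lads, refs[0, ]), "empty selection")
})

test_that("category and position filters honor the reference metadata", {
  grid <- c(50, 100)
  lads <- do.call(rbind, lapply(1:4, function(i) {
    data.frame(plot_id = i, campaign = c(1, 1, 3, 3)[i],
               position = c("side", "middle")[i %% 2 + 1],
               percentile = grid, height = c(0.4, 0.5) + i / 100)
  }))
  ref <- data.frame(plot_id = 1:4, campaign = c(1, 1, 3, 3),
                    height_m = c(0.51, 0.52, 0.43, 0.44))
  oA <- optimal_percentile(lads, ref, "A")
  oB <- optimal_percentile(lads, ref, "B")
  expect_identical(oA$n, 2L)
  expect_identical(oB$n, 2L)
  expect_identical(oA$percentile, 100)  # references near the top rung
  expect_identical(oB$percentile, 50)
  o_side <- optimal_percentile(lads, ref, "all", "middle")
  expect_identical(o_side$n, 2L)
})

test_that("derived percentage statistics reproduce their printed values", {
  expect_identical(percent_reduction(0.0643, 0.0354), 44.95)
  expect_identical(percent_reduction(0.0467, 0.0407), 12.85)
  expect_identical(percent_reduction(0.05, 0.05), 0)
  expect_error(percent_reduction(0, 0.1), "rmse_raw")

  expect_identical(percent_exceed(0.0657, 0.0398), 65.08)
  expect_identical(percent_exceed(0.0657, 0.0478), 37.45)
  expect_identical(percent_exceed(0.3, 0.3), 0)
  expect_error(percent_exceed(0.1, 0), "> 0")
})

test_that("the position-pooling penalty averages per-category RMSE increases", {
  tab3 <- list(list(combined_rmse = 0.0478, side_rmse = 0.0436,
                    middle_rmse = 0.0491),
               list(combined_rmse = 0.0398, side_rmse = 0.0395,
                    middle_rmse = 0.0327))
  expect_identical(average_rmse_increase(tab3), 0.0026)
  expect_identical(average_rmse_increase(list(list(combined_rmse = 0.05,
                                                   side_rmse = 0.04,
                                                   middle_rmse = 0.04))),
                   0.01)
  balanced <- list(list(combined_rmse = 0.04, side_rmse = 0.03,
                        middle_rmse = 0.05))
  expect_identical(average_rmse_increase(balanced), 0)
  expect_error(average_rmse_increase(list()), "empty")
})

test_that("round_half_up rounds halves away from zero", {
  expect_identical(round_half_up(0.002575, 4), 0.0026)
  expect_identical(round_half_up(2.5, 0), 3)
  expect_identical(round_half_up(-2.5, 0), -3)
  expect_identical(round_half_up(44.945, 2), 44.95)
})

test_that("comparison reports score perfect estimates perfectly and repeat exactly", {
  ref <- data.frame(plot_id = rep(1:5, 2), campaign = rep(c(1, 3), each = 5),
                    height_m = canopyscan:::with_seed(7, stats::runif(10, 0.3, 1)))
  us <- data.frame(plot_id = ref$plot_id, campaign = ref$campaign,
                   height_m = ref$height_m)
  rep1 <- build_comparison_report(ultrasonic = us, ref = ref)
  expect_equal(rep1$sensors$rmse, 0)
  expect_equal(rep1$sensors$r_squared, 1)
  rep2 <- build_comparison_report(ultrasonic = us, ref = ref)
  expect_identical(serialize(rep1, NULL), serialize(rep2, NULL))
})
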