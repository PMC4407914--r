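test_that("disparity matches hand values and the brute-force oracle", {
  expect_identical(disparity(c(3, 3, 3)), 0)
  expect_identical(disparity(c(0, 1)), 1)
  expect_equal(disparity(c(0, 1, 2)), 2)
  expect_identical(disparity(numeric(0)), 0)
  expect_identical(disparity(5), 0)
  set.seed(14)
  m <- matrix(rnorm(20), 10, 2)
  expect_equal(disparity(m), oracle_disparity(m), tolerance = 1e-12)
  v <- rnorm(25)
  expect_equal(disparity(v), oracle_disparity(v), tolerance = 1e-12)
  expect_error(disparity(c(1, NA)), "finite")
})

test_that("dtt reproduces the worked four-tip example", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  x <- c(A = 0, B = 2, C = 10, D = 12)
  got <- dtt(tr, x)
  expect_equal(got$rel_time, c(0, 0.5))
  d_tot <- (4 + 100 + 144 + 64 + 100 + 4) / 6
  expect_equal(got$disparity, c(1, mean(c(4, 4)) / d_tot), tolerance = 1e-12)
})

test_that("dtt of a two-tip tree is the single root point", {
  tr <- ape::read.tree(text = "(A:3,B:3);")
  got <- dtt(tr, c(A = 1, B = 4))
  expect_equal(got$rel_time, 0)
  expect_equal(got$disparity, 1)
  expect_equal(attr(got, "crown_age"), 3)
})

test_that("dtt validates inputs", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_error(dtt(tr, c(A = 1, B = 2, C = 3)), "D")
  expect_error(dtt(tr, c(A = 1, B = 1, C = 1, D = 1)), "degenerate")
})

test_that("dtt under Brownian motion starts at 1 and trends down", {
  tr <- sim_conditioned_tree(15, 100, 0.25, seed = 31)
  set.seed(32)
  curves <- replicate(40, {
    x <- sim_trait(tr, sigma2 = 1)
    dtt(tr, x)$disparity
  })
  expect_true(all(curves[1, ] == 1))
  avg <- rowMeans(curves)
  expect_true(all(avg >= 0 & avg < 1.5))
  third <- floor(length(avg) / 3)
  expect_lt(mean(avg[(length(avg) - third):length(avg)]),
            mean(avg[1:third]))
})

test_that("mdi matches trivial rectangles and the step-integration oracle", {
  mk <- function(t, v, ca = 10) radburst:::new_dtt(t, v, ca)
  obs <- mk(c(0, 0.4), c(1, 0.2))
  expect_identical(mdi(obs, obs), 0)
  expect_equal(mdi(mk(0, 1), mk(0, 0), t_max = 0.9), 0.9)
  a <- mk(c(0, 0.3), c(1, 0.5))
  b <- mk(c(0, 0.6), c(0.8, 0.1))
  grid <- sort(unique(c(a$rel_time, b$rel_time)))
  av <- c(1, 0.5, 0.5)
  bv <- c(0.8, 0.8, 0.1)
  expect_equal(mdi(a, b, 0.9),
               oracle_step_integral(grid, av - bv, 0.9), tolerance = 1e-12)
  expect_error(mdi(mk(0, 1, ca = 10), mk(0, 1, ca = 12)), "crown")
  expect_error(mdi(a, b, t_max = 0), "t_max")
})

test_that("MDI is invariant under affine transformation of the traits", {
  tr <- sim_conditioned_tree(15, 40, 0.3, seed = 41)
  x <- sim_trait(tr, sigma2 = 2, seed = 42)
  y <- dplyr::mutate(x, value = 3.7 * value - 11)
  expect_equal(dtt(tr, x)$disparity, dtt(tr, y)$disparity, tolerance = 1e-12)
  n0 <- dtt_null(tr, x, model = "bm", n_sims = 30, seed = 7)
  n1 <- dtt_null(tr, y, model = "bm", n_sims = 30, seed = 7)
  expect_equal(n0$mdi, n1$mdi, tolerance = 1e-9)
  expect_equal(n0$curve$null_median, n1$curve$null_median, tolerance = 1e-9)
})

test_that("null envelopes are ordered and evaluated on the observed node times", {
  tr <- sim_conditioned_tree(15, 30, 0.3, seed = 51)
  x <- sim_trait(tr, sigma2 = 1, seed = 52)
  nv <- dtt_null(tr, x, model = "bm", n_sims = 50, seed = 53)
  expect_equal(nv$curve$rel_time, dtt(tr, x)$rel_time)
  expect_true(all(nv$curve$q05 <= nv$curve$null_median + 1e-12))
  expect_true(all(nv$curve$null_median <= nv$curve$q95 + 1e-12))
  expect_equal(nv$curve$observed[1], 1)
  g <- glance(nv)
  expect_identical(g$mdi, nv$mdi)
})

test_that("an OU null raises late-time disparity above the BM null", {
  tr <- sim_conditioned_tree(15, 80, 0.25, seed = 61)
  x <- sim_trait(tr, sigma2 = 1, alpha = 0.25, seed = 62)
  bm <- dtt_null(tr, x, model = "bm", n_sims = 80, seed = 63)
  ou <- dtt_null(tr, x, model = "ou", n_sims = 80, seed = 63)
  late <- bm$curve$rel_time > 0.6
  expect_gt(mean(ou$curve$null_median[late] - bm$curve$null_median[late]), 0)
})
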