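test_that("zero-diffusion simulation follows the deterministic OU mean", {
  tr <- sim_conditioned_tree(15, 10, 0.3, seed = 3)
  # alpha = 0: every tip keeps the root state
  bm <- sim_trait(tr, sigma2 = 0, x0 = 0.7, seed = 1)
  expect_true(all(bm$value == 0.7))
  # alpha > 0: tips decay towards theta over the root-tip time
  ou <- sim_trait(tr, sigma2 = 0, alpha = 0.2, theta = 1, x0 = 0.7, seed = 1)
  expected <- 0.7 * exp(-0.2 * 15) + 1 * (1 - exp(-0.2 * 15))
  expect_equal(ou$value, rep(expected, 10), tolerance = 1e-12)
})

test_that("alpha = 0 path reproduces a dedicated BM oracle draw-for-draw", {
  tr <- sim_conditioned_tree(12, 30, 0.3, seed = 7)
  got <- sim_trait(tr, sigma2 = 1.7, x0 = -2, seed = 99)
  oracle <- oracle_bm_sim(tr, sigma2 = 1.7, x0 = -2, seed = 99)
  expect_identical(setNames(got$value, got$species), oracle)
})

test_that("window validation catches overlap and out-of-range ages", {
  tr <- sim_conditioned_tree(15, 6, 0.3, seed = 2)
  bad <- tibble::tibble(start_age = c(0, 4), end_age = c(5, 9),
                        multiplier = c(10, 10))
  expect_error(sim_trait(tr, windows = bad), "overlap")
  expect_error(
    sim_trait(tr, windows = tibble::tibble(start_age = 10, end_age = 20,
                                           multiplier = 10)),
    "crown age"
  )
  expect_error(
    sim_trait(tr, windows = tibble::tibble(start_age = 0, end_age = 5,
                                           multiplier = -1)),
    "multiplier"
  )
})

test_that("stage windows convert before-present intervals to root-forward thirds", {
  expect_null(stage_windows("none"))
  early <- stage_windows("early", crown_age = 15)
  expect_equal(c(early$start_age, early$end_age), c(0, 5))
  late <- stage_windows("late", crown_age = 15)
  expect_equal(c(late$start_age, late$end_age), c(10, 15))
})

test_that("an early rate window inflates tip variance beyond the homogeneous case", {
  tr <- sim_conditioned_tree(15, 60, 0.25, seed = 21)
  set.seed(42)
  v_hom <- mean(replicate(30, var(sim_trait(tr, sigma2 = 1)$value)))
  v_burst <- mean(replicate(30, {
    var(sim_trait(tr, sigma2 = 1, windows = stage_windows("early"))$value)
  }))
  expect_gt(v_burst, v_hom)
})

test_that("splitting a branch at a non-window point leaves the marginal law unchanged", {
  # Chapman-Kolmogorov: a multiplier-1 window boundary only splits segments
  two <- ape::read.tree(text = "(A:15,B:15);")
  w <- tibble::tibble(start_age = 0, end_age = 6.37, multiplier = 1)
  set.seed(11)
  plain <- as.vector(replicate(4000, sim_trait(two, sigma2 = 1, alpha = 0.2,
                                               theta = 0, x0 = 5)$value))
  set.seed(12)
  split <- as.vector(replicate(4000, sim_trait(two, sigma2 = 1, alpha = 0.2,
                                               theta = 0, x0 = 5,
                                               windows = w)$value))
  m_true <- 5 * exp(-0.2 * 15)
  v_true <- (1 - exp(-2 * 0.2 * 15)) / (2 * 0.2)
  for (x in list(plain, split)) {
    n <- length(x)
    expect_lt(abs(mean(x) - m_true), 3 * sd(x) / sqrt(n))
    expect_lt(abs(var(x) - v_true), 3 * v_true * sqrt(2 / (n - 1)))
  }
})

test_that("star-tree tip variance approaches the OU stationary variance", {
  star <- ape::stree(40, "star")
  star$edge.length <- rep(60, 40)  # >> 1/(2 alpha): effectively stationary
  set.seed(33)
  vals <- unlist(replicate(40, sim_trait(star, sigma2 = 1, alpha = 0.25,
                                         theta = 0, x0 = 0)$value,
                           simplify = FALSE))
  v_stat <- 1 / (2 * 0.25)
  expect_lt(abs(var(vals) - v_stat),
            3 * v_stat * sqrt(2 / (length(vals) - 1)))
})

test_that("recorded internal states are consistent with their descendant tips", {
  tr <- ape::read.tree(text = "((A:5,B:5):10,C:15);")
  alpha <- 0.15
  set.seed(8)
  pairs <- t(replicate(4000, {
    sim <- sim_trait(tr, sigma2 = 1, alpha = alpha, include_internal = TRUE)
    c(node = sim$value[sim$species == "node5"],
      tip = sim$value[sim$species == "A"])
  }))
  # conditional on the internal state x, tip A is OU over 5 myr from x
  resid <- pairs[, "tip"] - pairs[, "node"] * exp(-alpha * 5)
  v_true <- (1 - exp(-2 * alpha * 5)) / (2 * alpha)
  n <- nrow(pairs)
  expect_lt(abs(mean(resid)), 3 * sd(resid) / sqrt(n))
  expect_lt(abs(var(resid) - v_true), 3 * v_true * sqrt(2 / (n - 1)))
})

test_that("trait simulation is reproducible and tied to the seed", {
  tr <- sim_conditioned_tree(15, 20, 0.3, seed = 2)
  expect_identical(sim_trait(tr, sigma2 = 2, alpha = 0.1, seed = 5),
                   sim_trait(tr, sigma2 = 2, alpha = 0.1, seed = 5))
  expect_false(identical(sim_trait(tr, sigma2 = 2, seed = 5)$value,
                         sim_trait(tr, sigma2 = 2, seed = 6)$value))
})
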