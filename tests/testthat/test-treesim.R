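test_that("pure-birth forward simulation gives binary ultrametric trees of the right age", {
  tr <- sim_bd_tree(0.3, 0, 15, seed = 11)
  expect_s3_class(tr, "phylo")
  expect_true(is_ultrametric_tree(tr))
  expect_equal(crown_age(tr), 15, tolerance = 1e-12)
  # no extinction under Yule: node count = 2 tips - 1, all lengths positive
  expect_identical(ape::Ntip(tr) + tr$Nnode, 2L * ape::Ntip(tr) - 1L)
  expect_true(all(tr$edge.length > 0))
  expect_false(anyDuplicated(tr$tip.label) > 0)
})

test_that("Yule mean tip count matches 2 exp(lambda T)", {
  set.seed(21)
  n <- replicate(1000, {
    length(radburst:::.yule_event_times(0.3, 15, n0 = 2L)) + 2L
  })
  # E[N] = 2 e^(4.5) ~ 180.1; allow 3 Monte-Carlo SEs
  expect_lt(abs(mean(n) - 2 * exp(0.3 * 15)), 3 * sd(n) / sqrt(length(n)))
})

test_that("critical birth-death simulations go extinct on long horizons", {
  set.seed(5)
  extinct <- vapply(1:20, function(i) is.null(sim_bd_tree(0.3, 0.3, 200)),
                    logical(1))
  expect_gt(mean(extinct), 0.8)
})

test_that("birth-death trees are pruned to extant tips and keep the crown age", {
  set.seed(31)
  got_one <- FALSE
  for (i in 1:20) {
    tr <- sim_bd_tree(0.25, 0.1, 12)
    if (is.null(tr)) next
    got_one <- TRUE
    expect_true(is_ultrametric_tree(tr))
    expect_equal(crown_age(tr), 12, tolerance = 1e-9)
  }
  expect_true(got_one)
})

test_that("invalid rates are rejected", {
  expect_error(sim_bd_tree(-1, 0, 10), "lambda")
  expect_error(sim_bd_tree(0.2, -0.1, 10), "mu")
  expect_error(sim_bd_tree(0.2, 0, -5), "crown_age")
  expect_error(sim_conditioned_tree(15, 1, 0.2), "n_tips")
  expect_error(sim_conditioned_tree(15, 10, c(0.4, 0.1)), "low < high")
})

test_that("conditioned trees have exactly the requested tips and crown age", {
  for (seed in 1:5) {
    tr <- sim_conditioned_tree(15, 40, c(0.1, 0.4), seed = seed)
    expect_identical(ape::Ntip(tr), 40L)
    expect_equal(crown_age(tr), 15, tolerance = 1e-9)
    expect_true(is_ultrametric_tree(tr))
  }
  # near-zero rate: a two-tip tree is two straight branches
  tr2 <- sim_conditioned_tree(10, 2, 1e-6, seed = 1)
  expect_identical(ape::Ntip(tr2), 2L)
  expect_equal(sort(tr2$edge.length), c(10, 10), tolerance = 1e-12)
})

test_that("simulators are bit-reproducible given a seed", {
  expect_identical(sim_bd_tree(0.3, 0.1, 12, seed = 7),
                   sim_bd_tree(0.3, 0.1, 12, seed = 7))
  expect_identical(sim_conditioned_tree(15, 30, c(0.1, 0.4), seed = 3),
                   sim_conditioned_tree(15, 30, c(0.1, 0.4), seed = 3))
  t1 <- sim_conditioned_tree(15, 30, 0.25, seed = 3)
  t2 <- sim_conditioned_tree(15, 30, 0.25, seed = 4)
  expect_false(identical(t1$edge.length, t2$edge.length))
})

test_that("conditioning acceptance rate matches the analytic crown pure-birth law", {
  set.seed(17)
  attempts <- vapply(1:30, function(i) {
    attr(sim_conditioned_tree(15, 100, 0.26), "attempts")
  }, numeric(1))
  p_hat <- length(attempts) / sum(attempts)
  p_true <- oracle_yule_crown_pmf(100, 0.26, 15)
  expect_gt(p_hat, p_true / 2)
  expect_lt(p_hat, p_true * 2)
})

test_that("Yule tip counts follow the analytic crown distribution (chi-square)", {
  set.seed(23)
  lambda <- 0.26
  t_crown <- 15
  n <- vapply(1:5000, function(i) {
    length(radburst:::.yule_event_times(lambda, t_crown, n0 = 2L)) + 2L
  }, integer(1))
  breaks <- c(0, 40, 60, 80, 100, 120, 150, 200, Inf)
  obs <- table(cut(n, breaks))
  probs <- vapply(seq_len(length(breaks) - 1), function(i) {
    sum(oracle_yule_crown_pmf(
      seq(max(2, floor(breaks[i]) + 1), min(breaks[i + 1], 3000)),
      lambda, t_crown
    ))
  }, numeric(1))
  gof <- suppressWarnings(
    stats::chisq.test(as.vector(obs), p = probs / sum(probs))
  )
  expect_gt(gof$p.value, 0.01)
})

test_that("ltt starts at 2 lineages at the root and steps at node ages", {
  two <- ape::read.tree(text = "(A:5,B:5);")
  expect_equal(as.data.frame(ltt(two)),
               data.frame(age = 0, age_bp = 5, lineages = 2))
  three <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  got <- ltt(three)
  expect_equal(got$age, c(0, 1))
  expect_equal(got$lineages, c(2, 3))
  expect_error(ltt(ape::read.tree(text = "((A:1,B:2):1,C:2);")),
               "ultrametric")
})

test_that("log-lineage growth of Yule trees follows the analytic crown law", {
  set.seed(9)
  lambda <- 0.3
  ages <- c(5, 10, 15)
  # exact E[log N(t)] under the crown pure-birth tip-count law
  e_log <- vapply(ages, function(t) {
    n <- 2:20000
    sum(log(n) * oracle_yule_crown_pmf(n, lambda, t))
  }, numeric(1))
  # the exact mean log curve is linear in t with slope ~ lambda (the small
  # deficit is the finite-size concavity of log of a stochastic exponential)
  expect_lt(abs((e_log[3] - e_log[1]) / 10 - lambda), 0.05 * lambda)
  log_n <- replicate(300, {
    lt <- ltt(sim_bd_tree(lambda, 0, 15))
    vapply(ages, function(t) log(max(lt$lineages[lt$age <= t + 1e-9])),
           numeric(1))
  })
  for (i in seq_along(ages)) {
    se <- sd(log_n[i, ]) / sqrt(ncol(log_n))
    expect_lt(abs(mean(log_n[i, ]) - e_log[i]), 3 * se)
  }
})
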