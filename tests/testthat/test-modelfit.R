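test_that("two-tip BM likelihood equals the bivariate normal closed form", {
  tr <- ape::read.tree(text = "(A:4,B:4);")
  x <- c(A = 1.3, B = -0.4)
  s2 <- 0.8
  z0 <- 0.2
  closed <- sum(dnorm(x, z0, sqrt(s2 * 4), log = TRUE))
  expect_equal(bm_loglik(tr, x, s2, z0), closed, tolerance = 1e-12)
  expect_equal(bm_loglik(tr, x, s2, z0, method = "dense"), closed,
               tolerance = 1e-12)
})

test_that("single-branch OU likelihood matches the transition density", {
  tr <- ape::read.tree(text = "(A:7,B:7);")
  x <- c(A = 0.9, B = 2.1)
  a <- 0.3
  s2 <- 1.4
  z0 <- 1
  v <- s2 * (1 - exp(-2 * a * 7)) / (2 * a)
  closed <- sum(dnorm(x, z0, sqrt(v), log = TRUE))
  expect_equal(ou_loglik(tr, x, s2, a, z0), closed, tolerance = 1e-10)
})

test_that("dense and pruning likelihoods agree on random trees", {
  for (seed in 1:3) {
    tr <- sim_conditioned_tree(15, 50, 0.3, seed = seed)
    x <- sim_trait(tr, sigma2 = 1.2, alpha = 0.1, seed = seed + 100)
    xv <- setNames(x$value, x$species)
    expect_equal(bm_loglik(tr, xv, 0.9, 0.3),
                 bm_loglik(tr, xv, 0.9, 0.3, method = "dense"),
                 tolerance = 1e-8)
    expect_equal(ou_loglik(tr, xv, 0.9, 0.25, 0.3),
                 ou_loglik(tr, xv, 0.9, 0.25, 0.3, method = "dense"),
                 tolerance = 1e-8)
  }
})

test_that("the OU covariance matches an explicit root-path construction", {
  tr <- sim_conditioned_tree(10, 5, 0.3, seed = 5)
  V_pkg <- radburst:::.ou_vcv(tr, 1.3, 0.22)
  V_oracle <- oracle_ou_vcv(tr, 1.3, 0.22)
  dimnames(V_oracle) <- dimnames(V_pkg)
  expect_equal(V_pkg, V_oracle, tolerance = 1e-10)
})

test_that("OU collapses onto BM as alpha approaches zero", {
  tr <- sim_conditioned_tree(15, 40, 0.3, seed = 9)
  x <- sim_trait(tr, sigma2 = 1, seed = 10)
  xv <- setNames(x$value, x$species)
  expect_lt(abs(ou_loglik(tr, xv, 1.1, 1e-12, 0.2) -
                  bm_loglik(tr, xv, 1.1, 0.2)), 1e-6)
})

test_that("BM estimates satisfy the profile-likelihood identity", {
  tr <- sim_conditioned_tree(15, 30, 0.3, seed = 12)
  x <- sim_trait(tr, sigma2 = 2.5, seed = 13)
  xv <- setNames(x$value, x$species)
  fit <- fit_trait_model(tr, xv, "BM")
  C <- ape::vcv.phylo(tr)[names(xv), names(xv)]
  Ci <- solve(C)
  one <- rep(1, length(xv))
  z0_gls <- drop(one %*% Ci %*% xv) / drop(one %*% Ci %*% one)
  s2_prof <- drop(t(xv - z0_gls) %*% Ci %*% (xv - z0_gls)) / length(xv)
  expect_equal(fit$z0, z0_gls, tolerance = 1e-8)
  expect_equal(fit$sigma2, s2_prof, tolerance = 1e-8)
  # no sigma2 beats the profile value
  expect_gte(fit$loglik, bm_loglik(tr, xv, s2_prof * 1.1, z0_gls))
})

test_that("AICc bookkeeping is exact", {
  tr <- sim_conditioned_tree(15, 25, 0.3, seed = 15)
  x <- sim_trait(tr, sigma2 = 1, seed = 16)
  f <- fit_trait_model(tr, x, "BM")
  n <- f$n
  aic <- -2 * f$loglik + 2 * 2
  expect_equal(f$aicc, aic + 12 / (n - 3), tolerance = 1e-12)
  fo <- fit_trait_model(tr, x, "OU")
  expect_equal(fo$aicc, -2 * fo$loglik + 2 * 3 + 24 / (n - 4),
               tolerance = 1e-12)
})

test_that("fits are invariant to tip-order permutation and OU dominates BM", {
  tr <- sim_conditioned_tree(15, 30, 0.3, seed = 18)
  x <- sim_trait(tr, sigma2 = 1, alpha = 0.2, seed = 19)
  set.seed(20)
  x_perm <- x[sample.int(nrow(x)), ]
  for (m in c("BM", "OU")) {
    f1 <- fit_trait_model(tr, x, m)
    f2 <- fit_trait_model(tr, x_perm, m)
    expect_equal(f1$sigma2, f2$sigma2, tolerance = 1e-10)
    expect_equal(f1$alpha, f2$alpha, tolerance = 1e-10)
    expect_equal(f1$loglik, f2$loglik, tolerance = 1e-10)
  }
  # BM nested in OU at the alpha = 0 boundary
  for (seed in 1:5) {
    xx <- sim_trait(tr, sigma2 = 1, seed = 30 + seed)
    expect_gte(fit_trait_model(tr, xx, "OU")$loglik,
               fit_trait_model(tr, xx, "BM")$loglik)
  }
})

test_that("tidy and glance expose the estimates", {
  tr <- sim_conditioned_tree(15, 20, 0.3, seed = 22)
  f <- fit_trait_model(tr, sim_trait(tr, seed = 23), "OU")
  td <- tidy(f)
  expect_setequal(td$term, c("sigma2", "alpha", "z0"))
  expect_identical(glance(f)$AICc, f$aicc)
})

test_that("comparison over identical trees is unanimous and medians match", {
  tr <- sim_conditioned_tree(15, 30, 0.3, seed = 25)
  x <- sim_trait(tr, sigma2 = 1, seed = 26)
  tab <- compare_over_trees(rep(list(tr), 10), x)
  expect_identical(sort(tab$n_trees_preferred), c(0L, 10L))
  single <- fit_trait_model(tr, x, "BM")
  expect_equal(tab$sigma2[tab$model == "BM"], single$sigma2,
               tolerance = 1e-10)
})

test_that("tips with missing trait data are dropped with a warning", {
  tr <- sim_conditioned_tree(15, 10, 0.3, seed = 27)
  x <- sim_trait(tr, sigma2 = 1, seed = 28)
  x$value[x$species == tr$tip.label[1]] <- NA
  expect_warning(tab <- compare_over_trees(list(tr), x), "Dropping")
  expect_identical(nrow(tab), 2L)
})
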