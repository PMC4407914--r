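# Maximum-likelihood fitting of Brownian-motion and single-optimum
# Ornstein-Uhlenbeck models to tip data, AICc comparison, and batch
# comparison over posterior tree samples.
#
# Two independent likelihood routes are provided: a dense multivariate-normal
# evaluation from the explicit tip covariance, and an O(n) Felsenstein
# pruning evaluation. The OU pruning route exploits the fact that on an
# ultrametric tree the root-at-optimum OU covariance equals a Brownian
# covariance on a tree with exponentially rescaled node heights.

# ---- pruning machinery -----------------------------------------------------

# Felsenstein pruning for unit-rate Brownian motion: returns the n - 1
# independent contrasts with their variances, the GLS root estimate and its
# variance. loglik(z0, sigma2) and the closed-form ML estimates follow.
.bm_pruning <- function(tree, x) {
  n_tip <- ape::Ntip(tree)
  post <- ape::reorder.phylo(tree, "postorder")
  mu <- c(x, rep(NA_real_, tree$Nnode))
  v <- c(rep(0, n_tip), rep(NA_real_, tree$Nnode))
  edge_v <- numeric(n_tip + tree$Nnode)
  edge_v[post$edge[, 2]] <- post$edge.length
  contrasts <- numeric(0)
  c_var <- numeric(0)
  kids_of <- split(post$edge[, 2], post$edge[, 1])
  for (p in unique(post$edge[, 1])) {
    kids <- kids_of[[as.character(p)]]
    if (length(kids) != 2) {
      abort("Likelihood machinery requires a strictly binary tree.")
    }
    v1 <- v[kids[1]] + edge_v[kids[1]]
    v2 <- v[kids[2]] + edge_v[kids[2]]
    if (v1 + v2 <= 0) {
      abort(paste0(
        "Singular covariance: tips joined by zero total branch length. ",
        "Drop duplicate zero-length tips before fitting."
      ))
    }
    contrasts <- c(contrasts, mu[kids[1]] - mu[kids[2]])
    c_var <- c(c_var, v1 + v2)
    mu[p] <- (mu[kids[1]] / v1 + mu[kids[2]] / v2) / (1 / v1 + 1 / v2)
    v[p] <- v1 * v2 / (v1 + v2)
  }
  root <- n_tip + 1L
  list(contrasts = unname(contrasts), c_var = unname(c_var),
       root_mean = unname(mu[root]), root_var = unname(v[root]), n = n_tip)
}

.bm_pruning_loglik <- function(pr, sigma2, z0) {
  sum(dnorm(pr$contrasts, 0, sqrt(sigma2 * pr$c_var), log = TRUE)) +
    dnorm(pr$root_mean, z0, sqrt(sigma2 * pr$root_var), log = TRUE)
}

# ML estimates for given unit-rate structure: z0 = GLS root, sigma2 from the
# scaled quadratic form (n terms: n - 1 contrasts + the root term, which
# vanishes at the optimum).
.bm_pruning_mle <- function(pr) {
  sigma2 <- sum(pr$contrasts^2 / pr$c_var) / pr$n
  z0 <- pr$root_mean
  list(sigma2 = sigma2, z0 = z0,
       loglik = .bm_pruning_loglik(pr, sigma2, z0))
}

# Rescale node heights so that unit-rate BM on the rescaled tree has the
# root-at-optimum OU covariance (up to the factor sigma2):
# h' = (exp(-2 a (T - h)) - exp(-2 a T)) / (2 a).
.ou_rescale_tree <- function(tree, alpha) {
  if (alpha < 1e-9) return(tree)
  ages <- node_ages(tree)
  T_crown <- max(ages)
  h <- (exp(-2 * alpha * (T_crown - ages)) - exp(-2 * alpha * T_crown)) /
    (2 * alpha)
  out <- tree
  out$edge.length <- h[tree$edge[, 2]] - h[tree$edge[, 1]]
  out
}

# ---- dense-covariance machinery --------------------------------------------

.mvn_loglik <- function(x, mean, V) {
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    abort(paste0(
      "Singular trait covariance matrix. Check for duplicated tips joined ",
      "by zero-length branches."
    ))
  }
  d <- x - mean
  z <- backsolve(ch, d, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
}

.ou_vcv <- function(tree, sigma2, alpha) {
  s <- ape::vcv.phylo(tree)  # shared path lengths from the root
  d <- diag(s)               # root-to-tip times
  if (alpha < 1e-9) return(sigma2 * s)
  dsum <- outer(d, d, "+")
  sigma2 / (2 * alpha) * (1 - exp(-2 * alpha * s)) *
    exp(-alpha * (dsum - 2 * s))
}

#' Brownian-motion log-likelihood of tip data
#'
#' Multivariate-normal log-density of the tip values with mean `z0` and
#' covariance `sigma2 * C`, where `C[i, j]` is the shared path length of tips
#' i and j from the root.
#'
#' @param tree A `phylo`.
#' @param traits Named numeric vector or data frame with `species` column.
#' @param sigma2 Diffusion rate (> 0).
#' @param z0 Root state.
#' @param trait Trait column when `traits` has several.
#' @param method `"pruning"` (O(n), default) or `"dense"` (explicit
#'   covariance); the two agree to high precision and serve as mutual checks.
#' @return Log-likelihood (scalar).
#' @export
bm_loglik <- function(tree, traits, sigma2, z0, trait = NULL,
                      method = c("pruning", "dense")) {
  method <- match.arg(method)
  if (!is.finite(sigma2) || sigma2 <= 0) abort("`sigma2` must be > 0.")
  x <- as_trait_vector(traits, tree, trait)
  if (method == "pruning") {
    .bm_pruning_loglik(.bm_pruning(tree, x), sigma2, z0)
  } else {
    .mvn_loglik(x, z0, sigma2 * ape::vcv.phylo(tree))
  }
}

#' Ornstein-Uhlenbeck log-likelihood of tip data
#'
#' Single-optimum OU with the root at the optimum (`theta = z0`):
#' multivariate-normal log-density with mean `z0` and covariance
#' `V[i, j] = sigma2 / (2 alpha) (1 - exp(-2 alpha s_ij))
#' exp(-alpha (d_i + d_j - 2 s_ij))` where `s_ij` is the shared path length
#' and `d_i` the root-to-tip time. The `alpha -> 0` limit (Brownian motion)
#' is taken analytically below `1e-9`.
#'
#' @inheritParams bm_loglik
#' @param alpha Constraint parameter (>= 0).
#' @return Log-likelihood (scalar).
#' @export
ou_loglik <- function(tree, traits, sigma2, alpha, z0, trait = NULL,
                      method = c("pruning", "dense")) {
  method <- match.arg(method)
  if (!is.finite(sigma2) || sigma2 <= 0) abort("`sigma2` must be > 0.")
  if (!is.finite(alpha) || alpha < 0) abort("`alpha` must be >= 0.")
  x <- as_trait_vector(traits, tree, trait)
  if (method == "pruning") {
    assert_ultrametric(tree)
    .bm_pruning_loglik(.bm_pruning(.ou_rescale_tree(tree, alpha), x),
                       sigma2, z0)
  } else {
    .mvn_loglik(x, z0, .ou_vcv(tree, sigma2, alpha))
  }
}

# ---- model fitting ---------------------------------------------------------

#' Fit a trait-evolution model by maximum likelihood
#'
#' Brownian motion has closed-form ML estimates. The OU fit profiles the
#' likelihood over `alpha`: for each `alpha`, `sigma2` and `z0` have closed
#' forms via pruning on the rescaled tree, and the one-dimensional profile is
#' maximized by bounded quasi-Newton from log-spaced multi-starts over
#' `alpha_bounds`. `alpha = 0` (exactly the BM likelihood) is always included
#' as a candidate, so the fitted OU log-likelihood is never below BM.
#'
#' @param tree Ultrametric `phylo` with >= 4 tips.
#' @param traits Named numeric vector or data frame with `species` column.
#' @param model `"BM"` or `"OU"`.
#' @param trait Trait column when `traits` has several.
#' @param alpha_bounds Search bounds for `alpha` (default `c(1e-8, 10)`).
#' @param n_starts Number of log-spaced multi-starts (default 5).
#' @return An object of class `trait_fit`: list with `model`, `sigma2`,
#'   `alpha`, `z0` (= `theta` for OU), `loglik`, `k`, `n`, `aicc`,
#'   `convergence` (0 = clean).
#' @export
fit_trait_model <- function(tree, traits, model = c("BM", "OU"), trait = NULL,
                            alpha_bounds = c(1e-8, 10), n_starts = 5) {
  model <- match.arg(model)
  assert_ultrametric(tree)
  x <- as_trait_vector(traits, tree, trait)
  n <- length(x)
  if (n < 4) abort("Model fitting needs at least 4 tips.")
  pr0 <- .bm_pruning(tree, x)
  bm <- .bm_pruning_mle(pr0)
  if (model == "BM") {
    return(new_trait_fit("BM", bm$sigma2, 0, bm$z0, bm$loglik, k = 2, n = n,
                         convergence = 0))
  }
  profile <- function(log_alpha) {
    a <- exp(log_alpha)
    -.bm_pruning_mle(.bm_pruning(.ou_rescale_tree(tree, a), x))$loglik
  }
  starts <- log(exp(seq(log(alpha_bounds[1]), log(alpha_bounds[2]),
                        length.out = n_starts)))
  best <- list(value = -bm$loglik, par = -Inf, convergence = 0)
  for (s in starts) {
    o <- tryCatch(
      optim(s, profile, method = "L-BFGS-B", lower = log(alpha_bounds[1]),
            upper = log(alpha_bounds[2])),
      error = function(e) NULL
    )
    if (!is.null(o) && o$value < best$value) best <- o
  }
  alpha_hat <- if (is.finite(best$par)) exp(best$par) else 0
  est <- .bm_pruning_mle(.bm_pruning(.ou_rescale_tree(tree, alpha_hat), x))
  if (est$loglik < bm$loglik) {  # boundary: OU collapses onto BM
    alpha_hat <- 0
    est <- bm
  }
  new_trait_fit("OU", est$sigma2, alpha_hat, est$z0, est$loglik, k = 3,
                n = n, convergence = best$convergence %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_trait_fit <- function(model, sigma2, alpha, z0, loglik, k, n,
                          convergence) {
  out <- list(
    model = model, sigma2 = sigma2, alpha = alpha, z0 = z0,
    theta = if (model == "OU") z0 else NA_real_,
    loglik = loglik, k = k, n = n,
    aicc = -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1),
    convergence = convergence
  )
  class(out) <- "trait_fit"
  out
}

#' @export
print.trait_fit <- function(x, ...) {
  cat(sprintf(
    "%s fit (n = %d tips): sigma2 = %.4g%s, z0 = %.4g\nlogLik = %.4f, AICc = %.4f\n",
    x$model, x$n, x$sigma2,
    if (x$model == "OU") sprintf(", alpha = %.4g", x$alpha) else "",
    x$z0, x$loglik, x$aicc
  ))
  invisible(x)
}

#' @export
tidy.trait_fit <- function(x, ...) {
  terms <- c("sigma2", if (x$model == "OU") "alpha", "z0")
  tibble::tibble(
    term = terms,
    estimate = vapply(terms, function(t) x[[t]], numeric(1))
  )
}

#' @export
glance.trait_fit <- function(x, ...) {
  tibble::tibble(model = x$model, sigma2 = x$sigma2, alpha = x$alpha,
                 z0 = x$z0, logLik = x$loglik, k = x$k, n = x$n,
                 AICc = x$aicc, convergence = x$convergence)
}

#' Compare BM and OU fits across a sample of trees
#'
#' Fits both models to the same trait on every tree (tips without trait data
#' are dropped per tree, with a warning), and summarizes as medians of the
#' estimates, log-likelihood and AICc per model, plus the number of trees on
#' which each model has the lower AICc. Medians are used to blunt outlier
#' estimates from individual posterior trees.
#'
#' @param trees A list of ultrametric `phylo` objects (or a `multiPhylo`).
#' @param traits Data frame with `species` column, or named vector.
#' @param trait Trait column when `traits` has several.
#' @return A tibble with one row per model: `model`, `sigma2`, `alpha`,
#'   `loglik`, `aicc` (medians over trees) and `n_trees_preferred`.
#' @export
compare_over_trees <- function(trees, traits, trait = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  fits <- purrr::map(trees, function(tr) {
    if (is.data.frame(traits)) {
      species_col <- intersect(c("species", "tip", "label"), names(traits))[1]
      tcol <- trait %||% "value"
      have <- traits[[species_col]][!is.na(traits[[tcol]])]
      drop <- setdiff(tr$tip.label, have)
      if (length(drop) > 0) {
        warn(sprintf("Dropping %d tip(s) without trait data: %s",
                     length(drop), paste(drop, collapse = ", ")))
        tr <- ape::drop.tip(tr, drop)
      }
    }
    list(bm = fit_trait_model(tr, traits, "BM", trait),
         ou = fit_trait_model(tr, traits, "OU", trait))
  })
  prefer_ou <- vapply(fits, function(f) f$ou$aicc < f$bm$aicc, logical(1))
  summarize_model <- function(key, n_pref) {
    tibble::tibble(
      model = toupper(key),
      sigma2 = median(vapply(fits, function(f) f[[key]]$sigma2, 1)),
      alpha = median(vapply(fits, function(f) f[[key]]$alpha, 1)),
      loglik = median(vapply(fits, function(f) f[[key]]$loglik, 1)),
      aicc = median(vapply(fits, function(f) f[[key]]$aicc, 1)),
      n_trees_preferred = n_pref
    )
  }
  dplyr::bind_rows(
    summarize_model("bm", sum(!prefer_ou)),
    summarize_model("ou", sum(prefer_ou))
  )
}
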