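# Disparity-through-time curves, null envelopes and the morphological
# disparity index (MDI).

#' Morphological disparity of a set of taxa
#'
#' Average squared pairwise Euclidean distance among trait values:
#' `sum_{i<j} d_ij^2 / (n (n - 1) / 2)`. For a matrix, rows are taxa and
#' squared distances sum over columns. Returns 0 for fewer than two taxa.
#'
#' @param values Numeric vector, or matrix with taxa in rows.
#' @return Non-negative scalar.
#' @export
disparity <- function(values) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values))) {
    abort("`values` must be finite and numeric.")
  }
  n <- nrow(values)
  if (n < 2) return(0)
  per_col <- apply(values, 2, function(x) {
    (n * sum(x^2) - sum(x)^2) * 2 / (n * (n - 1))
  })
  sum(per_col)
}

# Precomputes everything about a tree that DTT evaluation needs, so that many
# trait replicates can be scored on the same tree cheaply. Returns the merged
# relative node times and eval(X): tip-value matrix (Ntip x n_reps, rows in
# tip order) -> curve matrix (n_times x n_reps).
.dtt_machine <- function(tree, tol = 1e-9) {
  assert_ultrametric(tree)
  n_tip <- ape::Ntip(tree)
  ages <- node_ages(tree)
  T_crown <- max(ages)
  eps <- tol * max(T_crown, 1)
  internal_ages <- ages[n_tip + seq_len(tree$Nnode)]
  times <- merge_tied_ages(sort(internal_ages), tol)
  post <- ape::reorder.phylo(tree, "postorder")
  # lineages crossing just before each node time: edges with
  # age(parent) < t - eps <= age(child)
  alive_children <- lapply(times, function(t) {
    if (t <= eps) return(n_tip + 1L)  # root: the whole clade
    sel <- ages[tree$edge[, 1]] < t - eps & ages[tree$edge[, 2]] >= t - eps
    tree$edge[sel, 2]
  })
  cnt <- c(rep(1, n_tip), rep(0, tree$Nnode))
  for (e in seq_len(nrow(post$edge))) {
    cnt[post$edge[e, 1]] <- cnt[post$edge[e, 1]] + cnt[post$edge[e, 2]]
  }
  pair_norm <- ifelse(cnt >= 2, 2 / (cnt * (cnt - 1)), 0)
  eval_fun <- function(X) {
    X <- as.matrix(X)
    n_reps <- ncol(X)
    S1 <- matrix(0, n_tip + tree$Nnode, n_reps)
    S2 <- matrix(0, n_tip + tree$Nnode, n_reps)
    S1[seq_len(n_tip), ] <- X
    S2[seq_len(n_tip), ] <- X^2
    for (e in seq_len(nrow(post$edge))) {
      p <- post$edge[e, 1]
      k <- post$edge[e, 2]
      S1[p, ] <- S1[p, ] + S1[k, ]
      S2[p, ] <- S2[p, ] + S2[k, ]
    }
    disp <- (cnt * S2 - S1^2) * pair_norm
    d_tot <- disp[n_tip + 1L, ]
    if (any(d_tot <= 0)) {
      abort("Whole-clade disparity is zero: degenerate trait data.")
    }
    out <- matrix(0, length(times), n_reps)
    for (i in seq_along(times)) {
      idx <- alive_children[[i]]
      out[i, ] <- .colMeans(disp[idx, , drop = FALSE],
                            length(idx), n_reps) / d_tot
    }
    out
  }
  list(times = times, rel_times = times / T_crown, crown_age = T_crown,
       eval = eval_fun)
}

#' Disparity-through-time curve
#'
#' At each internal-node age (simultaneous divergences merged), the average
#' over all lineages crossing that time of the relative disparity of the
#' lineage's descendant tips (clade disparity divided by whole-clade
#' disparity). The curve starts at 1 at the root; lineages subtending a
#' single tip contribute 0.
#'
#' @param tree Ultrametric `phylo`.
#' @param traits Named numeric vector or data frame with a `species` column.
#' @param trait Trait column to use when `traits` has several.
#' @return A tibble of class `radburst_dtt` with columns `rel_time` (node
#'   height / crown age) and `disparity`; the crown age (myr) is attached as
#'   attribute `crown_age`.
#' @export
dtt <- function(tree, traits, trait = NULL) {
  x <- as_trait_vector(traits, tree, trait)
  machine <- .dtt_machine(tree)
  vals <- machine$eval(matrix(x, ncol = 1))[, 1]
  new_dtt(machine$rel_times, vals, machine$crown_age)
}

new_dtt <- function(rel_time, disparity, crown_age) {
  out <- tibble::tibble(rel_time = rel_time, disparity = disparity)
  attr(out, "crown_age") <- crown_age
  class(out) <- c("radburst_dtt", class(out))
  out
}

#' Disparity-through-time with a simulated null envelope
#'
#' Simulates `n_sims` trait sets on the same tree under a null model of trait
#' evolution, evaluates every replicate's DTT on the observed node times, and
#' summarizes the null as a pointwise median and 5%/95% quantile envelope
#' (type-7 quantiles). The MDI is the signed step-function area between the
#' observed curve and the null median over the first `t_max` of the
#' chronogram. By default the null model's parameters are fitted to the
#' observed traits by maximum likelihood; note that for a Brownian null the
#' curve is invariant to `sigma2`, so fitting only matters for OU.
#'
#' @inheritParams dtt
#' @param model `"bm"`, `"ou"`, or `"fitted"` (AICc-best of the two).
#' @param n_sims Number of null simulations (default 100).
#' @param t_max MDI truncation fraction (default 0.9, discarding the most
#'   recent 10% where tip overdispersion dominates).
#' @param seed Optional integer seed.
#' @return An object of class `radburst_dtt_null`: list with `curve` (tibble
#'   `rel_time`, `observed`, `null_median`, `q05`, `q95`), `mdi`, `model`,
#'   `fit`, `n_sims`, `t_max`, `crown_age`.
#' @export
dtt_null <- function(tree, traits, trait = NULL,
                     model = c("fitted", "bm", "ou"), n_sims = 100,
                     t_max = 0.9, seed = NULL) {
  model <- match.arg(model)
  if (n_sims < 2) abort("`n_sims` must be >= 2.")
  x <- as_trait_vector(traits, tree, trait)
  if (!is.null(seed)) set.seed(seed)
  fit <- switch(model,
    bm = fit_trait_model(tree, x, model = "BM"),
    ou = fit_trait_model(tree, x, model = "OU"),
    fitted = {
      f_bm <- fit_trait_model(tree, x, model = "BM")
      f_ou <- fit_trait_model(tree, x, model = "OU")
      if (f_ou$aicc < f_bm$aicc) f_ou else f_bm
    }
  )
  machine <- .dtt_machine(tree)
  obs <- machine$eval(matrix(x, ncol = 1))[, 1]
  sims <- .sim_gauss_matrix(tree, n_sims, sigma2 = fit$sigma2,
                            alpha = fit$alpha, theta = fit$z0, x0 = fit$z0)
  null_curves <- machine$eval(sims)
  curve <- tibble::tibble(
    rel_time = machine$rel_times,
    observed = obs,
    null_median = apply(null_curves, 1, median),
    q05 = apply(null_curves, 1, quantile, probs = 0.05, type = 7),
    q95 = apply(null_curves, 1, quantile, probs = 0.95, type = 7)
  )
  out <- list(
    curve = curve,
    mdi = .step_integral(curve$rel_time, curve$observed - curve$null_median,
                         t_max),
    model = fit$model, fit = fit, n_sims = n_sims, t_max = t_max,
    crown_age = machine$crown_age
  )
  class(out) <- "radburst_dtt_null"
  out
}

#' @export
print.radburst_dtt_null <- function(x, ...) {
  cat(sprintf(
    "Disparity-through-time vs %s null (%d simulations)\nMDI over [0, %.2f]: %.4f\n",
    x$model, x$n_sims, x$t_max, x$mdi
  ))
  print(x$curve)
  invisible(x)
}

#' @export
tidy.radburst_dtt_null <- function(x, ...) x$curve

#' @export
glance.radburst_dtt_null <- function(x, ...) {
  tibble::tibble(mdi = x$mdi, model = x$model, n_sims = x$n_sims,
                 t_max = x$t_max, crown_age = x$crown_age)
}

# Right-continuous step-function integral of `values` over [0, upper]; the
# last step extends to `upper`. Exact step areas, no trapezoids.
.step_integral <- function(times, values, upper) {
  ends <- c(times[-1], max(upper, times[length(times)]))
  widths <- pmax(0, pmin(ends, upper) - pmin(times, upper))
  sum(values * widths)
}

#' Morphological disparity index
#'
#' Signed area between an observed DTT curve and a null-median DTT curve,
#' integrated as right-continuous step functions over relative time
#' `[0, t_max]`. Negative values indicate observed subclade disparity below
#' the null - the early-burst signature.
#'
#' @param observed,null_median Objects of class `radburst_dtt` (see [dtt()])
#'   on the same tree.
#' @param t_max Truncation fraction in (0, 1] (default 0.9).
#' @return Scalar MDI.
#' @export
mdi <- function(observed, null_median, t_max = 0.9) {
  if (!is.numeric(t_max) || t_max <= 0 || t_max > 1) {
    abort("`t_max` must be in (0, 1].")
  }
  ca_o <- attr(observed, "crown_age")
  ca_n <- attr(null_median, "crown_age")
  if (!is.null(ca_o) && !is.null(ca_n) &&
      abs(ca_o - ca_n) > 1e-6 * max(ca_o, ca_n)) {
    abort("Curves come from trees with different crown ages.")
  }
  grid <- sort(unique(c(observed$rel_time, null_median$rel_time)))
  at <- function(curve) {
    idx <- findInterval(grid + 1e-12, curve$rel_time)
    if (any(idx == 0)) abort("Curves must start at relative time 0.")
    curve$disparity[idx]
  }
  .step_integral(grid, at(observed) - at(null_median), t_max)
}
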