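# Per-interval Kendall-Moran diversification-rate estimates and their
# comparison against quantiles from conditioned simulated phylogenies.

#' Geological stage intervals
#'
#' The five Neogene/Quaternary stages used for per-interval diversification
#' rates: Tortonian (11.6-7.2 Ma), Messinian (7.2-5.3 Ma), Zanclean
#' (5.3-3.6 Ma), Piacenzian (3.6-2.6 Ma) and Pleistocene (2.6-0 Ma).
#'
#' @return A tibble with columns `stage`, `old_bound`, `young_bound` (Ma).
#' @export
geo_stages <- function() {
  tibble::tibble(
    stage = c("Tortonian", "Messinian", "Zanclean", "Piacenzian",
              "Pleistocene"),
    old_bound = c(11.6, 7.2, 5.3, 3.6, 2.6),
    young_bound = c(7.2, 5.3, 3.6, 2.6, 0)
  )
}

check_intervals <- function(intervals) {
  if (!is.data.frame(intervals) ||
      !all(c("old_bound", "young_bound") %in% names(intervals))) {
    abort("`intervals` needs columns `old_bound` and `young_bound`.")
  }
  if (any(intervals$old_bound <= intervals$young_bound) ||
      any(intervals$young_bound < 0)) {
    abort("Intervals need old_bound > young_bound >= 0.")
  }
  if (!"stage" %in% names(intervals)) {
    intervals$stage <- sprintf("(%g, %g]", intervals$young_bound,
                               intervals$old_bound)
  }
  intervals
}

#' Kendall-Moran diversification rate per time interval
#'
#' For each interval `(young_bound, old_bound]` (ages before present;
#' boundary events count toward the older interval), the rate is
#' `B / L`, where `B` is the number of branching events (internal nodes,
#' excluding the root, which is the conditioning event) with age strictly
#' inside the interval, and `L` is the total lineage-time: the summed overlap
#' of every branch's age span with the interval. Over a partition of the
#' tree's age range, the `B` sum to the non-root internal node count and the
#' `L` to the total tree length exactly.
#'
#' @param tree Ultrametric `phylo`.
#' @param intervals Data frame with `old_bound` and `young_bound` columns in
#'   Ma before present (default [geo_stages()]).
#' @return A tibble with columns `stage`, `old_bound`, `young_bound`,
#'   `n_events`, `lineage_time`, `rate`.
#' @export
km_rate <- function(tree, intervals = geo_stages()) {
  assert_ultrametric(tree)
  intervals <- check_intervals(intervals)
  n_tip <- ape::Ntip(tree)
  ages <- node_ages_bp(tree)
  root <- n_tip + 1L
  node_ages_int <- ages[setdiff(n_tip + seq_len(tree$Nnode), root)]
  br_old <- ages[tree$edge[, 1]]
  br_young <- ages[tree$edge[, 2]]
  res <- purrr::pmap_dfr(
    intervals[, c("stage", "old_bound", "young_bound")],
    function(stage, old_bound, young_bound) {
      B <- sum(node_ages_int > young_bound & node_ages_int <= old_bound)
      L <- sum(pmax(0, pmin(br_old, old_bound) -
                      pmax(br_young, young_bound)))
      if (L <= 0) {
        abort(sprintf(
          "Interval (%g, %g] has zero lineage time (older than the tree?).",
          young_bound, old_bound
        ))
      }
      tibble::tibble(stage = stage, old_bound = old_bound,
                     young_bound = young_bound, n_events = B,
                     lineage_time = L, rate = B / L)
    }
  )
  res
}

#' Simulated-rate envelope for per-interval diversification rates
#'
#' Simulates `n_sims` trees conditioned on `crown_age` and `n_extant`
#' species, trims each to `k` tips under the chosen sampling scheme,
#' computes per-interval Kendall-Moran rates, and returns their quantiles
#' alongside the rates of the supplied empirical tree(s). Empirical rates
#' exceeding a high simulated quantile flag intervals of exceptional
#' diversification relative to a homogeneous-rate expectation.
#'
#' @param trees An ultrametric `phylo` or a list of them (the empirical
#'   trees). The first tree's names are `tree_1`, `tree_2`, ... unless the
#'   list is named.
#' @param intervals As in [km_rate()].
#' @param crown_age,n_extant,lambda,mu Conditioning of the simulated trees
#'   (see [sim_conditioned_tree()]).
#' @param k Tip count to which simulated trees are trimmed (default: tip
#'   count of the first empirical tree). `NULL` skips trimming.
#' @param sampling Sampling scheme for trimming (see [sample_tips()]).
#' @param deep_fraction Semidiversified deep-clade fraction.
#' @param n_sims Number of simulated trees (default 500).
#' @param probs Quantiles to report (default 0.5, 0.95, 0.999).
#' @param seed Optional integer seed.
#' @return An object of class `km_envelope`: list with `quantiles` (tibble:
#'   stage bounds plus one `q*` column per requested quantile), `empirical`
#'   (tibble: `tree`, `stage`, `rate`), and `sim_rates` (matrix of simulated
#'   rates, intervals x simulations).
#' @export
km_rate_envelope <- function(trees, intervals = geo_stages(), crown_age,
                             n_extant, lambda, mu = 0, k = NULL,
                             sampling = c("random", "diversified",
                                          "semidiversified"),
                             deep_fraction = 0.5, n_sims = 500,
                             probs = c(0.5, 0.95, 0.999), seed = NULL) {
  sampling <- match.arg(sampling)
  if (inherits(trees, "phylo")) trees <- list(trees)
  intervals <- check_intervals(intervals)
  if (is.null(names(trees))) {
    names(trees) <- paste0("tree_", seq_along(trees))
  }
  if (is.null(k)) k <- ape::Ntip(trees[[1]])
  if (!is.null(seed)) set.seed(seed)
  empirical <- purrr::imap_dfr(trees, function(tr, nm) {
    dplyr::mutate(km_rate(tr, intervals)[, c("stage", "rate")], tree = nm,
                  .before = 1)
  })
  sim_rates <- matrix(NA_real_, nrow(intervals), n_sims)
  for (s in seq_len(n_sims)) {
    tr <- sim_conditioned_tree(crown_age, n_extant, lambda, mu)
    if (k < ape::Ntip(tr)) {
      tr <- sample_tips(tr, k, scheme = sampling,
                        deep_fraction = deep_fraction)
    }
    sim_rates[, s] <- km_rate(tr, intervals)$rate
  }
  qs <- t(apply(sim_rates, 1, quantile, probs = probs, type = 7))
  colnames(qs) <- paste0("q", sub("^0\\.", "", formatC(probs, format = "g")))
  quantiles <- dplyr::bind_cols(
    intervals[, c("stage", "old_bound", "young_bound")],
    tibble::as_tibble(qs)
  )
  out <- list(quantiles = quantiles, empirical = empirical,
              sim_rates = sim_rates, sampling = sampling, n_sims = n_sims)
  class(out) <- "km_envelope"
  out
}

#' @export
print.km_envelope <- function(x, ...) {
  cat(sprintf(
    "Kendall-Moran rate envelope (%d simulated trees, %s sampling)\n",
    x$n_sims, x$sampling
  ))
  print(dplyr::left_join(
    x$quantiles,
    tidyr::pivot_wider(x$empirical, names_from = "tree",
                       values_from = "rate"),
    by = "stage"
  ))
  invisible(x)
}

#' @export
tidy.km_envelope <- function(x, ...) {
  dplyr::left_join(x$empirical, x$quantiles, by = "stage")
}
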