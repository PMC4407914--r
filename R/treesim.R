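# Forward (Gillespie) simulation of reconstructed trees, crown-conditioned
# rejection sampling, and incomplete taxon-sampling schemes.

# ---- internal event-level machinery ----------------------------------------

# Pure-birth event times starting from `n0` lineages at time 0, run to t_max.
# Draws waiting times Exp(lambda * k) for k = n0, n0 + 1, ... in blocks.
# Stops early (returning times seen so far) once `stop_above` lineages exist.
.yule_event_times <- function(lambda, t_max, n0 = 2, stop_above = Inf,
                              block = 64L) {
  times <- numeric(0)
  t_now <- 0
  k <- n0
  repeat {
    w <- rexp(block, rate = lambda * (k + seq_len(block) - 1))
    tt <- t_now + cumsum(w)
    over <- which(tt > t_max)
    if (length(over) > 0) {
      times <- c(times, tt[seq_len(over[1] - 1L)])
      return(times)
    }
    times <- c(times, tt)
    k <- k + block
    t_now <- tt[block]
    if (length(times) + n0 > stop_above) return(times)
  }
}

# Birth-death event sequence from 2 crown lineages, tracking per-crown-side
# lineage counts. Returns times, types and sides, plus whether both crown
# lineages still have extant descendants at t_max.
.bd_event_sequence <- function(lambda, mu, t_max) {
  nA <- 1L
  nB <- 1L
  t_now <- 0
  rate_tot <- lambda + mu
  times <- numeric(0)
  birth <- logical(0)
  side <- integer(0)
  repeat {
    n <- nA + nB
    if (nA == 0L || nB == 0L) {
      return(list(times = times, birth = birth, side = side,
                  nA = nA, nB = nB, crown_extinct = TRUE))
    }
    t_now <- t_now + rexp(1, rate = n * rate_tot)
    if (t_now > t_max) break
    is_birth <- runif(1) < lambda / rate_tot
    s <- if (runif(1) < nA / n) 1L else 2L
    if (is_birth) {
      if (s == 1L) nA <- nA + 1L else nB <- nB + 1L
    } else {
      if (s == 1L) nA <- nA - 1L else nB <- nB - 1L
    }
    times <- c(times, t_now)
    birth <- c(birth, is_birth)
    side <- c(side, s)
  }
  list(times = times, birth = birth, side = side,
       nA = nA, nB = nB, crown_extinct = (nA == 0L || nB == 0L))
}

# Replay an event sequence into a lineage table. Lineages are picked uniformly
# at random among those active when an event fires. `parent = 0` marks the
# initial (crown) lineages.
.sim_lineages <- function(times, birth, t_end, n0) {
  n_ev <- length(times)
  cap <- n0 + 2L * sum(birth) + 1L
  parent <- integer(cap)
  t_birth <- numeric(cap)
  t_death <- rep(NA_real_, cap)
  is_split <- logical(cap)
  n_lin <- n0
  active <- seq_len(n0)
  for (i in seq_len(n_ev)) {
    j <- active[sample.int(length(active), 1L)]
    if (birth[i]) {
      is_split[j] <- TRUE
      t_death[j] <- times[i]
      kids <- n_lin + 1:2
      parent[kids] <- j
      t_birth[kids] <- times[i]
      n_lin <- n_lin + 2L
      active <- c(active[active != j], kids)
    } else {
      t_death[j] <- times[i]
      active <- active[active != j]
    }
  }
  t_death[active] <- t_end
  extant <- rep(FALSE, n_lin)
  extant[active] <- TRUE
  list(parent = parent[seq_len(n_lin)], t_birth = t_birth[seq_len(n_lin)],
       t_death = t_death[seq_len(n_lin)], is_split = is_split[seq_len(n_lin)],
       extant = extant)
}

# Assemble a phylo from one or two per-side lineage tables joined at the root.
.lineages_to_phylo <- function(sides, t_end) {
  offset <- 0L
  parent <- integer(0)
  t_birth <- numeric(0)
  t_death <- numeric(0)
  is_split <- logical(0)
  extant <- logical(0)
  for (s in sides) {
    p <- s$parent
    p[p > 0] <- p[p > 0] + offset
    parent <- c(parent, p)
    t_birth <- c(t_birth, s$t_birth)
    t_death <- c(t_death, s$t_death)
    is_split <- c(is_split, s$is_split)
    extant <- c(extant, s$extant)
    offset <- length(parent)
  }
  n_lin <- length(parent)
  tip_lineage <- which(!is_split)
  n_tip <- length(tip_lineage)
  node_of <- integer(n_lin)
  node_of[tip_lineage] <- seq_len(n_tip)
  split_lineage <- which(is_split)
  split_lineage <- split_lineage[order(t_death[split_lineage])]
  node_of[split_lineage] <- n_tip + 1L + seq_along(split_lineage)
  root <- n_tip + 1L
  parent_node <- ifelse(parent == 0L, root, node_of[pmax(parent, 1L)])
  edge <- cbind(parent_node, node_of)
  tr <- list(
    edge = edge,
    edge.length = t_death - t_birth,
    tip.label = paste0("t", seq_len(n_tip)),
    Nnode = length(split_lineage) + 1L
  )
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  dead <- which(!extant[tip_lineage])
  if (length(dead) > 0) {
    tr <- ape::drop.tip(tr, dead)
  }
  tr$tip.label <- paste0("t", seq_len(ape::Ntip(tr)))
  tr
}

# ---- exported simulators ---------------------------------------------------

#' Simulate a birth-death tree forward from a crown split
#'
#' Gillespie simulation starting from the two crown lineages at time 0 with
#' per-lineage speciation rate `lambda` and extinction rate `mu`, run to
#' `crown_age`. Extinct lineages are pruned so the returned tree is the
#' reconstructed (extant) tree. If either crown lineage leaves no extant
#' descendant the realized most-recent-common-ancestor age would be younger
#' than `crown_age`; in that case `NULL` is returned.
#'
#' @param lambda Speciation rate per lineage per myr (> 0).
#' @param mu Extinction rate per lineage per myr (>= 0); 0 gives a Yule tree.
#' @param crown_age Crown age in myr (> 0).
#' @param seed Optional integer seed for reproducibility.
#' @return An ultrametric `phylo` with root age `crown_age`, or `NULL` when
#'   one of the crown lineages went extinct.
#' @export
sim_bd_tree <- function(lambda, mu = 0, crown_age, seed = NULL) {
  check_bd_params(lambda, mu)
  if (!is.finite(crown_age) || crown_age <= 0) {
    abort("`crown_age` must be a positive number.")
  }
  if (!is.null(seed)) set.seed(seed)
  if (mu == 0) {
    times <- .yule_event_times(lambda, crown_age, n0 = 2L)
    lin <- .sim_lineages(times, rep(TRUE, length(times)), crown_age, n0 = 2L)
    return(.lineages_to_phylo(list(lin), crown_age))
  }
  ev <- .bd_event_sequence(lambda, mu, crown_age)
  if (ev$crown_extinct) return(NULL)
  linA <- .sim_lineages(ev$times[ev$side == 1L], ev$birth[ev$side == 1L],
                        crown_age, n0 = 1L)
  linB <- .sim_lineages(ev$times[ev$side == 2L], ev$birth[ev$side == 2L],
                        crown_age, n0 = 1L)
  .lineages_to_phylo(list(linA, linB), crown_age)
}

check_bd_params <- function(lambda, mu) {
  if (!is.numeric(lambda) || length(lambda) != 1 || !is.finite(lambda) ||
      lambda <= 0) {
    abort("`lambda` must be a single finite positive number.")
  }
  if (!is.numeric(mu) || length(mu) != 1 || !is.finite(mu) || mu < 0) {
    abort("`mu` must be a single finite non-negative number.")
  }
  invisible(NULL)
}

#' Simulate a tree conditioned on crown age and extant richness
#'
#' Rejection sampler: speciation rates are drawn from `lambda` (a fixed value
#' or a uniform range), a tree is simulated forward from the crown, and the
#' attempt is rejected unless exactly `n_tips` lineages are extant at
#' `crown_age` and both crown lineages survived. For the pure-birth case the
#' rejection predicate is evaluated from the event times alone and the
#' topology is only assembled for the accepted attempt, which is
#' distributionally identical to building every attempt's tree.
#'
#' @param crown_age Crown age in myr.
#' @param n_tips Required number of extant tips (>= 2).
#' @param lambda Speciation rate: a single value, or a length-2 vector giving
#'   the bounds of a uniform distribution sampled once per attempt.
#' @param mu Extinction rate (default 0).
#' @param seed Optional integer seed.
#' @param max_attempts Attempt budget before failing (default `1e6`).
#' @return An ultrametric `phylo` with exactly `n_tips` tips and root age
#'   `crown_age`. The drawn speciation rate and the number of attempts are
#'   attached as attributes `lambda` and `attempts`.
#' @export
sim_conditioned_tree <- function(crown_age, n_tips, lambda, mu = 0,
                                 seed = NULL, max_attempts = 1e6) {
  if (!is.numeric(n_tips) || n_tips < 2 || n_tips != round(n_tips)) {
    abort("`n_tips` must be an integer >= 2.")
  }
  if (!is.numeric(lambda) || !length(lambda) %in% c(1L, 2L) ||
      any(!is.finite(lambda)) || any(lambda <= 0)) {
    abort("`lambda` must be a positive value or a length-2 uniform range.")
  }
  if (length(lambda) == 2L && lambda[1] >= lambda[2]) {
    abort("`lambda` range must have low < high.")
  }
  if (!is.null(seed)) set.seed(seed)
  for (attempt in seq_len(max_attempts)) {
    lam <- if (length(lambda) == 2L) runif(1, lambda[1], lambda[2]) else lambda
    if (mu == 0) {
      times <- .yule_event_times(lam, crown_age, n0 = 2L,
                                 stop_above = n_tips)
      if (length(times) + 2L != n_tips) next
      lin <- .sim_lineages(times, rep(TRUE, length(times)), crown_age, n0 = 2L)
      tr <- .lineages_to_phylo(list(lin), crown_age)
    } else {
      ev <- .bd_event_sequence(lam, mu, crown_age)
      if (ev$crown_extinct || ev$nA + ev$nB != n_tips) next
      linA <- .sim_lineages(ev$times[ev$side == 1L], ev$birth[ev$side == 1L],
                            crown_age, n0 = 1L)
      linB <- .sim_lineages(ev$times[ev$side == 2L], ev$birth[ev$side == 2L],
                            crown_age, n0 = 1L)
      tr <- .lineages_to_phylo(list(linA, linB), crown_age)
    }
    attr(tr, "lambda") <- lam
    attr(tr, "attempts") <- attempt
    return(tr)
  }
  abort(sprintf(
    "No tree with %d tips accepted in %d attempts (acceptance rate < %.2g).",
    n_tips, max_attempts, 1 / max_attempts
  ))
}

#' Subsample tips under random, diversified or semidiversified schemes
#'
#' Returns the induced subtree on `k` retained tips (branch lengths
#' preserved; internal unifurcations collapsed). Schemes:
#' \describe{
#'   \item{random}{uniform sampling without replacement.}
#'   \item{diversified}{one uniformly chosen tip from each of the `k` subtrees
#'     hanging below the `k - 1` oldest internal nodes, so the deepest
#'     divergences are always represented.}
#'   \item{semidiversified}{one tip from each subtree below the
#'     `floor(deep_fraction * k)` oldest internal nodes; remaining slots are
#'     filled uniformly at random from the unsampled tips. The default
#'     `deep_fraction = 0.5` is a documented stand-in for the scheme's exact
#'     published definition.}
#' }
#' Ties in node age are broken by node index.
#'
#' @param tree Ultrametric `phylo`.
#' @param k Number of tips to retain (`2 <= k <= Ntip(tree)`).
#' @param scheme One of `"random"`, `"diversified"`, `"semidiversified"`.
#' @param deep_fraction Fraction of slots reserved for deep clades under the
#'   semidiversified scheme (default 0.5).
#' @param seed Optional integer seed.
#' @return A `phylo` with `k` tips.
#' @export
sample_tips <- function(tree, k, scheme = c("random", "diversified",
                                            "semidiversified"),
                        deep_fraction = 0.5, seed = NULL) {
  check_phylo(tree)
  scheme <- match.arg(scheme)
  n_tip <- ape::Ntip(tree)
  if (!is.numeric(k) || k != round(k) || k < 2 || k > n_tip) {
    abort("`k` must be an integer in [2, Ntip(tree)].")
  }
  if (!is.null(seed)) set.seed(seed)
  if (k == n_tip) return(tree)
  keep <- switch(
    scheme,
    random = sample.int(n_tip, k),
    diversified = .deep_clade_sample(tree, n_deep = k - 1L),
    semidiversified = {
      m <- max(1L, min(k - 1L, floor(deep_fraction * k)))
      deep <- .deep_clade_sample(tree, n_deep = m)
      pool <- setdiff(seq_len(n_tip), deep)
      extra <- k - length(deep)
      c(deep, if (extra > 0) pool[sample.int(length(pool), extra)])
    }
  )
  ape::keep.tip(tree, sort(keep))
}

# One uniformly chosen tip from each subtree hanging below the n_deep oldest
# internal nodes. The n_deep oldest internal nodes are ancestor-closed, so
# they form a connected backbone with exactly n_deep + 1 pendant subtrees.
.deep_clade_sample <- function(tree, n_deep) {
  n_tip <- ape::Ntip(tree)
  ages <- node_ages(tree)
  internal <- n_tip + seq_len(tree$Nnode)
  ord <- internal[order(ages[internal], internal - n_tip)]
  backbone <- ord[seq_len(n_deep)]
  desc <- descendant_tips(tree)
  picks <- integer(0)
  for (b in backbone) {
    kids <- tree$edge[tree$edge[, 1] == b, 2]
    for (kid in kids) {
      if (!kid %in% backbone) {
        tips <- desc[[kid]]
        picks <- c(picks, tips[sample.int(length(tips), 1L)])
      }
    }
  }
  picks
}

#' Lineage-through-time table
#'
#' Step function of the number of reconstructed lineages: starts at 2 at the
#' root and increments at each internal-node age. Simultaneous divergences
#' (ages tied within `1e-9` relative) are merged into a single step.
#'
#' @param tree Ultrametric `phylo`.
#' @return A tibble with columns `age` (myr forward from the root), `age_bp`
#'   (myr before present) and `lineages`.
#' @export
ltt <- function(tree) {
  assert_ultrametric(tree)
  n_tip <- ape::Ntip(tree)
  ages <- node_ages(tree)
  t_max <- max(ages)
  internal_ages <- sort(ages[n_tip + seq_len(tree$Nnode)])
  steps <- merge_tied_ages(internal_ages)
  counts <- 1 + vapply(
    steps,
    function(s) sum(internal_ages <= s + 1e-9 * max(t_max, 1)),
    numeric(1)
  )
  tibble::tibble(age = steps, age_bp = t_max - steps, lineages = counts)
}
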