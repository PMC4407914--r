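# Independent oracles used across the suite. These stay deliberately naive
# (double loops, enumeration, direct recursions) so they check the package's
# optimized paths from the outside.

# mean squared pairwise Euclidean distance, brute-force double loop
oracle_disparity <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) return(0)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + sum((x[i, ] - x[j, ])^2)
    }
  }
  tot / (n * (n - 1) / 2)
}

# right-continuous step integral by explicit segment loop
oracle_step_integral <- function(times, values, upper) {
  tot <- 0
  for (i in seq_along(times)) {
    lo <- times[i]
    hi <- if (i < length(times)) times[i + 1] else max(upper, lo)
    lo <- min(lo, upper)
    hi <- min(hi, upper)
    tot <- tot + values[i] * (hi - lo)
  }
  tot
}

# crown-conditioned pure-birth tip-count law: two independent geometric
# clades, P(N = n) = (n - 1) p^2 (1 - p)^(n - 2), p = exp(-lambda T)
oracle_yule_crown_pmf <- function(n, lambda, t) {
  p <- exp(-lambda * t)
  ifelse(n >= 2, (n - 1) * p^2 * (1 - p)^(n - 2), 0)
}

# dedicated Brownian-motion simulator: one rnorm per edge in cladewise order
# (the trait simulator must reproduce this exactly at alpha = 0, no windows)
oracle_bm_sim <- function(tree, sigma2, x0, seed) {
  set.seed(seed)
  tr <- ape::reorder.phylo(tree, "cladewise")
  n_tip <- ape::Ntip(tr)
  val <- numeric(n_tip + tr$Nnode)
  val[n_tip + 1L] <- x0
  for (i in seq_len(nrow(tr$edge))) {
    p <- tr$edge[i, 1]
    k <- tr$edge[i, 2]
    val[k] <- val[p] + sqrt(sigma2 * tr$edge.length[i]) * rnorm(1)
  }
  stats::setNames(val[seq_len(n_tip)], tr$tip.label)
}

# interval event/lineage-time bookkeeping by explicit per-branch loop
oracle_km <- function(tree, old, young) {
  ages <- radburst::node_ages_bp(tree)
  n_tip <- ape::Ntip(tree)
  B <- 0
  for (v in setdiff(n_tip + seq_len(tree$Nnode), n_tip + 1L)) {
    if (ages[v] > young && ages[v] <= old) B <- B + 1
  }
  L <- 0
  for (i in seq_len(nrow(tree$edge))) {
    a <- ages[tree$edge[i, 2]]  # younger end
    b <- ages[tree$edge[i, 1]]  # older end
    L <- L + max(0, min(b, old) - max(a, young))
  }
  c(B = B, L = L)
}

# OU tip covariance for small trees from explicit root-paths: shared time
# s_ij computed by walking both tips' ancestor paths (independent of
# ape::vcv.phylo and of the package's matrix construction)
oracle_ou_vcv <- function(tree, sigma2, alpha) {
  n_tip <- ape::Ntip(tree)
  parent <- integer(n_tip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  depth <- radburst::node_ages(tree)
  path <- function(v) {
    out <- v
    while (parent[v] != 0L) {
      v <- parent[v]
      out <- c(out, v)
    }
    out
  }
  V <- matrix(0, n_tip, n_tip)
  for (i in seq_len(n_tip)) {
    for (j in seq_len(n_tip)) {
      # deepest common ancestor by node depth
      common <- intersect(path(i), path(j))
      mrca <- common[which.max(depth[common])]
      s <- depth[mrca]
      di <- depth[i]
      dj <- depth[j]
      V[i, j] <- if (alpha == 0) {
        sigma2 * s
      } else {
        sigma2 / (2 * alpha) * (1 - exp(-2 * alpha * s)) *
          exp(-alpha * (di + dj - 2 * s))
      }
    }
  }
  V
}

# planted-shift tree: an unconditioned pure-birth background with one nested
# clade simulated at 10x the background speciation rate, grafted with a short
# stem. Both children of the planted crown carry >= 3 tips so the shifted
# node is identifiable (otherwise crown vs big-child placement differ by one
# lone tip only).
sim_planted_shift_tree <- function(lambda_bg = 0.1, t_bg = 25,
                                   lambda_fast = 1.0, t_fast = 3.8,
                                   stem = 0.4) {
  repeat {
    bg <- radburst::sim_bd_tree(lambda_bg, 0, t_bg)
    if (is.null(bg) || ape::Ntip(bg) < 15 || ape::Ntip(bg) > 50) next
    parent_bp <- radburst::node_ages_bp(bg)[bg$edge[, 1]]
    elig <- bg$edge[bg$edge[, 2] <= ape::Ntip(bg) &
                      parent_bp > t_fast + stem, 2]
    if (length(elig) > 0) break
  }
  repeat {
    fast <- radburst::sim_bd_tree(lambda_fast, 0, t_fast)
    n <- ape::Ntip(fast)
    if (n < 20 || n > 70) next
    kids <- fast$edge[fast$edge[, 1] == n + 1L, 2]
    nt <- vapply(kids, function(k) {
      if (k <= n) 1L else ape::Ntip(ape::extract.clade(fast, k))
    }, integer(1))
    if (all(nt >= 3)) break
  }
  host <- elig[sample.int(length(elig), 1L)]
  fast$tip.label <- paste0("x", seq_len(ape::Ntip(fast)))
  fast$root.edge <- stem
  tr <- ape::bind.tree(bg, fast, where = host, position = t_fast + stem)
  tr <- ape::drop.tip(tr, bg$tip.label[host])
  true_node <- ape::getMRCA(tr, grep("^x", tr$tip.label, value = TRUE))
  list(tree = tr, true_node = true_node,
       parent_node = tr$edge[tr$edge[, 2] == true_node, 1])
}
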