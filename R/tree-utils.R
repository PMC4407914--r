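# Shared tree bookkeeping. Internal convention: node "age" runs forward from
# the root (root = 0, tips = crown age). User-facing tables also report ages
# before present (tips = 0); conversion happens at the boundary.

#' Node ages measured forward from the root
#'
#' @param tree A `phylo` object.
#' @return Numeric vector over all nodes (tips first, then internals, in
#'   `ape` numbering): distance from the root in the tree's time units.
#' @export
node_ages <- function(tree) {
  check_phylo(tree)
  ape::node.depth.edgelength(tree)
}

#' Crown age of an ultrametric tree
#'
#' @param tree A `phylo` object; must be ultrametric.
#' @return Root-to-tip distance in the tree's time units (myr).
#' @export
crown_age <- function(tree) {
  assert_ultrametric(tree)
  max(node_ages(tree))
}

#' Node ages before the present
#'
#' @param tree An ultrametric `phylo` object.
#' @return Numeric vector over all nodes: time before present (tips = 0).
#' @export
node_ages_bp <- function(tree) {
  ages <- node_ages(tree)
  max(ages) - ages
}

check_phylo <- function(tree, arg = "tree") {
  if (!inherits(tree, "phylo")) {
    abort(sprintf("`%s` must be a `phylo` object.", arg))
  }
  invisible(tree)
}

#' Test whether a tree is ultrametric
#'
#' Relative tolerance on the spread of root-to-tip distances; stricter than
#' the `ape` default so corrupted chronograms are caught early.
#'
#' @param tree A `phylo` object.
#' @param tol Relative tolerance (default `1e-9`).
#' @return Logical scalar.
#' @export
is_ultrametric_tree <- function(tree, tol = 1e-9) {
  check_phylo(tree)
  depths <- node_ages(tree)[seq_len(ape::Ntip(tree))]
  diff(range(depths)) <= tol * max(depths, .Machine$double.eps)
}

assert_ultrametric <- function(tree, tol = 1e-8) {
  check_phylo(tree)
  if (!is_ultrametric_tree(tree, tol)) {
    abort("`tree` must be ultrametric (all tips contemporaneous).")
  }
  invisible(tree)
}

# Tips descending from each node, as a list indexed by node id.
descendant_tips <- function(tree) {
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  out <- vector("list", n_node)
  for (i in seq_len(n_tip)) out[[i]] <- i
  post <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(post$edge))) {
    p <- post$edge[e, 1]
    k <- post$edge[e, 2]
    out[[p]] <- c(out[[p]], out[[k]])
  }
  out
}

# Coerce a trait input (named vector, or data frame with species + value
# columns) to a named vector aligned with the tree's tip labels.
as_trait_vector <- function(traits, tree, trait = NULL) {
  if (is.data.frame(traits)) {
    species_col <- intersect(c("species", "tip", "label"), names(traits))[1]
    if (is.na(species_col)) {
      abort("Trait data frames need a `species` column.")
    }
    if (is.null(trait)) {
      value_cols <- setdiff(names(traits), species_col)
      if ("value" %in% value_cols) {
        trait <- "value"
      } else if (length(value_cols) == 1L) {
        trait <- value_cols
      } else {
        abort("Multiple trait columns present; pick one with `trait`.")
      }
    }
    if (!trait %in% names(traits)) {
      abort(sprintf("Trait column `%s` not found.", trait))
    }
    x <- setNames(traits[[trait]], traits[[species_col]])
  } else if (is.numeric(traits) && !is.null(names(traits))) {
    x <- traits
  } else {
    abort("`traits` must be a named numeric vector or a data frame.")
  }
  missing_tips <- setdiff(tree$tip.label, names(x))
  if (length(missing_tips) > 0) {
    abort(paste0(
      "Missing trait values for tips: ",
      paste(missing_tips, collapse = ", ")
    ))
  }
  x <- x[tree$tip.label]
  if (anyNA(x) || any(!is.finite(x))) {
    bad <- tree$tip.label[!is.finite(x)]
    abort(paste0(
      "Non-finite trait values for tips: ", paste(bad, collapse = ", ")
    ))
  }
  x
}

# Merge node ages that coincide within tolerance (simultaneous divergences);
# returns sorted unique representative ages.
merge_tied_ages <- function(ages, tol = 1e-9) {
  ages <- sort(ages)
  if (length(ages) <= 1) return(ages)
  scale <- max(abs(ages), 1)
  keep <- c(TRUE, diff(ages) > tol * scale)
  ages[keep]
}
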