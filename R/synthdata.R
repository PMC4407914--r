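# Synthetic fixture generation: a small radiation-shaped data set (tree,
# traits, richness) with the statistical signatures every analysis stage
# needs, so the full pipeline is testable without external downloads. The
# fixture emulates the *shape* of a notothenioid-like data set - it makes no
# claim about any real topology or trait values.

#' Generate a synthetic radiation fixture
#'
#' Builds a 49-tip ultrametric tree of crown age 13.4 myr with three
#' successively diverging species-poor outgroup lineages, a young
#' species-rich focal clade (crown at ~71% of the root age), and a very
#' young species-rich subclade nested inside it (crown age 1.2 myr, grafted
#' at a 3.5-myr stem); simulates five continuous traits under BM/OU models
#' with literature-scale parameters (e.g. a strongly constrained shape axis,
#' OU with alpha = 0.30 and sigma2 = 39.05; buoyancy as BM with
#' sigma2 = 0.23); and assigns extant-species richness summing to
#' `total_richness` with `focal_richness` in the focal clade. The habitat
#' temperature trait is truncated below at -1.86 (the freezing point of sea
#' water) and one deep focal lineage is set to a warm outlier value (7.64) to
#' mimic a secondarily temperate species.
#'
#' @param seed Integer seed; the fixture is byte-identical given the seed.
#' @param n_tips Total tip count (default 49; 3 outgroup tips).
#' @param crown_age Crown age in myr (default 13.4).
#' @param total_richness Total species count across all tips (default 132).
#' @param focal_richness Species count in the focal clade (default 122).
#' @param fast_clade_size,fast_crown_age,fast_stem_age Size and ages of the
#'   young nested subclade (defaults 7 tips, 1.2 myr crown, 3.5 myr stem).
#' @return A list of class `radburst_fixture`: `tree` (phylo), `traits`
#'   (tibble: `species` + 5 trait columns), `richness` (tibble: `species`,
#'   `n_species`), `clades` (tibble: `species`, `clade`, `role`),
#'   `trait_models` (tibble of generating parameters).
#' @export
make_fixture <- function(seed = 1, n_tips = 49, crown_age = 13.4,
                         total_richness = 132, focal_richness = 122,
                         fast_clade_size = 7, fast_crown_age = 1.2,
                         fast_stem_age = 3.5) {
  n_out <- 3L
  n_focal <- n_tips - n_out
  n_backbone <- n_focal - fast_clade_size + 1L  # one tip is replaced
  if (n_backbone < 4) abort("Clade plan infeasible: too few backbone tips.")
  out_richness <- total_richness - focal_richness
  if (out_richness < n_out || focal_richness < n_focal) {
    abort("Richness plan infeasible for the requested tip counts.")
  }
  set.seed(seed)

  focal_crown <- crown_age * 0.71
  # the graft needs a pendant branch crossing the fast clade's stem age
  repeat {
    backbone <- sim_conditioned_tree(focal_crown, n_backbone, lambda = 0.35)
    backbone$tip.label <- paste0("m", formatC(seq_len(n_backbone), width = 2,
                                              flag = "0"))
    parent_bp <- node_ages_bp(backbone)[backbone$edge[, 1]]
    tip_edges <- backbone$edge[, 2] <= ape::Ntip(backbone)
    eligible <- backbone$edge[tip_edges & parent_bp > fast_stem_age, 2]
    if (length(eligible) > 0) break
  }
  host_tip <- eligible[sample.int(length(eligible), 1L)]
  host_label <- backbone$tip.label[host_tip]
  fast <- sim_conditioned_tree(fast_crown_age, fast_clade_size, lambda = 2.5)
  fast$tip.label <- paste0("f", seq_len(fast_clade_size))
  fast$root.edge <- fast_stem_age - fast_crown_age
  grafted <- ape::bind.tree(backbone, fast, where = host_tip,
                            position = fast_stem_age)
  grafted <- ape::drop.tip(grafted, host_label)
  # pectinate spine of old, species-poor outgroup lineages below the focal
  # clade (divergences at 100%, 92% and 86% of the crown age)
  spine <- crown_age * c(1, 0.92, 0.86)
  focal_part <- sub(";$", "", ape::write.tree(grafted))
  tree <- ape::read.tree(text = sprintf(
    "(og1:%.10f,(og2:%.10f,(og3:%.10f,%s:%.10f):%.10f):%.10f);",
    spine[1], spine[2], spine[3],
    focal_part, spine[3] - focal_crown,
    spine[2] - spine[3], spine[1] - spine[2]
  ))
  stopifnot(is_ultrametric_tree(tree, tol = 1e-6))

  trait_models <- tibble::tibble(
    trait = c("cv1", "cv2", "body_size_log", "buoyancy", "temperature"),
    model = c("BM", "OU", "OU", "BM", "OU"),
    sigma2 = c(3.47, 39.05, 0.12, 0.23, 2.37),
    alpha = c(0, 0.30, 0.11, 0, 0.25),
    x0 = c(0, 0, 0, 0, -1)
  )
  traits <- tibble::tibble(species = tree$tip.label)
  for (i in seq_len(nrow(trait_models))) {
    sim <- sim_trait(tree, sigma2 = trait_models$sigma2[i],
                     alpha = trait_models$alpha[i],
                     theta = trait_models$x0[i], x0 = trait_models$x0[i])
    traits[[trait_models$trait[i]]] <-
      sim$value[match(tree$tip.label, sim$species)]
  }
  # sea water freezes at -1.86: hard lower bound by truncation
  traits$temperature <- pmax(traits$temperature, -1.86)
  # one focal species with a warm, temperate distribution despite a recent
  # divergence from a cold-water sister: the recently split pair carries a
  # huge late trait contrast, the driver of strongly positive temperature MDI
  backbone_tips <- grep("^m", tree$tip.label, value = TRUE)
  pend <- setNames(tree$edge.length[match(
    match(backbone_tips, tree$tip.label), tree$edge[, 2]
  )], backbone_tips)
  outlier_tip <- names(which.min(pend))
  traits$temperature[traits$species == outlier_tip] <- 7.64

  focal_tips <- grep("^m|^f", tree$tip.label, value = TRUE)
  richness <- setNames(rep(1L, n_tips), tree$tip.label)
  richness[paste0("og", seq_len(n_out))] <- .split_richness(out_richness,
                                                            n_out)
  extra <- focal_richness - length(focal_tips)
  rich_tips <- head(sort(grep("^m", tree$tip.label, value = TRUE)), 5)
  richness[rich_tips] <- richness[rich_tips] +
    .split_extras(extra, length(rich_tips))
  stopifnot(sum(richness) == total_richness,
            sum(richness[focal_tips]) == focal_richness)

  clades <- tibble::tibble(
    species = tree$tip.label,
    clade = dplyr::case_when(
      grepl("^og", tree$tip.label) ~ "outgroup",
      grepl("^f", tree$tip.label) ~ "focal_fast",
      TRUE ~ "focal"
    ),
    role = dplyr::if_else(tree$tip.label == outlier_tip,
                          "temperate_outlier", "regular")
  )
  out <- list(
    tree = tree,
    traits = traits,
    richness = tibble::tibble(species = names(richness),
                              n_species = unname(richness)),
    clades = clades,
    trait_models = trait_models,
    params = list(seed = seed, n_tips = n_tips, crown_age = crown_age,
                  total_richness = total_richness,
                  focal_richness = focal_richness)
  )
  class(out) <- "radburst_fixture"
  out
}

# n species over k tips, each >= 1, front-loaded deterministically
.split_richness <- function(n, k) {
  base <- rep(1L, k)
  base[1] <- base[1] + as.integer(n - k)
  base
}

# extra species over k already-counted tips, decreasing allocation
.split_extras <- function(extra, k) {
  w <- rev(seq_len(k))
  alloc <- floor(extra * w / sum(w))
  rem <- extra - sum(alloc)
  alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1L
  as.integer(alloc)
}

#' @export
print.radburst_fixture <- function(x, ...) {
  cat(sprintf(
    "Synthetic radiation fixture: %d tips, crown age %.2f myr, %d species total (%d focal)\n",
    ape::Ntip(x$tree), x$params$crown_age, x$params$total_richness,
    x$params$focal_richness
  ))
  cat("Traits:", paste(setdiff(names(x$traits), "species"), collapse = ", "),
      "\n")
  invisible(x)
}
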