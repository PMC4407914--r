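# Readers and writers for the package's interchange formats: Newick/NEXUS
# trees (via ape), and tab-separated trait and richness tables. Ages are
# serialized before-present (tips = 0) wherever tables carry times.

#' Read trees from Newick or NEXUS files
#'
#' Parses one or more trees, validates tip-label uniqueness, and flags each
#' tree's ultrametricity in an `ultrametric` attribute. Non-ultrametric trees
#' are accepted here; stages requiring a chronogram reject them at use.
#'
#' @param path File path.
#' @param format `"auto"` (by extension/content), `"newick"` or `"nexus"`.
#' @return A list of `phylo` objects (class `multiPhylo`), order preserved.
#' @export
read_trees <- function(path, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (format == "auto") {
    first <- toupper(trimws(readLines(path, n = 1, warn = FALSE)))
    format <- if (startsWith(first, "#NEXUS")) "nexus" else "newick"
  }
  trees <- tryCatch(
    if (format == "nexus") ape::read.nexus(path) else ape::read.tree(path),
    error = function(e) {
      abort(sprintf("Could not parse %s as %s: %s", path, format,
                    conditionMessage(e)))
    }
  )
  if (inherits(trees, "phylo")) {
    trees <- structure(list(trees), class = "multiPhylo")
  }
  for (i in seq_along(trees)) {
    labs <- trees[[i]]$tip.label
    if (anyDuplicated(labs)) {
      abort(sprintf("Tree %d has duplicate tip labels: %s", i,
                    paste(unique(labs[duplicated(labs)]), collapse = ", ")))
    }
    attr(trees[[i]], "ultrametric") <- is_ultrametric_tree(trees[[i]], 1e-6)
  }
  trees
}

#' Write trees to a Newick file
#'
#' @param trees A `phylo`, `multiPhylo` or list of `phylo`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trees <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  class(trees) <- "multiPhylo"
  ape::write.tree(trees, file = path)
  invisible(path)
}

#' Read a species-by-trait table
#'
#' Tab-separated with a header; one `species` column, all other columns
#' numeric traits. Missing values stay `NA` (they are never treated as
#' zero); non-numeric cells raise an error naming the offending rows.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_traits <- function(path) {
  df <- .read_tsv(path)
  if (!"species" %in% names(df)) abort("Trait tables need a `species` column.")
  for (col in setdiff(names(df), "species")) {
    raw <- df[[col]]
    parsed <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & is.na(parsed))
    if (length(bad) > 0) {
      abort(sprintf("Non-numeric values in trait `%s`, row(s) %s.", col,
                    paste(bad, collapse = ", ")))
    }
    parsed[raw == ""] <- NA_real_
    df[[col]] <- parsed
  }
  tibble::as_tibble(df)
}

#' Read a clade-richness table
#'
#' Tab-separated with columns `species` (tip label) and `n_species`
#' (integer extant richness of the terminally unresolved clade).
#'
#' @param path File path.
#' @return A tibble with `species` and integer `n_species`.
#' @export
read_richness <- function(path) {
  df <- .read_tsv(path)
  if (!all(c("species", "n_species") %in% names(df))) {
    abort("Richness tables need `species` and `n_species` columns.")
  }
  n <- suppressWarnings(as.numeric(df$n_species))
  bad <- which(is.na(n) | n != round(n) | n < 1)
  if (length(bad) > 0) {
    abort(sprintf("Richness must be integers >= 1; bad row(s): %s.",
                  paste(bad, collapse = ", ")))
  }
  tibble::tibble(species = as.character(df$species), n_species = as.integer(n))
}

.read_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
}

#' Write a tibble as TSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
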