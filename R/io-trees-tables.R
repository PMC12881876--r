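#' Read a time-calibrated phylogeny
#'
#' Thin wrapper around [ape::read.tree()] that checks the structural
#' assumptions downstream comparative analyses rely on: branch lengths
#' present and non-negative, tip labels unique.
#'
#' @param path newick file.
#' @return an [ape::phylo] tree.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick in ", path, call. = FALSE)
  validate_tree(tree)
  tree
}

validate_tree <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths", call. = FALSE)
  if (anyDuplicated(tree$tip.label) > 0) stop("tree tip labels are not unique", call. = FALSE)
  invisible(tree)
}

#' Prune a phylogeny to a tip set
#'
#' Retains exactly `keep_tips`, collapsing the freed internal nodes so that
#' path lengths between retained tips are unchanged.
#'
#' @param tree an [ape::phylo] tree.
#' @param keep_tips character vector of tip labels to keep.
#' @return the pruned tree.
#' @export
prune_tree <- function(tree, keep_tips) {
  absent <- setdiff(keep_tips, tree$tip.label)
  if (length(absent) > 0) {
    stop("tip(s) not in tree: ", paste(absent, collapse = ", "), call. = FALSE)
  }
  ape::keep.tip(tree, keep_tips)
}

#' Write and re-read result tables
#'
#' Plain-CSV persistence for the pipeline's tabular outputs (complexity
#' records, PC scores, ANOVA and disparity tables). `read_results_table()`
#' restores what `write_results_table()` wrote, so tables round-trip
#' losslessly.
#'
#' @param records a data frame (possibly empty: a header-only file results).
#' @param path output CSV path.
#' @return `path` invisibly; `read_results_table()` returns a tibble.
#' @export
write_results_table <- function(records, path) {
  records <- tibble::as_tibble(records)
  ok <- tryCatch(
    {
      readr::write_csv(records, path, progress = FALSE)
      TRUE
    },
    error = function(e) e
  )
  if (!isTRUE(ok)) stop("could not write ", path, ": ", conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read a specimen metadata table
#'
#' Metadata CSV with one row per specimen: `specimen_id`, `species`, `clade`,
#' `age_category` (foetal/infant/subadult/adult), `developmental_mode`
#' (super_altricial to precocial), `diet`, and optionally `centroid_size` and
#' `relative_age`.
#'
#' @param path CSV path.
#' @return a tibble.
#' @export
read_metadata <- function(path) {
  df <- read_results_table(path)
  need <- c("specimen_id", "species", "age_category")
  if (!all(need %in% names(df))) {
    stop("metadata must contain columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(df$age_category), c("foetal", "infant", "subadult", "adult"))
  if (length(bad) > 0) {
    stop("unknown age_category value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  df
}
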