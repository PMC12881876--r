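#' Published reference values for replication checks
#'
#' The headline quantities printed in the original comparative study of
#' cranial-suture ontogeny whose supplementary appendices this pipeline can
#' re-analyse: PC1 variance shares per suture for the full developmental
#' dataset, and ancestral coronal/interfrontal/sagittal PSD complexity for the
#' marsupial and placental most recent common ancestors. Used only as the
#' comparison column of [replicate_study()]'s report; nothing in the pipeline
#' computes from them.
#'
#' @return a tibble with `check`, `quantity`, `published`.
#' @export
replication_reference <- function() {
  tibble::tribble(
    ~check, ~quantity, ~published,
    "pc_variance", "interfrontal_pc1_percent", 55.72,
    "pc_variance", "sagittal_pc1_percent", 50.19,
    "pc_variance", "coronal_pc1_percent", 40.76,
    "ancestral_psd", "marsupial_coronal_psd", 1.705,
    "ancestral_psd", "placental_coronal_psd", 1.532,
    "ancestral_psd", "marsupial_interfrontal_psd", 1.461,
    "ancestral_psd", "placental_interfrontal_psd", 1.474,
    "ancestral_psd", "marsupial_sagittal_psd", 1.457,
    "ancestral_psd", "placental_sagittal_psd", 1.448
  )
}

#' Replicate the published analyses from supplementary data
#'
#' Recomputes what the supplied supplementary files permit and reports each
#' quantity side by side with its published value. Checks whose inputs are
#' absent are marked `SKIPPED`, never failed, so the report degrades
#' gracefully with partial inputs.
#'
#' Supported inputs (all optional):
#' * `pc_scores` — CSV of per-specimen PC scores with columns `suture`,
#'   `PC1`, `PC2`, ... : variance shares are recomputed from the score
#'   columns.
#' * `complexity` — CSV of adult per-species complexity scores with columns
#'   `species`, `suture`, `psd` (and optionally `fd`).
#' * `metadata` — CSV mapping `species` to `clade`.
#' * `tree` — newick time-calibrated phylogeny covering the adult species.
#'   With `complexity` + `metadata` + `tree`, ancestral marsupial/placental
#'   PSD values are re-estimated by Brownian-motion ML.
#'
#' @param paths named list of file paths (see above).
#' @param reference comparison table, by default [replication_reference()].
#' @return a tibble: `check`, `quantity`, `published`, `recomputed`,
#'   `abs_diff`, `status` (`OK`/`SKIPPED`).
#' @export
replicate_study <- function(paths = list(), reference = replication_reference()) {
  out <- dplyr::mutate(reference,
    recomputed = NA_real_, abs_diff = NA_real_, status = "SKIPPED"
  )
  put <- function(out, quantity, value) {
    i <- out$quantity == quantity
    out$recomputed[i] <- value
    out$abs_diff[i] <- abs(value - out$published[i])
    out$status[i] <- "OK"
    out
  }
  if (!is.null(paths$pc_scores) && file.exists(paths$pc_scores)) {
    sc <- read_results_table(paths$pc_scores)
    pc_cols <- grep("^PC[0-9]+$", names(sc), value = TRUE)
    for (su in unique(sc$suture)) {
      d <- sc[sc$suture == su, pc_cols, drop = FALSE]
      v <- vapply(d, var, numeric(1))
      out <- put(out, paste0(su, "_pc1_percent"), 100 * v[1] / sum(v))
    }
  }
  have_anc <- all(vapply(
    c("complexity", "metadata", "tree"),
    function(k) !is.null(paths[[k]]) && file.exists(paths[[k]]), logical(1)
  ))
  if (have_anc) {
    comp <- read_results_table(paths$complexity)
    meta <- read_results_table(paths$metadata)
    tree <- read_tree(paths$tree)
    comp <- dplyr::left_join(comp, meta[c("species", "clade")], by = "species")
    tree <- prune_tree(tree, intersect(tree$tip.label, unique(comp$species)))
    for (su in unique(comp$suture)) {
      d <- comp[comp$suture == su & comp$species %in% tree$tip.label, ]
      est <- asr_bm_ml(tree, setNames(d$psd, d$species))
      for (cl in c("Marsupialia", "Placentalia")) {
        tips <- d$species[d$clade == cl]
        if (length(tips) < 1) next
        val <- tryCatch(clade_ancestor_value(est, tips), error = function(e) NA_real_)
        if (!is.na(val)) {
          out <- put(out, paste0(
            tolower(sub("ia$", "", cl)), "_", su, "_psd"
          ), val)
        }
      }
    }
  }
  out
}
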