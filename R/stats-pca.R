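#' Vectorize a study's suture shapes
#'
#' Flattens one suture's semilandmark configurations into an n-specimens by
#' (points x dimensions) matrix, the response form used by the PCA, ANOVA,
#' disparity and trajectory functions.
#'
#' @param study a `suture_study` tibble after alignment (and projection for
#'   2D).
#' @param suture `"interfrontal"`, `"sagittal"` or `"coronal"`.
#' @param space `"3d"` (aligned semilandmarks) or `"2d"` (projected curves).
#' @return a numeric matrix with specimen ids as rownames.
#' @export
shape_matrix <- function(study, suture = SUTURE_NAMES, space = c("3d", "2d")) {
  suture <- match.arg(suture)
  space <- match.arg(space)
  col <- if (space == "3d") "curves_aligned" else "curves_2d"
  if (!col %in% names(study)) stop("study lacks column '", col, "'", call. = FALSE)
  mats <- lapply(study[[col]], function(cl) as.vector(cl[[suture]]))
  out <- do.call(rbind, mats)
  rownames(out) <- study$specimen_id
  out
}

#' Principal component analysis of suture shapes
#'
#' Eigen-decomposition of the mean-centred covariance of vectorized shapes;
#' scores are projections of the centred data on the eigenvectors and the
#' percent variance of each component is its eigenvalue share.
#'
#' @param shapes n x p numeric matrix (rows are specimens), e.g. from
#'   [shape_matrix()].
#' @return a `suture_pca` object with `scores`, `loadings`,
#'   `percent_variance` and `consensus` (the mean shape vector). Use [tidy()]
#'   for per-component summaries and [autoplot()] for the morphospace.
#' @export
shape_pca <- function(shapes) {
  shapes <- as.matrix(shapes)
  if (nrow(shapes) < 2) stop("PCA needs at least 2 specimens", call. = FALSE)
  pc <- prcomp(shapes, center = TRUE, scale. = FALSE)
  keep <- pc$sdev^2 > max(pc$sdev^2) * 1e-12
  ev <- pc$sdev[keep]^2
  structure(
    list(
      scores = pc$x[, keep, drop = FALSE],
      loadings = pc$rotation[, keep, drop = FALSE],
      percent_variance = 100 * ev / sum(pc$sdev^2),
      consensus = pc$center,
      n = nrow(shapes)
    ),
    class = "suture_pca"
  )
}

#' @export
print.suture_pca <- function(x, ...) {
  cat(
    "Suture shape PCA:", x$n, "specimens,", length(x$percent_variance),
    "non-null components\n"
  )
  pv <- utils::head(x$percent_variance, 5)
  cat(
    "  ", paste(sprintf("PC%d %.2f%%", seq_along(pv), pv), collapse = ", "),
    if (length(x$percent_variance) > 5) "..." else "", "\n"
  )
  invisible(x)
}

#' @export
tidy.suture_pca <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$percent_variance),
    std_dev = apply(x$scores, 2, sd),
    percent_variance = x$percent_variance,
    cumulative_variance = cumsum(x$percent_variance)
  )
}

#' @export
glance.suture_pca <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_components = length(x$percent_variance),
    pc1_percent = x$percent_variance[1],
    pc2_percent = if (length(x$percent_variance) > 1) x$percent_variance[2] else NA_real_
  )
}

#' Augment PC scores with specimen metadata
#'
#' @param pca a `suture_pca` object.
#' @param study the study the shapes came from (matched on `specimen_id`).
#' @param components how many components to keep (default 4).
#' @return a tibble of metadata plus `PC1..PCk` columns.
#' @export
pca_scores <- function(pca, study = NULL, components = 4L) {
  k <- min(components, ncol(pca$scores))
  sc <- tibble::as_tibble(pca$scores[, seq_len(k), drop = FALSE])
  sc$specimen_id <- rownames(pca$scores)
  if (!is.null(study)) {
    meta_cols <- intersect(
      c(
        "specimen_id", "species", "clade", "age_category",
        "developmental_mode", "diet", "centroid_size", "relative_age"
      ),
      names(study)
    )
    sc <- dplyr::left_join(sc, tibble::as_tibble(study)[meta_cols], by = "specimen_id")
  }
  dplyr::relocate(sc, "specimen_id")
}

#' @export
autoplot.suture_pca <- function(object, study = NULL, colour = "age_category", ...) {
  df <- pca_scores(object, study)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if (!is.null(study) && colour %in% names(df)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]), size = 2)
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::labs(
    x = sprintf("PC1 (%.1f%%)", object$percent_variance[1]),
    y = sprintf("PC2 (%.1f%%)", object$percent_variance[2])
  ) + ggplot2::theme_minimal()
}
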