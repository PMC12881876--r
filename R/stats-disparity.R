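#' Morphological disparity as Procrustes variance
#'
#' Procrustes variance of a group is the mean squared Procrustes distance of
#' its members to the group mean shape, divided by the number of
#' semilandmarks (so values are comparable across sutures sampled with
#' different point counts). Pairwise absolute differences between group
#' variances are tested by permutation of group labels.
#'
#' Allometric adjustment (optional) removes size-driven disparity before
#' measuring: `"residual"` (default when `log_sizes` given) computes variances
#' on the residuals of the multivariate regression of shape on log centroid
#' size; `"divide"` divides each specimen's coordinates by its log centroid
#' size — the literal form of the adjustment this pipeline also supports for
#' replication purposes.
#'
#' @param shapes n x p matrix of vectorized shapes.
#' @param groups grouping factor of length n.
#' @param log_sizes log centroid sizes (required for adjustment).
#' @param n_semilandmarks divisor for the per-group variances (default: the
#'   point count implied by `ncol(shapes)` assuming `dims` coordinates per
#'   point).
#' @param dims coordinates per point used to infer `n_semilandmarks`
#'   (default 3).
#' @param adjust `"none"`, `"residual"` or `"divide"`.
#' @param n_perm label permutations for the pairwise tests (default 1000).
#' @param seed RNG seed (default 42).
#' @return a `suture_disparity` object: per-group variances, pairwise
#'   absolute differences and permutation p-values.
#' @export
shape_disparity <- function(shapes, groups, log_sizes = NULL,
                            n_semilandmarks = NULL, dims = 3L,
                            adjust = c("none", "residual", "divide"),
                            n_perm = 1000L, seed = 42L) {
  shapes <- as.matrix(shapes)
  adjust <- match.arg(adjust)
  groups <- factor(groups)
  if (is.null(n_semilandmarks)) n_semilandmarks <- ncol(shapes) / dims
  if (adjust != "none") {
    if (is.null(log_sizes)) stop("allometric adjustment needs log_sizes", call. = FALSE)
    shapes <- switch(adjust,
      residual = resid(lm(shapes ~ log_sizes)),
      divide = shapes / log_sizes
    )
  }
  pv_of <- function(idx) {
    g <- groups[idx]
    vapply(levels(groups), function(lv) {
      m <- shapes[idx[g == lv], , drop = FALSE]
      if (nrow(m) == 0) {
        return(NA_real_)
      }
      ctr <- colMeans(m)
      mean(rowSums(sweep(m, 2, ctr)^2)) / n_semilandmarks
    }, numeric(1))
  }
  pv <- pv_of(seq_along(groups))
  lv <- levels(groups)
  small <- names(which(table(groups) < 2))
  diffs <- abs(outer(pv, pv, `-`))
  dimnames(diffs) <- list(lv, lv)

  pmat <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  if (length(lv) >= 2 && n_perm > 0) {
    set.seed(seed)
    exceed <- matrix(0L, length(lv), length(lv))
    for (b in seq_len(n_perm)) {
      gp <- sample(groups)
      pvp <- vapply(lv, function(l) {
        m <- shapes[gp == l, , drop = FALSE]
        if (nrow(m) == 0) {
          return(NA_real_)
        }
        mean(rowSums(sweep(m, 2, colMeans(m))^2)) / n_semilandmarks
      }, numeric(1))
      exceed <- exceed + (abs(outer(pvp, pvp, `-`)) >= diffs - 1e-15)
    }
    pmat <- (exceed + 1) / (n_perm + 1)
    diag(pmat) <- NA_real_
    pmat[small, ] <- NA_real_
    pmat[, small] <- NA_real_
  }
  structure(
    list(
      group_variances = tibble::tibble(group = lv, procrustes_variance = unname(pv)),
      pairwise_abs_diffs = diffs, pairwise_p = pmat,
      n_permutations = n_perm, seed = seed, adjust = adjust,
      excluded_groups = small
    ),
    class = "suture_disparity"
  )
}

#' @export
print.suture_disparity <- function(x, ...) {
  cat("Procrustes-variance disparity (", x$adjust, " adjustment, ",
    x$n_permutations, " permutations)\n",
    sep = ""
  )
  print(as.data.frame(x$group_variances), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
tidy.suture_disparity <- function(x, ...) {
  lv <- x$group_variances$group
  pairs <- which(upper.tri(x$pairwise_abs_diffs), arr.ind = TRUE)
  tibble::tibble(
    group_1 = lv[pairs[, 1]], group_2 = lv[pairs[, 2]],
    variance_1 = x$group_variances$procrustes_variance[pairs[, 1]],
    variance_2 = x$group_variances$procrustes_variance[pairs[, 2]],
    abs_diff = x$pairwise_abs_diffs[pairs],
    p_value = x$pairwise_p[pairs]
  )
}

#' @export
glance.suture_disparity <- function(x, ...) {
  tibble::tibble(
    n_groups = nrow(x$group_variances),
    max_variance = max(x$group_variances$procrustes_variance, na.rm = TRUE),
    n_permutations = x$n_permutations, seed = x$seed
  )
}

#' @export
autoplot.suture_disparity <- function(object, ...) {
  ggplot2::ggplot(
    object$group_variances,
    ggplot2::aes(x = .data$group, y = .data$procrustes_variance)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Procrustes variance") +
    ggplot2::theme_minimal()
}
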