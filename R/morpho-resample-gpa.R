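#' Resample a curve to equally spaced points by arc length
#'
#' Places `n` points at equal arc-length spacing along the piecewise-linear
#' input curve; the two endpoints are preserved exactly. Idempotent for curves
#' that are already equally spaced.
#'
#' @param curve m x d ordered point matrix (m >= 2, positive total length).
#' @param n number of output points (default 500, the semilandmark count used
#'   throughout the pipeline).
#' @return an n x d matrix.
#' @export
resample_curve <- function(curve, n = 500L) {
  curve <- as.matrix(curve)
  if (nrow(curve) < 2) stop("curve needs at least 2 points", call. = FALSE)
  s <- arc_lengths(curve)
  total <- s[length(s)]
  if (total <= 0) stop("curve has zero arc length", call. = FALSE)
  target <- seq(0, total, length.out = n)
  out <- sapply(seq_len(ncol(curve)), function(d) approx(s, curve[, d], xout = target, ties = "ordered")$y)
  out[1, ] <- curve[1, ]
  out[n, ] <- curve[nrow(curve), ]
  out
}

#' Resample every suture curve in a study
#'
#' @param study a `suture_study` tibble.
#' @param n semilandmarks per suture (default 500).
#' @return the study with resampled `curves`.
#' @export
resample_curves <- function(study, n = 500L) {
  study$curves <- lapply(study$curves, function(cl) lapply(cl, resample_curve, n = n))
  restore_study(study, study)
}

#' Generalized Procrustes superimposition
#'
#' Iterative superimposition of the fixed landmark configurations: each is
#' translated to a zero centroid, scaled to unit centroid size, and rotated by
#' the orthogonal (no-reflection) least-squares rotation onto the running
#' consensus; the consensus is the mean of the rotated set, re-normalized, and
#' iteration stops when it changes by less than `tol`. Suture semilandmarks
#' take no part in the fit: each specimen's translation, scale and rotation is
#' applied to them passively, so they end up expressed in the consensus frame.
#'
#' Superimposition uses `landmarks_full` (originals plus mirrored copies) when
#' present, else `landmarks`. Pre-scaling centroid sizes are recorded in the
#' `centroid_size` column.
#'
#' @param study a `suture_study` tibble with complete configurations.
#' @param tol consensus convergence tolerance (default 1e-9).
#' @param max_iter iteration cap (default 100).
#' @return the study with `aligned` (landmark) and `curves_aligned`
#'   (semilandmark) list-columns, a `centroid_size` column, and the consensus
#'   configuration in the `consensus` attribute.
#' @export
align_gpa <- function(study, tol = 1e-9, max_iter = 100L) {
  use_col <- if ("landmarks_full" %in% names(study)) "landmarks_full" else "landmarks"
  configs <- study[[use_col]]
  n <- length(configs)
  if (n < 2) stop("superimposition needs at least 2 specimens", call. = FALSE)
  centroids <- lapply(configs, colMeans)
  centered <- Map(function(m, c) sweep(as.matrix(m), 2, c), configs, centroids)
  sizes <- vapply(centered, function(m) sqrt(sum(m^2)), numeric(1))
  if (any(sizes <= 0)) stop("degenerate (all-coincident) configuration", call. = FALSE)
  scaled <- Map(`/`, centered, sizes)

  rot_to <- function(m, target) {
    # orthogonal Procrustes rotation, reflections forbidden
    sv <- svd(crossprod(m, target))
    d <- sign(det(sv$v %*% t(sv$u)))
    sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  }
  consensus <- scaled[[1]]
  consensus <- consensus / sqrt(sum(consensus^2))
  rotations <- rep(list(diag(3)), n)
  for (it in seq_len(max_iter)) {
    rotations <- lapply(scaled, rot_to, target = consensus)
    rotated <- Map(`%*%`, scaled, rotations)
    new_cons <- Reduce(`+`, rotated) / n
    new_cons <- sweep(new_cons, 2, colMeans(new_cons))
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    delta <- sqrt(sum((new_cons - consensus)^2))
    consensus <- new_cons
    if (delta < tol) break
  }
  rotations <- lapply(scaled, rot_to, target = consensus)
  aligned <- Map(`%*%`, scaled, rotations)
  consensus <- Reduce(`+`, aligned) / n # reported consensus: arithmetic mean

  study$centroid_size <- sizes
  study$aligned <- aligned
  if ("curves" %in% names(study)) {
    study$curves_aligned <- lapply(seq_len(n), function(i) {
      lapply(study$curves[[i]], function(cv) {
        sweep(as.matrix(cv), 2, centroids[[i]]) %*% rotations[[i]] / sizes[i]
      })
    })
  }
  attr(study, "consensus") <- consensus
  attr(study, "gpa") <- list(iterations = it, tol = tol)
  restore_study(study, study)
}

#' Consensus (mean aligned) landmark configuration of a study
#'
#' @param study a study processed by [align_gpa()].
#' @return the arithmetic mean of the aligned configurations.
#' @export
consensus_shape <- function(study) attr(study, "consensus", exact = TRUE)
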