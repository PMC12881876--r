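#' Ontogenetic allometric trajectory comparison
#'
#' Fits, per species, the multivariate regression of vectorized shape on log
#' centroid size; each species' trajectory is its slope vector (shape change
#' per unit log size). Pairs of species are compared by (a) the angle between
#' their slope vectors and (b) the absolute difference of trajectory lengths
#' (slope-vector norms). Null distributions come from residual randomization:
#' residuals of the common-trajectory model (`shape ~ log_size + species`) are
#' shuffled, per-species slopes refit, and the pairwise statistics recomputed.
#' Raw p-values are Bonferroni-adjusted over all pairs for each statistic.
#'
#' Species whose specimens all share one size cannot define a trajectory and
#' are excluded with a warning.
#'
#' @param shapes n x p matrix of vectorized shapes.
#' @param species species label per specimen (each retained species needs >= 3
#'   specimens spanning >= 2 sizes).
#' @param log_sizes log centroid size per specimen.
#' @param n_perm permutations (default 1000).
#' @param seed RNG seed (default 42).
#' @param count_rule which statistic marks a pair significant in
#'   `significant_pair_count`: `"either"` (default), `"angle"` or `"length"`.
#' @param alpha significance level for the count (default 0.05, on adjusted
#'   p).
#' @return a `suture_trajectories` object; `tidy()` returns the pairwise
#'   table.
#' @export
trajectory_analysis <- function(shapes, species, log_sizes, n_perm = 1000L,
                                seed = 42L, count_rule = c("either", "angle", "length"),
                                alpha = 0.05) {
  count_rule <- match.arg(count_rule)
  shapes <- as.matrix(shapes)
  species <- as.character(species)
  ok_species <- vapply(split(seq_along(species), species), function(idx) {
    length(idx) >= 3 && length(unique(log_sizes[idx])) >= 2
  }, logical(1))
  dropped <- names(ok_species)[!ok_species]
  if (length(dropped) > 0) {
    warning(
      "excluded species without a size range: ",
      paste(dropped, collapse = ", "),
      call. = FALSE
    )
  }
  keep <- species %in% names(ok_species)[ok_species]
  shapes <- shapes[keep, , drop = FALSE]
  species <- species[keep]
  log_sizes <- log_sizes[keep]
  sp <- sort(unique(species))
  if (length(sp) < 2) stop("need at least 2 species with trajectories", call. = FALSE)

  fit_slopes <- function(Y) {
    t(vapply(sp, function(s) {
      i <- species == s
      x <- log_sizes[i] - mean(log_sizes[i])
      drop(crossprod(x, sweep(Y[i, , drop = FALSE], 2, colMeans(Y[i, , drop = FALSE])))) /
        sum(x^2)
    }, numeric(ncol(Y))))
  }
  pair_stats <- function(B) {
    L <- sqrt(rowSums(B^2))
    cosang <- tcrossprod(B / pmax(L, 1e-300))
    ang <- acos(pmax(pmin(cosang, 1), -1)) * 180 / pi
    list(angle = ang, lendiff = abs(outer(L, L, `-`)), lengths = L)
  }
  B_obs <- fit_slopes(shapes)
  obs <- pair_stats(B_obs)

  # common-trajectory reduced model for RRPP
  dat <- data.frame(log_size = log_sizes, species = factor(species))
  X_red <- model.matrix(~ log_size + species, dat)
  H_red <- tcrossprod(qr.Q(qr(X_red))[, seq_len(qr(X_red)$rank), drop = FALSE])
  fit_red <- H_red %*% shapes
  res_red <- shapes - fit_red

  n <- nrow(shapes)
  exceed_ang <- matrix(0L, length(sp), length(sp))
  exceed_len <- matrix(0L, length(sp), length(sp))
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    Yp <- fit_red + res_red[sample.int(n), , drop = FALSE]
    st <- pair_stats(fit_slopes(Yp))
    exceed_ang <- exceed_ang + (st$angle >= obs$angle - 1e-12)
    exceed_len <- exceed_len + (st$lendiff >= obs$lendiff - 1e-12)
  }
  p_ang <- (exceed_ang + 1) / (n_perm + 1)
  p_len <- (exceed_len + 1) / (n_perm + 1)
  n_pairs <- choose(length(sp), 2)
  ut <- which(upper.tri(p_ang), arr.ind = TRUE)
  pairs <- tibble::tibble(
    species_1 = sp[ut[, 1]], species_2 = sp[ut[, 2]],
    angle_deg = obs$angle[ut],
    length_diff = obs$lendiff[ut],
    p_angle = p_ang[ut],
    p_length = p_len[ut],
    p_angle_adj = pmin(1, p_ang[ut] * n_pairs),
    p_length_adj = pmin(1, p_len[ut] * n_pairs)
  )
  sig <- switch(count_rule,
    either = pairs$p_angle_adj < alpha | pairs$p_length_adj < alpha,
    angle = pairs$p_angle_adj < alpha,
    length = pairs$p_length_adj < alpha
  )
  structure(
    list(
      slopes = B_obs, species = sp, trajectory_lengths = setNames(obs$lengths, sp),
      pairs = pairs, significant_pair_count = sum(sig),
      count_rule = count_rule, alpha = alpha,
      n_permutations = n_perm, seed = seed, excluded_species = dropped
    ),
    class = "suture_trajectories"
  )
}

#' @export
print.suture_trajectories <- function(x, ...) {
  cat(
    "Ontogenetic trajectories:", length(x$species), "species,",
    nrow(x$pairs), "pairs;", x$significant_pair_count,
    "significant (", x$count_rule, ", Bonferroni alpha", x$alpha, ")\n"
  )
  invisible(x)
}

#' @export
tidy.suture_trajectories <- function(x, ...) x$pairs

#' @export
glance.suture_trajectories <- function(x, ...) {
  tibble::tibble(
    n_species = length(x$species), n_pairs = nrow(x$pairs),
    significant_pair_count = x$significant_pair_count,
    count_rule = x$count_rule, n_permutations = x$n_permutations, seed = x$seed
  )
}

#' Plot ontogenetic trajectories on a PC axis
#'
#' Scatter of a PC score against log centroid size with per-species
#' least-squares trajectories.
#'
#' @param pca a `suture_pca` object.
#' @param study the originating study (for `species` and sizes).
#' @param component which PC to display (default 1).
#' @return a ggplot.
#' @export
plot_trajectories <- function(pca, study, component = 1L) {
  df <- pca_scores(pca, study, components = max(2L, component))
  df$score <- df[[paste0("PC", component)]]
  df$log_size <- log(df$centroid_size)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$log_size, y = .data$score,
    colour = .data$species
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", se = FALSE, formula = y ~ x, linewidth = 0.5) +
    ggplot2::labs(
      x = "log centroid size",
      y = sprintf("PC%d (%.1f%%)", component, pca$percent_variance[component])
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
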