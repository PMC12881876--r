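#' Box-count fractal dimension of a planar curve
#'
#' Rotates the curve into a canonical pose (chord along the x axis, so the
#' estimate is invariant to rigid motions of the input), normalizes it into
#' the unit square (translation plus a single isotropic scale, so aspect
#' ratio is preserved), overlays dyadic grids of
#' box size `2^-k` for `k` in `scales`, counts the boxes the piecewise-linear
#' curve passes through (segments are subdivided finer than half the smallest
#' box so no crossing is missed), and returns the slope of the least-squares
#' line of `log N(s)` against `log(1/s)`. For planar curves the estimate sits
#' in the `[1, 2]` band up to estimator noise: 1 for a straight segment, 2 in
#' the space-filling limit.
#'
#' @param curve m x 2 point matrix with at least 2 distinct points.
#' @param scales integer exponents of the dyadic box sizes (default `2:8`,
#'   i.e. 7 scales from 1/4 down to 1/256 of the bounding box; finer boxes
#'   are not resolved by 500-point curves).
#' @return the fractal-dimension estimate (a dimensionless slope).
#' @export
fd_boxcount <- function(curve, scales = 2:8) {
  curve <- unname(as.matrix(curve)[, 1:2, drop = FALSE])
  if (length(scales) < 4) stop("need at least 4 box scales", call. = FALSE)
  curve <- canonical_pose(curve)
  rng <- apply(curve, 2, range)
  span <- max(rng[2, ] - rng[1, ])
  if (span <= 0) stop("degenerate curve: all points identical", call. = FALSE)
  pts <- sweep(curve, 2, rng[1, ]) / span

  s_min <- 2^-max(scales)
  pts <- subdivide_polyline(pts, s_min / 2)
  counts <- vapply(scales, function(k) {
    s <- 2^-k
    nb <- 2^k
    ix <- pmin(floor(pts[, 1] / s), nb - 1)
    iy <- pmin(floor(pts[, 2] / s), nb - 1)
    length(unique(ix * nb + iy))
  }, numeric(1))
  unname(coef(lm(log(counts) ~ log(2^scales)))[2])
}

# Rotate a planar curve into its canonical pose (chord along +x, falling back
# to the principal axis for closed curves) so the box count — and with it the
# fractal-dimension estimate — is exactly invariant to rigid motions.
canonical_pose <- function(pts) {
  ctr <- colMeans(pts)
  pts <- sweep(pts, 2, ctr)
  chord <- pts[nrow(pts), ] - pts[1, ]
  scale <- max(abs(pts), 1e-300)
  dir <- if (sqrt(sum(chord^2)) > 1e-9 * scale) {
    chord
  } else {
    eigen(crossprod(pts), symmetric = TRUE)$vectors[, 1]
  }
  dir <- dir / sqrt(sum(dir^2))
  R <- rbind(c(dir[1], dir[2]), c(-dir[2], dir[1]))
  pts %*% t(R)
}

# Insert points along segments so consecutive points are closer than max_step.
subdivide_polyline <- function(pts, max_step) {
  seg <- pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE]
  len <- sqrt(rowSums(seg^2))
  n_sub <- pmax(1L, ceiling(len / max_step))
  if (all(n_sub == 1L)) {
    return(pts)
  }
  idx <- rep.int(seq_along(len), n_sub)
  frac <- unlist(lapply(n_sub, function(k) seq_len(k) / k - 1 / (2 * k)), use.names = FALSE)
  mid <- pts[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * frac
  rbind(pts, mid)
}

#' Power-spectrum-density complexity of a planar curve
#'
#' Builds the curve's one-dimensional deviation signal — the signed
#' perpendicular distance of each point from the chord joining the curve's
#' endpoints, after scaling the curve to unit chord length — then takes a
#' short-time Fourier transform, squares the coefficient magnitudes at each
#' frequency, averages across the local transforms and sums the averages over
#' all harmonics. Higher values mean deeper/denser interdigitation; a straight
#' suture scores exactly zero. The score is invariant to translation, rotation
#' and uniform scaling of the curve and quadruples when deviation amplitude
#' doubles.
#'
#' @param curve m x 2 ordered point matrix.
#' @param window_length STFT window length in samples (Hann window,
#'   default 128).
#' @param overlap_fraction fractional window overlap (default 0.5).
#' @param n_signal length the deviation signal is resampled to before the
#'   transform (default 512).
#' @return the PSD complexity score (non-negative).
#' @export
psd_score <- function(curve, window_length = 128L, overlap_fraction = 0.5,
                      n_signal = 512L) {
  curve <- as.matrix(curve)[, 1:2, drop = FALSE]
  m <- nrow(curve)
  if (window_length > n_signal) {
    stop("window_length exceeds the signal length", call. = FALSE)
  }
  chord <- curve[m, ] - curve[1, ]
  clen <- sqrt(sum(chord^2))
  if (clen <= 0) stop("degenerate curve: coincident endpoints give no chord", call. = FALSE)
  u <- chord / clen
  rel <- sweep(curve, 2, curve[1, ]) / clen
  dev <- rel[, 1] * (-u[2]) + rel[, 2] * u[1] # signed perpendicular distance
  sig <- approx(seq_len(m), dev, xout = seq(1, m, length.out = n_signal))$y
  if (all(abs(sig) < .Machine$double.eps)) {
    return(0)
  }
  overlap <- floor(window_length * overlap_fraction)
  sp <- signal::specgram(sig,
    n = window_length, Fs = 1,
    window = signal::hanning(window_length), overlap = overlap
  )
  power <- Mod(sp$S)^2
  sum(rowMeans(power))
}

#' Complexity scores for every specimen and suture
#'
#' Applies [fd_boxcount()] and [psd_score()] to the projected 2D curves of a
#' study, yielding three records per specimen. Specimens lacking a projected
#' curve are skipped and reported in the `skipped` attribute rather than
#' failing the run. Deterministic given inputs and configuration.
#'
#' @param study a `suture_study` tibble after [project_sutures()].
#' @param fd_scales,window_length,overlap_fraction metric configuration passed
#'   through to the two scorers.
#' @return a tibble with columns `specimen_id`, `suture`, `fd`, `psd`.
#' @export
complexity_table <- function(study, fd_scales = 2:8, window_length = 128L,
                             overlap_fraction = 0.5) {
  if (!"curves_2d" %in% names(study)) stop("run project_sutures() first", call. = FALSE)
  skipped <- character(0)
  rows <- purrr::map_dfr(seq_len(nrow(study)), function(i) {
    cv <- study$curves_2d[[i]]
    purrr::map_dfr(SUTURE_NAMES, function(su) {
      if (is.null(cv[[su]])) {
        skipped <<- c(skipped, paste(study$specimen_id[i], su, sep = ":"))
        return(NULL)
      }
      tibble::tibble(
        specimen_id = study$specimen_id[i], suture = su,
        fd = fd_boxcount(cv[[su]], scales = fd_scales),
        psd = psd_score(cv[[su]],
          window_length = window_length,
          overlap_fraction = overlap_fraction
        )
      )
    })
  })
  if (nrow(rows) == 0) {
    rows <- tibble::tibble(
      specimen_id = character(0), suture = character(0),
      fd = numeric(0), psd = numeric(0)
    )
  }
  attr(rows, "skipped") <- skipped
  rows
}

#' Correlation between the two complexity metrics
#'
#' Spearman rank correlation between paired complexity scores, pooled and per
#' suture stratum. Strata with constant scores are flagged (`NA` correlation)
#' rather than erroring.
#'
#' @param records a complexity table (see [complexity_table()]).
#' @param metric_a,metric_b column names of the two scores.
#' @param by_suture also report per-suture strata (default TRUE).
#' @return a tibble with `stratum`, `n`, `rho`, `p_value`.
#' @export
score_correlation <- function(records, metric_a = "fd", metric_b = "psd",
                              by_suture = TRUE) {
  one <- function(d, label) {
    x <- d[[metric_a]]
    y <- d[[metric_b]]
    if (length(x) < 3 || sd(x) == 0 || sd(y) == 0) {
      return(tibble::tibble(stratum = label, n = length(x), rho = NA_real_, p_value = NA_real_))
    }
    ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
    tibble::tibble(
      stratum = label, n = length(x),
      rho = unname(ct$estimate), p_value = ct$p.value
    )
  }
  out <- one(records, "pooled")
  if (by_suture) {
    out <- dplyr::bind_rows(
      out,
      purrr::map_dfr(
        split(records, records$suture),
        ~ one(.x, .x$suture[1])
      )
    )
  }
  out
}
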