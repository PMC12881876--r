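#' Mirror a landmark configuration across its midsagittal plane
#'
#' Reflects every landmark across the plane through the three midline
#' landmarks, turning a half-digitized (left-side) configuration into a full
#' bilateral set. Midline landmarks map onto themselves; the output stacks the
#' originals first, then the reflections of the non-midline landmarks.
#'
#' @param lm k x 3 landmark matrix with no missing rows.
#' @param midline indices of the three (distinct, non-collinear) midline
#'   landmarks.
#' @return a (2k - 3) x 3 matrix: originals followed by reflected copies.
#' @export
mirror_landmarks <- function(lm, midline = c(1L, 2L, 3L)) {
  lm <- as.matrix(lm)
  if (any(is_missing_row(lm))) {
    stop("mirror_landmarks requires a complete configuration; estimate missing landmarks first",
      call. = FALSE
    )
  }
  refl <- reflect_across_plane(lm, lm[midline[1], ], lm[midline[2], ], lm[midline[3], ])
  rbind(lm, refl[-midline, , drop = FALSE])
}

#' Mirror every specimen of a study
#'
#' @param study a `suture_study` tibble with complete landmark configurations.
#' @return the study with a `landmarks_full` list-column of bilateral
#'   configurations.
#' @export
mirror_configurations <- function(study) {
  ml <- study_midline(study)
  study$landmarks_full <- lapply(study$landmarks, mirror_landmarks, midline = ml)
  restore_study(study, study)
}

# Thin-plate spline interpolation map in d dimensions with kernel U(r) = -r
# (the 3D biharmonic kernel). Fits source -> target on paired complete
# landmarks and evaluates at query points.
tps_map <- function(source, target, query) {
  source <- as.matrix(source)
  target <- as.matrix(target)
  query <- as.matrix(query)
  k <- nrow(source)
  d <- ncol(source)
  if (k < d + 1) stop("too few landmarks for a thin-plate spline fit", call. = FALSE)
  U <- function(a, b) {
    -sqrt(pmax(
      outer(rowSums(a^2), rep(1, nrow(b))) +
        outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b),
      0
    ))
  }
  K <- U(source, source)
  P <- cbind(1, source)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, d + 1, d + 1)))
  rhs <- rbind(target, matrix(0, d + 1, d))
  coefs <- tryCatch(solve(L, rhs), error = function(e) {
    stop("singular thin-plate spline system (degenerate landmark configuration)",
      call. = FALSE
    )
  })
  W <- coefs[seq_len(k), , drop = FALSE]
  A <- coefs[k + seq_len(d + 1), , drop = FALSE]
  U(query, source) %*% W + cbind(1, query) %*% A
}

#' Estimate missing landmarks by thin-plate spline
#'
#' Fits the 3D thin-plate spline that maps the reference configuration's
#' observed-correspondent landmarks onto the specimen's observed landmarks and
#' evaluates it at the reference positions of the missing ones. The map
#' reproduces affine (hence similarity) transforms exactly, so a specimen that
#' is a transformed copy of the reference has its deleted landmarks recovered
#' exactly. Observed landmarks are untouched.
#'
#' @param lm k x 3 matrix with missing landmarks as `NA` rows.
#' @param reference complete k x 3 reference configuration.
#' @return the completed k x 3 matrix.
#' @export
estimate_missing_tps <- function(lm, reference) {
  lm <- as.matrix(lm)
  reference <- as.matrix(reference)
  miss <- is_missing_row(lm)
  if (!any(miss)) {
    return(lm)
  }
  if (any(is_missing_row(reference))) {
    stop("reference configuration must be complete", call. = FALSE)
  }
  if (sum(!miss) < 4) {
    stop("fewer than 4 observed landmarks; cannot fit a 3D thin-plate spline",
      call. = FALSE
    )
  }
  est <- tps_map(
    source = reference[!miss, , drop = FALSE],
    target = lm[!miss, , drop = FALSE],
    query = reference[miss, , drop = FALSE]
  )
  lm[miss, ] <- est
  lm
}

#' Estimate missing landmarks across a study
#'
#' Reference choice per specimen: the mean configuration of complete
#' conspecific specimens when at least `min_conspecific` exist, otherwise the
#' mean of all complete specimens. Performed before mirroring and
#' superimposition.
#'
#' @param study a `suture_study` tibble.
#' @param reference `"species_mean"` (with global fallback) or `"global_mean"`.
#' @param min_conspecific minimum complete conspecifics for a species-level
#'   reference (default 3).
#' @return the study with completed `landmarks`.
#' @export
estimate_missing <- function(study, reference = c("species_mean", "global_mean"),
                             min_conspecific = 3L) {
  reference <- match.arg(reference)
  complete <- !vapply(study$landmarks, function(m) any(is_missing_row(m)), logical(1))
  if (all(complete)) {
    return(study)
  }
  mean_config <- function(idx) {
    Reduce(`+`, study$landmarks[idx]) / length(idx)
  }
  if (any(complete)) {
    global_ref <- mean_config(which(complete))
  } else {
    # no fully complete specimen: per-landmark mean over the specimens in
    # which that landmark was observed (configurations share a frame only
    # approximately, so this reference is coarser; flagged to the user)
    warning("no complete specimens; reference built from per-landmark observed means",
      call. = FALSE
    )
    arr <- simplify2array(study$landmarks) # k x 3 x n
    global_ref <- apply(arr, c(1, 2), mean, na.rm = TRUE)
    if (anyNA(global_ref)) {
      stop("some landmarks are missing in every specimen", call. = FALSE)
    }
  }
  study$landmarks <- lapply(seq_len(nrow(study)), function(i) {
    if (complete[i]) {
      return(study$landmarks[[i]])
    }
    ref <- global_ref
    if (reference == "species_mean" && "species" %in% names(study)) {
      consp <- which(complete & study$species == study$species[i])
      if (length(consp) >= min_conspecific) ref <- mean_config(consp)
    }
    estimate_missing_tps(study$landmarks[[i]], ref)
  })
  restore_study(study, study)
}
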