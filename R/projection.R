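#' Rotation matrix about the anteroposterior (x) axis
#'
#' The rotation used to collapse the coronal suture into two dimensions:
#' x-coordinates are left unchanged and the y-z plane is rotated by `theta`.
#'
#' @param theta angle in radians.
#' @return a 3 x 3 orthogonal matrix with determinant +1 and first row
#'   (1, 0, 0).
#' @export
rotation_matrix <- function(theta) {
  stopifnot(is.finite(theta))
  matrix(c(
    1, 0, 0,
    0, cos(theta), -sin(theta),
    0, sin(theta), cos(theta)
  ), nrow = 3, byrow = TRUE)
}

#' Specimen-specific coronal rotation angle
#'
#' The coronal suture lies in an oblique plane defined by three skull-roof
#' landmarks (by convention landmarks 20, 23 and 27). Substituting the
#' z-coordinates of the second and third landmark with that of the first
#' yields a "pseudo-frontal" (horizontal) plane; the rotation angle is the
#' angle between the unit normals of the original and the substituted plane.
#' The sign is chosen so that applying [rotation_matrix()] with the returned
#' angle reduces the z-spread of the three original landmarks; the magnitude
#' is in `[0, pi/2]`.
#'
#' @param lm20,lm23,lm27 the three 3D landmarks (numeric length-3 vectors).
#' @return the signed rotation angle in radians.
#' @export
coronal_angle <- function(lm20, lm23, lm27) {
  n_orig <- plane_normal(lm20, lm23, lm27)
  sub23 <- c(lm23[1], lm23[2], lm20[3])
  sub27 <- c(lm27[1], lm27[2], lm20[3])
  n_sub <- plane_normal(lm20, sub23, sub27) # proportional to (0, 0, 1)
  theta <- acos(pmin(1, abs(sum(n_orig * n_sub))))
  if (theta == 0) {
    return(0)
  }
  triple <- rbind(lm20, lm23, lm27)
  zspread <- function(th) diff(range((triple %*% t(rotation_matrix(th)))[, 3]))
  if (zspread(-theta) < zspread(theta)) -theta else theta
}

#' Project the coronal suture to 2D
#'
#' Rotates the curve by [rotation_matrix()] with the specimen-specific angle,
#' then drops the z-coordinate. For a curve lying in an oblique plane whose
#' normal is in the y-z plane the collapse is information-lossless; otherwise
#' the residual z-spread after rotation quantifies the approximation (returned
#' in the `residual_z_spread` attribute).
#'
#' @param curve m x 3 point matrix.
#' @param theta angle from [coronal_angle()] for the same specimen.
#' @return an m x 2 matrix of (x, y) coordinates.
#' @export
project_coronal <- function(curve, theta) {
  rot <- as.matrix(curve) %*% t(rotation_matrix(theta))
  out <- rot[, 1:2, drop = FALSE]
  attr(out, "residual_z_spread") <- diff(range(rot[, 3]))
  out
}

#' Project a midline suture to 2D
#'
#' Drops one coordinate axis of a curve already expressed in the aligned
#' consensus frame (x anteroposterior, y mediolateral, z dorsoventral). The
#' default drops the dorsoventral (z) axis, retaining the horizontal-plane
#' course of the interfrontal and sagittal sutures; `drop_axis = "y"` retains
#' the lateral profile instead.
#'
#' @param curve m x 3 point matrix.
#' @param drop_axis `"z"` (default) or `"y"`.
#' @return an m x 2 matrix.
#' @export
project_midline <- function(curve, drop_axis = c("z", "y")) {
  drop_axis <- match.arg(drop_axis)
  curve <- as.matrix(curve)
  if (ncol(curve) == 2) {
    return(curve)
  } # already 2D: idempotent
  keep <- if (drop_axis == "z") c(1, 2) else c(1, 3)
  curve[, keep, drop = FALSE]
}

#' Project all suture curves of a study to 2D
#'
#' Midline sutures (interfrontal, sagittal) are projected by axis drop;
#' the coronal suture is first rotated by its specimen-specific angle computed
#' from three skull-roof landmarks of the aligned configuration.
#'
#' @param study a `suture_study` tibble after [align_gpa()] (and usually
#'   [slide_semilandmarks()]).
#' @param plane_landmarks indices of the three landmarks defining the coronal
#'   plane (default `c(20, 23, 27)`).
#' @param drop_axis axis dropped for midline sutures (see
#'   [project_midline()]).
#' @return the study with a `curves_2d` list-column plus per-specimen
#'   `coronal_theta` and `coronal_residual_z` diagnostic columns.
#' @export
project_sutures <- function(study, plane_landmarks = c(20L, 23L, 27L),
                            drop_axis = c("z", "y")) {
  drop_axis <- match.arg(drop_axis)
  if (!"curves_aligned" %in% names(study)) {
    stop("run align_gpa() before projection", call. = FALSE)
  }
  n <- nrow(study)
  thetas <- numeric(n)
  resid_z <- numeric(n)
  study$curves_2d <- lapply(seq_len(n), function(i) {
    lm <- study$aligned[[i]]
    cv <- study$curves_aligned[[i]]
    out <- list()
    for (nm in names(cv)) {
      if (nm == "coronal") {
        th <- coronal_angle(
          lm[plane_landmarks[1], ], lm[plane_landmarks[2], ],
          lm[plane_landmarks[3], ]
        )
        proj <- project_coronal(cv[[nm]], th)
        thetas[i] <<- th
        resid_z[i] <<- attr(proj, "residual_z_spread")
        attr(proj, "residual_z_spread") <- NULL
        out[[nm]] <- proj
      } else {
        out[[nm]] <- project_midline(cv[[nm]], drop_axis = drop_axis)
      }
    }
    out
  })
  study$coronal_theta <- thetas
  study$coronal_residual_z <- resid_z
  restore_study(study, study)
}
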