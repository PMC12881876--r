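# Bending-energy matrix of a reference point set: the upper-left k x k block
# of the inverse of the TPS system matrix built from the reference, using the
# 3D kernel U(r) = -r. Quadratic form of the TPS bending energy: for any
# per-coordinate value vector v, energy contribution is t(v) %*% Be %*% v.
bending_energy_matrix <- function(ref, ridge = 1e-10) {
  ref <- as.matrix(ref)
  k <- nrow(ref)
  d <- ncol(ref)
  D <- as.matrix(dist(ref))
  K <- -D
  P <- cbind(1, ref)
  L <- rbind(cbind(K + diag(ridge, k), P), cbind(t(P), matrix(0, d + 1, d + 1)))
  Linv <- solve(L)
  Be <- Linv[seq_len(k), seq_len(k), drop = FALSE]
  (Be + t(Be)) / 2
}

# Slide one specimen's curve along local tangents to minimize bending energy
# against the reference curve. Endpoints stay fixed; tangents at interior
# points come from central differences of the flanking semilandmarks.
slide_one_curve <- function(curve, reference, Be, ridge = 1e-9) {
  curve <- as.matrix(curve)
  k <- nrow(curve)
  interior <- 2:(k - 1)
  tang <- curve[3:k, , drop = FALSE] - curve[1:(k - 2), , drop = FALSE]
  tang <- tang / pmax(sqrt(rowSums(tang^2)), 1e-300)
  V <- curve - reference
  # quadratic coefficients of the sliding amounts t (one per interior point):
  #   A[i,j] = Be[i,j] * (u_i . u_j),  b[j] = sum_i Be[i,j] (v_i . u_j)
  Bi <- Be[interior, interior, drop = FALSE]
  A <- Bi * tcrossprod(tang)
  BeV <- Be[interior, , drop = FALSE] %*% V
  b <- rowSums(BeV * tang)
  t_amt <- tryCatch(
    solve(A + diag(ridge * mean(diag(A)), nrow(A)), -b),
    error = function(e) rep(0, length(interior))
  )
  out <- curve
  out[interior, ] <- curve[interior, ] + t_amt * tang
  out
}

curve_bending_energy <- function(curve, reference, Be) {
  V <- as.matrix(curve) - as.matrix(reference)
  sum(vapply(seq_len(ncol(V)), function(d) drop(crossprod(V[, d], Be %*% V[, d])), numeric(1)))
}

#' Slide semilandmarks against the consensus
#'
#' Displaces interior semilandmarks of each suture curve along their local
#' tangent directions so as to minimize the thin-plate-spline bending energy
#' of each specimen's curve relative to the current consensus (the mean curve
#' across specimens); curve endpoints remain fixed. The consensus is
#' recomputed between iterations. Curves must already be in a common frame
#' (run after [align_gpa()], which transforms semilandmarks passively into the
#' consensus frame).
#'
#' @param study a `suture_study` tibble with a `curves_aligned` list-column.
#' @param iterations sliding iterations (default 3).
#' @param tol residual criterion: if the relative drop in total bending energy
#'   over an iteration is below `tol`, sliding stops early.
#' @return the study with slid `curves_aligned`; the per-iteration total
#'   bending energy is stored in the `sliding_energy` attribute. If the
#'   criterion has not levelled off after `iterations`, a warning reports the
#'   residual value.
#' @export
slide_semilandmarks <- function(study, iterations = 3L, tol = 1e-6) {
  if (!"curves_aligned" %in% names(study)) {
    stop("run align_gpa() before sliding (curves must share a frame)", call. = FALSE)
  }
  n <- nrow(study)
  sutures <- names(study$curves_aligned[[1]])
  energy_trace <- numeric(0)
  last_drop <- Inf
  for (it in seq_len(iterations)) {
    total_e <- 0
    for (su in sutures) {
      curves <- lapply(study$curves_aligned, `[[`, su)
      cons <- Reduce(`+`, curves) / n
      Be <- bending_energy_matrix(cons)
      slid <- lapply(curves, slide_one_curve, reference = cons, Be = Be)
      for (i in seq_len(n)) study$curves_aligned[[i]][[su]] <- slid[[i]]
      cons2 <- Reduce(`+`, slid) / n
      total_e <- total_e + sum(vapply(slid, curve_bending_energy,
        numeric(1),
        reference = cons2, Be = Be
      ))
    }
    energy_trace <- c(energy_trace, total_e)
    if (it > 1) {
      prev <- energy_trace[it - 1]
      last_drop <- if (prev > 0) (prev - total_e) / prev else 0
      if (is.finite(last_drop) && abs(last_drop) < tol) break
    }
  }
  if (is.finite(last_drop) && last_drop > tol && iterations > 1) {
    warning(
      "semilandmark sliding not converged after ", iterations,
      " iterations (relative energy drop ", signif(last_drop, 3), ")",
      call. = FALSE
    )
  }
  attr(study, "sliding_energy") <- energy_trace
  restore_study(study, study)
}
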