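# Low-level geometry helpers shared across modules.

SUTURE_NAMES <- c("interfrontal", "sagittal", "coronal")
SENTINEL_MISSING <- 9999

#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of all points from their
#' centroid; the standard size variable of geometric morphometrics.
#'
#' @param x numeric matrix, one landmark per row.
#' @return a positive scalar (zero only for fully coincident points).
#' @export
centroid_size <- function(x) {
  x <- as.matrix(x)
  ctr <- colMeans(x)
  sqrt(sum(sweep(x, 2, ctr)^2))
}

# Unit normal of the plane through three points; errors when collinear.
plane_normal <- function(p1, p2, p3) {
  v1 <- p2 - p1
  v2 <- p3 - p1
  n <- c(
    v1[2] * v2[3] - v1[3] * v2[2],
    v1[3] * v2[1] - v1[1] * v2[3],
    v1[1] * v2[2] - v1[2] * v2[1]
  )
  len <- sqrt(sum(n^2))
  scale <- max(sqrt(sum(v1^2)), sqrt(sum(v2^2)))
  if (len <= 1e-12 * scale^2) {
    stop("degenerate plane: the three points are collinear", call. = FALSE)
  }
  n / len
}

# Reflect points across the plane through p1, p2, p3.
reflect_across_plane <- function(x, p1, p2, p3) {
  n <- plane_normal(p1, p2, p3)
  d <- as.matrix(x) %*% n - sum(p1 * n)
  as.matrix(x) - 2 * d %*% t(n)
}

# Cumulative arc length of an ordered point sequence (piecewise linear).
arc_lengths <- function(x) {
  x <- as.matrix(x)
  seg <- sqrt(rowSums((x[-1, , drop = FALSE] - x[-nrow(x), , drop = FALSE])^2))
  c(0, cumsum(seg))
}

# Deterministic child seeds: every stochastic sub-artifact draws from its own
# stream derived from (seed, key), so components are independently reproducible.
derive_seed <- function(seed, key) {
  h <- sum(utf8ToInt(paste0(key)) * seq_along(utf8ToInt(paste0(key))))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483587) + 1L
}

is_missing_row <- function(x) {
  apply(as.matrix(x), 1, function(r) any(is.na(r)) || all(r == SENTINEL_MISSING))
}
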