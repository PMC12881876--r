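# Programmatic fixtures shared across the suite.

# Koch-curve polyline after `iter` construction steps (analytic fractal
# dimension log4/log3).
koch_polyline <- function(iter = 5) {
  p <- rbind(c(0, 0), c(1, 0))
  for (i in seq_len(iter)) {
    out <- vector("list", nrow(p) - 1)
    for (j in seq_len(nrow(p) - 1)) {
      a <- p[j, ]
      b <- p[j + 1, ]
      d <- (b - a) / 3
      rot <- c(
        d[1] * cos(pi / 3) - d[2] * sin(pi / 3),
        d[1] * sin(pi / 3) + d[2] * cos(pi / 3)
      )
      out[[j]] <- rbind(a, a + d, a + d + rot, a + 2 * d)
    }
    p <- rbind(do.call(rbind, out), p[nrow(p), ])
  }
  p
}

# Dense boustrophedon sweep of the unit square (space-filling limit).
boustrophedon <- function(m = 256) {
  xs <- seq(0, 1, length.out = m)
  do.call(rbind, lapply(seq_len(m), function(i) {
    cbind(if (i %% 2 == 0) rev(xs) else xs, (i - 1) / (m - 1))
  }))
}

# A small complete synthetic study, processed through the morphometry chain.
small_aligned_study <- function(n_species = 4, seed = 42, slide = FALSE) {
  sim <- generate_study(study_design(n_species = n_species), seed = seed)
  st <- sim$study |>
    add_relative_age() |>
    mirror_configurations() |>
    resample_curves(n = 120) |>
    align_gpa()
  if (slide) st <- suppressWarnings(slide_semilandmarks(st, iterations = 2))
  attr(st, "tree") <- sim$tree
  st
}

# Sinusoidal planar test curve.
wiggle_curve <- function(amplitude, waves = 10, n = 500) {
  s <- seq(0, 1, length.out = n)
  cbind(s, amplitude * sin(2 * pi * waves * s))
}

expect_tbl_equal <- function(a, b, tol = 1e-12) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tol)
}
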