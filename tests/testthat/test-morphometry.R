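test_that("mirroring reflects across the midline plane and is an involution", {
  # plane z = 0 through three midline points
  lm <- rbind(
    c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), # midline triple
    c(1, 1, 0), # in-plane point
    c(1, 1, 2) # off-plane point
  )
  out <- mirror_landmarks(lm, midline = 1:3)
  expect_equal(nrow(out), 2 * 5 - 3)
  expect_equal(out[4 + 2, ], c(1, 1, 0)) # in-plane point maps to itself
  expect_equal(out[5 + 2, ], c(1, 1, -2)) # reflection formula
  # reflecting the reflections recovers the originals
  twice <- suturemorph:::reflect_across_plane(out[6:7, ], lm[1, ], lm[2, ], lm[3, ])
  expect_equal(twice, lm[4:5, ], tolerance = 1e-12)
  # midline landmarks stay put under the underlying reflection
  refl_mid <- suturemorph:::reflect_across_plane(lm[1:3, ], lm[1, ], lm[2, ], lm[3, ])
  expect_equal(refl_mid, lm[1:3, ], tolerance = 1e-9)
})

test_that("collinear midline landmarks are a degeneracy error", {
  lm <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(1, 1, 1))
  expect_error(mirror_landmarks(lm, midline = 1:3), "collinear")
})

test_that("thin-plate spline estimation recovers deleted landmarks", {
  set.seed(7)
  ref <- matrix(runif(30 * 3), 30, 3)
  # identity: nothing missing
  expect_identical(estimate_missing_tps(ref, ref), ref)
  # self-map: deleting one landmark from a copy of the reference recovers it
  lm <- ref
  lm[12, ] <- NA
  out <- estimate_missing_tps(lm, ref)
  expect_equal(out[12, ], ref[12, ], tolerance = 1e-8)
  expect_identical(out[-12, ], ref[-12, ])
  # similarity-transformed copy: TPS reproduces affine maps exactly
  th <- 0.6
  R <- rbind(
    c(cos(th), -sin(th), 0),
    c(sin(th), cos(th), 0),
    c(0, 0, 1)
  )
  moved <- sweep(2.5 * ref %*% R, 2, c(3, -1, 7), `+`)
  lm2 <- moved
  lm2[5, ] <- NA
  out2 <- estimate_missing_tps(lm2, ref)
  expect_equal(out2[5, ], moved[5, ], tolerance = 1e-6 * max(abs(moved)))
  # insufficiency
  lm3 <- ref
  lm3[4:30, ] <- NA
  expect_error(estimate_missing_tps(lm3, ref), "fewer than 4")
})

test_that("study-level estimation uses conspecific means and clears all masks", {
  sim <- generate_study(study_design(n_species = 3, missing_fraction = 0.02), seed = 5)
  st <- sim$study
  expect_true(any(vapply(st$landmarks, anyNA, logical(1))))
  fixed <- suppressWarnings(estimate_missing(st))
  expect_false(any(vapply(fixed$landmarks, anyNA, logical(1))))
  # estimates stay close to the generative truth (same species, same frame)
  i <- which(vapply(st$landmarks, anyNA, logical(1)))[1]
  miss_rows <- which(apply(is.na(st$landmarks[[i]]), 1, any))
  truth <- generate_specimen(
    study_design(n_species = 3, missing_fraction = 0),
    as.integer(sub("spec_(\\d+)_.*", "\\1", st$specimen_id[i])),
    st$age_category[i], seed = 5,
    replicate = st$replicate[i], clade = st$clade[i]
  )$landmarks
  scale_i <- centroid_size(truth)
  expect_lt(
    max(abs(fixed$landmarks[[i]][miss_rows, ] - truth[miss_rows, ])) / scale_i,
    0.05
  )
})

test_that("arc-length resampling spaces points equally and is idempotent", {
  seg <- rbind(c(0, 0, 0), c(1, 0, 0))
  out <- resample_curve(seg, 5)
  expect_equal(out[, 1], c(0, 0.25, 0.5, 0.75, 1))
  xg <- seq(0, 1, length.out = 2000)
  bent <- cbind(xg, 0.2 * sin(2 * pi * xg), 0)
  r <- resample_curve(bent, 500)
  expect_equal(nrow(r), 500)
  # equal arc spacing measured on the source polyline: recover each output
  # point's arc position independently
  s_src <- suturemorph:::arc_lengths(bent)
  pos <- vapply(seq_len(500), function(i) {
    seg <- which.min(sqrt(rowSums(sweep(bent, 2, r[i, ])^2)))
    lo <- max(1, seg - 2)
    hi <- min(2000 - 1, seg + 2)
    best <- Inf
    at <- NA_real_
    for (j in lo:hi) {
      d <- bent[j + 1, ] - bent[j, ]
      t <- sum((r[i, ] - bent[j, ]) * d) / sum(d^2)
      t <- min(1, max(0, t))
      gap <- sum((bent[j, ] + t * d - r[i, ])^2)
      if (gap < best) {
        best <- gap
        at <- s_src[j] + t * sqrt(sum(d^2))
      }
    }
    at
  }, numeric(1))
  steps <- diff(pos)
  expect_lt(diff(range(steps)) / mean(steps), 1e-6)
  expect_equal(r[1, ], unname(bent[1, ]))
  expect_equal(r[500, ], unname(bent[2000, ]))
  # idempotence: re-resampling a dense, already-equally-spaced polyline moves
  # points only by the chord-vs-arc discrepancy of the sampled curve
  r2 <- resample_curve(r, 500)
  expect_lt(max(abs(r2 - r)), 1e-5)
  # exact idempotence when vertices already sit at equal chord spacing
  line <- resample_curve(rbind(c(0, 0, 0), c(2, 1, 0)), 500)
  expect_equal(resample_curve(line, 500), line, tolerance = 1e-12)
  expect_error(resample_curve(rbind(c(1, 1, 1), c(1, 1, 1)), 5), "zero arc length")
})

test_that("relative age is a percentage of the adult centroid size", {
  expect_equal(relative_age(10, 10), 100)
  expect_equal(relative_age(5, 10), 50)
  expect_equal(relative_age(12, 10), 120) # no cap
  expect_error(relative_age(5, 10, species = "a", adult_species = "b"), "same species")
  expect_error(relative_age(5, 0), "positive")
})

test_that("GPA is invariant to similarity transforms and normalizes correctly", {
  sim <- generate_study(study_design(n_species = 3), seed = 11)
  st <- sim$study |> resample_curves(n = 60)
  g1 <- align_gpa(st)
  # unit centroid size and mean-centring
  for (a in g1$aligned) {
    expect_equal(centroid_size(a), 1, tolerance = 1e-8)
    expect_equal(colMeans(a), c(0, 0, 0), tolerance = 1e-8)
  }
  mean_dev <- Reduce(`+`, g1$aligned) / length(g1$aligned) - consensus_shape(g1)
  expect_lt(max(abs(mean_dev)), 1e-8)
  # arbitrary similarity transform of one input specimen changes nothing
  th <- 0.9
  R <- rbind(
    c(cos(th), 0, sin(th)),
    c(0, 1, 0),
    c(-sin(th), 0, cos(th))
  )
  st2 <- st
  st2$landmarks[[2]] <- sweep(3.2 * st2$landmarks[[2]] %*% R, 2, c(5, -2, 1), `+`)
  st2$curves[[2]] <- lapply(st2$curves[[2]], function(cv) {
    sweep(3.2 * cv %*% R, 2, c(5, -2, 1), `+`)
  })
  g2 <- align_gpa(st2)
  expect_equal(g2$aligned[[2]], g1$aligned[[2]], tolerance = 1e-6)
  expect_equal(g2$curves_aligned[[2]]$coronal, g1$curves_aligned[[2]]$coronal,
    tolerance = 1e-6
  )
})

test_that("two similarity-equivalent copies align to Procrustes distance zero", {
  set.seed(3)
  base <- matrix(rnorm(20 * 3), 20, 3)
  th <- 37 * pi / 180
  R <- rbind(
    c(cos(th), -sin(th), 0),
    c(sin(th), cos(th), 0),
    c(0, 0, 1)
  )
  st <- suture_study(
    meta = tibble::tibble(specimen_id = c("a", "b")),
    landmarks = list(base, 3 * base %*% R),
    curves = list(list(), list())
  )
  g <- align_gpa(st)
  expect_lt(sqrt(sum((g$aligned[[1]] - g$aligned[[2]])^2)), 1e-9)
  st0 <- suture_study(
    meta = tibble::tibble(specimen_id = c("a", "b")),
    landmarks = list(matrix(1, 5, 3), matrix(2, 5, 3)),
    curves = list(list(), list())
  )
  expect_error(align_gpa(st0), "degenerate")
})

test_that("sliding is a no-op at the optimum, keeps endpoints, lowers energy", {
  sim <- generate_study(study_design(n_species = 3), seed = 13)
  st <- sim$study |>
    resample_curves(n = 80) |>
    align_gpa()
  # dataset where every specimen already equals the consensus
  cons_curves <- lapply(seq_len(3), function(k) {
    Reduce(`+`, lapply(st$curves_aligned, `[[`, k)) / nrow(st)
  })
  names(cons_curves) <- c("interfrontal", "sagittal", "coronal")
  st_same <- st
  for (i in seq_len(nrow(st_same))) st_same$curves_aligned[[i]] <- cons_curves
  slid_same <- slide_semilandmarks(st_same, iterations = 1)
  for (i in seq_len(nrow(st_same))) {
    expect_lt(
      max(abs(slid_same$curves_aligned[[i]]$sagittal - cons_curves$sagittal)),
      1e-10
    )
  }
  # real dataset: endpoints fixed, bending energy non-increasing
  before <- st$curves_aligned
  slid <- suppressWarnings(slide_semilandmarks(st, iterations = 3))
  for (i in seq_len(nrow(st))) {
    for (su in names(before[[i]])) {
      m0 <- before[[i]][[su]]
      m1 <- slid$curves_aligned[[i]][[su]]
      expect_equal(m1[1, ], m0[1, ])
      expect_equal(m1[nrow(m1), ], m0[nrow(m0), ])
    }
  }
  energy <- attr(slid, "sliding_energy")
  expect_true(all(diff(energy) <= 1e-8))
})
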