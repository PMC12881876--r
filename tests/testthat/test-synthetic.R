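test_that("curve generation is deterministic and anchored to the base path", {
  p <- suture_params("sagittal")
  c1 <- generate_suture_curve(p, 80, seed = 5)
  c2 <- generate_suture_curve(p, 80, seed = 5)
  expect_identical(c1, c2)
  expect_false(identical(c1, generate_suture_curve(p, 80, seed = 6)))
  # zero amplitude, zero noise: a smooth arc with dimension ~1
  p0 <- suture_params("sagittal", amplitude = 0, noise_sd = 0)
  arc <- generate_suture_curve(p0, 80, seed = 5)
  expect_equal(fd_boxcount(arc[, 1:2]), 1, tolerance = 0.05)
  # with noise only, the curve stays within a few noise SDs of the base path
  pn <- suture_params("sagittal", amplitude = 0, noise_sd = 1e-3)
  noisy <- generate_suture_curve(pn, 80, seed = 5)
  expect_lt(max(abs(noisy - arc)), 6e-3)
})

test_that("generated complexity rises with wave count and amplitude", {
  base <- suture_params("coronal", tilt = 0)
  lo <- generate_suture_curve(suture_params("coronal", tilt = 0, n_waves = 5, amplitude = 0.05),
    100,
    seed = 3
  )
  hi <- generate_suture_curve(suture_params("coronal", tilt = 0, n_waves = 30, amplitude = 0.05),
    100,
    seed = 3
  )
  expect_gt(fd_boxcount(hi[, 1:2]), fd_boxcount(lo[, 1:2]))
})

test_that("the three sutures keep the intended complexity ordering", {
  fd_of <- function(su, age) {
    mean(vapply(1:6, function(k) {
      cv <- generate_suture_curve(suture_params(su, tilt = 0), age, seed = k)
      fd_boxcount(cv[, 1:2])
    }, numeric(1)))
  }
  for (age in c(40, 90)) {
    f <- c(fd_of("interfrontal", age), fd_of("sagittal", age), fd_of("coronal", age))
    expect_true(all(diff(f) > -0.01)) # coronal >= sagittal >= interfrontal
  }
})

test_that("specimen generation controls the missing-landmark rate", {
  d0 <- study_design(n_species = 2, missing_fraction = 0)
  s0 <- generate_specimen(d0, 1, "adult", seed = 1)
  expect_false(anyNA(s0$landmarks))
  expect_equal(s0$meta$true_relative_age, 100)
  # binomial 3-SD band: 100 draws of 63 free landmarks at 5%
  dm <- study_design(n_species = 2, missing_fraction = 0.05)
  n_miss <- 0
  for (r in 1:25) {
    for (st in c("foetal", "infant", "subadult", "adult")) {
      sp <- generate_specimen(dm, 1, st, seed = r, replicate = r)
      n_miss <- n_miss + sum(apply(is.na(sp$landmarks), 1, any))
    }
  }
  expected <- 100 * 63 * 0.05
  band <- 3 * sqrt(100 * 63 * 0.05 * 0.95)
  expect_gt(n_miss, expected - band)
  expect_lt(n_miss, expected + band)
})

test_that("a default study has the designed size, tree and clade structure", {
  sim <- generate_study(study_design(), seed = 3)
  expect_equal(length(unique(sim$study$species)), 22)
  expect_gte(nrow(sim$study), 88)
  expect_setequal(sim$tree$tip.label, unique(sim$study$species))
  # pure-birth, unit depth, ultrametric
  depths <- ape::node.depth.edgelength(sim$tree)[seq_along(sim$tree$tip.label)]
  expect_equal(unname(depths), rep(1, 22), tolerance = 1e-8)
  # clades are monophyletic by construction
  clades <- unique(tibble::as_tibble(sim$study)[c("species", "clade")])
  for (cl in c("Marsupialia", "Placentalia")) {
    tips <- clades$species[clades$clade == cl]
    if (length(tips) < 2) next
    mrca <- ape::getMRCA(sim$tree, tips)
    expect_setequal(ape::extract.clade(sim$tree, mrca)$tip.label, tips)
  }
  # every species has exactly one reference adult at relative age 100
  st <- add_relative_age(sim$study)
  ad <- tibble::as_tibble(st) |>
    dplyr::filter(.data$age_category == "adult") |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(m = max(.data$relative_age))
  expect_equal(ad$m, rep(100, 22))
})

test_that("the generative oblique tilt is recovered by the coronal angle", {
  for (tau in c(0.15, 0.3, 0.45)) {
    cv <- generate_suture_curve(
      suture_params("coronal", tilt = tau, noise_sd = 0), 100,
      seed = 2
    )
    th <- coronal_angle(cv[1, ], cv[150, ], cv[500, ])
    expect_lt(abs(abs(th) - tau), 1 * pi / 180)
  }
})
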