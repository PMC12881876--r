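test_that("box-count dimension matches analytic oracles", {
  seg <- cbind(seq(0, 1, length.out = 100), 0)
  expect_equal(fd_boxcount(seg), 1, tolerance = 0.05)
  expect_equal(fd_boxcount(koch_polyline(5)), log(4) / log(3), tolerance = 0.05)
  expect_equal(fd_boxcount(boustrophedon(256)), 2, tolerance = 0.1)
  expect_error(fd_boxcount(matrix(1, 10, 2)), "degenerate")
  expect_error(fd_boxcount(koch_polyline(3), scales = 2:4), "4 box scales")
})

test_that("fractal dimension responds monotonically to interdigitation", {
  amps <- c(0.005, 0.02, 0.05, 0.1)
  fds <- vapply(amps, function(a) fd_boxcount(wiggle_curve(a, waves = 12)), numeric(1))
  expect_true(all(diff(fds) > -0.02)) # estimator slack
  expect_gt(fds[4], fds[1])
  # more waves at fixed amplitude: never simpler
  f5 <- fd_boxcount(wiggle_curve(0.05, waves = 5))
  f30 <- fd_boxcount(wiggle_curve(0.05, waves = 30))
  expect_gt(f30, f5)
})

test_that("both scores are invariant to similarity transforms", {
  cv <- wiggle_curve(0.06, waves = 9)
  th <- 1.1
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  moved <- sweep(cv %*% t(R) * 4.2, 2, c(-7, 3), `+`)
  expect_equal(fd_boxcount(moved), fd_boxcount(cv), tolerance = 1e-6)
  expect_equal(psd_score(moved), psd_score(cv), tolerance = 1e-6 * psd_score(cv))
})

test_that("PSD obeys its spectral contracts", {
  s <- seq(0, 1, length.out = 500)
  expect_equal(psd_score(cbind(s, 0)), 0)
  p1 <- psd_score(wiggle_curve(0.04))
  p2 <- psd_score(wiggle_curve(0.08))
  expect_lt(abs(p2 / p1 - 4) / 4, 1e-6)
  expect_error(psd_score(wiggle_curve(0.04), window_length = 1024), "window_length")
})

test_that("the complexity table is complete, deterministic and skip-tolerant", {
  st <- small_aligned_study(n_species = 3, seed = 31) |> project_sutures()
  tab <- complexity_table(st)
  expect_equal(nrow(tab), 3 * nrow(st))
  expect_true(all(tab$fd > 0.9 & tab$fd < 2.3))
  expect_true(all(tab$psd >= 0) && all(is.finite(tab$psd)))
  tab2 <- complexity_table(st)
  expect_identical(tab, tab2)
  # a missing curve is skipped and reported, not fatal
  st$curves_2d[[2]]$sagittal <- NULL
  tab3 <- complexity_table(st)
  expect_equal(nrow(tab3), 3 * nrow(st) - 1)
  expect_match(attr(tab3, "skipped"), "sagittal")
  # empty study gives an empty, well-formed table
  empty <- st[0, ]
  expect_equal(nrow(complexity_table(empty)), 0)
})

test_that("score correlation behaves at the rank extremes and under the null", {
  rec <- tibble::tibble(
    specimen_id = as.character(1:30), suture = "sagittal",
    fd = seq(1, 2, length.out = 30)
  )
  rec$psd <- rec$fd^3 # monotone increasing
  out <- score_correlation(rec)
  expect_equal(out$rho[out$stratum == "pooled"], 1)
  rec$psd <- -rec$fd
  expect_equal(score_correlation(rec)$rho[1], -1)
  # independent scores rarely show |rho| > 0.3 at n = 100
  set.seed(8)
  hits <- 0
  for (b in 1:40) {
    r <- tibble::tibble(
      specimen_id = as.character(1:100), suture = "coronal",
      fd = runif(100), psd = runif(100)
    )
    if (abs(score_correlation(r, by_suture = FALSE)$rho) < 0.3) hits <- hits + 1
  }
  expect_gte(hits / 40, 0.95)
  # constant scores are flagged, not an error
  rc <- tibble::tibble(
    specimen_id = as.character(1:5), suture = "coronal",
    fd = rep(1.5, 5), psd = runif(5)
  )
  expect_true(is.na(score_correlation(rc, by_suture = FALSE)$rho))
})
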