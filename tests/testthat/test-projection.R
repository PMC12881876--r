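test_that("the x-axis rotation matrix has the required algebraic structure", {
  expect_equal(rotation_matrix(0), diag(3))
  expect_equal(drop(rotation_matrix(pi / 2) %*% c(0, 1, 0)), c(0, 0, 1), tolerance = 1e-12)
  R <- rotation_matrix(0.37)
  expect_equal(t(R) %*% R, diag(3), tolerance = 1e-12)
  expect_equal(det(R), 1, tolerance = 1e-12)
  expect_equal(R[1, ], c(1, 0, 0))
  # composition: R(a) R(b) = R(a + b)
  expect_equal(rotation_matrix(0.2) %*% rotation_matrix(1.1),
    rotation_matrix(1.3),
    tolerance = 1e-12
  )
})

test_that("the coronal angle matches plane-normal geometry", {
  # all three landmarks share z: planes coincide
  expect_equal(coronal_angle(c(0, 0, 1), c(1, 0, 1), c(0, 1, 1)), 0)
  # hand case: substituted plane z = 0, original normal (0, -1, 1): 45 degrees
  th <- coronal_angle(c(0, 0, 0), c(1, 0, 0), c(0, 1, 1))
  expect_equal(abs(th), pi / 4, tolerance = 1e-9)
  # the signed angle must reduce the z-spread of the defining triple
  triple <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 1))
  rot <- triple %*% t(rotation_matrix(th))
  expect_lt(diff(range(rot[, 3])), diff(range(triple[, 3])))
  # translation invariance
  shift <- c(3.2, -1.5, 0.7)
  th2 <- coronal_angle(c(0, 0, 0) + shift, c(1, 0, 0) + shift, c(0, 1, 1) + shift)
  expect_equal(th2, th, tolerance = 1e-9)
  expect_error(coronal_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), "collinear")
})

test_that("coronal projection flattens in-plane curves losslessly", {
  # curve inside a plane whose normal lies in the y-z plane
  tau <- 0.42
  s <- seq(0, 1, length.out = 500)
  e_along <- c(0, cos(tau), -sin(tau))
  dev <- 0.07 * sin(2 * pi * 9 * s)
  curve <- outer(s, e_along) + outer(dev, c(1, 0, 0))
  th <- coronal_angle(curve[1, ], curve[250, ], curve[500, ])
  proj <- project_coronal(curve, th)
  rot <- curve %*% t(rotation_matrix(th))
  var_total <- sum(scale(curve, scale = FALSE)^2)
  var_lost <- sum(scale(rot[, 3], scale = FALSE)^2)
  expect_lt(var_lost / var_total, 1e-6)
  # x distances unchanged by an x rotation
  expect_equal(as.numeric(dist(proj[, 1])), as.numeric(dist(curve[, 1])),
    tolerance = 1e-12
  )
  # theta = 0 is a plain axis drop
  flat <- cbind(s, dev, 0)
  expect_equal(project_coronal(flat, 0)[, 1:2], flat[, 1:2], ignore_attr = TRUE)
})

test_that("midline projection drops one axis and is idempotent", {
  s <- seq(0, 1, length.out = 500)
  curve <- cbind(s, 0.05 * sin(2 * pi * 7 * s), 0.33)
  proj <- project_midline(curve)
  expect_equal(dim(proj), c(500, 2))
  # constant z: all pairwise distances preserved
  expect_equal(as.numeric(dist(proj)), as.numeric(dist(curve)), tolerance = 1e-12)
  expect_equal(project_midline(proj), proj)
  # alternative axis drop retains the lateral profile
  expect_equal(project_midline(curve, drop_axis = "y")[, 2], curve[, 3])
})

test_that("zero coronal angle makes both projections coincide", {
  s <- seq(0, 1, length.out = 200)
  curve <- cbind(s, 0.03 * sin(2 * pi * 5 * s), 0.5)
  pc <- project_coronal(curve, 0)
  attr(pc, "residual_z_spread") <- NULL
  expect_equal(pc, project_midline(curve), ignore_attr = TRUE)
})

test_that("study-level projection recovers the generative tilt", {
  st <- small_aligned_study(n_species = 3, seed = 21)
  st <- project_sutures(st)
  # aligned frame matches the anatomical frame up to GPA noise; the known
  # oblique tilt of 0.3 rad should be recovered within ~1 degree + shape noise
  expect_true(all(abs(abs(st$coronal_theta) - 0.3) < 0.1))
  expect_true(all(st$coronal_residual_z < 0.05))
  expect_equal(ncol(st$curves_2d[[1]]$sagittal), 2)
})
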