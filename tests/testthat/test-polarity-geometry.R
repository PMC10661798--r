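test_that("polygon centroid matches closed forms and is orientation-free", {
  sq <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2))
  expect_equal(unname(polygon_centroid(sq)), c(1, 1))
  expect_equal(unname(polygon_centroid(sq[4:1, ])), c(1, 1))  # reversed
  expect_equal(unname(polygon_centroid(rbind(sq, sq[1, ]))), c(1, 1))

  tri <- rbind(c(0, 0), c(3, 0), c(0, 3))
  expect_equal(unname(polygon_centroid(tri)), c(1, 1))

  expect_error(polygon_centroid(rbind(c(0, 0), c(1, 1), c(2, 2))),
               "degenerate")
  expect_error(polygon_centroid(rbind(c(0, 0), c(1, 1))), "3")
})

test_that("polygon centroid agrees with dense rasterization", {
  set.seed(71)
  for (i in 1:10) {
    poly <- random_convex_polygon()
    cen <- polygon_centroid(poly)
    ras <- oracle_raster_centroid(poly, h = 0.02)
    expect_lt(max(abs(cen - ras)), 0.01)
  }
})

test_that("translational distance and patch angle follow the conventions", {
  expect_equal(translational_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(translational_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(translational_distance(c(3, 4), c(0, 0)), 5)  # symmetric
  expect_equal(translational_distance(c(1, 1), c(1, 1 + 1e-9)), 1e-9,
               tolerance = 1e-6)
  expect_error(translational_distance(c(0, 0), c(NA, 1)), "finite")

  expect_equal(bb_patch_angle(c(0, 0), c(1, 0)), 0)
  # image y points down, so +y displacement is 270 in the y-up frame
  expect_equal(bb_patch_angle(c(0, 0), c(0, 1)), 270)
  expect_equal(bb_patch_angle(c(0, 0), c(0, -1)), 90)
  expect_true(is.na(bb_patch_angle(c(2, 2), c(2, 2))))  # flag, no error
})

test_that("Feret measurements match axis cases and the all-pairs oracle", {
  f <- ferets_angle(rbind(c(0, 0), c(4, 0), c(2, 0.5)))
  expect_equal(f$LD, 4)
  expect_equal(f$FA, 0)

  f2 <- ferets_angle(rbind(c(0, 0), c(0, 3)))
  expect_equal(f2$LD, 3)
  expect_equal(f2$FA, 90)

  expect_error(ferets_angle(rbind(c(1, 1), c(1, 1))), "distinct")

  set.seed(83)
  for (i in 1:50) {
    p <- cbind(runif(40, 0, 50), runif(40, 0, 50))
    f <- ferets_angle(p)
    o <- oracle_feret(p)
    expect_equal(f$LD, o$LD, tolerance = 1e-12)
    expect_equal(f$FA, o$FA, tolerance = 1e-9)
  }
})

test_that("TD, TA, FA, LD obey translation, rotation and scale equivariance", {
  set.seed(97)
  for (i in 1:50) {
    C <- runif(2, 10, 90)
    bb <- cbind(rnorm(12, C[1] + 5), rnorm(12, C[2] - 3))
    BC <- colMeans(bb)
    td <- translational_distance(C, BC)
    ta <- bb_patch_angle(C, BC)
    fer <- ferets_angle(bb)

    # translation invariance
    dlt <- runif(2, -20, 20)
    bb_t <- sweep(bb, 2, dlt, "+")
    expect_equal(translational_distance(C + dlt, colMeans(bb_t)), td,
                 tolerance = 1e-9)
    expect_equal(bb_patch_angle(C + dlt, colMeans(bb_t)), ta,
                 tolerance = 1e-6)
    expect_equal(ferets_angle(bb_t)$LD, fer$LD, tolerance = 1e-9)
    expect_equal(ferets_angle(bb_t)$FA, fer$FA, tolerance = 1e-6)

    # rotation equivariance: TA and FA shift by theta, TD and LD fixed
    th <- runif(1, 5, 355)
    bb_r <- rotate_points(bb, th, center = C)
    ta_r <- bb_patch_angle(C, colMeans(bb_r))
    expect_lt(abs(((ta_r - ta - th + 180) %% 360) - 180), 1e-6)
    fer_r <- ferets_angle(bb_r)
    expect_lt(abs(((fer_r$FA - fer$FA - th + 90) %% 180) - 90), 1e-6)
    expect_equal(fer_r$LD, fer$LD, tolerance = 1e-9)
    expect_equal(translational_distance(C, colMeans(bb_r)), td,
                 tolerance = 1e-9)

    # scale equivariance about the origin
    s <- runif(1, 0.3, 3)
    expect_equal(translational_distance(s * C, s * BC), s * td,
                 tolerance = 1e-9)
    expect_equal(ferets_angle(s * bb)$LD, s * fer$LD, tolerance = 1e-9)
  }
})

test_that("rotational vectors pair feet to nearest basal bodies one-to-one", {
  v <- rotational_vectors(rbind(c(0, 0)), rbind(c(1, 0)), max_gate = 5)
  expect_equal(nrow(v$vectors), 1)
  expect_equal(v$vectors$angle, 0)
  expect_equal(v$vectors$length, 1)
  expect_length(v$unmatched_feet, 0)

  # gate exclusion: distant basal body is not paired
  v2 <- rotational_vectors(rbind(c(0, 0)), rbind(c(10, 0)), max_gate = 5)
  expect_equal(nrow(v2$vectors), 0)
  expect_equal(v2$unmatched_feet, 1L)

  expect_error(rotational_vectors(matrix(numeric(0), ncol = 2),
                                  rbind(c(0, 0))), "nonempty")

  # one-to-one: two feet cannot claim the same basal body
  feet <- rbind(c(0, 0), c(0.5, 0))
  bbs <- rbind(c(1, 0), c(30, 30))
  v3 <- rotational_vectors(feet, bbs, max_gate = 3)
  expect_equal(nrow(v3$vectors), 1)       # nearer foot wins
  expect_equal(v3$vectors$foot_id, 2L)
  expect_equal(v3$unmatched_feet, 1L)
})

test_that("rotational vectors recover a concentrated foot-direction field", {
  set.seed(7)
  n <- 30
  # basal bodies on a jittered grid spaced well beyond the foot offset,
  # as in a real patch, so the true parent is the identifiable nearest
  g <- expand.grid(x = seq(10, 60, by = 10), y = seq(10, 60, by = 10))
  bb <- as.matrix(g[1:n, ]) + matrix(runif(2 * n, -2, 2), n, 2)
  dirs <- sample_von_mises(90, 1e8, n, seed = 55)
  th <- dirs * pi / 180
  feet <- cbind(bb[, 1] - 2 * cos(th), bb[, 2] + 2 * sin(th))
  v <- rotational_vectors(feet, bb, max_gate = 4)
  expect_equal(nrow(v$vectors), n)
  expect_equal(v$vectors$bb_id, v$vectors$foot_id)  # true parents
  cm <- circular_mean_R(angle_sample(v$vectors$angle))
  expect_lt(abs(cm$mean - 90), 0.5)
})

test_that("cell summaries report SEM and the two-group t-test", {
  # SEM equals sd/sqrt(n) on a hand-computed 4-value group
  m <- data.frame(cell_id = 1:8, n_bb = 2,
                  TD = c(1, 2, 3, 4, 11, 12, 13, 15),
                  TD_norm = 0.1, TA = 10, FA = 20, LD = 1,
                  border = FALSE,
                  group = rep(c("a", "b"), each = 4))
  s <- summarize_cells(m)
  expect_equal(s$summary$td_sem[s$summary$group == "a"],
               sd(c(1, 2, 3, 4)) / 2)
  expect_lt(s$t_test$p, 0.01)

  # identical groups: t = 0, p = 1
  m2 <- m
  m2$TD <- rep(c(1, 2, 3, 4), 2)
  s2 <- summarize_cells(m2)
  expect_equal(s2$t_test$t, 0)
  expect_equal(s2$t_test$p, 1)

  # a group with n < 2 disables the test
  s3 <- summarize_cells(m[c(1, 5), ])
  expect_null(s3$t_test)
})
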