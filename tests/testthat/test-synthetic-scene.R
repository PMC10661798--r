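small_scene <- function(...) {
  scene_config(n_cells = 30, domain_size = c(240, 240), bb_per_patch = 8,
               ...)
}

test_that("scene configuration validates its invariants", {
  expect_error(scene_config(kappa_trans = -1), "nonnegative")
  expect_error(scene_config(offset_frac = 1), "offset_frac")
  expect_error(scene_config(n_cells = 0), "n_cells")
  expect_error(scene_config(n_cells = 10000, domain_size = c(100, 100)),
               "domain")
})

test_that("mosaic generation is deterministic and partitions the domain", {
  cfg <- small_scene(seed = 5)
  m1 <- generate_mosaic(cfg)
  m2 <- generate_mosaic(cfg)
  expect_identical(m1$label, m2$label)
  expect_identical(m1$points, m2$points)

  # every pixel belongs to exactly one cell
  expect_true(all(m1$label >= 1 & m1$label <= cfg$n_cells))
  expect_setequal(unique(as.vector(m1$label)), seq_len(cfg$n_cells))

  # one truth record per cell, one per basal body
  expect_equal(nrow(m1$truth$cells), cfg$n_cells)
  expect_equal(nrow(m1$truth$bbs), cfg$n_cells * cfg$bb_per_patch)
  expect_true(all(m1$truth$cells$psi_true >= 0 &
                    m1$truth$cells$psi_true < 360))
  expect_true(all(m1$truth$cells$axis_true >= 0 &
                    m1$truth$cells$axis_true < 180))
})

test_that("every basal foot sits at foot_offset_px from its basal body", {
  m <- generate_mosaic(small_scene(seed = 9))
  bbs <- m$truth$bbs[!m$truth$cells$clipped[
    match(m$truth$bbs$cell_id, m$truth$cells$cell_id)], ]
  d <- sqrt((bbs$x - bbs$foot_x)^2 + (bbs$y - bbs$foot_y)^2)
  expect_true(all(abs(d - m$config$foot_offset_px) < 1e-9))
})

test_that("zero offset and degenerate concentration behave as designed", {
  m0 <- generate_mosaic(small_scene(offset_frac = 0, seed = 13))
  expect_true(all(m0$truth$cells$td_true == 0))
  meas <- measure_polarity(cells_from_label(m0$label), m0$points)
  keep <- meas[!meas$border, ]
  # measured TD is pure patch-sampling noise around 0; with 8 points in
  # an ellipse of ~0.45 r_eq the centroid noise stays within ~1 px of 0
  expect_lt(mean(keep$TD), 2)

  m40 <- generate_mosaic(small_scene(kappa_trans = 1e8, mu_global = 40,
                                     seed = 14))
  dpsi <- abs(((m40$truth$cells$psi_true - 40 + 180) %% 360) - 180)
  expect_true(all(dpsi < 0.1))
})

test_that("scene ground truth supports downstream parameter recovery", {
  cfg <- scene_config(n_cells = 200, domain_size = c(640, 640),
                      offset_frac = 0.35, kappa_trans = 8, seed = 17)
  m <- generate_mosaic(cfg)
  meas <- measure_polarity(cells_from_label(m$label), m$points)
  keep <- meas[!meas$border & !is.na(meas$TD_norm), ]
  expect_lt(abs(mean(keep$TD_norm) - 0.35), 0.05)
})

test_that("scene-wide rotational polarity is recoverable from the point tables", {
  m <- generate_mosaic(scene_config(n_cells = 60,
                                    domain_size = c(360, 360),
                                    mu_global = 90, kappa_rot = 8,
                                    seed = 19))
  pts <- m$points
  rv <- rotational_vectors(pts[pts$kind == "foot", c("x", "y")],
                           pts[pts$kind == "bb", c("x", "y")])
  # most feet pair with their true parent (basal bodies are spaced
  # wider than the foot offset), so the field's mean and concentration
  # come back close to the generating values
  expect_gt(nrow(rv$vectors) / sum(pts$kind == "foot"), 0.9)
  cm <- circular_mean_R(angle_sample(rv$vectors$angle))
  expect_lt(abs(((cm$mean - 90 + 180) %% 360) - 180), 5)
  expect_gt(cm$R, 0.7)

  # uncoordinated preset: direction field near-uniform
  mu <- generate_mosaic(scene_preset("mutant", n_cells = 60,
                                     domain_size = c(360, 360),
                                     seed = 20))
  rvm <- rotational_vectors(mu$points[mu$points$kind == "foot",
                                      c("x", "y")],
                            mu$points[mu$points$kind == "bb",
                                      c("x", "y")])
  expect_lt(circular_mean_R(angle_sample(rvm$vectors$angle))$R, 0.2)
})

test_that("flow video generation is deterministic and drops leavers", {
  cfg <- flow_config("coherent", n_particles = 20, n_frames = 10,
                     seed = 23)
  v1 <- generate_flow_video(cfg)
  v2 <- generate_flow_video(cfg)
  expect_identical(v1$frames, v2$frames)
  expect_identical(v1$truth$positions, v2$truth$positions)
  expect_equal(length(v1$frames), 10)

  # all recorded positions are inside the domain
  p <- v1$truth$positions
  expect_true(all(p$x >= 0 & p$x < 256 & p$y >= 0 & p$y < 256))
  # frames strictly increasing per particle
  expect_true(all(tapply(p$frame, p$particle_id,
                         function(f) all(diff(f) == 1))))
})

test_that("noise-free coherent advection gives exact true directions", {
  cfg <- flow_config("coherent", mean_direction = 45, diffusion_px = 0,
                     n_particles = 15, n_frames = 10, spawn_inset = 40,
                     seed = 29)
  v <- generate_flow_video(cfg)
  expect_true(all(abs(v$truth$net$direction - 45) < 1e-9))
})

test_that("the disorganized field spreads true directions over the circle", {
  cfg <- flow_config("disorganized", n_particles = 100, n_frames = 30,
                     seed = 31)
  v <- generate_flow_video(cfg)
  R <- circular_mean_R(angle_sample(v$truth$net$direction))$R
  expect_lt(R, 0.5)
  # directions span at least a half circle
  expect_gt(diff(range(v$truth$net$direction)), 180)
})

test_that("flow configuration validates its parameters", {
  expect_error(flow_config(n_particles = 0), "positive")
  expect_error(flow_config(n_frames = 0), "positive")
  expect_error(flow_config(diffusion_px = -1), "nonnegative")
})
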