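test_that("rendering is deterministic and respects the image invariants", {
  g <- fx_geometry()
  tgt <- target_spec(fx_targets9()$theta[[3]], 5)
  a <- render_scene(g, fx_home(), tgt)
  b <- render_scene(g, fx_home(), tgt)
  expect_identical(unclass(a), unclass(b))
  expect_silent(validate_scene_image(a, g))
  expect_setequal(unique(as.numeric(a)), c(0, 1)) # hard masks are binary
})

test_that("the target_visible flag controls only the red plane", {
  g <- fx_geometry()
  tgt <- target_spec(fx_targets9()$theta[[5]], 5)
  on <- render_scene(g, fx_home(), tgt, target_visible = TRUE)
  off <- render_scene(g, fx_home(), tgt, target_visible = FALSE)
  expect_true(all(off[1, , ] == 0))
  expect_identical(on[3, , ], off[3, , ])
})

test_that("the rasterized target centroid sits at the target hand position", {
  g <- fx_geometry()
  # an unoccluded configuration: limb folded left, target to the right
  ik <- inverse_kinematics(g, c(95, 70))
  arm <- inverse_kinematics(g, c(35, 55))$theta
  img <- render_scene(g, arm, target_spec(ik$theta, 5))
  red <- img[1, , ]
  xs <- matrix(rep(seq_len(nrow(red)) - 0.5, ncol(red)), nrow(red))
  ys <- matrix(rep(seq_len(ncol(red)) - 0.5, each = nrow(red)), nrow(red))
  cx <- sum(xs * red) / sum(red)
  cy <- sum(ys * red) / sum(red)
  expect_lt(sqrt(sum((c(cx, cy) - hand_position(g, ik$theta))^2)), 1)
})

test_that("the limb occludes the target when they overlap", {
  g <- fx_geometry()
  hb <- fx_home()
  # target centered at the hand: its disc must lose pixels to the limb
  img_occ <- render_scene(g, hb, target_spec(hb, 6))
  far <- inverse_kinematics(g, c(100, 75))$theta
  img_free <- render_scene(g, far, target_spec(hb, 6))
  expect_lt(sum(img_occ[1, , ]), sum(img_free[1, , ]))
  expect_true(all(img_occ[1, , ] * img_occ[3, , ] == 0))
})

test_that("nine grid targets: count, reachability, midline symmetry", {
  g <- fx_geometry()
  tg <- fx_targets9()
  expect_equal(nrow(tg), 9)
  for (i in 1:9) {
    h <- hand_position(g, tg$theta[[i]])
    expect_lt(sqrt(sum((h - c(tg$x[i], tg$y[i]))^2)), 0.5)
    expect_true(all(tg$theta[[i]] >= g$lower & tg$theta[[i]] <= g$upper))
    # in-frame with full disc
    expect_true(tg$x[i] > 5 && tg$x[i] < g$img_width - 5)
    expect_true(tg$y[i] > 5 && tg$y[i] < g$img_height - 5)
  }
  for (i in 1:9) {
    mirrored <- c(2 * g$base[1] - tg$x[i], tg$y[i])
    d <- sqrt((tg$x - mirrored[1])^2 + (tg$y - mirrored[2])^2)
    expect_lt(min(d), 1e-6)
  }
})

test_that("unreachable grid points are rejected with an error", {
  g <- fx_geometry()
  expect_error(place_nine_targets(g, depths = c(200, 210, 220)),
               "unreachable")
})

test_that("dataset generation: labels re-render to the stored images", {
  g <- fx_geometry()
  ds <- generate_dataset(g, 6, seed = 9, images = TRUE)
  expect_equal(nrow(ds), 6)
  expect_true(all(ds$radius >= 5 & ds$radius <= 12))
  for (i in 1:6) {
    re <- render_scene(g, ds$theta_arm[[i]],
                       target_spec(ds$theta_target[[i]], ds$radius[i]))
    expect_identical(unclass(re), unclass(ds$image[[i]]))
  }
})

test_that("a paper-scale dataset of 20000 configurations can be drawn", {
  ds <- generate_dataset(fx_geometry(), 20000, seed = 1, images = FALSE)
  expect_equal(nrow(ds), 20000)
  rng <- range(ds$radius)
  expect_true(rng[1] >= 5 && rng[2] <= 12)
})

test_that("a single record round-trips through save/load identically", {
  skip_if_not_installed("png")
  g <- fx_geometry()
  ds <- generate_dataset(g, 1, seed = 4, images = TRUE)
  dir <- withr::local_tempdir()
  save_dataset(ds, dir)
  back <- load_dataset(dir)
  expect_equal(back$theta_arm[[1]], ds$theta_arm[[1]], tolerance = 1e-12)
  expect_equal(back$theta_target[[1]], ds$theta_target[[1]], tolerance = 1e-12)
  expect_equal(back$radius, ds$radius, tolerance = 1e-12)
  expect_equal(as.numeric(back$image[[1]]), as.numeric(ds$image[[1]]))
})

test_that("random reachable targets avoid hidden and unreachable spots", {
  g <- fx_geometry()
  tg <- fx_random_targets(20)
  hb <- fx_home()
  for (i in seq_len(nrow(tg))) {
    expect_lt(inverse_kinematics(g, c(tg$x[i], tg$y[i]))$error, 0.5)
    with_limb <- render_scene(g, hb, target_spec(tg$theta[[i]], 5))
    expect_gt(sum(with_limb[1, , ]), 0.5 * pi * 25 * 0.5)
  }
})
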