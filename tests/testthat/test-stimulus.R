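# Grid geometry, contour selection, orientation assignment, blocks and
# the double-pass session design.

test_that("hex grid has the right size, centring and pitch", {
  g <- build_hex_grid(39, 25, 1.044)
  expect_equal(nrow(g), 975)
  # bounding box centred on the origin
  expect_equal(min(g$x) + max(g$x), 0, tolerance = 1e-12)
  expect_equal(min(g$y) + max(g$y), 0, tolerance = 1e-12)
  # degenerate single-element grid sits at the centre
  g1 <- build_hex_grid(1, 1, 1.0)
  expect_equal(c(g1$x, g1$y), c(0, 0))
  # element count conservation across shapes
  for (dims in list(c(2, 9), c(5, 4), c(13, 1))) {
    expect_equal(nrow(build_hex_grid(dims[1], dims[2], 0.7)),
                 dims[1] * dims[2])
  }
  expect_error(build_hex_grid(0, 5, 1), "n_cols")
  expect_error(build_hex_grid(5, 5, -1), "spacing")
})

test_that("small grid matches brute-force hexagonal geometry", {
  g <- build_hex_grid(4, 3, 1.0)
  expect_equal(nrow(g), 12)
  d <- as.numeric(dist(cbind(g$x, g$y)))
  expect_equal(min(d), 1.0, tolerance = 1e-12)
  # row-to-row vertical gap is sqrt(3)/2 times the spacing
  expect_equal(sort(unique(g$y)), sort(unique(g$y))[1] + sqrt(3) / 2 * (0:2),
               tolerance = 1e-12)
})

test_that("every interior element has six neighbours at lattice distance", {
  g <- build_hex_grid(39, 25, 1.044)
  interior <- which(g$col > 1 & g$col < 39 & g$row > 1 & g$row < 25)
  for (i in sample(interior, 25)) {
    d <- sqrt((g$x - g$x[i])^2 + (g$y - g$y[i])^2)
    expect_equal(sum(abs(d - 1.044) < 1e-9), 6)
  }
})

test_that("contour path is collinear, evenly spaced and near-centred", {
  g <- build_hex_grid(39, 25, 1.044)
  idx <- select_contour_path(g, 12, 60, spacing = 1.044)
  expect_length(idx, 12)
  px <- g$x[match(idx, g$index)]
  py <- g$y[match(idx, g$index)]
  steps <- sqrt(diff(px)^2 + diff(py)^2)
  expect_equal(steps, rep(1.044, 11), tolerance = 1e-9)
  expect_equal(atan2(diff(py), diff(px)) * 180 / pi, rep(60, 11),
               tolerance = 1e-9)
  # centroid as close to the screen centre as the lattice allows:
  # within half a vertical pitch
  expect_lt(abs(mean(px)), 1.044 / 2)
  expect_lt(abs(mean(py)), 1.044 * sqrt(3) / 4 + 1e-9)
  # a 2-element path straddles the centre as nearly as representable
  idx2 <- select_contour_path(g, 2, 60, spacing = 1.044)
  expect_lt(abs(mean(g$x[match(idx2, g$index)])), 1.044 / 2)
  expect_lt(abs(mean(g$y[match(idx2, g$index)])), 1.044 * sqrt(3) / 4 + 1e-9)
  expect_error(select_contour_path(g, 12, 33, spacing = 1.044),
               "lattice direction")
  expect_error(select_contour_path(g, 60, 60, spacing = 1.044),
               "fits inside")
})

test_that("balanced jitter keeps the contour mean exact and SD = delta", {
  set.seed(7)
  for (delta in c(0, 10, 20, 30, 45, 60)) {
    a <- assign_orientations(975, 101:112, "signal", delta)
    expect_equal(mean(a$contour_unwrapped), 60, tolerance = 1e-12)
    # population SD about the mean equals delta exactly
    expect_equal(sqrt(mean((a$contour_unwrapped - 60)^2)), delta,
                 tolerance = 1e-12)
    expect_true(all(a$orientations > -90 & a$orientations <= 90))
  }
  # no-noise condition: every contour element at exactly 60
  a0 <- assign_orientations(975, 101:112, "signal", 0)
  expect_true(all(a0$orientations[101:112] == 60))
  # 45-degree condition: six at 15, six at 105 (wrapped to -75)
  a45 <- assign_orientations(975, 101:112, "signal", 45)
  expect_equal(sort(table(a45$orientations[101:112])),
               sort(table(c(rep(15, 6), rep(-75, 6)))),
               ignore_attr = TRUE)
  expect_error(assign_orientations(100, 1:11, "signal", 10), "even")
})

test_that("background orientations are uniform with SD 180/sqrt(12)", {
  set.seed(11)
  a <- assign_orientations(2e5, integer(0), "noise", 10)
  expect_equal(sd(a$orientations), 180 / sqrt(12), tolerance = 0.01)
  expect_equal(mean(a$orientations), 0, tolerance = 0.5)
  ks <- suppressWarnings(
    ks.test(a$orientations[1:5000], "punif", -90, 90))
  expect_gt(ks$p.value, 0.01)
})

test_that("blocks hold 30 signal + 30 noise trials in seeded random order", {
  spec <- stimulus_spec()
  blk <- generate_block(spec, 10, seed = 5)
  expect_length(blk$trials, 60)
  expect_equal(sum(blk$classes == "signal"), 30)
  expect_equal(sum(blk$classes == "noise"), 30)
  blk2 <- generate_block(spec, 10, seed = 5)
  expect_identical(lapply(blk$trials, `[[`, "orientations"),
                   lapply(blk2$trials, `[[`, "orientations"))
  expect_identical(blk$classes, blk2$classes)
  expect_error(generate_block(spec, 17, seed = 1), "not one of")
})

test_that("signal positions are a uniform random interleaving", {
  spec <- mini_spec()
  counts <- numeric(8)
  n_blocks <- 3000
  set.seed(3)
  for (b in seq_len(n_blocks)) {
    blk <- generate_block(spec, 10, n_signal = 4, n_noise = 4,
                          seed = sample.int(2^31 - 2, 1))
    counts <- counts + (blk$classes == "signal")
  }
  # each of the 8 positions holds a signal trial in half the blocks
  chi2 <- sum((counts - n_blocks / 2)^2 / (n_blocks / 4))
  expect_lt(chi2, qchisq(0.999, df = 7))
})

test_that("sessions have 8 blocks, repeats last, exact pass-2 replicas", {
  spec <- stimulus_spec()
  s <- generate_session_design(spec, seed = 9)
  expect_length(s$blocks, 8)
  lv <- vapply(s$blocks, `[[`, numeric(1), "noise_level")
  ps <- vapply(s$blocks, `[[`, integer(1), "pass")
  expect_equal(ps, c(rep(1L, 6), 2L, 2L))
  expect_setequal(lv[1:6], spec$noise_levels)
  expect_setequal(lv[7:8], c(10, 45))
  expect_equal(sum(vapply(s$blocks, function(b) length(b$trials), 1L)), 480)
  for (j in 7:8) {
    b1 <- s$blocks[[which(lv[1:6] == lv[j])]]
    expect_identical(lapply(b1$trials, `[[`, "orientations"),
                     lapply(s$blocks[[j]]$trials, `[[`, "orientations"))
    expect_identical(b1$classes, s$blocks[[j]]$classes)
  }
  # deterministic under the seed
  s2 <- generate_session_design(spec, seed = 9)
  expect_identical(lapply(s$blocks, `[[`, "classes"),
                   lapply(s2$blocks, `[[`, "classes"))
  bad <- stimulus_spec()
  bad$double_pass_levels <- c(10, 50)
  expect_error(generate_session_design(bad, 1), "double-pass")
})

test_that("rendered stimuli have screen dimensions and zero-mean elements", {
  spec <- stimulus_spec()
  blk <- generate_block(spec, 0, n_signal = 1, n_noise = 0, seed = 2)
  img <- render_stimulus(spec, blk$trials[[1]])
  expect_equal(dim(img), c(1080, 1920))
  expect_true(all(img >= 0 & img <= 1))
  # odd-phase carriers integrate to zero: mean stays at background
  expect_equal(mean(img), 0.5, tolerance = 1e-3)
  # zero contrast collapses to a uniform background
  spec0 <- stimulus_spec(contrast = 0, px_per_deg = 8)
  img0 <- render_stimulus(spec0, blk$trials[[1]])
  expect_true(all(img0 == 0.5))
  # a single element also has background mean
  sp1 <- stimulus_spec(n_cols = 1, n_rows = 1, contour_length = 2,
                       screen_deg = c(2, 2), px_per_deg = 48)
  t1 <- make_trial_stimulus(1, "noise", 0, 1, integer(0))
  img1 <- render_stimulus(sp1, t1, grid = build_hex_grid(1, 1, 1.044))
  expect_equal(mean(img1), 0.5, tolerance = 1e-3)
})

test_that("orientation table labels contour elements", {
  spec <- mini_spec()
  g <- build_hex_grid(spec$n_cols, spec$n_rows, spec$spacing)
  ci <- select_contour_path(g, spec$contour_length,
                            spec$contour_orientation, spec$spacing)
  blk <- generate_block(spec, 10, n_signal = 1, n_noise = 1, seed = 4)
  sig <- blk$trials[[which(blk$classes == "signal")]]
  noi <- blk$trials[[which(blk$classes == "noise")]]
  tb_s <- trial_orientation_table(sig, g)
  tb_n <- trial_orientation_table(noi, g)
  expect_equal(sum(tb_s$is_contour), spec$contour_length)
  expect_equal(sum(tb_n$is_contour), 0)
  expect_equal(nrow(tb_s), nrow(g))
})
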