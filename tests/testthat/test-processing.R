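test_that("black-level subtraction floors at zero and records the level", {
  stk <- make_stack(list(uniform_frame(100), uniform_frame(20)))
  expect_identical(subtract_black(stk, 0)$frames, stk$frames)
  out <- subtract_black(stk, 30)
  expect_true(all(out$frames[[1]] == 70L))
  expect_true(all(out$frames[[2]] == 0L))
  expect_equal(out$meta$black_subtracted, 30)
  expect_true(all(subtract_black(stk, 500)$frames[[2]] == 0L))
})

test_that("de-interleaving splits by stride and round-trips", {
  frames <- lapply(1:6, uniform_frame)
  stk <- make_stack(frames, tags = rep(c("spinning_tirf", "widefield"), 3),
                    labels = rep(c("T", "W"), 3))
  subs <- deinterleave(stk, 2)
  expect_named(subs, c("T", "W"))
  expect_equal(length(subs$T$frames), 3)
  expect_true(all(subs$T$mode_tags == "spinning_tirf"))
  expect_equal(subs$W$timestamps, c(1, 3, 5) * 0.005)
  expect_identical(deinterleave(stk, 1)[[1]]$frames, stk$frames)
  back <- interleave_stacks(subs)
  expect_identical(back$frames, stk$frames)
  expect_identical(back$labels, stk$labels)
  # an odd frame count leaves substack lengths differing by at most one
  subs5 <- deinterleave(make_stack(frames[1:5],
                                   labels = rep(c("T", "W"), 3)[1:5]), 2)
  expect_equal(lengths(lapply(subs5, `[[`, "frames")), c(T = 3, W = 2))
  bad <- make_stack(frames, labels = c("T", "W", "W", "T", "T", "W"))
  expect_error(deinterleave(bad, 2), class = "spintirf_tag_mismatch_error")
})

test_that("delta-F/F0 normalizes to the resting baseline", {
  const <- make_stack(lapply(rep(50, 4), uniform_frame))
  r <- df_f0(const, c(1, 2))
  expect_true(all(vapply(r$frames, function(f) all(f == 0), logical(1))))
  # pixel doubling from F0 = 50 gives ratio 1
  stk <- make_stack(list(uniform_frame(50), uniform_frame(100)))
  expect_true(all(df_f0(stk, c(1, 1))$frames[[2]] == 1))
  # 3-frame toy stack: values 10, 10, 20 with baseline frames 1-2
  toy <- df_f0(make_stack(lapply(c(10, 10, 20), uniform_frame)), c(1, 2))
  expect_equal(vapply(toy$frames, function(f) f[1, 1], numeric(1)),
               c(0, 0, 1))
  expect_error(df_f0(make_stack(lapply(c(0, 0, 5), uniform_frame)),
                     c(1, 2)),
               class = "spintirf_empty_baseline_error")
})

test_that("delta-F/F0 masks dim pixels and is exactly gain-invariant", {
  f1 <- matrix(c(0L, 40L, 40L, 40L), 2, 2)
  f2 <- matrix(c(0L, 80L, 60L, 20L), 2, 2)
  stk <- make_stack(list(f1, f2))
  r <- df_f0(stk, c(1, 1))
  expect_true(is.na(r$frames[[2]][1, 1]))   # F0 below the floor is masked
  expect_false(r$mask[1, 1])
  r2 <- df_f0(make_stack(list(f1 * 3L, f2 * 3L)), c(1, 1))
  expect_equal(r$frames[[2]][-1], r2$frames[[2]][-1], tolerance = 1e-12)
  # baseline frames have mean ratio exactly zero by construction
  many <- make_stack(lapply(c(9, 11, 10, 30), uniform_frame))
  rb <- df_f0(many, c(1, 3))
  expect_equal(mean(vapply(rb$frames[1:3], mean, numeric(1))), 0,
               tolerance = 1e-12)
})

test_that("max projection is the pixelwise maximum over the range", {
  f <- matrix(0L, 3, 3)
  frames <- lapply(1:3, function(i) { m <- f; m[i, i] <- 10L; m })
  stk <- make_stack(frames)
  expect_identical(max_projection(stk, c(2, 2)), frames[[2]])
  proj <- max_projection(stk)
  expect_true(all(vapply(frames, function(fr) all(proj >= fr),
                         logical(1))))
  expect_equal(diag(proj), rep(10L, 3))
})

test_that("ROI traces average the ROI pixels frame by frame", {
  stk <- make_stack(list(uniform_frame(7, 5)))
  expect_equal(roi_trace(stk, roi_rect(0, 0, 5, 5))$value, 7)
  hand <- matrix(1:25, 5, 5)
  tr <- roi_trace(make_stack(list(hand)), roi_center(2, 2, 3))
  expect_equal(tr$value, mean(hand[2:4, 2:4]))
  expect_error(roi_trace(stk, roi_rect(3, 3, 8, 8)),
               class = "spintirf_roi_error")
})

test_that("linked ROIs on de-interleaved stacks give offset timestamps", {
  frames <- lapply(1:6, uniform_frame)
  stk <- make_stack(frames, labels = rep(c("T", "W"), 3))
  subs <- deinterleave(stk, 2)
  roi <- roi_center(4, 4, 3, label = "site1", group = "g1")
  trT <- roi_trace(subs$T, roi)
  trW <- roi_trace(subs$W, roi)
  expect_equal(nrow(trT), nrow(trW))
  expect_equal(trW$time - trT$time, rep(stk$exposure_time, 3))
})

test_that("linescan returns the ordered row profile", {
  row <- matrix(1:7, 1, 7)
  expect_equal(linescan(row)$value, 1:7)
  img <- matrix(stats::runif(63), 9, 7)
  expect_equal(nrow(linescan(img)), 7)
  expect_equal(linescan(img, row = 5)$value, img[5, ])
})

test_that("uniformity metrics quantify tile-to-tile variation", {
  expect_equal(unlist(uniformity_metrics(matrix(5, 16, 16), 4)),
               c(cv = 0, adjacent_variation = 0))
  # checkerboard of 4x4 tiles with means 70 / 130: (130-70)/200 = 30%
  tile_vals <- outer(0:3, 0:3, function(i, j) ifelse((i + j) %% 2 == 0,
                                                     70, 130))
  board <- tile_vals[rep(1:4, each = 4), rep(1:4, each = 4)]
  m <- uniformity_metrics(board, 4)
  expect_equal(m$adjacent_variation, 30)
  img <- matrix(stats::runif(256, 50, 150), 16, 16)
  expect_equal(uniformity_metrics(img, 4)$cv,
               uniformity_metrics(img * 7, 4)$cv, tolerance = 1e-12)
})

test_that("stability trace reports the max percent deviation of frame means", {
  frames <- lapply(c(100, 101, 99, 100), uniform_frame)
  st <- stability_trace(make_stack(frames), region_size = 4)
  expect_equal(st$trace$value, c(100, 101, 99, 100))
  expect_equal(st$max_deviation_pct, 100 * 1 / 100, tolerance = 1e-9)
})
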