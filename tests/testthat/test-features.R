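test_that("SSV and ASV match their defining sums", {
  uniform <- pressure_sequence(list(matrix(1, 32, 32)))
  expect_equal(ssv_series(uniform), 1024)
  expect_equal(asv(uniform), 1024)

  zeros <- pressure_sequence(list(matrix(0, 4, 4)))
  expect_equal(ssv_series(zeros), 0)

  # random 4x4 frames equal the naive double-loop sum
  seq <- toy_sequence(seed = 11, n = 4, t = 5)
  oracle <- oracle_frame_series(seq)
  expect_equal(ssv_series(seq), oracle$ssv, tolerance = 1e-12)

  # ASV averages the frame totals: totals 4, 6, 8 -> 6
  tot <- pressure_sequence(list(matrix(4 / 16, 4, 4), matrix(6 / 16, 4, 4),
                                matrix(8 / 16, 4, 4)))
  expect_equal(asv(tot), 6)
  one <- pressure_sequence(list(toy_frame(2)))
  expect_equal(asv(one), ssv_series(one))
})

test_that("COP is the pressure-weighted mean coordinate", {
  # single active sensor at (x = 5, y = 7): COP sits on it
  seq <- pressure_sequence(list(point_frame(row = 7, col = 5)))
  cop <- cop_series(seq)
  expect_equal(cop$lat_cop, 5)
  expect_equal(cop$lon_cop, 7)

  # uniform frame: COP at the grid centre
  unif <- pressure_sequence(list(matrix(2, 32, 32)))
  expect_equal(cop_series(unif)$lat_cop, 16.5)
  expect_equal(cop_series(unif)$lon_cop, 16.5)

  # two sensors (x=10,y=10,p=3), (x=20,y=30,p=1): direct weighted mean
  fr <- matrix(0, 32, 32)
  fr[10, 10] <- 3
  fr[30, 20] <- 1
  cop <- cop_series(pressure_sequence(list(fr)))
  expect_equal(cop$lat_cop, (10 * 3 + 20 * 1) / 4)  # 12.5
  expect_equal(cop$lon_cop, (10 * 3 + 30 * 1) / 4)  # 15

  # all-zero frame is flagged invalid, not an error
  both <- pressure_sequence(list(fr, matrix(0, 32, 32)))
  cop2 <- cop_series(both)
  expect_equal(cop2$valid, c(TRUE, FALSE))
  expect_true(is.na(cop2$lat_cop[2]))
})

test_that("ratio halves follow the configured axis convention", {
  # left half all 3, right half all 1 (semantic): LR ratio = 3
  fr <- cbind(matrix(3, 4, 2), matrix(1, 4, 2))
  seq <- pressure_sequence(list(fr))
  expect_equal(ratio_series(seq, "semantic")$lr_ratio, 3)

  # laterally symmetric frame: LR ratio = 1
  sym <- pressure_sequence(list(matrix(rep(c(1, 2, 2, 1), each = 4), 4, 4)))
  expect_equal(ratio_series(sym, "semantic")$lr_ratio, 1)

  # random grids match the explicit index-set oracle in both modes
  seq <- toy_sequence(seed = 21, n = 4, t = 4)
  for (mode in c("semantic", "literal")) {
    rat <- ratio_series(seq, mode)
    oracle <- oracle_frame_series(seq, mode)
    expect_equal(rat$lr_ratio, oracle$lr, tolerance = 1e-12)
    expect_equal(rat$fb_ratio, oracle$fb, tolerance = 1e-12)
  }

  # literal mode swaps the axes relative to semantic mode
  expect_equal(ratio_series(seq, "literal")$lr_ratio,
               oracle_frame_series(seq, "semantic")$fb)

  odd <- pressure_sequence(list(matrix(1, 3, 4)))
  expect_error(ratio_series(odd), "even")
})

test_that("whole series pipeline matches the term-by-term oracle", {
  seq <- toy_sequence(seed = 31, n = 4, t = 3, subject = "S1",
                      task = "back-and-forth", side = "affected",
                      label = "TLF")
  oracle <- oracle_frame_series(seq)
  fs <- frame_series(seq)
  expect_equal(fs$ssv, oracle$ssv, tolerance = 1e-12)
  expect_equal(fs$lat_cop, oracle$lat, tolerance = 1e-12)
  expect_equal(fs$lon_cop, oracle$lon, tolerance = 1e-12)
  expect_equal(fs$lr_ratio, oracle$lr, tolerance = 1e-12)
  expect_equal(fs$fb_ratio, oracle$fb, tolerance = 1e-12)

  fv <- extract_features(seq)
  expect_equal(fv$asv, mean(oracle$ssv), tolerance = 1e-12)
  v <- oracle$valid
  expect_equal(fv$sd_lat_cop, sd(oracle$lat[v]), tolerance = 1e-12)
  expect_equal(fv$sd_lon_cop, sd(oracle$lon[v]), tolerance = 1e-12)
  expect_equal(fv$sd_lr_ratio, sd(oracle$lr[v]), tolerance = 1e-12)
  expect_equal(fv$sd_fb_ratio, sd(oracle$fb[v]), tolerance = 1e-12)
  expect_equal(fv$label, "TLF")
})

test_that("static sequences have zero SD features", {
  fr <- toy_frame(5)
  seq <- pressure_sequence(list(fr, fr, fr))
  fv <- extract_features(seq)
  expect_equal(fv$sd_lat_cop, 0)
  expect_equal(fv$sd_lon_cop, 0)
  expect_equal(fv$sd_lr_ratio, 0)
  expect_equal(fv$sd_fb_ratio, 0)
})

test_that("features obey scale invariance and translation equivariance", {
  seq <- toy_sequence(seed = 41, n = 6, t = 5)
  seq$frames[, 6, ] <- 0  # free the last column so a shift loses no mass
  fv <- extract_features(seq)

  # scaling all pressures by c > 0: ASV scales, SDs unchanged
  c_ <- 3.7
  scaled <- pressure_sequence(seq$frames * c_)
  fvs <- extract_features(scaled)
  expect_equal(fvs$asv, c_ * fv$asv)
  expect_equal(fvs[names(fvs) != "asv" &
                     vapply(fvs, is.numeric, logical(1))],
               fv[names(fv) != "asv" & vapply(fv, is.numeric, logical(1))],
               tolerance = 1e-12)

  # shifting one column toward higher x: LatCOP + 1 exactly, SD unchanged
  shifted_frames <- seq$frames
  shifted_frames[] <- 0
  shifted_frames[, 2:6, ] <- seq$frames[, 1:5, ]
  shifted <- pressure_sequence(shifted_frames)
  expect_equal(cop_series(shifted)$lat_cop, cop_series(seq)$lat_cop + 1,
               tolerance = 1e-12)
  expect_equal(extract_features(shifted)$sd_lat_cop, fv$sd_lat_cop,
               tolerance = 1e-12)
})

test_that("COP stays inside the grid and LR ratio conserves half sums", {
  for (s in 1:5) {
    seq <- toy_sequence(seed = 100 + s, n = 8, t = 6)
    fs <- frame_series(seq)
    v <- fs$valid
    expect_true(all(fs$lat_cop[v] >= 1 & fs$lat_cop[v] <= 8))
    expect_true(all(fs$lon_cop[v] >= 1 & fs$lon_cop[v] <= 8))
    # lr_ratio * right-half sum == left-half sum (semantic mode)
    left <- apply(seq$frames[, 1:4, , drop = FALSE], 3, sum)
    right <- apply(seq$frames[, 5:8, , drop = FALSE], 3, sum)
    expect_equal(fs$lr_ratio[v] * right[v], left[v], tolerance = 1e-12)
  }
})

test_that("too few valid frames is an error naming the trial", {
  zero <- matrix(0, 4, 4)
  seq <- pressure_sequence(list(toy_frame(1), zero, zero),
                           subject = "S7", task = "up-and-down",
                           label = "SE")
  expect_error(extract_features(seq), "S7")
})
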