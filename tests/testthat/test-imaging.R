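test_that("width averaging reduces to the mean across the strip width", {
  px <- matrix(17, 100, 20)
  img <- strip_image(px, expected_line_position = 50)
  prof <- width_averaged_profile(img)
  expect_equal(as.numeric(prof), rep(17, 100))
  expect_equal(attr(prof, "positions"), 0:99)

  # roi restricts both the extent and the averaged columns
  px2 <- px
  px2[, 11:20] <- 99
  img2 <- strip_image(px2, roi = c(10, 90, 0, 10), expected_line_position = 50)
  expect_equal(as.numeric(width_averaged_profile(img2)), rep(17, 80))

  expect_error(strip_image(px, roi = c(0, 101, 0, 20),
                           expected_line_position = 50), "roi out of image")
  expect_error(strip_image(px, roi = c(0, 100, 0, 20),
                           expected_line_position = 95),
               "search window")
})

test_that("a dark line is a minimum raw and a maximum after inversion", {
  px <- matrix(200, 100, 20)
  px[41, ] <- 60                 # 0-based flow position 40
  raw <- width_averaged_profile(strip_image(px, expected_line_position = 40))
  expect_equal(which.min(raw) - 1L, 40L)
  inv <- width_averaged_profile(strip_image(px, expected_line_position = 40,
                                            invert = TRUE))
  expect_equal(which.max(inv) - 1L, 40L)

  # color: dark blue line on white reads high under inverted luminance
  col <- array(1, c(100, 20, 3)) * 255
  col[41, , 1:2] <- 40
  cimg <- strip_image(col, expected_line_position = 40)
  cprof <- width_averaged_profile(cimg)
  expect_equal(which.max(cprof) - 1L, 40L)
})

test_that("peak location respects the window and breaks ties toward expected", {
  prof <- rep(0, 101)
  prof[51] <- 10                                  # position 50
  expect_equal(locate_test_line(prof, 50, 10, smooth = 1), 50)
  prof2 <- rep(0, 101)
  prof2[56] <- 10                                 # +5 offset
  expect_equal(locate_test_line(prof2, 50, 10, smooth = 1), 55)
  prof3 <- rep(0, 101)
  prof3[c(46, 56)] <- 10                          # equidistant equal peaks
  expect_equal(locate_test_line(prof3, 50, 10, smooth = 1), 50)
  expect_equal(locate_test_line(rep(3, 101), 50, 10), 50)   # flat window
})

test_that("flank-median baseline removes constant and linear backgrounds", {
  pos <- 0:119
  line <- 25 * exp(-(pos - 60)^2 / (2 * 2^2))
  flat <- 40 + line
  bg <- subtract_background(flat, 60)
  expect_equal(bg$corrected[61], 25, tolerance = 1e-6)
  expect_equal(bg$baseline[61], 40, tolerance = 1e-6)

  ramp <- 10 + 0.5 * pos
  bg2 <- subtract_background(ramp, 60)
  expect_lt(max(abs(bg2$corrected)), 1e-9)

  sloped <- 10 + 0.5 * pos + line
  bg3 <- subtract_background(sloped, 60)
  expect_equal(bg3$corrected[61], 25, tolerance = 1e-6)

  expect_error(subtract_background(flat, 5), "widen the roi")
})

test_that("synthetic strips with sloped backgrounds recover amplitude and position", {
  errs <- numeric(100)
  for (s in 1:100) {
    tr <- strip_truth(line_amplitude = 30, line_center = 60,
                      background_level = 40,
                      background_slope = ((s %% 5) - 2) / 20, noise_sd = 2,
                      seed = 1000 + s)
    sig <- line_signal(render_strip(tr, shape = c(120, 30))$image)
    expect_lte(abs(sig$peak_position - 60), 1)
    errs[s] <- abs(sig$signal - 30)
  }
  expect_lt(mean(errs), 3 * 2)     # mean |error| under 3 x pixel-noise sd
})

test_that("signal is offset-invariant, zero on blanks, monotone in amplitude", {
  tr <- strip_truth(20, 60, background_slope = 0.1, seed = 5)
  img <- render_strip(tr, shape = c(120, 30))$image
  shifted <- img
  shifted$pixels <- shifted$pixels + 11.5
  expect_lt(abs(line_signal(img)$signal - line_signal(shifted)$signal), 1e-6)

  blank <- render_strip(strip_truth(0, 60, noise_sd = 0, seed = 1),
                        shape = c(120, 30))$image
  expect_equal(line_signal(blank)$signal, 0)
  # noisy blank: clipped at zero, raw diagnostic kept
  nb <- line_signal(render_strip(strip_truth(0, 60, noise_sd = 2, seed = 2),
                                 shape = c(120, 30))$image)
  expect_gte(nb$signal, 0)
  expect_true(is.finite(nb$corrected_peak))

  sigs <- vapply(c(10, 20, 40), function(a)
    line_signal(render_strip(strip_truth(a, 60, noise_sd = 1, seed = 77),
                             shape = c(120, 30))$image)$signal, 0)
  expect_true(all(diff(sigs) > 0))
})

test_that("identical image bytes give identical line signals", {
  tr <- strip_truth(25, 60, background_slope = 0.05, seed = 9)
  s1 <- line_signal(render_strip(tr, shape = c(120, 30))$image)
  s2 <- line_signal(render_strip(tr, shape = c(120, 30))$image)
  expect_identical(s1, s2)
})

test_that("PNG round trip preserves the signal to 8-bit quantization", {
  tr <- strip_truth(30, 60, background_slope = 0.05, seed = 12)
  st <- render_strip(tr, shape = c(120, 30))
  f <- withr::local_tempfile(fileext = ".png")
  write_strip_png(st$image, f)
  img2 <- read_strip_image(f, expected_line_position = 60)
  direct <- line_signal(st$image)$signal
  roundtrip <- line_signal(img2)$signal
  expect_lt(abs(direct - roundtrip), 1)
})

test_that("replicate strip pairs correlate according to shared line amplitude", {
  set.seed(33)
  amp <- runif(40, 5, 50)
  pair <- vapply(seq_along(amp), function(i) {
    s1 <- line_signal(render_strip(strip_truth(amp[i], 60, noise_sd = 2,
                                               seed = 5000 + i),
                                   shape = c(120, 30))$image)$signal
    s2 <- line_signal(render_strip(strip_truth(amp[i], 60, noise_sd = 2,
                                               seed = 9000 + i),
                                   shape = c(120, 30))$image)$signal
    c(s1, s2)
  }, numeric(2))
  r <- method_correlation(pair[1, ], pair[2, ])$r
  expect_gt(r, 0.98)   # replicate noise ~0.5 intensity units vs 45-unit range
})
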