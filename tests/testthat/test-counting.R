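test_that("disjoint blobs of exact per-fly area are counted exactly", {
  im <- make_blob_frame(10, area = 25)
  res <- count_flies_threshold(im, threshold = 128, per_fly_area = 25)
  expect_equal(res$count, 10)
  expect_equal(res$foreground_area, 250)

  blank <- cage_image(matrix(230, 50, 50))
  expect_equal(count_flies_threshold(blank, threshold = 128,
                                     per_fly_area = 25)$count, 0)

  # auto threshold lands between the two intensity modes
  auto <- count_flies_threshold(im, threshold = "auto", per_fly_area = 25)
  expect_equal(auto$count, 10)
  expect_gt(auto$threshold_used, 30)
  expect_lt(auto$threshold_used, 230)
})

test_that("counts are invariant under threshold-preserving remappings", {
  im <- make_blob_frame(7, area = 25)
  ref <- count_flies_threshold(im, threshold = 128, per_fly_area = 25)

  # a strictly monotone remap that keeps every pixel on its side of 128
  px <- im$pixels
  remapped <- ifelse(px < 128, px / 2, 128 + (px - 128) / 3 + 10)
  im2 <- cage_image(remapped, ground_truth_count = 7)
  res2 <- count_flies_threshold(im2, threshold = 128, per_fly_area = 25)
  expect_equal(res2$count, ref$count)
  expect_equal(res2$foreground_area, ref$foreground_area)
})

test_that("duplicating every blob doubles the count", {
  im <- make_blob_frame(6, area = 25, size = 100)
  doubled <- rbind(im$pixels, im$pixels)   # same blobs twice, no overlap
  im2 <- cage_image(doubled)
  c1 <- count_flies_threshold(im, threshold = 128, per_fly_area = 25)
  c2 <- count_flies_threshold(im2, threshold = 128, per_fly_area = 25)
  expect_equal(c2$count, 2 * c1$count)
})

test_that("ROI restricts counting and bad parameters error", {
  im <- make_blob_frame(4, area = 25, size = 120)
  # ROI covering only the first blob column
  roi_im <- cage_image(im$pixels, roi = c(0, 9, 0, 120))
  res <- count_flies_threshold(roi_im, threshold = 128, per_fly_area = 25)
  expect_lt(res$count, 4)

  expect_error(count_flies_threshold(im, threshold = 128, per_fly_area = 0),
               class = "lurevp_parameter_error")
  expect_error(cage_image(matrix(300, 5, 5)), class = "lurevp_parameter_error")
  expect_error(cage_image(matrix(10, 5, 5), roi = c(0, 10, 0, 5)),
               class = "lurevp_parameter_error")
})

test_that("per-fly area is the median of per-image foreground ratios", {
  mk <- function(total_px, truth) {
    m <- matrix(230, 60, 60)
    m[seq_len(ceiling(total_px / 60)), ][seq_len(total_px)] <- 30
    cage_image(m, ground_truth_count = truth)
  }
  # one image: 5 flies covering 150 px -> 30 px per fly
  expect_equal(estimate_per_fly_area(mk(150, 5), threshold = 128), 30)
  imgs <- list(mk(28, 1), mk(60, 2), mk(44, 1))
  expect_equal(estimate_per_fly_area(imgs, threshold = 128), 30)

  none <- list(cage_image(matrix(230, 20, 20), ground_truth_count = 0))
  expect_error(estimate_per_fly_area(none, threshold = 128),
               class = "lurevp_insufficient_data")
})

test_that("calibration on rendered frames recovers the nominal fly area", {
  frames <- render_cage_frames(rep(8, 12), fly_area_px = 25,
                               overlap_allowed = FALSE, seed = 21)
  est <- estimate_per_fly_area(frames, threshold = 128)
  expect_gt(est, 25 * 0.9)
  expect_lt(est, 25 * 1.1)
})

test_that("Spearman concordance matches its defining formula and oracle", {
  # identical and exactly reversed sequences
  ident <- concordance(1:8, 1:8)
  expect_equal(ident$rho, 1)
  expect_equal(ident$S, 0)
  expect_equal(concordance(1:5, 5:1)$rho, -1)

  # untied data: formula rho = 1 - 6S/(n(n^2-1)) and rank-then-Pearson agree
  set.seed(5)
  for (rep in 1:10) {
    x <- sample(100, 20)
    y <- x + sample(-5:5, 20, replace = TRUE) * 7  # keeps ranks untied mostly
    if (anyDuplicated(rank(y))) next
    res <- concordance(x, y)
    expect_equal(res$rho, 1 - 6 * res$S / (res$n * (res$n^2 - 1)),
                 tolerance = 1e-12)
    expect_equal(res$rho, oracle_spearman(x, y), tolerance = 1e-12)
  }

  # ties are handled by mid-ranks, still matching the oracle
  a <- c(3, 3, 7, 9, 9, 12)
  b <- c(2, 4, 7, 8, 8, 13)
  expect_equal(concordance(a, b)$rho, oracle_spearman(a, b))

  expect_error(concordance(1:4, 1:5), class = "lurevp_parameter_error")
  expect_error(concordance(1:2, 1:2), class = "lurevp_parameter_error")
})

test_that("cage images round-trip through 8-bit PNG", {
  im <- make_blob_frame(3, area = 25, size = 60)
  path <- withr::local_tempfile(fileext = ".png")
  write_cage_image(im, path)
  back <- read_cage_image(path, ground_truth_count = 3)
  expect_equal(back$pixels, im$pixels)
  expect_equal(back$ground_truth_count, 3)
})
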