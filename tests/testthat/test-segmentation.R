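test_that("robust background threshold reproduces the worked example exactly", {
  px <- c(rep(0, 8), 100, 100)
  # trim floor(0.05*10)=0 each side; mean 20, population SD 40
  expect_equal(robust_background_threshold(px), (20 + 2 * 40) * 0.89)
  expect_equal(robust_background_threshold(px), 89)

  # constant image: SD 0, threshold = 50 * 0.89; everything is foreground
  expect_equal(robust_background_threshold(rep(50, 100)), 44.5)
  mask <- binarize(matrix(50, 10, 10), 44.5)
  expect_true(all(mask))

  expect_error(robust_background_threshold(5), "at least 2")
  # over-trimming (only reachable with raw, unvalidated parameter lists)
  raw <- list(lower_outlier_fraction = 0.9, upper_outlier_fraction = 0.9,
              n_deviations = 2, correction_factor = 0.89)
  expect_error(robust_background_threshold(c(1, 2), raw), "removed all")
})

test_that("robust background threshold agrees with the trimmed-statistics oracle", {
  set.seed(7)
  for (i in 1:400) {
    n <- sample(10:200, 1)
    px <- switch(sample(3, 1),
                 stats::rexp(n, 1 / 50),
                 stats::runif(n, 0, 255),
                 c(stats::rnorm(n, 30, 5), stats::rnorm(5, 200, 10)))
    got <- robust_background_threshold(px)
    expect_lt(abs(got - robust_threshold_oracle(px)), 1e-9)
  }
})

test_that("pre-threshold smoothing is a sigma-1 Gaussian at the default scale", {
  img <- matrix(runif(60 * 60), 60, 60)
  expect_identical(smooth_for_threshold(img, 0), img)
  imp <- matrix(0, 101, 101)
  imp[51, 51] <- 1
  sm <- smooth_for_threshold(imp)           # default scale -> sigma 1
  expect_equal(max(sm), 1 / (2 * pi), tolerance = 0.02)
  expect_equal(sum(sm), 1, tolerance = 1e-3)
})

test_that("binarize counts qualifying pixels exactly", {
  set.seed(11)
  img <- matrix(runif(80 * 80), 80, 80)
  for (thr in c(-0.1, 0.25, 0.5, 0.99, 1.5)) {
    mask <- binarize(img, thr)
    expect_equal(sum(mask), sum(as.vector(img) > thr))
  }
  expect_true(all(binarize(img, -1)))
  expect_false(any(binarize(img, 2)))
})

test_that("declumping splits touching discs along the bisector", {
  expect_equal(max(declump_by_shape(matrix(FALSE, 50, 50))), 0)

  one <- disc_mask(c(80, 80), cbind(40, 40), 15)
  expect_equal(max(declump_by_shape(one)), 1)

  two <- disc_mask(c(90, 110), rbind(c(45, 46), c(45, 64)), 12)
  labs <- declump_by_shape(two)
  expect_equal(max(labs), 2)
  # each lobe is a single distinct label
  left <- setdiff(unique(labs[45, 40:50]), 0L)
  right <- setdiff(unique(labs[45, 60:70]), 0L)
  expect_length(left, 1)
  expect_length(right, 1)
  expect_false(left == right)
  # the label changes within 2 px of the perpendicular bisector (col 55)
  boundary_col <- max(which(labs[45, ] == left))
  expect_lte(abs(boundary_col + 0.5 - 55), 2.5)
})

test_that("declumping has the documented operating band", {
  r <- 12
  # separation >= 1.2 r: two objects
  for (sep in c(1.2 * r, 1.5 * r, 1.8 * r)) {
    m <- disc_mask(c(90, 110), rbind(c(45, 50), c(45, 50 + sep)), r)
    expect_equal(max(declump_by_shape(m)), 2)
  }
  # separation < 0.5 r: merged into one
  for (sep in c(0.2 * r, 0.45 * r)) {
    m <- disc_mask(c(90, 110), rbind(c(45, 50), c(45, 50 + sep)), r)
    expect_equal(max(declump_by_shape(m)), 1)
  }
})

test_that("object filtering enforces diameter range and border exclusion", {
  labs <- matrix(0L, 60, 60)
  labs[10, 50:51] <- 1L                      # 2 px: below min diameter 5
  d <- disc_mask(c(60, 60), cbind(35, 20), 15)
  labs[d & labs == 0L] <- 2L                 # diameter 30: kept
  labs[1, 50:55] <- 3L                       # touches border
  out <- filter_objects(labs, seg_params())
  expect_equal(max(out), 1L)                 # only the disc survives
  expect_true(all(out[d] == 1L))
  out2 <- filter_objects(labs, seg_params(exclude_border = FALSE,
                                          diameter_range_px = c(1, 50)))
  expect_equal(max(out2), 3L)

  # relabelling is always contiguous 1..N
  set.seed(3)
  for (i in 1:20) {
    m <- matrix(stats::rbinom(400, 1, 0.3), 20, 20)
    lab <- EBImage::bwlabel(m)
    out <- filter_objects(matrix(as.integer(lab), 20, 20),
                          seg_params(diameter_range_px = c(1, 50),
                                     exclude_border = FALSE))
    u <- sort(unique(out[out > 0]))
    expect_identical(u, seq_along(u))
  }
})

test_that("segment_pair recovers the object count of sparse nucleus fields", {
  cfg <- small_cfg(n_cells = 60L,
                   class_fractions = c(live = 1, etotic = 0, dead = 0),
                   min_separation_px = 16, seed = 13L)
  sc <- generate_scene(cfg)
  seg <- segment_pair(bg_correct(sc$hoechst), bg_correct(sc$sytox))
  expect_false(seg$degenerate)
  expect_lte(abs(seg$n_objects - 60) / 60, 0.02)
  # labels contiguous and 4-connected-compatible
  u <- sort(unique(seg$labels[seg$labels > 0]))
  expect_identical(u, seq_along(u))
})
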