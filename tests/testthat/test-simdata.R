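test_that("empty and single-class scenes degenerate correctly", {
  cfg <- small_cfg(n_cells = 0L,
                   noise = list(gaussian_sd = 0, poisson_scale = 0),
                   background_level = 0.05)
  sc <- generate_scene(cfg)
  expect_equal(nrow(sc$truth$cells), 0L)
  expect_true(all(sc$hoechst == 0.05))       # background only
  expect_true(all(sc$sytox == 0.05))
  expect_true(all(sc$truth$mask == 0L))

  # all-live, noiseless, zero Sytox uptake: Sytox channel identically 0
  cfg <- small_cfg(n_cells = 10L,
                   class_fractions = c(live = 1, etotic = 0, dead = 0),
                   live_params = list(radius_px = c(mean = 3.5, sd = 0.5),
                                      hoechst_amp = 0.7, sytox_amp = 0),
                   noise = list(gaussian_sd = 0, poisson_scale = 0),
                   background_level = 0)
  sc <- generate_scene(cfg)
  expect_equal(nrow(sc$truth$cells), 10L)
  expect_true(all(sc$truth$cells$class == "live"))
  expect_true(all(sc$sytox == 0))
  expect_gt(max(sc$hoechst), 0.5)
})

test_that("scene generation is deterministic and follows the multinomial split", {
  cfg <- small_cfg(n_cells = 120L,
                   class_fractions = c(live = 0.7, etotic = 0.2, dead = 0.1),
                   seed = 1L)
  sc1 <- generate_scene(cfg)
  sc2 <- generate_scene(cfg)
  expect_identical(sc1$hoechst, sc2$hoechst)
  expect_identical(sc1$sytox, sc2$sytox)
  expect_identical(sc1$truth$mask, sc2$truth$mask)

  set.seed(1L)
  expected <- drop(stats::rmultinom(1, 120L, c(0.7, 0.2, 0.1)))
  expect_equal(unname(sc1$truth$counts), expected)
  expect_equal(as.vector(table(factor(sc1$truth$cells$class,
                                      c("live", "etotic", "dead")))),
               expected)
})

test_that("truth mask labels and cell table are consistent", {
  sc <- fixture("mixed_scene", generate_scene(
    small_cfg(class_fractions = c(live = 0.6, etotic = 0.2, dead = 0.2),
              seed = 5L)))
  labs <- sort(unique(sc$truth$mask[sc$truth$mask > 0]))
  expect_true(all(labs %in% sc$truth$cells$id))
  expect_equal(sum(sc$truth$counts), nrow(sc$truth$cells))
  # centroids respect the placement margin and minimum separation
  cells <- sc$truth$cells
  expect_true(all(cells$row > 16 & cells$row < 256 - 16))
  d <- as.matrix(stats::dist(cells[, c("row", "col")]))
  diag(d) <- Inf
  expect_gte(min(d), 11)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(class_fractions = c(live = 0.5, etotic = 0.5,
                                              dead = 0.5)), "sum to 1")
  expect_error(sim_config(etotic_params = list(
    cloud_radius_px = c(mean = 10, sd = 1), n_filaments = 4L,
    hoechst_amp = 0.9, sytox_amp = 0.01)), "exceed")
  expect_error(sim_config(illumination = list(type = "vignette",
                                              relative_amplitude = 0.1)),
               "unknown illumination type")
  expect_error(sim_config(defocus_sigma_px = -1), "defocus")
})

test_that("placement failure reports the achieved count", {
  cfg <- small_cfg(image_shape = c(80L, 80L), n_cells = 400L,
                   min_separation_px = 12, border_margin_px = 10)
  expect_error(generate_scene(cfg), "placement failed: placed [0-9]+ of 400")
})

test_that("illumination fields have the stated range and shape", {
  img <- matrix(100, 60, 200)
  out <- apply_illumination(img, list(type = "none", relative_amplitude = 0.5))
  expect_identical(out, img)
  out <- apply_illumination(img, list(type = "linear", relative_amplitude = 0))
  expect_identical(out, img)

  out <- apply_illumination(img, list(type = "linear", relative_amplitude = 0.5))
  expect_equal(min(out), 100)
  expect_equal(max(out), 150)
  expect_true(all(diff(out[1, ]) > 0))       # monotone along the gradient

  out <- apply_illumination(matrix(10, 101, 101),
                            list(type = "radial", relative_amplitude = 0.3))
  expect_equal(max(out) / min(out), 1.3, tolerance = 1e-6)
  expect_error(apply_illumination(img, list(type = "bad",
                                            relative_amplitude = 0.1)),
               "unknown")
})

test_that("noise model is deterministic with calibrated moments", {
  img <- matrix(5, 100, 100)
  expect_identical(apply_noise(img, list(gaussian_sd = 0, poisson_scale = 0)),
                   img)
  big <- matrix(50, 1000, 1000)
  out <- apply_noise(big, list(gaussian_sd = 2, poisson_scale = 0), seed = 3)
  expect_equal(stats::sd(out - big), 2, tolerance = 0.01)
  out2 <- apply_noise(big, list(gaussian_sd = 2, poisson_scale = 0), seed = 3)
  expect_identical(out, out2)
  # scaled Poisson: variance of out approx mean/scale
  outp <- apply_noise(matrix(0.2, 600, 600),
                      list(gaussian_sd = 0, poisson_scale = 1000), seed = 4)
  expect_equal(mean(outp), 0.2, tolerance = 0.005)
  expect_equal(stats::var(as.vector(outp)), 0.2 / 1000, tolerance = 0.05)
  expect_true(all(apply_noise(matrix(0, 50, 50),
                              list(gaussian_sd = 1, poisson_scale = 0),
                              seed = 1) >= 0))
})

test_that("defocus blur matches Gaussian closed forms", {
  img <- matrix(runif(64 * 64), 64, 64)
  expect_identical(apply_defocus(img, 0), img)
  expect_error(apply_defocus(img, -2), "non-negative")

  imp <- matrix(0, 129, 129)
  imp[65, 65] <- 7
  bl <- apply_defocus(imp, 3)
  expect_equal(max(bl), 7 / (2 * pi * 9), tolerance = 0.02)
  expect_equal(sum(bl), 7, tolerance = 1e-3 * 7)   # mass conserved

  smooth <- gauss_blur(matrix(runif(128 * 128), 128, 128), 4)
  twice <- apply_defocus(apply_defocus(smooth, 2), 3)
  once <- apply_defocus(smooth, sqrt(13))
  expect_lt(max(abs(twice - once)), 1e-6)          # semigroup property
})

test_that("phenotype populations are separable as designed", {
  sc <- fixture("mixed_scene", generate_scene(
    small_cfg(class_fractions = c(live = 0.6, etotic = 0.2, dead = 0.2),
              seed = 5L)))
  ob <- truth_objects(sc)
  lsy <- log10(ob$sytox_mean + 1e-6)
  # dead cells sit at least a decade above live cells in Sytox
  expect_gte(mean(lsy[ob$truth_class == "dead"]) -
               mean(lsy[ob$truth_class == "live"]), 1)
  # ET clouds are larger and Hoechst-dimmer than live nuclei
  expect_gt(mean(ob$area[ob$truth_class == "etotic"]),
            2 * mean(ob$area[ob$truth_class == "live"]))
  expect_lt(mean(ob$hoechst_mean[ob$truth_class == "etotic"]),
            mean(ob$hoechst_mean[ob$truth_class == "live"]))
})

test_that("datasets round-trip through 16-bit TIFF exactly", {
  dir <- withr::local_tempdir()
  sc <- generate_scene(small_cfg(n_cells = 25L, seed = 9L))
  sc$image_id <- "im1"; sc$animal <- "a1"; sc$treatment <- "control"
  sc$replicate <- 1L
  man <- write_dataset(list(sc), dir)
  expect_equal(nrow(man), 1L)
  expect_setequal(list.files(dir),
                  c("im1_hoechst.tif", "im1_sytox.tif", "im1_truth.tif",
                    "metadata.csv"))
  back <- tiff::readTIFF(file.path(dir, "im1_hoechst.tif"))
  quantized <- round(pmin(pmax(sc$hoechst, 0), 1) * 65535) / 65535
  expect_equal(back, quantized, tolerance = 1e-12)
  mask_back <- round(tiff::readTIFF(file.path(dir, "im1_truth.tif")) * 65535)
  expect_equal(mask_back, unname(sc$truth$mask + 0))
})

test_that("plate layouts have the full animal x treatment x replicate grid", {
  ds <- fixture("plate_small", simulate_dataset(
    treatments = list(control = c(live = 0.9, etotic = 0.05, dead = 0.05),
                      pma = c(live = 0.75, etotic = 0.2, dead = 0.05)),
    animals = 2, replicates = 3,
    base_config = small_cfg(), seed = 7))
  expect_equal(nrow(ds$metadata), 2 * 2 * 3)
  expect_equal(length(ds$pairs), 12L)
  expect_false(anyDuplicated(ds$metadata$image_id) > 0)
  tab <- table(ds$metadata$animal, ds$metadata$treatment)
  expect_true(all(tab == 3))
})

test_that("simulator configs survive the YAML round trip", {
  path <- withr::local_tempfile(fileext = ".yaml")
  cfg <- small_cfg(defocus_sigma_px = 1.5, seed = 77L)
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back$n_cells, cfg$n_cells)
  expect_equal(back$class_fractions, cfg$class_fractions)
  expect_equal(back$defocus_sigma_px, 1.5)
  expect_identical(generate_scene(back)$hoechst, generate_scene(cfg)$hoechst)
})
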