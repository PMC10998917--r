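test_that("gate rules apply in the documented order", {
  g <- gate_config(gate_sytox = -1, gate_hoechst = -1.5)
  obj <- data.frame(
    hoechst_mean = c(10^-0.2, 10^-0.5, 10^-2.5, 10^-2.2, 10^-0.5),
    sytox_mean   = c(10^-0.3, 10^-2.0, 10^-2.0, 10^-0.4, 10^-1.5),
    area = c(30, 30, 300, 200, 30))
  out <- classify_objects(obj, g)
  # bright-Hoechst + bright-Sytox is dead: the Sytox gate wins
  expect_equal(out$class, c("dead", "live", "etotic", "dead", "live"))
  expect_true(all(out$class %in% c("live", "etotic", "dead")))

  # minimum ET area pushes small Hoechst-low objects to live
  g2 <- gate_config(-1, -1.5, min_et_area_px = 100)
  out2 <- classify_objects(obj, g2)
  expect_equal(out2$class[3], "etotic")
  small_et <- obj; small_et$area[3] <- 10
  expect_equal(classify_objects(small_et, g2)$class[3], "live")
})

test_that("classification is exhaustive and exclusive on random features", {
  set.seed(5)
  obj <- data.frame(hoechst_mean = 10^stats::runif(500, -4, 0),
                    sytox_mean = 10^stats::runif(500, -4, 0),
                    area = sample(5:500, 500, TRUE))
  out <- classify_objects(obj, gate_config(-1.2, -1.1))
  expect_false(any(is.na(out$class)))
  expect_true(all(out$class %in% c("live", "etotic", "dead")))
  # rules reproduce a direct tally
  ls <- log10(obj$sytox_mean + 1e-6); lh <- log10(obj$hoechst_mean + 1e-6)
  expect_equal(sum(out$class == "dead"), sum(ls > -1.2))
  expect_equal(sum(out$class == "etotic"), sum(ls <= -1.2 & lh < -1.1))
})

test_that("auto gates match the normal-theory location on synthetic controls", {
  set.seed(9)
  ctrl <- data.frame(hoechst_mean = 10^stats::rnorm(1e4, -0.5, 0.08),
                     sytox_mean = 10^stats::rnorm(1e4, 1, 0.1))
  g <- auto_gates(ctrl)
  # for a log-normal control, median + 3 * scaled MAD estimates mu + 3 sigma
  expect_equal(g$gate_sytox, 1 + 3 * 0.1, tolerance = 0.02)
  expect_equal(g$gate_hoechst, -0.5 - 3 * 0.08, tolerance = 0.02)
  expect_equal(g$provenance, "auto")
  expect_false(g$degenerate)

  expect_error(auto_gates(ctrl[1:49, ]), "manual")

  const <- data.frame(hoechst_mean = rep(0.5, 60), sytox_mean = rep(0.02, 60))
  gd <- auto_gates(const)
  expect_true(gd$degenerate)
  expect_equal(gd$gate_sytox, log10(0.02 + 1e-6))
})

test_that("auto gates shift by exactly log10 k under global rescaling", {
  set.seed(10)
  ctrl <- data.frame(hoechst_mean = 10^stats::rnorm(500, -0.5, 0.1),
                     sytox_mean = 10^stats::rnorm(500, -2, 0.15))
  g1 <- auto_gates(ctrl, epsilon = 1e-12)
  k <- 0.37
  g2 <- auto_gates(transform(ctrl, hoechst_mean = k * hoechst_mean,
                             sytox_mean = k * sytox_mean), epsilon = 1e-12)
  expect_equal(g2$gate_sytox - g1$gate_sytox, log10(k), tolerance = 1e-9)
  expect_equal(g2$gate_hoechst - g1$gate_hoechst, log10(k), tolerance = 1e-9)
})

test_that("rescaling intensities with rederived auto gates preserves classes", {
  sc <- fixture("mixed_scene", generate_scene(
    small_cfg(class_fractions = c(live = 0.6, etotic = 0.2, dead = 0.2),
              seed = 5L)))
  ob <- truth_objects(sc)
  ctrl <- fixture("control_scene", generate_scene(small_cfg(seed = 21L)))
  ctrl_ob <- truth_objects(ctrl)
  g1 <- auto_gates(ctrl_ob)
  c1 <- classify_objects(ob, g1)$class
  for (k in c(0.5, 2)) {
    scale_tab <- function(tab) transform(tab, hoechst_mean = k * hoechst_mean,
                                         sytox_mean = k * sytox_mean)
    g2 <- auto_gates(scale_tab(ctrl_ob))
    c2 <- classify_objects(scale_tab(ob), g2)$class
    expect_equal(c2, c1)
  }
})

test_that("population percentages tally correctly and sum to 100", {
  cls <- data.frame(animal = "a1", treatment = "t", replicate = 1L,
                    class = rep(c("live", "etotic", "dead"), c(7, 2, 1)))
  out <- population_percentages(cls)
  expect_equal(out$n_objects, 10L)
  expect_equal(c(out$pct_live, out$pct_etotic, out$pct_dead), c(70, 20, 10))

  solo <- data.frame(animal = "a", treatment = "t", replicate = 1L,
                     class = rep("live", 4))
  out <- population_percentages(solo)
  expect_equal(c(out$pct_live, out$pct_etotic, out$pct_dead), c(100, 0, 0))

  set.seed(2)
  rnd <- data.frame(animal = sample(c("a", "b"), 300, TRUE),
                    treatment = sample(c("x", "y"), 300, TRUE),
                    replicate = sample(1:2, 300, TRUE),
                    class = sample(c("live", "etotic", "dead"), 300, TRUE))
  out <- population_percentages(rnd)
  expect_true(all(abs(out$pct_live + out$pct_etotic + out$pct_dead - 100)
                  < 1e-9))
  for (i in seq_len(nrow(out))) {
    sel <- rnd$animal == out$animal[i] & rnd$treatment == out$treatment[i] &
      rnd$replicate == out$replicate[i]
    expect_equal(out$n_objects[i], sum(sel))
    expect_equal(out$pct_dead[i], 100 * sum(rnd$class[sel] == "dead") / sum(sel))
  }
})
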