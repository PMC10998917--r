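# shared fixtures, memoized so expensive scenes are generated once per run
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# a compact field with the default per-area cell density
small_cfg <- function(...) {
  args <- list(...)
  defaults <- list(image_shape = c(256L, 256L), n_cells = 160L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# default single-image correction as used by the pipeline
bg_correct <- function(img, ...) {
  correct_illumination(img, estimate_background(img), ...)
}

# truth-labelled object table measured on corrected channels
truth_objects <- function(scene) {
  ob <- measure_objects(scene$truth$mask,
                        bg_correct(scene$hoechst),
                        bg_correct(scene$sytox))
  ob$truth_class <- scene$truth$cells$class[ob$object_id]
  ob
}

# brute-force Otsu oracle: explicit scan over all 256 level candidates of
# an 8-bit histogram, computing class moments directly from the counts
otsu_bruteforce <- function(counts) {
  stopifnot(length(counts) == 256L)
  x <- (0:255) / 255
  n <- sum(counts)
  best_k <- NA_integer_
  best_b <- -Inf
  for (k in 1:255) {                       # background = levels 0..k-1
    n0 <- sum(counts[1:k])
    n1 <- n - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:k] * x[1:k]) / n0
    mu1 <- sum(counts[(k + 1):256] * x[(k + 1):256]) / n1
    b <- (n0 / n) * (n1 / n) * (mu1 - mu0)^2
    if (b > best_b + 1e-15) {
      best_b <- b
      best_k <- k
    }
  }
  list(threshold01 = (best_k - 1) / 255, between_var = best_b)
}

# direct trimmed-statistics oracle for the robust background threshold
robust_threshold_oracle <- function(px, lower = 0.05, upper = 0.05,
                                    ndev = 2, cf = 0.89) {
  n <- length(px)
  s <- sort(px)
  keep <- s[(floor(lower * n) + 1):(n - floor(upper * n))]
  m <- sum(keep) / length(keep)
  sdp <- sqrt(sum((keep - m)^2) / length(keep))
  (m + ndev * sdp) * cf
}

# union of filled discs as a logical mask, for declumping fixtures
disc_mask <- function(dims, centers, radius) {
  m <- matrix(FALSE, dims[1], dims[2])
  for (k in seq_len(nrow(centers))) {
    d2 <- outer((seq_len(dims[1]) - centers[k, 1])^2,
                (seq_len(dims[2]) - centers[k, 2])^2, `+`)
    m <- m | (d2 <= radius^2)
  }
  m
}
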