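#' Configuration for the synthetic two-channel scene generator
#'
#' Builds a validated configuration for [generate_scene()]. The generator
#' renders three phenotypes seen in dual Hoechst/SytoxGreen staining of
#' invertebrate immune-cell preparations:
#'
#' * **live** cells: compact Gaussian-profile nuclei, bright in Hoechst
#'   (membrane-permeable DNA dye) and dim in SytoxGreen
#'   (membrane-impermeant);
#' * **etotic** cells: cells that have cast an extracellular chromatin trap
#'   -- a large, diffuse, low-amplitude cloud with radiating filament
#'   texture, faint in both channels;
#' * **dead** cells: compact nuclei with a compromised membrane, bright in
#'   SytoxGreen and spanning a wide (one-decade, log-uniform) range of
#'   Hoechst intensity.
#'
#' Default amplitudes are expressed as fractions of the detector dynamic
#' range and were chosen so the three populations are linearly separable in
#' log10 mean-intensity space; `overlap` (0..1) geometrically pulls the
#' etotic and dead amplitudes toward the live values for stress testing.
#'
#' @param image_shape integer `c(rows, cols)`.
#' @param n_cells number of cells to place.
#' @param class_fractions named numeric `c(live=, etotic=, dead=)`, summing
#'   to 1.
#' @param live_params,dead_params lists with `radius_px = c(mean, sd)`,
#'   `hoechst_amp`, `sytox_amp`.
#' @param etotic_params list with `cloud_radius_px = c(mean, sd)`,
#'   `n_filaments`, `hoechst_amp`, `sytox_amp`.
#' @param chromatin nuclear substructure texture: `n_foci` condensed
#'   chromatin foci per nucleus, their Gaussian `sigma_px`, and their
#'   amplitude relative to the nuclear envelope (`rel_amp`).
#' @param bacteria list with `density` (expected specks per image) and
#'   `amp`; bacterial DNA takes up both dyes, so specks appear in both
#'   channels.
#' @param background_level flat autofluorescence baseline added to both
#'   channels before the illumination field is applied.
#' @param illumination list with `type` in `none|linear|radial` and
#'   `relative_amplitude`.
#' @param noise list with `gaussian_sd` (additive read noise) and
#'   `poisson_scale` (full-scale photon count; 0 disables shot noise).
#' @param defocus_sigma_px Gaussian defocus blur applied to both channels.
#' @param min_separation_px minimum distance between cell centroids.
#' @param border_margin_px centroids are kept at least this far from the
#'   image border.
#' @param overlap class-separability stress knob in `[0, 1]`; 0 keeps the
#'   default well-separated populations.
#' @param seed integer RNG seed; identical config + seed reproduces
#'   bit-identical images.
#' @return an object of class `sim_config`.
#' @seealso [generate_scene()], [simulate_dataset()]
#' @export
sim_config <- function(image_shape = c(512L, 512L),
                       n_cells = 650L,
                       class_fractions = c(live = 0.90, etotic = 0.05,
                                           dead = 0.05),
                       live_params = list(radius_px = c(mean = 3.5, sd = 0.5),
                                          hoechst_amp = 0.70,
                                          sytox_amp = 0.008),
                       etotic_params = list(cloud_radius_px = c(mean = 10, sd = 1.5),
                                            n_filaments = 6L,
                                            hoechst_amp = 0.18,
                                            sytox_amp = 0.003),
                       dead_params = list(radius_px = c(mean = 3.2, sd = 0.5),
                                          hoechst_amp = 0.70,
                                          sytox_amp = 0.80),
                       chromatin = list(n_foci = 4L, sigma_px = 1.2,
                                        rel_amp = 0.7),
                       bacteria = list(density = 0, amp = 0.15),
                       background_level = 0.02,
                       illumination = list(type = "none",
                                           relative_amplitude = 0),
                       noise = list(gaussian_sd = 0.002,
                                    poisson_scale = 5000),
                       defocus_sigma_px = 0,
                       min_separation_px = 11,
                       border_margin_px = 16,
                       overlap = 0,
                       seed = 1L) {
  cfg <- list(image_shape = as.integer(image_shape),
              n_cells = as.integer(n_cells),
              class_fractions = class_fractions,
              live_params = live_params,
              etotic_params = etotic_params,
              dead_params = dead_params,
              chromatin = chromatin,
              bacteria = bacteria,
              background_level = background_level,
              illumination = illumination,
              noise = noise,
              defocus_sigma_px = defocus_sigma_px,
              min_separation_px = min_separation_px,
              border_margin_px = border_margin_px,
              overlap = overlap,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  fr <- cfg$class_fractions
  if (!all(c("live", "etotic", "dead") %in% names(fr)))
    stop("class_fractions must be named live, etotic, dead")
  fr <- fr[c("live", "etotic", "dead")]
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9)
    stop("class_fractions must be non-negative and sum to 1 (within 1e-9)")
  if (length(cfg$image_shape) != 2L || any(cfg$image_shape < 1L))
    stop("image_shape must be two positive integers")
  if (cfg$n_cells < 0L) stop("n_cells must be >= 0")
  amps <- c(cfg$live_params$hoechst_amp, cfg$live_params$sytox_amp,
            cfg$etotic_params$hoechst_amp, cfg$etotic_params$sytox_amp,
            cfg$dead_params$hoechst_amp, cfg$dead_params$sytox_amp,
            cfg$bacteria$amp)
  if (any(amps < 0)) stop("all amplitudes must be >= 0")
  if (cfg$live_params$hoechst_amp <= cfg$etotic_params$hoechst_amp)
    stop("live hoechst_amp must exceed etotic hoechst_amp ",
         "(ET chromatin clouds are diffuse and Hoechst-low)")
  if (!cfg$illumination$type %in% c("none", "linear", "radial"))
    stop("unknown illumination type: ", cfg$illumination$type)
  if (cfg$defocus_sigma_px < 0) stop("defocus_sigma_px must be >= 0")
  if (cfg$overlap < 0 || cfg$overlap > 1) stop("overlap must be in [0, 1]")
  invisible(cfg)
}

#' Generate one synthetic two-channel field of view with ground truth
#'
#' Renders a Hoechst and a SytoxGreen channel according to `config` and
#' returns them together with the ground truth used to draw them: a cell
#' table (id, class, centroid, nominal radius) and an integer label mask
#' (later-placed cells win where extents overlap). The scene is composed as
#' background + cells + bacterial specks, then multiplied by the
#' illumination field, blurred by the defocus sigma, degraded by shot and
#' read noise, and finally clipped to `[0, 1]`.
#'
#' The RNG stream is fully determined by `config$seed`; the first draw is
#' the multinomial split of `n_cells` over the three classes.
#'
#' @param config a [sim_config()] object.
#' @return a list of class `tq_scene` with elements `hoechst`, `sytox`
#'   (numeric matrices), `truth` (list: `cells` data frame, `mask` integer
#'   matrix, `counts` named integer vector) and `config`.
#' @export
generate_scene <- function(config) {
  validate_sim_config(config)
  nr <- config$image_shape[1]
  nc <- config$image_shape[2]
  with_seed(config$seed, {
    fr <- config$class_fractions[c("live", "etotic", "dead")]
    counts <- if (config$n_cells > 0)
      drop(stats::rmultinom(1, config$n_cells, fr))
    else c(live = 0L, etotic = 0L, dead = 0L)
    names(counts) <- c("live", "etotic", "dead")
    classes <- rep(names(counts), counts)

    pos <- place_centroids(config$n_cells, nr, nc,
                           config$min_separation_px,
                           config$border_margin_px)

    hoechst <- matrix(0, nr, nc)
    sytox <- matrix(0, nr, nc)
    mask <- matrix(0L, nr, nc)
    radius <- numeric(config$n_cells)

    ov <- config$overlap
    lp <- config$live_params
    ep <- config$etotic_params
    dp <- config$dead_params
    # geometric interpolation toward the live amplitudes: overlap = 1
    # collapses the classes onto each other in log-intensity space
    et_h <- ep$hoechst_amp * (lp$hoechst_amp / ep$hoechst_amp)^ov
    et_s <- ep$sytox_amp
    dead_s <- dp$sytox_amp * (max(lp$sytox_amp, 1e-4) / dp$sytox_amp)^ov

    for (i in seq_len(config$n_cells)) {
      cl <- classes[i]
      if (cl == "live") {
        r <- max(2, stats::rnorm(1, lp$radius_px[["mean"]],
                                 lp$radius_px[["sd"]]))
        amp_h <- lp$hoechst_amp * 10^stats::runif(1, -0.15, 0)
        # membrane integrity varies: half a decade of residual Sytox uptake
        amp_s <- lp$sytox_amp * 10^stats::runif(1, -0.5, 0)
        p <- nucleus_patch(dim(hoechst), pos[i, 1], pos[i, 2], r,
                           config$chromatin)
      } else if (cl == "dead") {
        r <- max(2, stats::rnorm(1, dp$radius_px[["mean"]],
                                 dp$radius_px[["sd"]]))
        # "a range of Hoechst staining": log-uniform over one decade
        amp_h <- dp$hoechst_amp * 10^stats::runif(1, -1, 0)
        amp_s <- dead_s * 10^stats::runif(1, -0.15, 0)
        p <- nucleus_patch(dim(hoechst), pos[i, 1], pos[i, 2], r,
                           config$chromatin)
      } else {
        r <- max(4, stats::rnorm(1, ep$cloud_radius_px[["mean"]],
                                 ep$cloud_radius_px[["sd"]]))
        jit <- 10^stats::runif(1, -0.2, 0)
        amp_h <- et_h * jit
        amp_s <- et_s * jit
        p <- cloud_patch(dim(hoechst), pos[i, 1], pos[i, 2], r,
                         ep$n_filaments)
      }
      if (!is.null(p)) {
        hoechst[p$rr, p$cc] <- hoechst[p$rr, p$cc] + amp_h * p$m
        if (amp_s > 0)
          sytox[p$rr, p$cc] <- sytox[p$rr, p$cc] + amp_s * p$m
      }
      radius[i] <- r
      mask <- paint_disc(mask, pos[i, 1], pos[i, 2], r, i)
    }

    if (config$bacteria$density > 0) {
      nb <- stats::rpois(1, config$bacteria$density)
      for (b in seq_len(nb)) {
        br <- stats::runif(1, 1, nr)
        bc <- stats::runif(1, 1, nc)
        bs <- stats::runif(1, 1, 2)
        ba <- config$bacteria$amp * 10^stats::runif(1, -0.5, 0)
        hoechst <- add_blob(hoechst, br, bc, bs, ba)
        sytox <- add_blob(sytox, br, bc, bs, 0.8 * ba)
      }
    }

    hoechst <- hoechst + config$background_level
    sytox <- sytox + config$background_level
    hoechst <- apply_illumination(hoechst, config$illumination)
    sytox <- apply_illumination(sytox, config$illumination)
    if (config$defocus_sigma_px > 0) {
      hoechst <- apply_defocus(hoechst, config$defocus_sigma_px)
      sytox <- apply_defocus(sytox, config$defocus_sigma_px)
    }
    hoechst <- apply_noise(hoechst, config$noise)
    sytox <- apply_noise(sytox, config$noise)
    hoechst <- pmin(hoechst, 1)
    sytox <- pmin(sytox, 1)

    cells <- data.frame(id = seq_len(config$n_cells),
                        class = classes,
                        row = if (config$n_cells) pos[, 1] else numeric(0),
                        col = if (config$n_cells) pos[, 2] else numeric(0),
                        radius_px = radius,
                        stringsAsFactors = FALSE)
    out <- list(hoechst = hoechst, sytox = sytox,
                truth = list(cells = cells, mask = mask, counts = counts),
                config = config)
    class(out) <- "tq_scene"
    out
  })
}

#' @export
print.tq_scene <- function(x, ...) {
  cat(sprintf("synthetic scene %dx%d px, %d cells (live %d, etotic %d, dead %d)\n",
              nrow(x$hoechst), ncol(x$hoechst), nrow(x$truth$cells),
              x$truth$counts[["live"]], x$truth$counts[["etotic"]],
              x$truth$counts[["dead"]]))
  invisible(x)
}

# dart-throwing placement with a minimum centroid separation; errors with
# the achieved count when the field cannot hold n points
place_centroids <- function(n, nr, nc, min_sep, margin, max_tries = 500L) {
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  lo_r <- 1 + margin; hi_r <- nr - margin
  lo_c <- 1 + margin; hi_c <- nc - margin
  if (lo_r >= hi_r || lo_c >= hi_c)
    stop(sprintf("placement failed: image %dx%d too small for margin %g (placed 0 of %d cells)",
                 nr, nc, margin, n))
  pos <- matrix(NA_real_, n, 2)
  placed <- 0L
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      r <- stats::runif(1, lo_r, hi_r)
      c <- stats::runif(1, lo_c, hi_c)
      if (placed == 0L ||
          min((pos[seq_len(placed), 1] - r)^2 +
              (pos[seq_len(placed), 2] - c)^2) >= min_sep^2) {
        placed <- placed + 1L
        pos[placed, ] <- c(r, c)
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop(sprintf("placement failed: placed %d of %d cells at minimum separation %g px in a %dx%d image",
                   placed, n, min_sep, nr, nc))
  }
  pos
}

# add a Gaussian-profile blob of peak `amp` and sd `sigma` in a local window
add_blob <- function(img, row, col, sigma, amp, extent = 4) {
  if (amp <= 0 || sigma <= 0) return(img)
  w <- ceiling(extent * sigma)
  r0 <- max(1L, floor(row - w)); r1 <- min(nrow(img), ceiling(row + w))
  c0 <- max(1L, floor(col - w)); c1 <- min(ncol(img), ceiling(col + w))
  if (r0 > r1 || c0 > c1) return(img)
  dr <- (r0:r1) - row
  dc <- (c0:c1) - col
  img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] +
    amp * exp(-outer(dr^2, dc^2, `+`) / (2 * sigma^2))
  img
}

# unit-peak Gaussian blob as a local patch with its target image indices;
# NULL when the window falls entirely outside the image
blob_patch <- function(dims, row, col, sigma, extent = 4) {
  if (sigma <= 0) return(NULL)
  w <- ceiling(extent * sigma)
  r0 <- max(1L, floor(row - w)); r1 <- min(dims[1], ceiling(row + w))
  c0 <- max(1L, floor(col - w)); c1 <- min(dims[2], ceiling(col + w))
  if (r0 > r1 || c0 > c1) return(NULL)
  dr <- (r0:r1) - row
  dc <- (c0:c1) - col
  list(rr = r0:r1, cc = c0:c1,
       m = exp(-outer(dr^2, dc^2, `+`) / (2 * sigma^2)))
}

# nucleus as a local patch: Gaussian envelope (sd = radius/2) plus a few
# brighter condensed-chromatin foci; identical geometry is reused for both
# channels so a cell's Hoechst/Sytox profiles are spatially coherent
nucleus_patch <- function(dims, row, col, radius, chromatin) {
  sigma <- radius / 2
  w <- ceiling(2 * radius + 4 * chromatin$sigma_px + 2)
  r0 <- floor(row) - w; c0 <- floor(col) - w
  side <- 2L * w + 1L
  prow <- row - r0 + 1; pcol <- col - c0 + 1
  patch <- add_blob(matrix(0, side, side), prow, pcol, sigma, 1)
  for (f in seq_len(chromatin$n_foci)) {
    fr <- prow + stats::rnorm(1, 0, 0.45 * radius)
    fc <- pcol + stats::rnorm(1, 0, 0.45 * radius)
    patch <- add_blob(patch, fr, fc, chromatin$sigma_px, chromatin$rel_amp)
  }
  rr <- max(1L, r0):min(dims[1], r0 + side - 1L)
  cc <- max(1L, c0):min(dims[2], c0 + side - 1L)
  list(rr = rr, cc = cc, m = patch[rr - r0 + 1L, cc - c0 + 1L])
}

# unit-peak diffuse chromatin cloud with radiating filament texture as a
# local patch; the same geometry is scaled per channel by the caller
cloud_patch <- function(dims, row, col, radius, n_filaments) {
  sigma <- radius / 2
  w <- ceiling(radius + 2 * sigma + 6)
  r0 <- floor(row) - w; c0 <- floor(col) - w
  side <- 2L * w + 1L
  prow <- row - r0 + 1; pcol <- col - c0 + 1
  patch <- add_blob(matrix(0, side, side), prow, pcol, sigma, 1)
  angles <- stats::runif(n_filaments, 0, 2 * pi)
  for (a in angles) {
    ts <- seq(0.3 * radius, radius, by = 2)
    wig <- cumsum(stats::rnorm(length(ts), 0, 0.6))
    for (k in seq_along(ts)) {
      t <- ts[k]
      fr <- prow + t * cos(a) - wig[k] * sin(a)
      fc <- pcol + t * sin(a) + wig[k] * cos(a)
      patch <- add_blob(patch, fr, fc, 1.3,
                        1.8 * exp(-t^2 / (2 * sigma^2)))
    }
  }
  rr <- max(1L, r0):min(dims[1], r0 + side - 1L)
  cc <- max(1L, c0):min(dims[2], c0 + side - 1L)
  list(rr = rr, cc = cc, m = patch[rr - r0 + 1L, cc - c0 + 1L])
}

# paint a filled disc of `id` into an integer mask (later calls overwrite)
paint_disc <- function(mask, row, col, radius, id) {
  r0 <- max(1L, floor(row - radius)); r1 <- min(nrow(mask), ceiling(row + radius))
  c0 <- max(1L, floor(col - radius)); c1 <- min(ncol(mask), ceiling(col + radius))
  if (r0 > r1 || c0 > c1) return(mask)
  dr <- (r0:r1) - row
  dc <- (c0:c1) - col
  sub <- mask[r0:r1, c0:c1]
  sub[outer(dr^2, dc^2, `+`) <= radius^2] <- as.integer(id)
  mask[r0:r1, c0:c1] <- sub
  mask
}

#' Apply a smooth multiplicative illumination field
#'
#' Multiplies the image by a smooth field with range exactly
#' `[1, 1 + relative_amplitude]`: `linear` ramps along the column axis,
#' `radial` is brightest at the image centre and falls off quadratically to
#' 1 at the farthest corner, `none` returns the input unchanged.
#'
#' @param image numeric matrix.
#' @param illumination list with `type` (`none`, `linear`, `radial`) and
#'   `relative_amplitude >= 0`.
#' @return the shaded image.
#' @export
apply_illumination <- function(image, illumination) {
  amp <- illumination$relative_amplitude
  if (is.null(amp) || amp < 0)
    stop("relative_amplitude must be >= 0")
  type <- illumination$type
  if (type == "none" || amp == 0) return(image)
  nr <- nrow(image); nc <- ncol(image)
  if (type == "linear") {
    ramp <- if (nc > 1) (seq_len(nc) - 1) / (nc - 1) else 0
    field <- matrix(1 + amp * ramp, nr, nc, byrow = TRUE)
  } else if (type == "radial") {
    cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
    d2 <- outer((seq_len(nr) - cr)^2, (seq_len(nc) - cc)^2, `+`)
    field <- 1 + amp * (1 - d2 / max(d2))
  } else {
    stop("unknown illumination type: ", type)
  }
  image * field
}

#' Add shot and read noise to an image
#'
#' Applies scaled Poisson (shot) noise -- the pixel value is treated as a
#' photon rate of `value * poisson_scale` counts at full scale -- followed by
#' additive Gaussian read noise, and clips the result at 0.
#'
#' @param image non-negative numeric matrix on the `[0, 1]` scale.
#' @param noise list with `gaussian_sd >= 0` and `poisson_scale >= 0`
#'   (0 disables the respective component).
#' @param seed optional seed; `NULL` continues the caller's RNG stream.
#' @return the noisy image.
#' @export
apply_noise <- function(image, noise, seed = NULL) {
  if (noise$gaussian_sd < 0 || noise$poisson_scale < 0)
    stop("noise parameters must be >= 0")
  with_seed(seed, {
    out <- image
    if (noise$poisson_scale > 0)
      out <- matrix(stats::rpois(length(out), pmax(out, 0) * noise$poisson_scale),
                    nrow(out), ncol(out)) / noise$poisson_scale
    if (noise$gaussian_sd > 0)
      out <- out + matrix(stats::rnorm(length(out), 0, noise$gaussian_sd),
                          nrow(out), ncol(out))
    pmax(out, 0)
  })
}

#' Defocus an image with a Gaussian blur
#'
#' `sigma_px = 0` is the identity; total intensity is conserved (periodic
#' boundary, see [gauss_blur()]).
#'
#' @param image numeric matrix.
#' @param sigma_px blur standard deviation in pixels, `>= 0`.
#' @return the blurred image.
#' @export
apply_defocus <- function(image, sigma_px) {
  if (!is_scalar_num(sigma_px) || sigma_px < 0)
    stop("sigma_px must be a single non-negative number")
  gauss_blur(image, sigma_px)
}

#' Write a set of scenes to TIFF files plus a metadata table
#'
#' Writes one 16-bit grayscale TIFF per channel per scene, the ground-truth
#' label mask as a 16-bit TIFF, and a `metadata.csv` with columns
#' `image_id, animal, treatment, replicate, hoechst_path, sytox_path,
#' truth_path`. Intensities are clipped to `[0, 1]` and quantized to 16
#' bits on write.
#'
#' @param scenes list of `tq_scene` objects; each must carry `image_id`,
#'   `animal`, `treatment`, `replicate` elements (as attached by
#'   [simulate_dataset()]).
#' @param directory output directory (created if missing).
#' @return the manifest data frame (also written as `metadata.csv`),
#'   invisibly.
#' @export
write_dataset <- function(scenes, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory))
    stop("cannot create output directory: ", directory)
  rows <- lapply(scenes, function(sc) {
    id <- sc$image_id
    if (is.null(id)) stop("scene lacks an image_id")
    hp <- paste0(id, "_hoechst.tif")
    sp <- paste0(id, "_sytox.tif")
    tp <- paste0(id, "_truth.tif")
    write_tiff16(sc$hoechst, file.path(directory, hp))
    write_tiff16(sc$sytox, file.path(directory, sp))
    write_tiff16(sc$truth$mask / 65535, file.path(directory, tp))
    data.frame(image_id = id,
               animal = sc$animal %||% NA,
               treatment = sc$treatment %||% NA,
               replicate = sc$replicate %||% NA,
               hoechst_path = hp, sytox_path = sp, truth_path = tp,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(directory, "metadata.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

write_tiff16 <- function(img, path) {
  # quantize explicitly so written = round(clipped * 65535) / 65535 exactly
  q <- round(pmin(pmax(img, 0), 1) * 65535) / 65535
  ok <- try(tiff::writeTIFF(q, path, bits.per.sample = 16L), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed to write TIFF at ", path, ": ", attr(ok, "condition")$message)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a full plate layout of scenes
#'
#' Generates one scene per animal x treatment x technical replicate, the
#' replicate structure of a plate-based stimulation experiment. Treatments
#' are given as named class-fraction vectors, e.g. an elevated ETotic
#' fraction for a stimulated condition. Per-image seeds are drawn from
#' `seed` so the whole dataset is reproducible.
#'
#' @param treatments named list of `c(live=, etotic=, dead=)` fraction
#'   vectors, one per treatment.
#' @param animals number of animals (biological replicates).
#' @param replicates technical replicates per animal x treatment.
#' @param base_config a [sim_config()] used as the template for every scene.
#' @param seed integer master seed.
#' @param directory optional; when given, the dataset is also written with
#'   [write_dataset()].
#' @return list with `pairs` (scenes carrying metadata, directly usable by
#'   [run_pipeline()]) and `metadata` (data frame).
#' @export
simulate_dataset <- function(treatments,
                             animals = 4L,
                             replicates = 3L,
                             base_config = sim_config(),
                             seed = 1L,
                             directory = NULL) {
  stopifnot(length(treatments) >= 1, !is.null(names(treatments)))
  grid <- expand.grid(replicate = seq_len(replicates),
                      treatment = names(treatments),
                      animal = paste0("animal", seq_len(animals)),
                      stringsAsFactors = FALSE)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, nrow(grid)))
  pairs <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- base_config
    fr <- treatments[[grid$treatment[i]]]
    cfg$class_fractions <- fr[c("live", "etotic", "dead")]
    cfg$seed <- seeds[i]
    validate_sim_config(cfg)
    sc <- generate_scene(cfg)
    sc$image_id <- sprintf("%s_%s_r%d", grid$animal[i], grid$treatment[i],
                           grid$replicate[i])
    sc$animal <- grid$animal[i]
    sc$treatment <- grid$treatment[i]
    sc$replicate <- grid$replicate[i]
    pairs[[i]] <- sc
  }
  metadata <- data.frame(image_id = vapply(pairs, `[[`, "", "image_id"),
                         animal = grid$animal,
                         treatment = grid$treatment,
                         replicate = grid$replicate,
                         stringsAsFactors = FALSE)
  if (!is.null(directory)) write_dataset(pairs, directory)
  list(pairs = pairs, metadata = metadata)
}

#' Read or write a simulator configuration as YAML
#'
#' Serializes every [sim_config()] field to a plain-text YAML file and
#' back; named numeric vectors (`class_fractions`, `radius_px`) survive
#' the round trip.
#'
#' @param path YAML file path.
#' @return for `read_sim_config`, a validated [sim_config()].
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (nm in c("class_fractions", "image_shape"))
    if (!is.null(y[[nm]])) y[[nm]] <- unlist(y[[nm]])
  for (nm in c("live_params", "dead_params"))
    if (!is.null(y[[nm]]$radius_px))
      y[[nm]]$radius_px <- unlist(y[[nm]]$radius_px)
  if (!is.null(y$etotic_params$cloud_radius_px))
    y$etotic_params$cloud_radius_px <- unlist(y$etotic_params$cloud_radius_px)
  do.call(sim_config, y)
}

#' @rdname read_sim_config
#' @param config a [sim_config()] to serialize.
#' @export
write_sim_config <- function(config, path) {
  y <- unclass(config)
  # named atomic vectors must become maps, or YAML drops the names
  y$class_fractions <- as.list(y$class_fractions)
  y$live_params$radius_px <- as.list(y$live_params$radius_px)
  y$dead_params$radius_px <- as.list(y$dead_params$radius_px)
  y$etotic_params$cloud_radius_px <- as.list(y$etotic_params$cloud_radius_px)
  yaml::write_yaml(y, path)
  invisible(path)
}
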