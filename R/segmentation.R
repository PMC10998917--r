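#' Segmentation parameter set
#'
#' Defaults follow the global robust-background recipe used for nucleus
#' and trap segmentation: 5% outlier trimming on both tails, threshold =
#' (trimmed mean + 2 trimmed SD) x 0.89, pre-threshold smoothing scale
#' 1.3488 (i.e. a sigma-1 Gaussian), typical object diameters 5--50 px.
#'
#' @param lower_outlier_fraction,upper_outlier_fraction fraction of pixels
#'   trimmed from each tail before computing the robust statistics.
#' @param n_deviations number of trimmed standard deviations added to the
#'   trimmed mean.
#' @param correction_factor multiplier applied to the raw threshold.
#' @param smoothing_scale pre-binarization smoothing scale; Gaussian sigma
#'   is `smoothing_scale / 1.3488`, so the default scale is a sigma-1 blur
#'   and 0 disables smoothing.
#' @param diameter_range_px objects with equivalent diameter outside this
#'   range are discarded.
#' @param declump_min_separation_px minimum separation between declumping
#'   seeds; defaults to the lower diameter bound.
#' @param exclude_border drop objects touching the image border.
#' @param max_foreground_fraction segmentations whose foreground exceeds
#'   this fraction are flagged degenerate.
#' @return list of class `seg_params`.
#' @export
seg_params <- function(lower_outlier_fraction = 0.05,
                       upper_outlier_fraction = 0.05,
                       n_deviations = 2,
                       correction_factor = 0.89,
                       smoothing_scale = 1.3488,
                       diameter_range_px = c(5, 50),
                       declump_min_separation_px = NULL,
                       exclude_border = TRUE,
                       max_foreground_fraction = 0.5) {
  if (lower_outlier_fraction < 0 || upper_outlier_fraction < 0 ||
      lower_outlier_fraction + upper_outlier_fraction >= 1)
    stop("outlier fractions must be >= 0 and sum to < 1")
  if (correction_factor <= 0) stop("correction_factor must be > 0")
  if (smoothing_scale < 0) stop("smoothing_scale must be >= 0")
  if (is.null(declump_min_separation_px))
    declump_min_separation_px <- diameter_range_px[1]
  structure(list(lower_outlier_fraction = lower_outlier_fraction,
                 upper_outlier_fraction = upper_outlier_fraction,
                 n_deviations = n_deviations,
                 correction_factor = correction_factor,
                 smoothing_scale = smoothing_scale,
                 diameter_range_px = diameter_range_px,
                 declump_min_separation_px = declump_min_separation_px,
                 exclude_border = exclude_border,
                 max_foreground_fraction = max_foreground_fraction),
            class = "seg_params")
}

#' Global robust-background threshold
#'
#' Sorts the pixel sample, discards the lowest
#' `floor(lower * n)` and highest `floor(upper * n)` values, and returns
#' `(trimmed mean + n_deviations * trimmed SD) * correction_factor`. The SD
#' uses the population (divide-by-n) convention. Foreground is defined as
#' pixels strictly greater than the threshold.
#'
#' @param pixels numeric vector, length >= 2.
#' @param params a [seg_params()] object (only the trimming, deviation and
#'   correction fields are used).
#' @return the threshold (single numeric).
#' @export
robust_background_threshold <- function(pixels, params = seg_params()) {
  n <- length(pixels)
  if (n < 2L) stop("need at least 2 pixels")
  s <- sort(pixels)
  n_lo <- floor(params$lower_outlier_fraction * n)
  n_hi <- floor(params$upper_outlier_fraction * n)
  if (n_lo + n_hi >= n)
    stop("outlier trimming removed all pixels")
  trimmed <- s[(n_lo + 1):(n - n_hi)]
  m <- mean(trimmed)
  sd_pop <- sqrt(mean((trimmed - m)^2))
  (m + params$n_deviations * sd_pop) * params$correction_factor
}

#' Pre-threshold smoothing
#'
#' Gaussian blur with `sigma = smoothing_scale / 1.3488` (the default
#' scale therefore gives a sigma-1 blur); scale 0 is the identity. This
#' smoothing is applied only to the image used for thresholding --
#' intensity measurements are always taken on the unsmoothed corrected
#' image.
#'
#' @param image numeric matrix.
#' @param smoothing_scale smoothing scale, `>= 0`.
#' @return smoothed image.
#' @export
smooth_for_threshold <- function(image, smoothing_scale = 1.3488) {
  if (smoothing_scale < 0) stop("smoothing_scale must be >= 0")
  gauss_blur(image, smoothing_scale / 1.3488)
}

#' Binarize an image at a global threshold
#'
#' @param image numeric matrix.
#' @param threshold finite numeric; foreground is `image > threshold`
#'   (strict).
#' @return logical matrix.
#' @export
binarize <- function(image, threshold) {
  if (!is_scalar_num(threshold)) stop("threshold must be a finite scalar")
  image > threshold
}

#' Split clumped objects by shape
#'
#' Shape-based declumping: the Euclidean distance transform of the mask is
#' smoothed with a sigma-1 Gaussian, and a watershed constrained to the
#' mask is run on it. Local maxima closer than
#' `declump_min_separation_px` collapse into a single seed, so a connected
#' region with one seed stays one object. Labels are relabelled to a
#' contiguous `1..N`.
#'
#' @param mask logical (or 0/1) matrix.
#' @param params a [seg_params()]; uses `declump_min_separation_px`.
#' @return integer label matrix (0 = background).
#' @export
declump_by_shape <- function(mask, params = seg_params()) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  if (!any(m > 0))
    return(matrix(0L, nrow(mask), ncol(mask)))
  dm <- EBImage::distmap(m)
  dms <- gauss_blur(as.matrix(dm), 1)
  dms[m == 0] <- 0
  ws <- EBImage::watershed(EBImage::Image(dms),
                           tolerance = 0.5,
                           ext = max(1L, round(params$declump_min_separation_px)))
  relabel(matrix(as.integer(EBImage::imageData(ws)), nrow(mask), ncol(mask)))
}

#' Filter labelled objects by size and border contact
#'
#' Removes objects whose equivalent diameter (`2 * sqrt(area / pi)`) lies
#' outside `diameter_range_px`, and (optionally) objects touching the
#' image border, then relabels contiguously.
#'
#' @param labels integer label matrix.
#' @param params a [seg_params()].
#' @return filtered, relabelled integer label matrix.
#' @export
filter_objects <- function(labels, params = seg_params()) {
  nlab <- max(labels)
  if (nlab == 0L) return(labels)
  area <- tabulate(labels[labels > 0], nbins = nlab)
  diam <- 2 * sqrt(area / pi)
  keep <- area > 0 & diam >= params$diameter_range_px[1] &
    diam <= params$diameter_range_px[2]
  if (params$exclude_border) {
    border <- unique(c(labels[1, ], labels[nrow(labels), ],
                       labels[, 1], labels[, ncol(labels)]))
    keep[border[border > 0]] <- FALSE
  }
  out <- labels
  out[!is.na(out) & out > 0 & !keep[pmax(out, 1)]] <- 0L
  relabel(out)
}

# map labels to contiguous 1..N preserving first-appearance order of the
# original label values
relabel <- function(labels) {
  u <- sort(unique(labels[labels > 0]))
  if (length(u) == 0L) return(labels)
  map <- integer(max(u))
  map[u] <- seq_along(u)
  out <- labels
  pos <- labels > 0
  out[pos] <- map[labels[pos]]
  out
}

#' Segment a corrected image pair into labelled objects
#'
#' Builds the segmentation input (by default the pixelwise maximum of the
#' two channels, which share the `[0, 1]` dynamic-range scale, so that
#' Hoechst-low ETotic clouds and Sytox-high dead nuclei are both
#' detectable), smooths it, thresholds it with the global robust-background
#' rule, declumps by shape, and applies the size/border filter.
#'
#' @param hoechst,sytox corrected channel matrices (same shape).
#' @param params a [seg_params()].
#' @param channel which image drives segmentation: `"max"` (default),
#'   `"hoechst"` or `"sytox"`.
#' @return list with `labels` (integer matrix), `threshold`, `n_objects`
#'   and `degenerate` (TRUE when the thresholded foreground fraction
#'   exceeds `max_foreground_fraction`).
#' @export
segment_pair <- function(hoechst, sytox, params = seg_params(),
                         channel = c("max", "hoechst", "sytox")) {
  channel <- match.arg(channel)
  if (!all(dim(hoechst) == dim(sytox)))
    stop("channel shapes differ")
  segimg <- switch(channel,
    hoechst = hoechst,
    sytox = sytox,
    max = pmax(hoechst, sytox))
  sm <- smooth_for_threshold(segimg, params$smoothing_scale)
  thr <- robust_background_threshold(as.vector(sm), params)
  mask <- binarize(sm, thr)
  degenerate <- mean(mask) > params$max_foreground_fraction
  labels <- filter_objects(declump_by_shape(mask, params), params)
  list(labels = labels, threshold = thr,
       n_objects = max(labels), degenerate = degenerate)
}
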