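#' Two-class Otsu split of an intensity sample
#'
#' Classic discrete Otsu thresholding: values are min-max rescaled to
#' `[0, 1]`, quantized to 256 levels, and the threshold maximizing the
#' between-class variance (equivalently minimizing the weighted
#' within-class variance) is searched over all level candidates. Ties are
#' broken toward the smallest threshold. Foreground is defined as values
#' strictly greater than the threshold.
#'
#' @param values numeric vector of at least one finite, non-negative value.
#' @return list with `threshold` (on the original value scale),
#'   `within_var` and `between_var` (weighted within- and between-class
#'   variance on the rescaled `[0, 1]` scale) and `degenerate` (`TRUE` when
#'   all values are identical, in which case the common value is returned
#'   as the threshold and both variances are 0).
#' @export
otsu_split <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1L || any(!is.finite(values)) || any(values < 0))
    stop("'values' must contain >= 1 finite non-negative values")
  lo <- min(values); hi <- max(values)
  if (lo == hi)
    return(list(threshold = lo, within_var = 0, between_var = 0,
                degenerate = TRUE))
  v <- (values - lo) / (hi - lo)
  lev <- pmin(floor(v * 256), 255)                 # quantized level 0..255
  h <- tabulate(lev + 1L, nbins = 256L)
  x <- (0:255) / 255                               # level values on [0,1]
  n <- length(values)
  w0 <- cumsum(h) / n
  s0 <- cumsum(h * x)
  s0q <- cumsum(h * x^2)
  stot <- s0[256]
  # candidate k: background = levels <= k-1, threshold t = (k-1)/255
  k <- which(w0 > 0 & w0 < 1)                      # both classes non-empty
  mu0 <- s0[k] / (w0[k] * n)
  mu1 <- (stot - s0[k]) / ((1 - w0[k]) * n)
  between <- w0[k] * (1 - w0[k]) * (mu1 - mu0)^2
  best <- k[which.max(between)]                    # which.max takes first tie
  t01 <- (best - 1) / 255
  var0 <- s0q[best] / (w0[best] * n) - mu0[which(k == best)]^2
  sq1 <- (s0q[256] - s0q[best]) / ((1 - w0[best]) * n)
  var1 <- sq1 - mu1[which(k == best)]^2
  within <- w0[best] * max(var0, 0) + (1 - w0[best]) * max(var1, 0)
  list(threshold = lo + t01 * (hi - lo),
       within_var = within,
       between_var = max(between),
       degenerate = FALSE)
}

#' Tile-based focus score of an image
#'
#' Partitions the image into non-overlapping `tile_px x tile_px` tiles
#' (partial edge tiles are dropped) and returns the mean over tiles of the
#' normalized intensity variance `var_t / mean_t` (population variance;
#' tiles with zero mean contribute 0). Sharp, structured images score high;
#' defocused or flat fields score near 0, and a constant image scores
#' exactly 0. Input intensities are expected on the `[0, 1]` dynamic-range
#' scale (as read from TIFF).
#'
#' @param image numeric matrix at least one full tile in each dimension.
#' @param tile_px tile edge length in pixels (default 20).
#' @return a single non-negative focus score.
#' @export
focus_score <- function(image, tile_px = 20L) {
  stopifnot(is.matrix(image))
  tile_px <- as.integer(tile_px)
  ntr <- nrow(image) %/% tile_px
  ntc <- ncol(image) %/% tile_px
  if (ntr < 1L || ntc < 1L)
    stop(sprintf("image (%dx%d) smaller than one %dx%d tile",
                 nrow(image), ncol(image), tile_px, tile_px))
  crop <- image[seq_len(ntr * tile_px), seq_len(ntc * tile_px), drop = FALSE]
  arr <- array(crop, dim = c(tile_px, ntr, tile_px, ntc))
  mu <- apply(arr, c(2, 4), mean)
  mu2 <- apply(arr^2, c(2, 4), mean)
  v <- pmax(mu2 - mu^2, 0)
  nv <- ifelse(mu > 0, v / mu, 0)
  mean(nv)
}

#' Partition images into kept and removed sets by focus score
#'
#' An image is removed when any of its channels scores strictly below the
#' threshold (`focus_score < threshold` removed, `>= threshold` kept) --
#' the conservative rule that a field must be in focus in both dyes.
#'
#' @param records data frame with columns `image_id`, `channel`,
#'   `focus_score`; one row per image x channel (duplicates are an error).
#' @param threshold focus cutoff, default 0.2.
#' @return list with character vectors `kept` and `removed` (disjoint,
#'   exhaustive over the input image ids).
#' @export
qc_filter <- function(records, threshold = 0.2) {
  stopifnot(is.data.frame(records),
            all(c("image_id", "channel", "focus_score") %in% names(records)))
  if (nrow(records) == 0L)
    return(list(kept = character(0), removed = character(0)))
  key <- paste(records$image_id, records$channel, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate image_id/channel in QC records: ",
         records$image_id[duplicated(key)][1])
  fail <- tapply(records$focus_score < threshold, records$image_id, any)
  ids <- names(fail)
  list(kept = ids[!fail], removed = ids[fail])
}

#' Score both channels of a set of image pairs
#'
#' Convenience wrapper producing the QC record table consumed by
#' [qc_filter()]: one row per image and channel with the focus score and
#' its pass flag.
#'
#' @param pairs list of image pairs; each element needs `image_id`,
#'   `hoechst` and `sytox` matrices.
#' @param tile_px tile size for [focus_score()].
#' @param threshold pass cutoff.
#' @return data frame with columns `image_id`, `channel`, `focus_score`,
#'   `passed`.
#' @export
qc_report <- function(pairs, tile_px = 20L, threshold = 0.2) {
  rows <- lapply(pairs, function(p) {
    data.frame(image_id = p$image_id,
               channel = c("hoechst", "sytox"),
               focus_score = c(focus_score(p$hoechst, tile_px),
                               focus_score(p$sytox, tile_px)),
               stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, rows)
  if (is.null(rec))
    rec <- data.frame(image_id = character(0), channel = character(0),
                      focus_score = numeric(0))
  rec$passed <- rec$focus_score >= threshold
  rec
}
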