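#' Estimate a block-based background illumination field
#'
#' Divides the image into `block_px x block_px` blocks (final partial
#' blocks keep their own statistic) and takes a per-block background value
#' -- the block minimum by default, or a low percentile when noise makes
#' the minimum too pessimistic. The field is expanded back to image size
#' piecewise-constant (nearest neighbour, no smoothing), so every upsampled
#' pixel equals its source block value.
#'
#' @param image non-empty numeric matrix.
#' @param block_px block edge length, default 50.
#' @param statistic `"min"` (default) or `"percentile"`.
#' @param percentile probability used when `statistic = "percentile"`
#'   (default 0.02).
#' @return object of class `illum_field`: list with `block_px`, `values`
#'   (block grid matrix) and `field` (full-size matrix).
#' @export
estimate_background <- function(image, block_px = 50L,
                                statistic = c("min", "percentile"),
                                percentile = 0.02) {
  stopifnot(is.matrix(image), nrow(image) >= 1, ncol(image) >= 1)
  statistic <- match.arg(statistic)
  block_px <- as.integer(block_px)
  ri <- (seq_len(nrow(image)) - 1L) %/% block_px + 1L
  ci <- (seq_len(ncol(image)) - 1L) %/% block_px + 1L
  nbr <- max(ri); nbc <- max(ci)
  values <- matrix(NA_real_, nbr, nbc)
  for (i in seq_len(nbr)) {
    rows <- which(ri == i)
    for (j in seq_len(nbc)) {
      blk <- image[rows, which(ci == j)]
      values[i, j] <- if (statistic == "min") min(blk)
                      else stats::quantile(blk, percentile, names = FALSE)
    }
  }
  field <- values[ri, ci, drop = FALSE]
  structure(list(block_px = block_px, statistic = statistic,
                 values = values, field = field),
            class = "illum_field")
}

#' Remove an illumination field from an image
#'
#' `combine = "subtract"` (default) treats the block-background field as an
#' additive offset: `max(image - field, 0)`. `combine = "divide"` treats
#' the field as a multiplicative shading profile and flattens it while
#' preserving the mean background level:
#' `image * mean(field) / field`.
#'
#' @param image numeric matrix.
#' @param field an `illum_field` from [estimate_background()] (or a plain
#'   matrix of the same shape as `image`).
#' @param combine `"subtract"` or `"divide"`.
#' @return corrected image, same shape, non-negative.
#' @export
correct_illumination <- function(image, field,
                                 combine = c("subtract", "divide")) {
  combine <- match.arg(combine)
  f <- if (inherits(field, "illum_field")) field$field else field
  if (!is.matrix(f) || !all(dim(f) == dim(image)))
    stop(sprintf("field shape (%s) does not match image shape (%s)",
                 paste(dim(f), collapse = "x"),
                 paste(dim(image), collapse = "x")))
  if (combine == "subtract")
    return(pmax(image - f, 0))
  pos <- f > 0
  if (!any(pos)) return(image)               # field all zero: nothing to do
  scale <- mean(f[pos])
  out <- image
  out[pos] <- image[pos] * scale / f[pos]
  pmax(out, 0)
}
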