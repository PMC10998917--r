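#' @keywords internal
"_PACKAGE"

## Images are plain numeric matrices with intensities expressed as a
## fraction of the detector dynamic range, i.e. values nominally in [0, 1]
## (16-bit TIFFs are read and written on that scale by the tiff package).

#' Gaussian blur with exact mass conservation
#'
#' Convolves an image with an isotropic Gaussian by multiplying its discrete
#' Fourier transform with the analytic Gaussian transfer function
#' \eqn{\exp(-2\pi^2\sigma^2(f_r^2+f_c^2))}. The boundary is periodic, so
#' total intensity is conserved exactly and blurring with sigma `a` then `b`
#' equals a single blur with `sqrt(a^2+b^2)` to machine precision.
#'
#' @param img numeric matrix.
#' @param sigma Gaussian standard deviation in pixels; 0 returns `img`
#'   unchanged.
#' @return numeric matrix of the same shape.
#' @export
gauss_blur <- function(img, sigma) {
  stopifnot(is.matrix(img), is.numeric(sigma), length(sigma) == 1L)
  if (is.na(sigma) || sigma < 0)
    stop("'sigma' must be a single non-negative number")
  if (sigma == 0)
    return(img)
  nr <- nrow(img)
  nc <- ncol(img)
  fr <- fft_freq(nr)
  fc <- fft_freq(nc)
  H <- exp(-2 * pi^2 * sigma^2 * outer(fr^2, fc^2, `+`))
  Re(stats::fft(stats::fft(img) * H, inverse = TRUE)) / (nr * nc)
}

# DFT sample frequencies in cycles per pixel (numpy fftfreq layout)
fft_freq <- function(n) {
  half <- n %/% 2
  c(0:half, -rev(seq_len(n - half - 1L))) / n
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's
# RNG state afterwards so library functions stay reproducible but do not
# perturb user code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv())
    else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# single stop() with a consistent prefix for stage errors
stop_stage <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
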