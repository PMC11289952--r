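#' Acuity-limited viewing-distance blur
#'
#' Simulates the loss of spatial detail when the scene is viewed from a given
#' distance by an observer of finite spatial acuity. Spatial frequencies above
#' the minimum resolvable angle (MRA = 1/acuity degrees) are attenuated with a
#' channel-wise Gaussian low-pass filter whose standard deviation is chosen so
#' that the modulation transfer at the acuity cutoff frequency is 10%. The
#' operator is linear, identical across channels, and leaves a uniform image
#' unchanged; catches remain strictly positive.
#'
#' @param img A [cone_catch_image()].
#' @param vs A [visual_system()] supplying the acuity in cycles per degree.
#' @param geom A [viewing_geometry()].
#' @return A blurred [cone_catch_image()] at the same size and scale.
#' @export
apply_acuity <- function(img, vs, geom) {
  stopifnot(inherits(img, "cone_catch_image"),
            inherits(geom, "viewing_geometry"))
  sigma <- acuity_sigma_px(vs$acuity, geom)
  out <- img
  if (sigma < 1e-3) return(out)  # cutoff beyond Nyquist: no perceptible blur
  k <- gaussian_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  if (2L * r + 1L > min(dim(img$catch)[1:2]))
    stop("acuity blur extent (", 2L * r + 1L,
         " px) exceeds the image size; use a larger image or shorter distance")
  for (ch in seq_len(dim(img$catch)[3]))
    out$catch[, , ch] <- separable_blur(img$catch[, , ch], k)
  out
}

# sigma (px) with 10% modulation transfer at the acuity frequency:
# MTF(f) = exp(-2 pi^2 sigma^2 f^2) = 0.1 at f_c (cycles/px)
acuity_sigma_px <- function(acuity_cpd, geom) {
  f_c <- acuity_cpd * geom$deg_per_px
  sqrt(log(10) / (2 * pi^2)) / f_c
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# separable convolution with reflective boundary
separable_blur <- function(m, k) {
  r <- (length(k) - 1L) / 2L
  m <- apply_1d(m, k, r)            # along rows (vertical)
  t(apply_1d(t(m), k, r))           # along columns (horizontal)
}

apply_1d <- function(m, k, r) {
  n <- nrow(m)
  idx <- c(seq(r + 1L, 2L, -1L), seq_len(n), seq(n - 1L, n - r, -1L))
  mp <- m[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k))
    out <- out + k[j] * mp[seq(j, j + n - 1L), , drop = FALSE]
  out
}
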