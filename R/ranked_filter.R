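#' RNL ranked filter
#'
#' Edge-preserving smoothing used to remove the shallow gradients that
#' Gaussian acuity blur introduces at patch boundaries, while leaving true
#' edges in place. For every pixel, the neighbours inside a circular window
#' of the given radius are ranked by their combined perceptual distance
#' `sqrt(dS^2 + dL^2)` (chromatic and luminance JND units) to the centre
#' pixel; the centre is replaced by the rank-weighted mean of the neighbour
#' catches with weight `(1 - rank/N)^falloff`. The pass is repeated
#' `repetition` times (0 returns the input unchanged). Defaults follow the
#' conventional setting falloff 3, radius 5, repetition 5.
#'
#' @param img A [cone_catch_image()] (4 channels).
#' @param vs A [visual_system()].
#' @param falloff Integer weight exponent (>= 0).
#' @param radius Window radius in pixels (>= 1).
#' @param repetition Number of passes (>= 0).
#' @return A filtered [cone_catch_image()].
#' @export
rnl_ranked_filter <- function(img, vs, falloff = 3, radius = 5, repetition = 5) {
  stopifnot(inherits(img, "cone_catch_image"))
  if (radius < 1) stop("'radius' must be >= 1")
  if (repetition < 0) stop("'repetition' must be >= 0")
  if (falloff < 0) stop("'falloff' must be >= 0")
  if (repetition == 0) return(img)
  wc <- chromatic_weber(vs)
  wl <- unname(vs$weber[match(vs$luminance_channel, vs$channel_names)])
  out <- img
  out$catch <- .ranked_filter_cpp(img$catch, wc, wl, as.integer(falloff),
                                  as.integer(radius), as.integer(repetition))
  out
}
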