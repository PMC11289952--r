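#' Construct a receptor-noise-limited observer
#'
#' Describes the modeled viewer: photoreceptor channel names, relative
#' channel abundances, the single-receptor noise level, the derived Weber
#' fractions, and spatial acuity. The default observer is a trichromatic
#' triggerfish-like reef fish with a double cone serving the luminance
#' channel: relative abundances 1:2:2:2 (sw:mw:lw:dbl), receptor noise 0.05
#' and an acuity of 3 cycles per degree, giving Weber fractions of
#' 0.07:0.05:0.05:0.05 after rounding.
#'
#' @param abundances Named numeric vector of relative photoreceptor
#'   abundances, one entry per channel. Must be strictly positive.
#' @param noise Unitless single-receptor noise level (> 0).
#' @param acuity Spatial acuity in cycles per degree (> 0).
#' @param chromatic Names of the channels entering chromatic comparisons.
#' @param luminance Name of the channel carrying achromatic (luminance)
#'   contrast.
#' @return An object of class `visual_system`: a list with elements
#'   `channel_names`, `abundances`, `noise`, `weber`, `acuity`,
#'   `chromatic_channels`, `luminance_channel`.
#' @examples
#' vs <- visual_system()
#' round(vs$weber, 2)
#' @export
visual_system <- function(abundances = c(sw = 1, mw = 2, lw = 2, dbl = 2),
                          noise = 0.05,
                          acuity = 3,
                          chromatic = c("sw", "mw", "lw"),
                          luminance = "dbl") {
  if (is.null(names(abundances)) || any(!nzchar(names(abundances))))
    stop("'abundances' must be a fully named vector")
  if (!all(chromatic %in% names(abundances)))
    stop("chromatic channels missing from 'abundances'")
  if (!luminance %in% names(abundances))
    stop("luminance channel missing from 'abundances'")
  if (!is.numeric(acuity) || length(acuity) != 1L || acuity <= 0)
    stop("'acuity' must be a single positive number")
  w <- weber_fractions(abundances, noise)
  structure(
    list(
      channel_names = names(abundances),
      abundances = abundances,
      noise = noise,
      weber = w,
      acuity = acuity,
      chromatic_channels = chromatic,
      luminance_channel = luminance
    ),
    class = "visual_system"
  )
}

#' @export
print.visual_system <- function(x, ...) {
  cat("RNL visual system\n")
  cat("  channels:   ", paste(x$channel_names, collapse = ", "), "\n")
  cat("  abundances: ", paste(x$abundances, collapse = ":"), "\n")
  cat("  noise:      ", x$noise, "\n")
  cat("  weber:      ", paste(sprintf("%.4f", x$weber), collapse = ", "), "\n")
  cat("  acuity:     ", x$acuity, "cpd\n")
  invisible(x)
}

#' Channel Weber fractions from abundances and receptor noise
#'
#' The per-channel Weber fraction is `noise * sqrt(max(abundances) /
#' abundances)`: the most abundant channel type carries the nominal receptor
#' noise and rarer channels are noisier in proportion to the square root of
#' their relative scarcity. With abundances 1:2:2:2 and noise 0.05 this gives
#' 0.0707:0.05:0.05:0.05, i.e. 0.07:0.05:0.05:0.05 at two decimals.
#'
#' @param abundances Strictly positive numeric vector of relative channel
#'   abundances.
#' @param noise Strictly positive unitless receptor noise.
#' @return Numeric vector of Weber fractions (full precision, not rounded),
#'   named like `abundances`.
#' @examples
#' weber_fractions(c(1, 2, 2, 2), 0.05)
#' @export
weber_fractions <- function(abundances, noise) {
  if (!is.numeric(abundances) || length(abundances) < 1L || any(abundances <= 0))
    stop("'abundances' must be positive numbers")
  if (!is.numeric(noise) || length(noise) != 1L || noise <= 0)
    stop("'noise' must be a single positive number")
  noise * sqrt(max(abundances) / abundances)
}

#' Viewing geometry for acuity modeling
#'
#' Couples a viewing distance to the image's physical scale so that spatial
#' frequencies in cycles per degree can be mapped to cycles per pixel.
#'
#' @param distance_cm Viewing distance in centimeters (> 0).
#' @param px_per_mm Image scale in pixels per millimeter (> 0).
#' @return An object of class `viewing_geometry` with fields `distance_cm`,
#'   `px_per_mm` and `deg_per_px` (the visual angle subtended by one pixel).
#' @export
viewing_geometry <- function(distance_cm, px_per_mm) {
  if (!is.numeric(distance_cm) || length(distance_cm) != 1L || distance_cm <= 0)
    stop("'distance_cm' must be a single positive number")
  if (!is.numeric(px_per_mm) || length(px_per_mm) != 1L || px_per_mm <= 0)
    stop("'px_per_mm' must be a single positive number")
  px_mm <- 1 / px_per_mm
  deg_per_px <- atan2(px_mm, 10 * distance_cm) * 180 / pi
  structure(
    list(distance_cm = distance_cm, px_per_mm = px_per_mm,
         deg_per_px = deg_per_px),
    class = "viewing_geometry"
  )
}
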