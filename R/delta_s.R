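#' Chromatic RNL distance between cone-catch vectors
#'
#' Receptor-noise-limited chromatic distance (Delta S) between two catch
#' vectors over the observer's chromatic channels, in just-noticeable
#' difference (JND) units. For a trichromat with log catch differences
#' `df_i = log(qa_i / qb_i)` and Weber fractions `w`:
#'
#' `dS^2 = (w1^2 (df2 - df3)^2 + w2^2 (df1 - df3)^2 + w3^2 (df1 - df2)^2) /
#'         ((w1 w2)^2 + (w1 w3)^2 + (w2 w3)^2)`
#'
#' which is the Mahalanobis distance in log-catch space with covariance
#' `diag(w^2)`, taken modulo the achromatic direction (a common scaling of
#' all channels leaves the distance unchanged).
#'
#' @param catch_a,catch_b Strictly positive catch vectors over the chromatic
#'   channels (length 3 for the default observer), or matrices with one row
#'   per observation for vectorized use.
#' @param vs A [visual_system()].
#' @return Non-negative Delta S value(s).
#' @examples
#' vs <- visual_system()
#' delta_s_chromatic(c(0.5, 0.5, 0.5), c(0.55, 0.5, 0.5), vs)
#' @export
delta_s_chromatic <- function(catch_a, catch_b, vs) {
  w <- chromatic_weber(vs)
  fa <- chromatic_log(catch_a, length(w))
  fb <- chromatic_log(catch_b, length(w))
  if (!identical(dim(fa), dim(fb)))
    stop("catch_a and catch_b must have the same shape")
  rnl_delta_s_log(fa - fb, w)
}

chromatic_weber <- function(vs) {
  unname(vs$weber[match(vs$chromatic_channels, vs$channel_names)])
}

chromatic_log <- function(q, nch) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1L)
  if (ncol(q) != nch)
    stop("expected ", nch, " chromatic channels, got ", ncol(q))
  if (any(!is.finite(q)) || any(q <= 0))
    stop("cone catches must be strictly positive and finite")
  log(q)
}

# Delta S from a matrix of log-catch differences (rows = observations).
rnl_delta_s_log <- function(df, w) {
  if (is.null(dim(df))) df <- matrix(df, nrow = 1L)
  if (length(w) != 3L)
    stop("chromatic Delta S is implemented for trichromatic observers")
  num <- w[1]^2 * (df[, 2] - df[, 3])^2 +
    w[2]^2 * (df[, 1] - df[, 3])^2 +
    w[3]^2 * (df[, 1] - df[, 2])^2
  den <- (w[1] * w[2])^2 + (w[1] * w[3])^2 + (w[2] * w[3])^2
  sqrt(num / den)
}

#' Achromatic (luminance) RNL distance
#'
#' Luminance contrast in JND units between two catches of the observer's
#' luminance channel: `|log(qa / qb)| / w_lum` with `w_lum` the luminance
#' channel's Weber fraction.
#'
#' @param catch_a,catch_b Strictly positive luminance-channel catches
#'   (scalars or equal-length vectors).
#' @param vs A [visual_system()].
#' @return Non-negative Delta L value(s).
#' @examples
#' vs <- visual_system()
#' delta_s_luminance(exp(0.05) * 0.5, 0.5, vs)  # exactly 1 JND
#' @export
delta_s_luminance <- function(catch_a, catch_b, vs) {
  if (any(!is.finite(catch_a)) || any(!is.finite(catch_b)) ||
      any(catch_a <= 0) || any(catch_b <= 0))
    stop("cone catches must be strictly positive and finite")
  w <- unname(vs$weber[match(vs$luminance_channel, vs$channel_names)])
  abs(log(catch_a / catch_b)) / w
}

#' Orthonormal chromatic coordinates of the RNL space
#'
#' Returns a 3 x 2 matrix `B` such that `coords = log(q) %*% diag(1/w) %*% B`
#' maps chromatic log catches into a plane where Euclidean distance equals
#' chromatic Delta S. Used by the scene generator to place patch-class means
#' at exact perceptual spacings, and invertible up to the (irrelevant)
#' achromatic component via `log(q) = (B %*% coords) * w`.
#'
#' @param vs A [visual_system()].
#' @return List with `B` (3 x 2 orthonormal basis of the chromatic plane in
#'   whitened log-catch space) and `w` (chromatic Weber fractions).
#' @keywords internal
#' @export
rnl_chromatic_basis <- function(vs) {
  w <- chromatic_weber(vs)
  a <- (1 / w) / sqrt(sum(1 / w^2))  # achromatic direction, whitened space
  B <- qr.Q(qr(cbind(a, diag(3))))[, 2:3, drop = FALSE]
  list(B = B, w = w)
}
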