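#' Cone-catch image container
#'
#' A calibrated multi-channel image of photoreceptor quantum catches: an
#' `H x W x C` array of strictly positive linear catches (channel order
#' sw, mw, lw, dbl for the default observer) with a physical scale in pixels
#' per millimeter and an optional logical background mask.
#'
#' @param catch Numeric `H x W x C` array of strictly positive catches.
#' @param px_per_mm Scale, pixels per millimeter (> 0).
#' @param channels Character vector of channel names, length `C`.
#' @param mask Optional `H x W` logical matrix marking background pixels;
#'   defaults to all `TRUE`.
#' @return An object of class `cone_catch_image`.
#' @export
cone_catch_image <- function(catch, px_per_mm,
                             channels = c("sw", "mw", "lw", "dbl"),
                             mask = NULL) {
  if (!is.array(catch) || length(dim(catch)) != 3L)
    stop("'catch' must be an H x W x C array")
  if (dim(catch)[3] != length(channels))
    stop("third dimension of 'catch' must match 'channels'")
  if (any(!is.finite(catch)) || any(catch <= 0))
    stop("cone catches must be strictly positive and finite")
  if (!is.numeric(px_per_mm) || length(px_per_mm) != 1L || px_per_mm <= 0)
    stop("'px_per_mm' must be a single positive number")
  if (is.null(mask)) {
    mask <- matrix(TRUE, dim(catch)[1], dim(catch)[2])
  } else {
    if (!is.logical(mask) || !identical(dim(mask), dim(catch)[1:2]))
      stop("'mask' must be a logical H x W matrix")
  }
  structure(
    list(catch = catch, px_per_mm = px_per_mm, channels = channels,
         mask = mask),
    class = "cone_catch_image"
  )
}

#' @export
print.cone_catch_image <- function(x, ...) {
  d <- dim(x$catch)
  cat(sprintf("cone-catch image: %d x %d px, %d channels (%s), %.3g px/mm, %d mask px\n",
              d[1], d[2], d[3], paste(x$channels, collapse = ","),
              x$px_per_mm, sum(x$mask)))
  invisible(x)
}

#' @export
dim.cone_catch_image <- function(x) dim(x$catch)

# channel slab as matrix
channel <- function(img, name) {
  img$catch[, , match(name, img$channels)]
}

#' Write / read cone-catch images as multi-page TIFF
#'
#' Images are stored as 32-bit float multi-page TIFF, one page per channel in
#' the container's channel order, with a JSON sidecar (`<file>.json`) holding
#' the scale and channel names. Masks are written as single-page 8-bit
#' TIFF (0/255).
#'
#' @param img A [cone_catch_image()].
#' @param path Output TIFF path; the sidecar is written next to it.
#' @return `write_cone_catch` returns `path` invisibly; `read_cone_catch`
#'   returns a [cone_catch_image()].
#' @export
write_cone_catch <- function(img, path) {
  # float TIFF storage is only well defined on [0,1]; record the scale used
  scale <- max(img$catch)
  pages <- lapply(seq_along(img$channels), function(i) img$catch[, , i] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  side <- list(px_per_mm = img$px_per_mm, channels = img$channels,
               catch_scale = scale)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  mask_path <- sub("\\.tiff?$", "_mask.tif", path)
  tiff::writeTIFF(img$mask * 1, mask_path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_cone_catch
#' @export
read_cone_catch <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  catch <- array(unlist(pages),
                 dim = c(dim(pages[[1]]), length(pages)))
  if (!is.null(side$catch_scale)) catch <- catch * side$catch_scale
  mask_path <- sub("\\.tiff?$", "_mask.tif", path)
  mask <- NULL
  if (file.exists(mask_path)) mask <- tiff::readTIFF(mask_path) > 0.5
  cone_catch_image(catch, side$px_per_mm, side$channels, mask)
}
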