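#' Single-channel fluorescence image
#'
#' A 2D matrix of non-negative intensities with a channel name and pixel
#' size. Pixel coordinates throughout the package are 0-based `(row, col)`.
#'
#' @param pixels numeric matrix, finite and non-negative.
#' @param channel channel name, e.g. `"cd68"` or `"ptdp43"`.
#' @param um_per_px pixel side length in micrometres (> 0).
#' @return A `channel_image` object.
#' @export
channel_image <- function(pixels, channel, um_per_px) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || anyNA(pixels) || any(!is.finite(pixels))) {
    stop("channel_image: pixels must be finite numeric values", call. = FALSE)
  }
  if (any(pixels < 0)) {
    stop("channel_image: pixel intensities must be non-negative", call. = FALSE)
  }
  if (!is.numeric(um_per_px) || length(um_per_px) != 1L || um_per_px <= 0) {
    stop("channel_image: um_per_px must be a single positive number", call. = FALSE)
  }
  structure(
    list(pixels = pixels, channel = as.character(channel),
         um_per_px = um_per_px),
    class = "channel_image"
  )
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %s: %d x %d px, %.3g um/px, range [%.4g, %.4g]\n",
              x$channel, nrow(x$pixels), ncol(x$pixels), x$um_per_px,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Aligned multi-channel image set for one tissue section
#'
#' @param channels named list of `channel_image` objects (or plain matrices,
#'   which will be wrapped), all the same shape.
#' @param roi logical matrix, same shape: the analysed tissue region.
#' @param meta list with at least `case_id`, `group`, and `region` (or
#'   `timepoint` for longitudinal designs).
#' @param um_per_px pixel size, used when `channels` are plain matrices.
#' @return A `multiplex_image_set`.
#' @export
multiplex_image_set <- function(channels, roi, meta, um_per_px = NULL) {
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)))
  channels <- lapply(names(channels), function(nm) {
    ch <- channels[[nm]]
    if (inherits(ch, "channel_image")) ch
    else channel_image(ch, nm, um_per_px %||%
                         stop("um_per_px required for matrix channels"))
  })
  names(channels) <- vapply(channels, `[[`, "", "channel")
  dims <- vapply(channels, function(ch) dim(ch$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("multiplex_image_set: all channels must share dimensions", call. = FALSE)
  }
  roi <- matrix(as.logical(roi), nrow(channels[[1]]$pixels))
  if (!identical(dim(roi), dim(channels[[1]]$pixels))) {
    stop("multiplex_image_set: ROI mask must match channel dimensions", call. = FALSE)
  }
  structure(
    list(channels = channels, roi = roi, meta = meta,
         um_per_px = channels[[1]]$um_per_px),
    class = "multiplex_image_set"
  )
}

#' @export
print.multiplex_image_set <- function(x, ...) {
  cat(sprintf("<multiplex_image_set> case %s (%s, %s): %s; ROI %d px\n",
              x$meta$case_id %||% "?", x$meta$group %||% "?",
              x$meta$region %||% x$meta$timepoint %||% "?",
              paste(names(x$channels), collapse = ", "), sum(x$roi)))
  invisible(x)
}

#' Binary segmentation mask
#'
#' @param mask logical matrix.
#' @param source name of the channel the mask was derived from.
#' @param method one of `"clip"`, `"adaptive"`, `"union"`.
#' @param um_per_px pixel size in micrometres.
#' @return A `binary_mask` carrying `area_px` and `area_um2`.
#' @export
binary_mask <- function(mask, source, method, um_per_px) {
  mask <- matrix(as.logical(mask), nrow(mask))
  method <- match.arg(method, c("clip", "adaptive", "union"))
  area_px <- sum(mask)
  structure(
    list(mask = mask, source = source, method = method,
         um_per_px = um_per_px, area_px = area_px,
         area_um2 = area_px * um_per_px^2),
    class = "binary_mask"
  )
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s (%s): %d px (%.1f um^2) of %d x %d\n",
              x$source, x$method, x$area_px, x$area_um2,
              nrow(x$mask), ncol(x$mask)))
  invisible(x)
}

as_mask_matrix <- function(x) {
  if (inherits(x, "binary_mask")) x$mask else matrix(as.logical(x), nrow(x))
}

as_pixel_matrix <- function(x) {
  if (inherits(x, "channel_image")) x$pixels else as.matrix(x)
}
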