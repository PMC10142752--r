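#' Write a multiplex image set as a multi-page TIFF
#'
#' One 16-bit page per channel, channel name in each page's description
#' tag, plus a sidecar `<path>.channels.csv` mapping page order to channel
#' names and pixel size (the robust path for tools that drop description
#' tags). The ROI is written alongside as `<path>.roi.tif`.
#'
#' @param image_set a [multiplex_image_set()].
#' @param path output TIFF path.
#' @param max_intensity intensity mapped to the top of the 16-bit range.
#' @return `path`, invisibly.
#' @export
write_image_set <- function(image_set, path, max_intensity = 65535) {
  pages <- lapply(image_set$channels, function(ch) {
    img <- pmin(ch$pixels / max_intensity, 1)
    attr(img, "description") <- ch$channel
    img
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  sidecar <- data.frame(page = seq_along(pages),
                        channel = names(image_set$channels),
                        um_per_px = image_set$um_per_px,
                        max_intensity = max_intensity,
                        case_id = image_set$meta$case_id %||% NA,
                        group = image_set$meta$group %||% NA,
                        region = image_set$meta$region %||% NA)
  write.csv(sidecar, paste0(path, ".channels.csv"), row.names = FALSE)
  tiff::writeTIFF(ifelse(image_set$roi, 1, 0), paste0(path, ".roi.tif"),
                  bits.per.sample = 8L)
  invisible(path)
}

#' Read a multiplex image set written by [write_image_set()]
#'
#' @param path TIFF path (expects the sidecar CSV and ROI TIFF alongside).
#' @return A [multiplex_image_set()].
#' @export
read_image_set <- function(path) {
  sidecar <- read.csv(paste0(path, ".channels.csv"))
  pages <- tiff::readTIFF(path, all = TRUE)
  stopifnot(length(pages) == nrow(sidecar))
  channels <- lapply(seq_along(pages), function(i) {
    channel_image(pages[[i]] * sidecar$max_intensity[i],
                  sidecar$channel[i], sidecar$um_per_px[i])
  })
  names(channels) <- sidecar$channel
  roi <- tiff::readTIFF(paste0(path, ".roi.tif")) > 0.5
  multiplex_image_set(channels, roi,
                      meta = list(case_id = sidecar$case_id[1],
                                  group = sidecar$group[1],
                                  region = sidecar$region[1]))
}

#' Write a cell table (or any result table) as CSV
#'
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Read a cell table CSV
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_cell_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Serialise a threshold set to a key-value YAML file
#'
#' @param thresholds named list of `moi_threshold`s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_threshold_set <- function(thresholds, path) {
  yaml::write_yaml(lapply(thresholds, function(t) {
    list(cutoff = t$cutoff, provenance = t$provenance, method = t$method)
  }), path)
  invisible(path)
}

#' Read a threshold set written by [write_threshold_set()]
#'
#' @param path YAML path.
#' @return named list of `moi_threshold`s.
#' @export
read_threshold_set <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(t) {
    structure(list(cutoff = t$cutoff, provenance = t$provenance,
                   method = t$method, diagnostics = NULL),
              class = "moi_threshold")
  })
}
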