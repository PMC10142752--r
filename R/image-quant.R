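#' Fixed-threshold (clip) binary mask
#'
#' Marks pixels strictly above `threshold` — the classic "threshold clip"
#' used to isolate high immunoreactivity for pathology-load masks.
#'
#' @param img a [channel_image()].
#' @param threshold intensity cutoff (>= 0).
#' @return A [binary_mask()] with method `"clip"`.
#' @export
clip_threshold_mask <- function(img, threshold) {
  stopifnot(inherits(img, "channel_image"), threshold >= 0)
  binary_mask(img$pixels > threshold, img$channel, "clip", img$um_per_px)
}

# exact local mean over a (2h+1)-square window, clipped at borders,
# via summed-area tables
local_mean <- function(px, h) {
  nr <- nrow(px); nc <- ncol(px)
  box <- function(m) {
    # (nr+1) x (nc+1) integral image: cs[i+1, j+1] = sum(m[1:i, 1:j])
    cs <- matrix(0, nr + 1L, nc + 1L)
    cs[-1L, -1L] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
    r1 <- pmax(seq_len(nr) - h, 1L); r2 <- pmin(seq_len(nr) + h, nr)
    c1 <- pmax(seq_len(nc) - h, 1L); c2 <- pmin(seq_len(nc) + h, nc)
    cs[r2 + 1L, c2 + 1L, drop = FALSE] - cs[r1, c2 + 1L, drop = FALSE] -
      cs[r2 + 1L, c1, drop = FALSE] + cs[r1, c1, drop = FALSE]
  }
  box(px) / box(matrix(1, nr, nc))
}

#' Adaptive (local-mean) threshold mask
#'
#' Marks pixels exceeding the mean of a square neighbourhood of side
#' `window_um` by more than `offset`. This is the local-background-tracking
#' operator used to segment marker immunolabelling of varying brightness.
#' The default window of 25 um spans a microglial soma plus its proximal
#' domain.
#'
#' @param img a [channel_image()].
#' @param window_um window side in micrometres (> 0, at most the image size).
#' @param offset intensity offset above the local mean.
#' @return A [binary_mask()] with method `"adaptive"`.
#' @export
adaptive_threshold_mask <- function(img, window_um = 25, offset) {
  stopifnot(inherits(img, "channel_image"), window_um > 0)
  w <- max(1L, round(window_um / img$um_per_px))
  if (w > min(dim(img$pixels))) {
    stop("parameter error: adaptive window larger than the image", call. = FALSE)
  }
  h <- w %/% 2L
  lm <- local_mean(img$pixels, h)
  binary_mask(img$pixels > lm + offset, img$channel, "adaptive", img$um_per_px)
}

#' Remove HLA-DR bleed-through from a pTDP-43 image
#'
#' Residual high HLA-DR immunoreactivity from a previous labelling round can
#' cross into the pTDP-43 channel. A high-HLA-DR mask is built with
#' [clip_threshold_mask()] and the corresponding pTDP-43 pixels are zeroed
#' (a mask subtraction, not an arithmetic one).
#'
#' @param ptdp_img,hla_img [channel_image()]s of identical shape.
#' @param clip_threshold intensity defining "high" HLA-DR.
#' @return The corrected pTDP-43 [channel_image()].
#' @export
subtract_bleedthrough <- function(ptdp_img, hla_img, clip_threshold) {
  stopifnot(inherits(ptdp_img, "channel_image"),
            inherits(hla_img, "channel_image"))
  if (!identical(dim(ptdp_img$pixels), dim(hla_img$pixels))) {
    stop("input error: pTDP-43 and HLA-DR images differ in shape", call. = FALSE)
  }
  m <- clip_threshold_mask(hla_img, clip_threshold)
  px <- ptdp_img$pixels
  px[m$mask] <- 0
  channel_image(px, ptdp_img$channel, ptdp_img$um_per_px)
}

#' Pixelwise union of binary masks ("master mask")
#'
#' Combines per-marker masks into the master mask whose connected components
#' are treated as cells. For the human arm the inputs are the Iba1, HLA-DR,
#' CD68 and CD74 masks; for the mouse arm a single Iba1 mask suffices.
#'
#' @param masks list of [binary_mask()]s (or one or more masks as `...`),
#'   all the same shape.
#' @return A [binary_mask()] with method `"union"`.
#' @export
master_mask <- function(masks, ...) {
  if (inherits(masks, "binary_mask")) masks <- c(list(masks), list(...))
  stopifnot(length(masks) >= 1L)
  dims <- lapply(masks, function(m) dim(as_mask_matrix(m)))
  if (length(unique(dims)) != 1L) {
    stop("input error: masks differ in shape", call. = FALSE)
  }
  u <- Reduce(`|`, lapply(masks, as_mask_matrix))
  um <- if (inherits(masks[[1]], "binary_mask")) masks[[1]]$um_per_px else 1
  src <- paste(unique(vapply(masks, function(m) {
    if (inherits(m, "binary_mask")) m$source else "mask"
  }, "")), collapse = "+")
  binary_mask(u, src, "union", um)
}

# 8-connectivity connected components of a logical matrix, labelled in
# row-major order of each component's first pixel. Returns an integer
# matrix (0 = background).
label_components8 <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  idx <- which(fg)
  labels <- matrix(0L, nr, nc)
  if (length(idx) == 0L) return(labels)
  edge_pairs <- function(dr, dc) {
    rows_ok <- if (dr >= 0) seq_len(nr - dr) else seq(1 - dr, nr)
    cols_ok <- seq_len(nc - dc)
    sub <- fg[rows_ok, cols_ok, drop = FALSE] &
      fg[rows_ok + dr, cols_ok + dc, drop = FALSE]
    w <- which(sub)
    if (!length(w)) return(NULL)
    r <- ((w - 1L) %% length(rows_ok)) + rows_ok[1]
    c <- ((w - 1L) %/% length(rows_ok)) + 1L
    from <- r + (c - 1L) * nr
    to <- (r + dr) + (c + dc - 1L) * nr
    cbind(from, to)
  }
  edges <- do.call(rbind, Filter(Negate(is.null), list(
    edge_pairs(1L, 0L),   # S
    edge_pairs(0L, 1L),   # E
    edge_pairs(1L, 1L),   # SE
    edge_pairs(-1L, 1L)   # NE
  )))
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges)) {
    g <- igraph::add_edges(g, rbind(match(edges[, 1], idx),
                                    match(edges[, 2], idx)))
  }
  comp <- igraph::components(g)$membership
  # relabel so component ids follow the row-major position of first pixels
  first_pix <- tapply(idx, comp, min)
  relabel <- integer(length(first_pix))
  relabel[order(first_pix)] <- seq_along(first_pix)
  labels[idx] <- relabel[comp]
  labels
}

#' Identify cells as connected components of a mask
#'
#' Components (8-connectivity) of `mask` restricted to the ROI; components
#' smaller than `min_area_px` are discarded (soma fragments). Objects
#' touching the ROI border are kept. Centroids are 0-based `(row, col)`
#' pixel coordinates.
#'
#' @param mask a [binary_mask()] or logical matrix.
#' @param roi logical matrix (defaults to the full field).
#' @param min_area_px minimum object area in pixels (>= 1); the default of
#'   20 px excludes fragments below ~5 um^2 at 0.5 um/px.
#' @return list with `labels` (integer matrix, 0 = background) and
#'   `objects` (data.frame: `id`, `row`, `col`, `area_px`).
#' @export
label_objects <- function(mask, roi = NULL, min_area_px = 20L) {
  stopifnot(min_area_px >= 1L)
  m <- as_mask_matrix(mask)
  if (!is.null(roi)) {
    roi <- as_mask_matrix(roi)
    if (!identical(dim(roi), dim(m))) {
      stop("input error: ROI shape differs from mask", call. = FALSE)
    }
    m <- m & roi
  }
  labels <- label_components8(m)
  if (!any(labels > 0L)) {
    return(list(labels = labels,
                objects = data.frame(id = integer(0), row = numeric(0),
                                     col = numeric(0), area_px = integer(0))))
  }
  idx <- which(labels > 0L)
  lab <- labels[idx]
  area <- tabulate(lab)
  keep <- which(area >= min_area_px)
  if (length(keep) == 0L) {
    labels[] <- 0L
    return(list(labels = labels,
                objects = data.frame(id = integer(0), row = numeric(0),
                                     col = numeric(0), area_px = integer(0))))
  }
  relabel <- integer(length(area))
  relabel[keep] <- seq_along(keep)
  labels[idx] <- relabel[lab]
  idx <- which(labels > 0L)
  lab <- labels[idx]
  nr <- nrow(m)
  rows0 <- ((idx - 1L) %% nr)        # 0-based row
  cols0 <- ((idx - 1L) %/% nr)       # 0-based col
  objects <- data.frame(
    id = seq_along(keep),
    row = as.numeric(tapply(rows0, lab, mean)),
    col = as.numeric(tapply(cols0, lab, mean)),
    area_px = as.integer(tabulate(lab))
  )
  list(labels = labels, objects = objects)
}

#' Measure per-cell mean marker intensities
#'
#' For every labelled object, the mean pixel intensity of each requested
#' marker over the object's pixels — with uniform labelling this is
#' proportional to the protein concentration per cell. Case metadata is
#' copied from the image set.
#'
#' @param labelled result of [label_objects()].
#' @param image_set a [multiplex_image_set()] of the same shape.
#' @param markers channels to measure (default the five functional markers).
#' @return data.frame: `cell_id`, `case_id`, `group`, `region`, `row`,
#'   `col`, `area_px`, one column per marker.
#' @export
measure_cells <- function(labelled, image_set,
                          markers = GLIAMUX_MARKERS) {
  stopifnot(inherits(image_set, "multiplex_image_set"))
  missing_m <- setdiff(markers, names(image_set$channels))
  if (length(missing_m)) {
    stop(sprintf("input error: marker(s) %s absent from image set",
                 paste(missing_m, collapse = ", ")), call. = FALSE)
  }
  labels <- labelled$labels
  if (!identical(dim(labels), dim(image_set$roi))) {
    stop("input error: labels and channels differ in shape", call. = FALSE)
  }
  obj <- labelled$objects
  meta <- image_set$meta
  out <- data.frame(
    cell_id = if (nrow(obj)) sprintf("%s_c%05d", meta$case_id, obj$id)
              else character(0),
    case_id = rep(meta$case_id %||% NA_character_, nrow(obj)),
    group = rep(meta$group %||% NA_character_, nrow(obj)),
    region = rep(meta$region %||% meta$timepoint %||% NA_character_,
                 nrow(obj)),
    row = obj$row, col = obj$col, area_px = obj$area_px
  )
  idx <- which(labels > 0L)
  lab <- labels[idx]
  for (m in markers) {
    px <- image_set$channels[[m]]$pixels[idx]
    means <- as.numeric(tapply(px, lab, mean))
    out[[m]] <- if (nrow(obj)) means else numeric(0)
  }
  out
}

roi_area_um2 <- function(roi, um_per_px) {
  n <- sum(as_mask_matrix(roi))
  if (n == 0L) stop("input error: ROI is empty", call. = FALSE)
  n * um_per_px^2
}

#' Integrated-intensity pathology load
#'
#' Sum of pixel intensities over `mask` within the ROI, normalised to the
#' ROI area in um^2 — the pTDP-43 "load" measure.
#'
#' @param img a [channel_image()].
#' @param mask a [binary_mask()] (high-immunoreactivity mask).
#' @param roi logical ROI matrix.
#' @return Intensity per um^2 (scalar).
#' @export
pathology_load <- function(img, mask, roi) {
  stopifnot(inherits(img, "channel_image"))
  m <- as_mask_matrix(mask); r <- as_mask_matrix(roi)
  if (!identical(dim(img$pixels), dim(m)) || !identical(dim(m), dim(r))) {
    stop("input error: image, mask and ROI must share shape", call. = FALSE)
  }
  sum(img$pixels[m & r]) / roi_area_um2(r, img$um_per_px)
}

#' Mask-area load (area fraction)
#'
#' Area of `mask` within the ROI divided by the ROI area — e.g. the GFAP
#' astrogliosis measure. Dimensionless, in `[0, 1]`.
#'
#' @param mask a [binary_mask()] or logical matrix.
#' @param roi logical ROI matrix.
#' @return Fraction in `[0, 1]`.
#' @export
area_load <- function(mask, roi) {
  m <- as_mask_matrix(mask); r <- as_mask_matrix(roi)
  if (!identical(dim(m), dim(r))) {
    stop("input error: mask and ROI must share shape", call. = FALSE)
  }
  if (sum(r) == 0L) stop("input error: ROI is empty", call. = FALSE)
  sum(m & r) / sum(r)
}

#' Cell density in cells per mm^2
#'
#' @param cells data.frame of cells (one row per cell) or an integer count.
#' @param roi logical ROI matrix.
#' @param um_per_px pixel size in micrometres.
#' @return Cells per mm^2.
#' @export
cell_density <- function(cells, roi, um_per_px) {
  n <- if (is.data.frame(cells)) nrow(cells) else as.integer(cells)
  area_mm2 <- roi_area_um2(roi, um_per_px) / 1e6
  n / area_mm2
}

#' Tissue-wide marker intensity
#'
#' Integrated marker intensity over the master mask (within the ROI),
#' normalised to the ROI area (`normalise = "roi"`, default) or to the
#' master-mask area (`normalise = "mask"`). Both normalisations are
#' legitimate bulk-expression measures; they differ by the mask area
#' fraction, so comparisons between groups must fix one.
#'
#' @param img a [channel_image()].
#' @param master a [binary_mask()] (typically the union master mask).
#' @param roi logical ROI matrix.
#' @param normalise `"roi"` or `"mask"`.
#' @return Intensity per um^2.
#' @export
tissue_wide_intensity <- function(img, master, roi,
                                  normalise = c("roi", "mask")) {
  normalise <- match.arg(normalise)
  stopifnot(inherits(img, "channel_image"))
  m <- as_mask_matrix(master); r <- as_mask_matrix(roi)
  if (!identical(dim(img$pixels), dim(m)) || !identical(dim(m), dim(r))) {
    stop("input error: image, mask and ROI must share shape", call. = FALSE)
  }
  tot <- sum(img$pixels[m & r])
  denom <- if (normalise == "roi") {
    roi_area_um2(r, img$um_per_px)
  } else {
    a <- sum(m & r) * img$um_per_px^2
    if (a == 0) return(0)
    a
  }
  tot / denom
}

#' Quantify one multiplex image set end to end
#'
#' Builds per-marker masks (clip thresholds), the master mask (human arm:
#' Iba1 + HLA-DR + CD68 + CD74; mouse arm: Iba1 only), labels cells,
#' measures the five markers per cell, and computes the tissue-wide
#' load measures (pTDP-43 load after optional HLA-DR bleed correction,
#' GFAP area load, cell density, tissue-wide marker intensities).
#'
#' @param image_set a [multiplex_image_set()].
#' @param clip_thresholds named intensity cutoffs per channel; must cover
#'   the mask channels in use plus `ptdp43` and `gfap` when present.
#' @param arm `"human"` (master mask) or `"mouse"` (Iba1 mask only).
#' @param min_area_px minimum object area, see [label_objects()].
#' @param bleed_clip_threshold when non-`NULL`, HLA-DR bleed-through is
#'   removed from the pTDP-43 channel at this clip threshold first.
#' @param normalise normalisation for [tissue_wide_intensity()].
#' @return list with `cells` (data.frame), `loads` (one-row data.frame),
#'   `labels`, and `master` mask.
#' @export
quantify_image_set <- function(image_set, clip_thresholds,
                               arm = c("human", "mouse"),
                               min_area_px = 20L,
                               bleed_clip_threshold = NULL,
                               normalise = "roi") {
  arm <- match.arg(arm)
  mask_markers <- if (arm == "human") MASTER_MASK_MARKERS else "iba1"
  masks <- lapply(mask_markers, function(m) {
    clip_threshold_mask(image_set$channels[[m]], clip_thresholds[[m]])
  })
  master <- master_mask(masks)
  labelled <- label_objects(master, image_set$roi, min_area_px)
  cells <- measure_cells(labelled, image_set)
  roi <- image_set$roi
  up <- image_set$um_per_px
  loads <- data.frame(case_id = image_set$meta$case_id %||% NA_character_,
                      group = image_set$meta$group %||% NA_character_,
                      region = image_set$meta$region %||% NA_character_)
  loads$cell_density <- cell_density(cells, roi, up)
  loads$master_area_fraction <- area_load(master, roi)
  if ("ptdp43" %in% names(image_set$channels)) {
    pt <- image_set$channels$ptdp43
    if (!is.null(bleed_clip_threshold)) {
      pt <- subtract_bleedthrough(pt, image_set$channels$hladr,
                                  bleed_clip_threshold)
    }
    pt_mask <- clip_threshold_mask(pt, clip_thresholds[["ptdp43"]])
    loads$ptdp_load <- pathology_load(pt, pt_mask, roi)
  }
  if ("gfap" %in% names(image_set$channels)) {
    gf_mask <- clip_threshold_mask(image_set$channels$gfap,
                                   clip_thresholds[["gfap"]])
    loads$gfap_load <- area_load(gf_mask, roi)
  }
  for (m in GLIAMUX_MARKERS) {
    loads[[paste0("tw_", m)]] <- tissue_wide_intensity(
      image_set$channels[[m]], master, roi, normalise)
  }
  list(cells = cells, loads = loads, labels = labelled, master = master)
}
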