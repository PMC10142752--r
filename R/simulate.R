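#' Named microglial phenotype presets
#'
#' A phenotype is a binary high/low assignment over the five functional
#' markers; each preset names the markers that are *high*. The presets
#' mirror the recurring cluster phenotypes of reactive human microglia:
#' a homeostatic Iba1-only state, a pan-low state, phagocytic CD68-high
#' states with or without L-ferritin co-elevation, an L-ferritin-high /
#' CD74-low state, and an antigen-presenting HLA-DR/CD74-high state.
#'
#' @return Named list of character vectors (markers scored high).
#' @export
phenotype_presets <- function() {
  list(
    homeostatic         = "iba1",
    pan_low             = character(0),
    cd68_high           = c("cd68", "iba1"),
    lferritin_cd68_high = c("lferritin", "cd68", "iba1"),
    lferritin_cd74_low  = c("lferritin", "iba1"),
    hladr_cd74_high     = c("hladr", "cd74", "iba1")
  )
}

#' Default log-normal intensity parameters
#'
#' Per-cell marker intensities are log-normal: right-skewed and strictly
#' positive, matching single-cell immunofluorescence density curves. Low and
#' high modes are separated by 6 log-sd by default (1.5 natural-log units at
#' sdlog 0.25), comfortably above the 4 log-sd separation at which high/low
#' gating is reliable. The absolute scale (low mode ~60 on a 16-bit range)
#' is arbitrary and fully config-exposed.
#'
#' @return data.frame with columns marker, meanlog_low, meanlog_high, sdlog.
#' @export
default_intensity_params <- function() {
  data.frame(
    marker = GLIAMUX_MARKERS,
    meanlog_low = log(60),
    meanlog_high = log(60) + 1.5,
    sdlog = 0.25
  )
}

#' Default image-rendering parameters
#'
#' Somata are rendered as non-overlapping uniform disks; astrocytes appear
#' only in the GFAP and L-ferritin channels; pTDP-43 aggregates are small
#' high-intensity blobs. Intensities sit on a 16-bit scale at 0.5 um/px.
#'
#' @return Named list of rendering parameters.
#' @export
default_image_params <- function() {
  list(
    width_px = 1024, height_px = 1024, um_per_px = 0.5,
    soma_radius_um = 5, min_cell_area_px = 20,
    background_mean = 20, noise_sd = 5,
    n_astrocytes = 15, astro_radius_um = 7,
    aggregate_count_per_case = 150, aggregate_intensity = 3000,
    aggregate_radius_um = 1.5,
    bleedthrough_coefficient = 0,
    roi_margin_px = 8, min_separation_px = 4,
    max_intensity = 65535
  )
}

default_groups <- function(n_cases = 10) {
  g <- expand.grid(group = c("control", "disease"),
                   region = c("motor_cortex", "hippocampus"),
                   stringsAsFactors = FALSE)
  g$n_cases <- n_cases
  g
}

default_phenotype_fractions <- function() {
  ctrl <- c(homeostatic = 0.60, pan_low = 0.20, hladr_cd74_high = 0.12,
            cd68_high = 0.05, lferritin_cd68_high = 0.03)
  dis_mc <- c(homeostatic = 0.35, pan_low = 0.10, hladr_cd74_high = 0.12,
              cd68_high = 0.25, lferritin_cd68_high = 0.18)
  list(
    control = ctrl,
    disease.motor_cortex = dis_mc,
    disease.hippocampus = ctrl
  )
}

#' Build and validate a simulation configuration
#'
#' Defines the synthetic cohort: the case groups, the phenotype mixture per
#' group (the disease effect is a shift in mixture *fractions*, i.e. in the
#' number of high-expressing cells, not in the component means), the
#' log-normal intensity parameters per marker, and image-rendering
#' parameters. Per-case biological variability is introduced by jittering
#' the mixture fractions on the log scale (`case_fraction_sd`), and in
#' disease cases the expected pTDP-43 aggregate count scales with the case's
#' realised CD68-high fraction, so aggregate load and %CD68-high are
#' co-planted across cases. Control cases carry no aggregates.
#'
#' @param groups data.frame with columns `group` (`"control"`/`"disease"`),
#'   `region` (or `timepoint`), `n_cases`.
#' @param cells_per_case cells simulated per case (>= 1).
#' @param phenotype_fractions named list of named numeric vectors; keys are
#'   `"group"` or `"group.region"` (the more specific key wins). Each vector
#'   must sum to 1 within 1e-9.
#' @param phenotypes named list mapping phenotype name to the markers scored
#'   high; defaults to [phenotype_presets()].
#' @param intensity_params data.frame as in [default_intensity_params()].
#' @param case_fraction_sd log-scale sd of the per-case mixture jitter.
#' @param severity_sd log-scale sd of the per-disease-case severity latent
#'   that jointly scales the CD68-linked phenotype fractions and the
#'   expected aggregate count (0 disables it).
#' @param image_params list as in [default_image_params()].
#' @param seed default seed used when the generator is called without one.
#' @return A validated `simulation_config`.
#' @export
simulation_config <- function(groups = default_groups(),
                              cells_per_case = 4000,
                              phenotype_fractions = default_phenotype_fractions(),
                              phenotypes = phenotype_presets(),
                              intensity_params = default_intensity_params(),
                              case_fraction_sd = 0.2,
                              severity_sd = 0.35,
                              image_params = default_image_params(),
                              seed = 1L) {
  stopifnot(is.data.frame(groups), all(c("group", "n_cases") %in% names(groups)))
  if (!"region" %in% names(groups) && "timepoint" %in% names(groups)) {
    groups$region <- as.character(groups$timepoint)
  }
  if (cells_per_case < 1) {
    stop("configuration error: cells_per_case must be >= 1", call. = FALSE)
  }
  for (key in names(phenotype_fractions)) {
    fr <- phenotype_fractions[[key]]
    if (abs(sum(fr) - 1) > 1e-9) {
      stop(sprintf(
        "configuration error: phenotype fractions for '%s' sum to %.12g, not 1",
        key, sum(fr)), call. = FALSE)
    }
    if (any(fr < 0)) {
      stop(sprintf("configuration error: negative fraction in '%s'", key),
           call. = FALSE)
    }
    unknown <- setdiff(names(fr), names(phenotypes))
    if (length(unknown)) {
      stop(sprintf("configuration error: unknown phenotype(s) %s in '%s'",
                   paste(unknown, collapse = ", "), key), call. = FALSE)
    }
  }
  stopifnot(all(GLIAMUX_MARKERS %in% intensity_params$marker))
  if (any(!is.finite(as.matrix(intensity_params[, -1]))) ||
      any(intensity_params$sdlog <= 0)) {
    stop("configuration error: intensity params must be finite with sdlog > 0",
         call. = FALSE)
  }
  ip <- utils::modifyList(default_image_params(), image_params)
  if (ip$um_per_px <= 0) {
    stop("configuration error: um_per_px must be > 0", call. = FALSE)
  }
  structure(
    list(groups = groups, cells_per_case = cells_per_case,
         phenotype_fractions = phenotype_fractions, phenotypes = phenotypes,
         intensity_params = intensity_params,
         case_fraction_sd = case_fraction_sd, severity_sd = severity_sd,
         image_params = ip, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

fractions_for <- function(config, group, region) {
  key <- paste(group, region, sep = ".")
  fr <- config$phenotype_fractions[[key]] %||%
    config$phenotype_fractions[[group]]
  if (is.null(fr)) {
    stop(sprintf("configuration error: no phenotype fractions for '%s'", key),
         call. = FALSE)
  }
  fr
}

case_frame <- function(config) {
  g <- config$groups
  out <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    data.frame(case_id = sprintf("%s_%s_%02d", g$group[i], g$region[i],
                                 seq_len(g$n_cases[i])),
               group = g$group[i], region = g$region[i])
  }))
  rownames(out) <- NULL
  out
}

# Per-case realised mixture: log-normal jitter of the group fractions,
# renormalised. Returns a named numeric summing to 1.
jitter_fractions <- function(fr, sdlog) {
  f <- fr * exp(rnorm(length(fr), 0, sdlog))
  f / sum(f)
}

# Disease cases carry a latent severity multiplier on the CD68-linked
# phenotype fractions; the same latent drives the aggregate burden, so
# %CD68-high and pTDP-43 load are co-planted across cases (disease cases
# span a wide severity range, from mildly to heavily affected).
apply_severity <- function(fr, phenotypes, severity) {
  linked <- vapply(phenotypes[names(fr)],
                   function(hm) "cd68" %in% hm, logical(1))
  f <- fr
  f[linked] <- f[linked] * severity
  f / sum(f)
}

aggregate_pixel_area <- function(ip) {
  r <- ip$aggregate_radius_um / ip$um_per_px
  nrow(disk_offsets(r))
}

roi_area_um2_for <- function(ip) {
  m <- ip$roi_margin_px
  (ip$width_px - 2 * m) * (ip$height_px - 2 * m) * ip$um_per_px^2
}

# Draw one case worth of cells. Returns list(cells, phenotype, fractions,
# n_aggregates, true_ptdp_load).
draw_case <- function(config, case_id, group, region) {
  fr0 <- fractions_for(config, group, region)
  if (group == "disease" && config$severity_sd > 0) {
    severity <- rlnorm(1, 0, config$severity_sd)
    fr0 <- apply_severity(fr0, config$phenotypes, severity)
  }
  fr <- jitter_fractions(fr0, config$case_fraction_sd)
  n <- config$cells_per_case
  phen <- sample(names(fr), n, replace = TRUE, prob = fr)
  ipar <- config$intensity_params
  cells <- data.frame(cell_id = sprintf("%s_c%05d", case_id, seq_len(n)),
                      case_id = case_id, group = group, region = region)
  for (m in GLIAMUX_MARKERS) {
    row <- ipar[ipar$marker == m, ]
    is_high <- vapply(config$phenotypes[phen],
                      function(hm) m %in% hm, logical(1))
    cells[[m]] <- rlnorm(n, ifelse(is_high, row$meanlog_high, row$meanlog_low),
                         row$sdlog)
  }
  ip <- config$image_params
  if (group == "disease") {
    # aggregate burden scales with the case's realised CD68-high fraction;
    # aggregate_count_per_case is the expected count at a reference
    # fraction of 0.4 (a heavily affected field)
    cd68_frac <- mean(vapply(config$phenotypes[phen],
                             function(hm) "cd68" %in% hm, logical(1)))
    n_agg <- rpois(1, ip$aggregate_count_per_case * cd68_frac / 0.4)
  } else {
    n_agg <- 0L
  }
  true_load <- n_agg * ip$aggregate_intensity * aggregate_pixel_area(ip) /
    roi_area_um2_for(ip)
  list(cells = cells, phenotype = phen, fractions = fr,
       n_aggregates = n_agg, true_ptdp_load = true_load)
}

truth_case_summary <- function(config, case_id, group, region, drawn,
                               gfap_area_fraction = NA_real_) {
  high_frac <- vapply(GLIAMUX_MARKERS, function(m) {
    mean(vapply(config$phenotypes[drawn$phenotype],
                function(hm) m %in% hm, logical(1)))
  }, numeric(1))
  out <- data.frame(case_id = case_id, group = group, region = region,
                    n_cells = length(drawn$phenotype),
                    n_aggregates = drawn$n_aggregates,
                    true_ptdp_load = drawn$true_ptdp_load,
                    true_gfap_area_fraction = gfap_area_fraction)
  for (m in GLIAMUX_MARKERS) {
    out[[paste0("true_frac_", m, "_high")]] <- high_frac[[m]]
  }
  out
}

#' Generate a ground-truthed synthetic single-cell table
#'
#' One row per cell, with per-cell intensities of the five markers drawn
#' from phenotype-specific log-normals and phenotypes assigned by the
#' group's (case-jittered) mixture fractions. Identical `(config, seed)`
#' reproduces the table bit for bit.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return list with `cells` (data.frame) and `truth` (a
#'   `simulation_truth`: per-cell planted phenotypes and per-case planted
#'   MOI-high fractions, aggregate loads, and counts).
#' @export
generate_cell_table <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  cf <- case_frame(config)
  cells_l <- vector("list", nrow(cf))
  truth_cells_l <- vector("list", nrow(cf))
  truth_case_l <- vector("list", nrow(cf))
  for (i in seq_len(nrow(cf))) {
    d <- draw_case(config, cf$case_id[i], cf$group[i], cf$region[i])
    cells_l[[i]] <- d$cells
    truth_cells_l[[i]] <- data.frame(cell_id = d$cells$cell_id,
                                     phenotype = d$phenotype)
    truth_case_l[[i]] <- truth_case_summary(config, cf$case_id[i],
                                            cf$group[i], cf$region[i], d)
  }
  truth <- structure(
    list(cells = do.call(rbind, truth_cells_l),
         cases = do.call(rbind, truth_case_l),
         seed = seed),
    class = "simulation_truth"
  )
  list(cells = do.call(rbind, cells_l), truth = truth)
}

# integer pixel offsets of a disk of radius r (px) centred at (0, 0)
disk_offsets <- function(r) {
  s <- ceiling(r)
  g <- expand.grid(dr = -s:s, dc = -s:s)
  g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
}

# Rejection-sample n disk centres with pairwise centre distance >= min_dist,
# inside [lo, hi] (rows) x [lo2, hi2] (cols). Errors when overcrowded.
place_disks <- function(n, row_range, col_range, min_dist,
                        avoid = NULL, avoid_dist = 0, what = "somata") {
  if (n == 0L) return(cbind(row = numeric(0), col = numeric(0)))
  rows <- numeric(n); cols <- numeric(n); placed <- 0L
  attempts <- 0L; max_attempts <- 400L * n
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop(sprintf("placement error: could not place non-overlapping %s (field overcrowded)",
                   what), call. = FALSE)
    }
    r <- runif(1, row_range[1], row_range[2])
    c <- runif(1, col_range[1], col_range[2])
    ok <- TRUE
    if (placed > 0L) {
      ok <- all((rows[seq_len(placed)] - r)^2 +
                  (cols[seq_len(placed)] - c)^2 >= min_dist^2)
    }
    if (ok && !is.null(avoid) && nrow(avoid) > 0L) {
      ok <- all((avoid[, 1] - r)^2 + (avoid[, 2] - c)^2 >= avoid_dist^2)
    }
    if (ok) {
      placed <- placed + 1L
      rows[placed] <- r; cols[placed] <- c
    }
  }
  cbind(row = round(rows), col = round(cols))
}

paint_disks <- function(canvas, centres, offsets, values) {
  nr <- nrow(canvas)
  for (i in seq_len(nrow(centres))) {
    idx <- (centres[i, 1] + offsets$dr) + (centres[i, 2] + offsets$dc - 1L) * nr
    canvas[idx] <- values[i]
  }
  canvas
}

#' Render ground-truthed multi-channel tissue images
#'
#' For every case in the configuration, renders one field: microglial somata
#' as non-overlapping uniform disks carrying that cell's marker intensities
#' in the five marker channels; astrocytes in the GFAP and L-ferritin
#' channels only; pTDP-43 aggregates as small high-intensity blobs (disease
#' cases only, count co-planted with the case's CD68-high fraction);
#' Gaussian background noise everywhere; and optional HLA-DR bleed-through
#' added into the pTDP-43 channel. The ROI covers the field minus a margin,
#' and all objects are placed wholly inside it.
#'
#' @param config a [simulation_config()]; `cells_per_case` and
#'   `image_params` must be compatible (total soma area at most 50% of the
#'   ROI, else a placement error is raised).
#' @param seed integer seed; defaults to `config$seed`.
#' @return list with `images` (list of [multiplex_image_set] objects, one
#'   per case) and `truth` (a `simulation_truth` whose `cells` table also
#'   records planted centroids and intensities).
#' @export
generate_image_set <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  ip <- config$image_params
  r_px <- ip$soma_radius_um / ip$um_per_px
  soma_area <- nrow(disk_offsets(r_px))
  roi_area_px <- (ip$width_px - 2 * ip$roi_margin_px) *
    (ip$height_px - 2 * ip$roi_margin_px)
  if (config$cells_per_case * soma_area > 0.5 * roi_area_px) {
    stop(sprintf(
      "placement error: %d somata x %d px exceeds 50%% of the %d-px ROI (overcrowded)",
      config$cells_per_case, soma_area, roi_area_px), call. = FALSE)
  }
  set.seed(seed)
  cf <- case_frame(config)
  images <- vector("list", nrow(cf))
  truth_cells_l <- vector("list", nrow(cf))
  truth_case_l <- vector("list", nrow(cf))
  soma_off <- disk_offsets(r_px)
  astro_off <- disk_offsets(ip$astro_radius_um / ip$um_per_px)
  agg_off <- disk_offsets(ip$aggregate_radius_um / ip$um_per_px)
  margin <- ip$roi_margin_px
  roi <- matrix(FALSE, ip$height_px, ip$width_px)
  roi[(margin + 1):(ip$height_px - margin),
      (margin + 1):(ip$width_px - margin)] <- TRUE
  roi_um2 <- sum(roi) * ip$um_per_px^2
  for (i in seq_len(nrow(cf))) {
    d <- draw_case(config, cf$case_id[i], cf$group[i], cf$region[i])
    n <- nrow(d$cells)
    pad <- ceiling(r_px) + 1
    centres <- place_disks(n, c(margin + pad, ip$height_px - margin - pad),
                           c(margin + pad, ip$width_px - margin - pad),
                           min_dist = 2 * r_px + ip$min_separation_px)
    apad <- ceiling(ip$astro_radius_um / ip$um_per_px) + 1
    astro <- place_disks(ip$n_astrocytes,
                         c(margin + apad, ip$height_px - margin - apad),
                         c(margin + apad, ip$width_px - margin - apad),
                         min_dist = 2 * apad + ip$min_separation_px,
                         avoid = centres,
                         avoid_dist = r_px + apad + ip$min_separation_px,
                         what = "astrocytes")
    gpad <- ceiling(ip$aggregate_radius_um / ip$um_per_px) + 1
    aggs <- place_disks(d$n_aggregates,
                        c(margin + gpad, ip$height_px - margin - gpad),
                        c(margin + gpad, ip$width_px - margin - gpad),
                        min_dist = 2 * gpad + ip$min_separation_px,
                        avoid = rbind(centres, astro),
                        avoid_dist = max(r_px, apad) + gpad +
                          ip$min_separation_px, what = "aggregates")
    dims <- c(ip$height_px, ip$width_px)
    noise <- function() {
      if (ip$noise_sd > 0) matrix(rnorm(prod(dims), 0, ip$noise_sd), dims[1])
      else matrix(0, dims[1], dims[2])
    }
    # astrocyte L-ferritin / GFAP intensities: high-mode log-normals
    ipar <- config$intensity_params
    lf <- ipar[ipar$marker == "lferritin", ]
    astro_lf <- rlnorm(nrow(astro), lf$meanlog_high, lf$sdlog)
    astro_gfap <- rlnorm(nrow(astro), lf$meanlog_high, lf$sdlog)
    channels <- list()
    for (m in GLIAMUX_MARKERS) {
      sig <- matrix(0, dims[1], dims[2])
      sig <- paint_disks(sig, centres, soma_off, d$cells[[m]])
      if (m == "lferritin" && nrow(astro) > 0) {
        sig <- paint_disks(sig, astro, astro_off, astro_lf)
      }
      px <- ifelse(sig > 0, sig, ip$background_mean) + noise()
      channels[[m]] <- pmin(pmax(px, 0), ip$max_intensity)
    }
    gf <- matrix(0, dims[1], dims[2])
    if (nrow(astro) > 0) gf <- paint_disks(gf, astro, astro_off, astro_gfap)
    gfap_area_frac <- sum(gf > 0 & roi) / sum(roi)
    channels$gfap <- pmin(pmax(ifelse(gf > 0, gf, ip$background_mean) + noise(),
                               0), ip$max_intensity)
    pt_sig <- matrix(0, dims[1], dims[2])
    if (nrow(aggs) > 0) {
      pt_sig <- paint_disks(pt_sig, aggs, agg_off,
                            rep(ip$aggregate_intensity, nrow(aggs)))
    }
    true_load <- sum(pt_sig[roi]) / roi_um2
    pt <- ifelse(pt_sig > 0, pt_sig, ip$background_mean)
    if (ip$bleedthrough_coefficient > 0) {
      hla_sig <- matrix(0, dims[1], dims[2])
      hla_sig <- paint_disks(hla_sig, centres, soma_off, d$cells$hladr)
      pt <- pt + ip$bleedthrough_coefficient * hla_sig
    }
    channels$ptdp43 <- pmin(pmax(pt + noise(), 0), ip$max_intensity)
    images[[i]] <- multiplex_image_set(
      channels, roi,
      meta = list(case_id = cf$case_id[i], group = cf$group[i],
                  region = cf$region[i]),
      um_per_px = ip$um_per_px
    )
    d$true_ptdp_load <- true_load
    tc <- data.frame(d$cells["cell_id"], phenotype = d$phenotype,
                     row = centres[, 1] - 1L, col = centres[, 2] - 1L)
    for (m in GLIAMUX_MARKERS) tc[[paste0("planted_", m)]] <- d$cells[[m]]
    truth_cells_l[[i]] <- tc
    truth_case_l[[i]] <- truth_case_summary(config, cf$case_id[i],
                                            cf$group[i], cf$region[i], d,
                                            gfap_area_fraction = gfap_area_frac)
  }
  names(images) <- cf$case_id
  truth <- structure(
    list(cells = do.call(rbind, truth_cells_l),
         cases = do.call(rbind, truth_case_l),
         seed = seed),
    class = "simulation_truth"
  )
  list(images = images, truth = truth)
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf("<simulation_truth> %d cells across %d cases (seed %d)\n",
              nrow(x$cells), nrow(x$cases), x$seed))
  invisible(x)
}
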