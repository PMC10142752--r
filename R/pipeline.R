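#' Default pipeline configuration
#'
#' A flat list with one section per stage. `simulate` holds the
#' [simulation_config()] arguments; `phenotype` the thresholding method;
#' `cluster` the embedding/clustering parameters; `stats` the FDR level.
#'
#' @return Named list of stage sections.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    simulate = list(cells_per_case = 2000L, n_cases = 10L),
    phenotype = list(method = "valley"),
    cluster = list(n_per_group = 500L, perplexity = 50, resolution = 1),
    stats = list(q = 0.01)
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop(sprintf("config error: file '%s' not found", config), call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  utils::modifyList(default_pipeline_config(), config %||% list())
}

stage_artefact <- function(out_dir, name) file.path(out_dir, name)

require_artefact <- function(out_dir, name, stage, needed_by) {
  p <- stage_artefact(out_dir, name)
  if (!file.exists(p)) {
    stop(sprintf(
      "dependency error: stage '%s' requires '%s' produced by stage '%s'",
      needed_by, name, stage), call. = FALSE)
  }
  p
}

#' Run the analysis pipeline
#'
#' Orchestrates simulate -> phenotype -> cluster -> stats on a synthetic
#' cohort (the quantify stage applies when image input is simulated; for
#' cell-table simulation it is subsumed by simulate). Each stage writes its
#' CSV artefacts into `out_dir`; a run manifest (config snapshot, seed,
#' package version, artefact MD5 hashes, timestamps) is written at the end.
#' Stages depend on their upstream artefacts and fail with a dependency
#' error when run out of order.
#'
#' @param config path to a YAML config, or a config list
#'   (see [default_pipeline_config()]).
#' @param stages subset of `c("simulate", "phenotype", "cluster", "stats")`.
#' @param out_dir output directory (created if needed).
#' @param seed overrides the config seed when non-`NULL`.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = list(),
                         stages = c("simulate", "phenotype", "cluster",
                                    "stats"),
                         out_dir, seed = NULL) {
  cfg <- read_pipeline_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  stages <- match.arg(stages, c("simulate", "phenotype", "cluster", "stats"),
                      several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artefacts <- character(0)
  t0 <- Sys.time()

  if ("simulate" %in% stages) {
    sim_cfg <- simulation_config(
      groups = default_groups(cfg$simulate$n_cases),
      cells_per_case = cfg$simulate$cells_per_case,
      seed = cfg$seed
    )
    sim <- generate_cell_table(sim_cfg, seed = cfg$seed)
    write_cell_table(sim$cells, stage_artefact(out_dir, "cells.csv"))
    write_cell_table(sim$truth$cells,
                     stage_artefact(out_dir, "truth_cells.csv"))
    write_cell_table(sim$truth$cases,
                     stage_artefact(out_dir, "truth_cases.csv"))
    artefacts <- c(artefacts, "cells.csv", "truth_cells.csv",
                   "truth_cases.csv")
  }

  if ("phenotype" %in% stages) {
    cells <- read_cell_table(
      require_artefact(out_dir, "cells.csv", "simulate", "phenotype"))
    thr <- fit_thresholds(cells, method = cfg$phenotype$method)
    cells <- classify_moi(cells, thr)
    pct <- percent_high(cells)
    write_threshold_set(thr, stage_artefact(out_dir, "thresholds.yaml"))
    write_cell_table(cells, stage_artefact(out_dir, "cells_gated.csv"))
    write_cell_table(pct, stage_artefact(out_dir, "percent_high.csv"))
    artefacts <- c(artefacts, "thresholds.yaml", "cells_gated.csv",
                   "percent_high.csv")
  }

  if ("cluster" %in% stages) {
    cells <- read_cell_table(
      require_artefact(out_dir, "cells_gated.csv", "phenotype", "cluster"))
    sub <- subsample_balanced(cells, cfg$cluster$n_per_group,
                              seed = cfg$seed)
    res <- cluster_cells(sub, perplexity = cfg$cluster$perplexity,
                         resolution = cfg$cluster$resolution,
                         seed = cfg$seed)
    write_cell_table(res$cells, stage_artefact(out_dir, "clustered.csv"))
    write_cell_table(cluster_group_contribution(res),
                     stage_artefact(out_dir, "cluster_contribution.csv"))
    write_cell_table(cluster_case_percentages(res),
                     stage_artefact(out_dir, "cluster_case_pct.csv"))
    write_cell_table(relative_moi_high(res),
                     stage_artefact(out_dir, "relative_moi_high.csv"))
    artefacts <- c(artefacts, "clustered.csv", "cluster_contribution.csv",
                   "cluster_case_pct.csv", "relative_moi_high.csv")
  }

  if ("stats" %in% stages) {
    pct <- read_cell_table(
      require_artefact(out_dir, "percent_high.csv", "phenotype", "stats"))
    endpoints <- data.frame(case_id = pct$case_id, group = pct$group,
                            region = pct$region,
                            endpoint = paste0("pct_", pct$marker, "_high"),
                            value = pct$pct_high)
    comp <- compare_groups(endpoints, q = cfg$stats$q)
    write_cell_table(comp, stage_artefact(out_dir, "group_comparisons.csv"))
    artefacts <- c(artefacts, "group_comparisons.csv")
    truth_path <- stage_artefact(out_dir, "truth_cases.csv")
    if (file.exists(truth_path)) {
      for (grp in unique(pct$group)) {
        wide <- percent_high_wide(pct[pct$group == grp, ])
        truth <- read_cell_table(truth_path)
        wide <- merge(wide, truth[, c("case_id", "true_ptdp_load")],
                      by = "case_id")
        suppress <- if (all(wide$true_ptdp_load == 0)) "true_ptdp_load"
                    else NULL
        cm <- suppressWarnings(spearman_matrix(
          wide, vars = c(paste0("pct_", GLIAMUX_MARKERS, "_high"),
                         "true_ptdp_load"),
          suppress_vars = suppress))
        write_cell_table(as.data.frame(cm$r),
                         stage_artefact(out_dir,
                                        sprintf("spearman_%s.csv", grp)))
        artefacts <- c(artefacts, sprintf("spearman_%s.csv", grp))
      }
    }
  }

  manifest <- list(
    config = cfg,
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("gliamux")),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    artefacts = lapply(setNames(nm = unique(artefacts)), function(a) {
      list(md5 = unname(tools::md5sum(stage_artefact(out_dir, a))))
    })
  )
  yaml::write_yaml(manifest, stage_artefact(out_dir, "manifest.yaml"))
  invisible(manifest)
}

# wide per-case table of MOI-high percentages (one column per marker)
percent_high_wide <- function(pct) {
  out <- unique(pct[, c("case_id", "group", "region")])
  for (m in unique(pct$marker)) {
    sub <- pct[pct$marker == m, c("case_id", "pct_high")]
    names(sub)[2] <- paste0("pct_", m, "_high")
    out <- merge(out, sub, by = "case_id")
  }
  out
}
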