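#' Balanced subsampling across case-group/region subgroups
#'
#' Draws exactly `n_per_group` cells without replacement from every
#' `(group, region)` subgroup, so that each subgroup contributes equally to
#' the embedding (e.g. 31,200 per subgroup over four subgroups gives a
#' 124,800-cell pool).
#'
#' @param cells cell table with `group` and `region` columns.
#' @param n_per_group cells to draw per subgroup.
#' @param seed RNG seed; the same seed reproduces the same selection.
#' @param subgroup_cols columns defining the subgroups.
#' @return The subsampled cell table.
#' @export
subsample_balanced <- function(cells, n_per_group, seed = 1L,
                               subgroup_cols = c("group", "region")) {
  key <- interaction(cells[subgroup_cols], drop = TRUE, sep = "/")
  set.seed(seed)
  picked <- unlist(lapply(levels(key), function(k) {
    ix <- which(key == k)
    if (length(ix) < n_per_group) {
      stop(sprintf(
        "subgroup '%s' has only %d cells, fewer than n_per_group = %d",
        k, length(ix), n_per_group), call. = FALSE)
    }
    sample(ix, n_per_group)
  }), use.names = FALSE)
  cells[picked, , drop = FALSE]
}

#' Log-transform marker intensities into a feature matrix
#'
#' Natural log of the five marker columns in fixed order (L-ferritin,
#' HLA-DR, CD68, CD74, Iba1), giving the markers equal weighting for the
#' embedding. A pseudocount of 1 is added (with a message) when zeros are
#' present; negative intensities are an error. No scaling is applied, so a
#' zero-variance column stays zero-variance.
#'
#' @param cells cell table.
#' @param markers marker columns, in the order the matrix should have.
#' @return N x length(markers) numeric matrix.
#' @export
log_transform <- function(cells, markers = GLIAMUX_MARKERS) {
  x <- as.matrix(cells[, markers, drop = FALSE])
  if (any(x < 0)) stop("input error: negative intensity", call. = FALSE)
  if (any(x == 0)) {
    message("log_transform: zeros present, adding pseudocount 1")
    x <- x + 1
  }
  log(x)
}

#' Barnes-Hut t-SNE embedding of the marker feature matrix
#'
#' Learning rate follows the N/EE rule: eta = N / `ee_factor`, where
#' `ee_factor` is also the early-exaggeration factor, applied for the first
#' `ee_iterations` of `max_iterations`. Perplexity defaults to 250 and is
#' reduced to `floor((N - 1) / 3)` with a warning when N is too small.
#'
#' @param features numeric matrix (cells x markers), no NAs.
#' @param perplexity t-SNE perplexity.
#' @param ee_factor early-exaggeration factor (and learning-rate divisor).
#' @param ee_iterations iterations with exaggeration applied.
#' @param max_iterations total iterations.
#' @param seed RNG seed fixing the initialisation.
#' @return N x 2 matrix of embedding coordinates, with attributes
#'   `learning_rate` and `perplexity`.
#' @export
tsne_embed <- function(features, perplexity = 250, ee_factor = 12,
                       ee_iterations = 250, max_iterations = 1000,
                       seed = 1L) {
  if (anyNA(features) || any(!is.finite(features))) {
    stop("input error: features contain NA or non-finite values", call. = FALSE)
  }
  n <- nrow(features)
  stopifnot(ee_factor > 0, ee_iterations <= max_iterations)
  max_perp <- floor((n - 1) / 3)
  if (perplexity > max_perp) {
    warning(sprintf("perplexity %g too large for N = %d; reduced to %d",
                    perplexity, n, max_perp))
    perplexity <- max_perp
  }
  eta <- n / ee_factor
  set.seed(seed)
  fit <- Rtsne::Rtsne(features, dims = 2, perplexity = perplexity,
                      theta = 0.5, eta = eta,
                      exaggeration_factor = ee_factor,
                      stop_lying_iter = ee_iterations,
                      max_iter = max_iterations,
                      pca = FALSE, check_duplicates = FALSE, verbose = FALSE)
  emb <- fit$Y
  attr(emb, "learning_rate") <- eta
  attr(emb, "perplexity") <- perplexity
  emb
}

#' k-nearest-neighbour graph of an embedding
#'
#' Undirected graph with an edge (i, j) whenever j is among i's k nearest
#' Euclidean neighbours (union-symmetrised, unweighted). Default
#' k = floor(sqrt(N)). For moderate N an exact search with ties broken by
#' index order is used; larger N uses a kd-tree (FNN), where exact ties at
#' the k-th neighbour — measure-zero for continuous coordinates — may
#' resolve differently.
#'
#' @param embedding numeric matrix (N x d).
#' @param k neighbours per point (0 < k < N).
#' @param exact_max largest N for the exact distance-matrix search.
#' @return An igraph graph with `k` stored as a graph attribute.
#' @export
knn_graph <- function(embedding, k = NULL, exact_max = 2000L) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (is.null(k)) k <- floor(sqrt(n))
  if (k <= 0) stop("parameter error: k must be positive", call. = FALSE)
  if (k >= n) stop("parameter error: k must be smaller than N", call. = FALSE)
  if (n <= exact_max) {
    d <- as.matrix(stats::dist(embedding))
    nn <- vapply(seq_len(n), function(i) {
      ord <- order(d[i, ], seq_len(n))   # distance, then index
      head(ord[ord != i], k)
    }, integer(k))
    nn <- if (k == 1L) matrix(nn, nrow = 1L) else nn
    from <- rep(seq_len(n), each = k)
    to <- as.vector(nn)
  } else {
    nn <- FNN::get.knn(embedding, k = k)$nn.index
    from <- rep(seq_len(n), times = k)
    to <- as.vector(nn)
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::simplify(g)
  g <- igraph::set_graph_attr(g, "k", k)
  g
}

#' Louvain community detection
#'
#' Greedy modularity maximisation on the neighbour graph. Deterministic
#' given `seed`. Cluster labels are contiguous from 1, ordered by
#' decreasing cluster size. `resolution` is the modularity resolution:
#' 1 is the classical objective (which on the kNN graph of a continuous
#' embedding subdivides contiguous islands into patch-scale communities —
#' the regime that yields dozens of clusters at full cohort scale), while
#' coarse values (around 0.1) return island-scale communities and are the
#' appropriate setting for recovering genuinely separated phenotypes.
#'
#' @param graph igraph graph.
#' @param seed RNG seed.
#' @param resolution modularity resolution parameter.
#' @return list with `labels` (integer vector), `n_clusters`, and
#'   `modularity` (at resolution 1, computed from the labels).
#' @export
louvain_cluster <- function(graph, seed = 1L, resolution = 1) {
  if (igraph::vcount(graph) == 0L) {
    stop("input error: empty graph", call. = FALSE)
  }
  set.seed(seed)
  cl <- igraph::cluster_louvain(graph, resolution = resolution)
  mem <- igraph::membership(cl)
  sizes <- table(mem)
  # rank original labels by decreasing size, ties by label
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  map <- setNames(seq_along(ord), names(sizes)[ord])
  labels <- as.integer(map[as.character(mem)])
  list(labels = labels,
       n_clusters = length(sizes),
       modularity = igraph::modularity(graph, mem))
}

#' Embed and cluster a cell table
#'
#' Convenience wrapper: log-transform, t-SNE, kNN graph with
#' k = floor(sqrt(N)), Louvain. Clustering runs on the 2D embedding by
#' default; `cluster_on = "features"` clusters the 5-D log-feature space
#' instead, as a sensitivity analysis.
#'
#' @param cells cell table (already subsampled if desired).
#' @param markers marker columns.
#' @param perplexity,ee_factor,ee_iterations,max_iterations see
#'   [tsne_embed()].
#' @param k kNN parameter; default floor(sqrt(N)).
#' @param resolution Louvain resolution, see [louvain_cluster()].
#' @param cluster_on `"embedding"` (default) or `"features"`.
#' @param seed RNG seed for the embedding, graph and clustering.
#' @return A `cluster_result`: list with `cells` (input plus `cluster`
#'   column), `embedding`, `k`, `n_clusters`, `modularity`.
#' @export
cluster_cells <- function(cells, markers = GLIAMUX_MARKERS,
                          perplexity = 250, ee_factor = 12,
                          ee_iterations = 250, max_iterations = 1000,
                          k = NULL, resolution = 1,
                          cluster_on = c("embedding", "features"),
                          seed = 1L) {
  cluster_on <- match.arg(cluster_on)
  feats <- log_transform(cells, markers)
  emb <- tsne_embed(feats, perplexity, ee_factor, ee_iterations,
                    max_iterations, seed = seed)
  space <- if (cluster_on == "embedding") emb else feats
  g <- knn_graph(space, k = k)
  cl <- louvain_cluster(g, seed = seed, resolution = resolution)
  cells$cluster <- cl$labels
  cells$tsne_x <- emb[, 1]
  cells$tsne_y <- emb[, 2]
  structure(
    list(cells = cells, embedding = emb, k = igraph::graph_attr(g, "k"),
         n_clusters = cl$n_clusters, modularity = cl$modularity),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "<cluster_result> %d cells, %d clusters (k = %d, modularity %.3f)\n",
    nrow(x$cells), x$n_clusters, x$k, x$modularity))
  invisible(x)
}

result_cells <- function(x) {
  if (inherits(x, "cluster_result")) x$cells else x
}

#' Group contribution to each cluster
#'
#' Per cluster, the percentage of its cells coming from each group; rows
#' sum to 100.
#'
#' @param result a `cluster_result` or a cell table with `cluster` and
#'   `group` columns.
#' @param by_region when `TRUE`, computed separately per region; default
#'   pools the regions.
#' @return data.frame: `cluster`, one percentage column per group,
#'   `n_cells` (and `region` when `by_region`).
#' @export
cluster_group_contribution <- function(result, by_region = FALSE) {
  cells <- result_cells(result)
  split_keys <- if (by_region) split(cells, cells$region) else list(cells)
  out <- do.call(rbind, lapply(names(split_keys) %||% "", function(rn) {
    cc <- if (by_region) split_keys[[rn]] else split_keys[[1]]
    tab <- table(cc$cluster, cc$group)
    pct <- 100 * prop.table(tab, margin = 1)
    df <- data.frame(cluster = as.integer(rownames(tab)))
    if (by_region) df$region <- rn
    for (g in colnames(pct)) df[[paste0("pct_", g)]] <- as.numeric(pct[, g])
    df$n_cells <- as.integer(rowSums(tab))
    df
  }))
  rownames(out) <- NULL
  out
}

#' Per-case distribution of cells across clusters
#'
#' For every case (within its region), the percentage of that case's cells
#' falling in each cluster; percentages sum to 100 per case.
#'
#' @param result a `cluster_result` or cell table with `cluster`,
#'   `case_id`, `group`, `region` columns.
#' @return data.frame: `case_id`, `group`, `region`, `cluster`,
#'   `pct_of_case`, `n_cells`.
#' @export
cluster_case_percentages <- function(result) {
  cells <- result_cells(result)
  clusters <- sort(unique(cells$cluster))
  rows <- lapply(split(cells, cells$case_id), function(cc) {
    counts <- table(factor(cc$cluster, levels = clusters))
    data.frame(case_id = cc$case_id[1], group = cc$group[1],
               region = cc$region[1], cluster = clusters,
               pct_of_case = 100 * as.numeric(counts) / nrow(cc),
               n_cells = as.integer(counts), row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative MOI-high percentage per cluster, case and marker
#'
#' For each cluster, case and marker: the percentage of MOI-high cells
#' among the case's cells *in that cluster*, minus the percentage of
#' MOI-high cells in the case *overall*, in percentage points. Zero means
#' the cluster mirrors the case; positive values mark enrichment of
#' high-expressing cells in the cluster. By construction, the mean over
#' clusters weighted by the case's cell share per cluster is exactly 0 for
#' every case and marker. Cluster-case pairs with no cells yield `NA`.
#'
#' @param result a `cluster_result` or gated, clustered cell table.
#' @param markers markers to phenotype.
#' @return data.frame: `cluster`, `case_id`, `group`, `region`, `marker`,
#'   `rel_pct_high`, `pct_high_cluster`, `pct_high_case`, `n_cells`.
#' @export
relative_moi_high <- function(result, markers = GLIAMUX_MARKERS) {
  cells <- result_cells(result)
  flags <- paste0(markers, "_high")
  if (!all(flags %in% names(cells))) {
    stop("input error: MOI-high flags missing; run classify_moi() first",
         call. = FALSE)
  }
  clusters <- sort(unique(cells$cluster))
  rows <- lapply(split(cells, cells$case_id), function(cc) {
    overall <- vapply(flags, function(f) 100 * mean(cc[[f]]), numeric(1))
    do.call(rbind, lapply(clusters, function(cl) {
      inc <- cc[cc$cluster == cl, , drop = FALSE]
      n <- nrow(inc)
      in_pct <- if (n > 0) {
        vapply(flags, function(f) 100 * mean(inc[[f]]), numeric(1))
      } else rep(NA_real_, length(flags))
      data.frame(cluster = cl, case_id = cc$case_id[1], group = cc$group[1],
                 region = cc$region[1], marker = markers,
                 rel_pct_high = in_pct - overall,
                 pct_high_cluster = in_pct, pct_high_case = overall,
                 n_cells = n, row.names = NULL)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
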