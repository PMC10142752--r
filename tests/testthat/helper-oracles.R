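# Independent reference implementations used as oracles. These deliberately
# take different routes from the package code paths they check.

# 8-connectivity object count by queue-based flood fill
flood_fill_count <- function(mask) {
  mask <- matrix(as.logical(mask), nrow(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  count <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || seen[i, j]) next
    count <- count + 1L
    queue <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(queue)) {
      p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  count
}

# two-sided Mann-Whitney p by enumeration over group assignments, with U
# computed by pairwise comparison (not rank sums) and the p-value as
# 2 * min(lower tail, upper tail) capped at 1
mw_permutation_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pool <- c(x, y)
  sets <- combn(nx + ny, nx)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">")) +
    0.5 * sum(outer(xs, ys, "=="))
  U <- u_of(x, y)
  Uall <- apply(sets, 2, function(ix) u_of(pool[ix], pool[-ix]))
  p_lo <- mean(Uall <= U); p_hi <- mean(Uall >= U)
  min(1, 2 * min(p_lo, p_hi))
}

# two-stage BKY discovery flags built from p.adjust(..., "BH")
bky_reference <- function(p, q = 0.01) {
  m <- length(p)
  q1 <- q / (1 + q)
  stage1 <- p.adjust(p, "BH") <= q1
  r1 <- sum(stage1)
  if (r1 == 0L) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  p.adjust(p, "BH") <= q1 * m / (m - r1)
}

# modularity from the definition: Q = (1/2m) sum_ij (A_ij - k_i k_j / 2m) d_ij
modularity_oracle <- function(graph, labels) {
  A <- as.matrix(igraph::as_adjacency_matrix(graph))
  k <- rowSums(A)
  m2 <- sum(A)
  same <- outer(labels, labels, "==")
  sum((A - outer(k, k) / m2) * same) / m2
}

# small image-simulation config used across image tests (1 um/px so a
# 256 px field holds tens of non-overlapping somata)
small_image_config <- function(n_cases = 1, cells_per_case = 40,
                               groups = NULL, seed = 1, ...) {
  ip <- utils::modifyList(
    list(width_px = 256, height_px = 256, um_per_px = 1,
         n_astrocytes = 4, aggregate_count_per_case = 40),
    list(...)
  )
  simulation_config(
    groups = groups %||% data.frame(group = "disease",
                                    region = "motor_cortex",
                                    n_cases = n_cases),
    cells_per_case = cells_per_case,
    image_params = ip,
    seed = seed
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

default_clip_thresholds <- c(iba1 = 40, hladr = 40, cd68 = 40, cd74 = 40,
                             ptdp43 = 200, gfap = 100)
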