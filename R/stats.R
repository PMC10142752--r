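#' Mann-Whitney U test
#'
#' Rank-sum test for a difference between two independent samples. For
#' combined sample sizes up to `exact_limit` (default 16) without ties, the
#' two-sided p-value is computed by exact enumeration of all
#' choose(n, n_x) group assignments; otherwise a normal approximation with
#' tie correction and continuity correction is used. `U` is reported for
#' `x` (number of (x, y) pairs with x > y, plus half the ties).
#'
#' @param x,y numeric samples (non-empty).
#' @param exact_limit largest combined n for the exact branch.
#' @return list with `U`, `p`, `method` (`"exact"` or `"normal_approx"`).
#' @export
mann_whitney_u <- function(x, y, exact_limit = 16L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) {
    stop("input error: empty sample", call. = FALSE)
  }
  nx <- length(x); ny <- length(y); n <- nx + ny
  comb <- c(x, y)
  r <- rank(comb)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(comb))
  m <- nx * ny
  if (n <= exact_limit && !ties) {
    # exact: U for every assignment of nx of the n ranks to group x
    ranks <- seq_len(n)
    sets <- combn(n, nx)
    Uall <- colSums(matrix(ranks[sets], nrow = nx)) - nx * (nx + 1) / 2
    obs <- min(U, m - U)
    p <- mean(pmin(Uall, m - Uall) <= obs)
    return(list(U = U, p = p, method = "exact"))
  }
  tie_tab <- table(comb)
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma2 <- m / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal_approx"))
  z <- U - m / 2
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
  p <- min(1, 2 * pnorm(-abs(z)))
  list(U = U, p = p, method = "normal_approx")
}

bh_step_up <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * alpha / m)
  reject <- logical(m)
  if (length(k)) reject[o[seq_len(max(k))]] <- TRUE
  reject
}

#' Two-stage Benjamini-Krieger-Yekutieli FDR discovery flags
#'
#' The adaptive two-stage linear step-up procedure at FDR level `q`:
#' stage 1 runs a linear step-up at q' = q/(1 + q); the number of
#' rejections r1 estimates the number of true nulls as m0 = m - r1; when
#' 0 < r1 < m, stage 2 re-runs the step-up at level q' * m / m0. No
#' stage-1 rejections means no discoveries; r1 = m rejects everything.
#'
#' @param pvals p-values in `[0, 1]`.
#' @param q FDR level in (0, 1); default 0.01.
#' @return logical vector of discovery flags.
#' @export
bky_two_stage_adjust <- function(pvals, q = 0.01) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1) {
    stop("parameter error: q must be in (0, 1)", call. = FALSE)
  }
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("input error: p-values outside [0, 1]", call. = FALSE)
  }
  m <- length(pvals)
  if (m == 0L) return(logical(0))
  q1 <- q / (1 + q)
  stage1 <- bh_step_up(pvals, q1)
  r1 <- sum(stage1)
  if (r1 == 0L) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  m0 <- m - r1
  bh_step_up(pvals, q1 * m / m0)
}

significance_stars <- function(p) {
  ifelse(p <= 1e-4, "****",
         ifelse(p <= 1e-3, "***",
                ifelse(p <= 0.01, "**",
                       ifelse(p <= 0.05, "*", "ns"))))
}

#' Compare endpoints between two groups with FDR control
#'
#' Runs a Mann-Whitney test per endpoint, separately per region, and
#' controls each region's family of endpoint tests together with the
#' two-stage BKY step-up at FDR `q`. The family composition (one family per
#' region, spanning the supplied endpoints) mirrors the per-figure test
#' families of group-comparison panels. Stars reflect the raw p-value;
#' the FDR decision is the `q_flag` column.
#'
#' @param endpoints long data.frame: `case_id`, `group`, `region`,
#'   `endpoint`, `value` (one row per case and endpoint).
#' @param q FDR level; default 0.01.
#' @return data.frame: `region`, `endpoint`, per-group medians, `U`, `p`,
#'   `q_flag`, `stars`.
#' @export
compare_groups <- function(endpoints, q = 0.01) {
  stopifnot(all(c("case_id", "group", "region", "endpoint", "value") %in%
                  names(endpoints)))
  groups <- sort(unique(endpoints$group))
  if (length(groups) < 2L) {
    stop("input error: need two groups to compare", call. = FALSE)
  }
  if (length(groups) > 2L) {
    stop("input error: more than two groups", call. = FALSE)
  }
  n_per <- table(unique(endpoints[c("case_id", "group")])$group)
  if (any(n_per < 3L)) {
    warning("fewer than 3 cases in a group; comparisons will be weak")
  }
  out <- do.call(rbind, lapply(split(endpoints, endpoints$region),
                               function(reg) {
    res <- do.call(rbind, lapply(split(reg, reg$endpoint), function(e) {
      xa <- e$value[e$group == groups[1]]
      xb <- e$value[e$group == groups[2]]
      mw <- mann_whitney_u(xa, xb)
      data.frame(region = e$region[1], endpoint = e$endpoint[1],
                 median_a = median(xa), median_b = median(xb),
                 U = mw$U, p = mw$p, row.names = NULL)
    }))
    res$q_flag <- bky_two_stage_adjust(res$p, q)
    res
  }))
  names(out)[names(out) == "median_a"] <- paste0("median_", groups[1])
  names(out)[names(out) == "median_b"] <- paste0("median_", groups[2])
  out$stars <- significance_stars(out$p)
  rownames(out) <- NULL
  out
}

#' Spearman correlation matrix
#'
#' Pairwise tie-corrected Spearman correlations with two-sided p-values,
#' pairwise-complete handling of missing cases, and a "very strong" flag at
#' |r| > 0.7. Constant variables yield `NA` correlations with a warning.
#' Variables named in `suppress_vars` are excluded from off-diagonal
#' correlations (returned `NA`) — used e.g. for pTDP-43 in control cases,
#' which carry no aggregates.
#'
#' @param data data.frame of per-case variables.
#' @param vars variables to correlate; default all numeric columns.
#' @param suppress_vars variables whose correlations are suppressed.
#' @return A `correlation_matrix`: list with matrices `r`, `p`, `n`,
#'   logical `very_strong`, and `vars`.
#' @export
spearman_matrix <- function(data, vars = NULL, suppress_vars = NULL) {
  if (is.null(vars)) {
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  k <- length(vars)
  r <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  nmat <- matrix(0L, k, k, dimnames = list(vars, vars))
  diag(r) <- 1; diag(p) <- 0
  constant <- vapply(vars, function(v) {
    x <- data[[v]][!is.na(data[[v]])]
    length(unique(x)) <= 1L
  }, logical(1))
  if (any(constant)) {
    warning(sprintf("constant variable(s): %s; correlations set to NA",
                    paste(vars[constant], collapse = ", ")))
  }
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (vars[i] %in% suppress_vars || vars[j] %in% suppress_vars ||
          constant[i] || constant[j]) next
      ok <- complete.cases(data[[vars[i]]], data[[vars[j]]])
      nmat[i, j] <- nmat[j, i] <- sum(ok)
      if (sum(ok) < 4L) next
      ct <- suppressWarnings(cor.test(data[[vars[i]]][ok],
                                      data[[vars[j]]][ok],
                                      method = "spearman", exact = FALSE))
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  structure(
    list(r = r, p = p, n = nmat, very_strong = !is.na(r) & abs(r) > 0.7,
         vars = vars),
    class = "correlation_matrix"
  )
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %d variables; very strong pairs: %d\n",
              length(x$vars),
              (sum(x$very_strong) - length(x$vars)) / 2))
  print(round(x$r, 3))
  invisible(x)
}

#' Two-way ANOVA with per-timepoint Bonferroni contrasts
#'
#' Fits `value ~ factor_a * factor_b` with sum-to-zero contrasts and
#' Type-III sums of squares (unbalanced cells allowed), then compares the
#' two `factor_a` levels at each `factor_b` level (pooled-error contrasts),
#' multiplying each raw p by the number of `factor_b` levels (Bonferroni),
#' capped at 1 — the longitudinal genotype-by-timepoint design.
#'
#' @param data data.frame.
#' @param value name of the response column.
#' @param factor_a grouping factor (e.g. genotype), 2+ levels.
#' @param factor_b stratifying factor (e.g. timepoint), 2+ levels.
#' @return list with `anova` (data.frame of F tests) and `contrasts`
#'   (data.frame: level of `factor_b`, estimate, t, raw `p`, `p_bonferroni`,
#'   `stars`).
#' @export
two_way_anova_bonferroni <- function(data, value, factor_a, factor_b) {
  data[[factor_a]] <- factor(data[[factor_a]])
  data[[factor_b]] <- factor(data[[factor_b]])
  cells <- table(data[[factor_a]], data[[factor_b]])
  if (any(cells == 0L)) {
    empty <- which(cells == 0L, arr.ind = TRUE)[1, ]
    stop(sprintf("input error: empty cell %s x %s",
                 rownames(cells)[empty[1]], colnames(cells)[empty[2]]),
         call. = FALSE)
  }
  fml <- as.formula(sprintf("%s ~ %s * %s", value, factor_a, factor_b))
  contr <- list(contr.sum, contr.sum)
  names(contr) <- c(factor_a, factor_b)
  fit <- lm(fml, data = data, contrasts = contr)
  a3 <- car::Anova(fit, type = 3)
  anova_df <- data.frame(term = rownames(a3), sum_sq = a3[["Sum Sq"]],
                         df = a3$Df, F = a3[["F value"]],
                         p = a3[["Pr(>F)"]], row.names = NULL)
  emm <- emmeans::emmeans(fit, as.formula(paste0("~ ", factor_a, " | ",
                                                 factor_b)))
  ctr <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "none"))
  k <- nlevels(data[[factor_b]])
  contrasts_df <- data.frame(
    contrast = ctr$contrast,
    level = ctr[[factor_b]],
    estimate = ctr$estimate,
    t = ctr$t.ratio,
    p = ctr$p.value,
    p_bonferroni = pmin(1, ctr$p.value * k)
  )
  contrasts_df$stars <- significance_stars(contrasts_df$p_bonferroni)
  list(anova = anova_df, contrasts = contrasts_df)
}
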