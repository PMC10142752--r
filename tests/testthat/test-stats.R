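test_that("exact Mann-Whitney matches enumeration on canonical examples", {
  mw <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 1 / 3)           # 2 of 6 arrangements as extreme
  expect_equal(mw$method, "exact")
  # U symmetry when swapping samples
  x <- c(5, 9, 2); y <- c(7, 1, 4, 8)
  expect_equal(mann_whitney_u(x, y)$U + mann_whitney_u(y, x)$U,
               length(x) * length(y))
  expect_error(mann_whitney_u(numeric(0), 1:3), "input error")
})

test_that("exact branch equals the permutation oracle for all n_x + n_y <= 10", {
  set.seed(20)
  for (nx in 1:5) for (ny in nx:(10 - nx)) {
    for (rep in 1:3) {
      x <- round(rnorm(nx, 0, 10), 4)
      y <- round(rnorm(ny, 1, 10), 4)
      if (any(duplicated(c(x, y)))) next
      mw <- mann_whitney_u(x, y)
      expect_equal(mw$method, "exact")
      expect_equal(mw$p, mw_permutation_oracle(x, y),
                   info = sprintf("nx=%d ny=%d rep=%d", nx, ny, rep))
    }
  }
})

test_that("approximate branch agrees with the tie-corrected normal reference", {
  set.seed(21)
  x <- rnorm(12); y <- rnorm(15, 0.5)
  mw <- mann_whitney_u(x, y)
  expect_equal(mw$method, "normal_approx")
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(mw$p, ref$p.value, tolerance = 1e-10)
  expect_equal(mw$U, unname(ref$statistic))
  # with ties
  xt <- c(1, 2, 2, 3, 5, 5, 8, 9, 9, 9)
  yt <- c(2, 4, 5, 5, 6, 7, 9, 10, 11)
  mwt <- mann_whitney_u(xt, yt)
  reft <- wilcox.test(xt, yt, exact = FALSE, correct = TRUE)
  expect_equal(mwt$p, reft$p.value, tolerance = 1e-10)
})

test_that("two-stage BKY flags obey the edge cases and monotonicity", {
  expect_false(any(bky_two_stage_adjust(rep(1, 10), 0.01)))
  expect_true(all(bky_two_stage_adjust(rep(0, 10), 0.01)))
  expect_error(bky_two_stage_adjust(runif(5), q = 1.5), "parameter error")
  expect_error(bky_two_stage_adjust(c(0.5, 2)), "input error")
  set.seed(22)
  for (i in 1:50) {
    p <- runif(20)^3
    flags <- bky_two_stage_adjust(p, 0.05)
    if (any(flags)) {
      expect_true(all(flags[p <= max(p[flags])]))  # monotone in p
    }
  }
})

test_that("BKY matches an independent reference over many random families", {
  set.seed(23)
  mismatches <- 0L
  for (i in 1:1000) {
    m <- sample(5:40, 1)
    n_sig <- rbinom(1, m, 0.3)
    p <- c(runif(n_sig, 0, 0.01), runif(m - n_sig))
    for (q in c(0.01, 0.05)) {
      if (!identical(bky_two_stage_adjust(p, q), bky_reference(p, q))) {
        mismatches <- mismatches + 1L
      }
    }
  }
  expect_equal(mismatches, 0L)
})

test_that("two-stage BKY out-discovers single-stage BH on clear signals", {
  # when stage 1 detects signal, the adaptive stage-2 level q'(m/m0)
  # exceeds q, so every BH discovery is also a BKY discovery; the
  # adaptivity can only lose in borderline families where stage 1 finds
  # nothing at all
  set.seed(24)
  total_bky <- 0L; total_bh <- 0L
  for (i in 1:100) {
    p <- c(runif(8, 0, 0.005), runif(12))
    q <- 0.05
    bky <- bky_two_stage_adjust(p, q)
    bh <- p.adjust(p, "BH") <= q
    if (any(bky)) expect_true(all(bh <= bky))
    total_bky <- total_bky + sum(bky); total_bh <- total_bh + sum(bh)
  }
  expect_gte(total_bky, total_bh)
})

test_that("compare_groups flags planted differences and not identical groups", {
  mk_endpoints <- function(shift) {
    set.seed(25)
    cases <- data.frame(case_id = sprintf("c%02d", 1:20),
                        group = rep(c("control", "disease"), each = 10))
    do.call(rbind, lapply(c("cd68", "iba1"), function(ep) {
      data.frame(cases, region = "motor_cortex", endpoint = ep,
                 value = rnorm(20, 10, 1) +
                   ifelse(ep == "cd68" & cases$group == "disease", shift, 0))
    }))
  }
  null_res <- compare_groups(mk_endpoints(0), q = 0.01)
  expect_false(any(null_res$q_flag))
  eff_res <- compare_groups(mk_endpoints(8), q = 0.01)
  expect_true(eff_res$q_flag[eff_res$endpoint == "cd68"])
  expect_false(eff_res$q_flag[eff_res$endpoint == "iba1"])
  one_group <- mk_endpoints(0)
  one_group$group <- "control"
  expect_error(compare_groups(one_group), "two groups")
})

test_that("spearman matrix equals Pearson on ranks and is monotone-invariant", {
  inc <- data.frame(a = 1:8, b = (1:8)^2)
  cm <- spearman_matrix(inc)
  expect_equal(cm$r["a", "b"], 1)
  dec <- data.frame(a = 1:8, b = -(1:8)^3)
  expect_equal(spearman_matrix(dec)$r["a", "b"], -1)
  set.seed(26)
  with_ties <- data.frame(x = sample(1:5, 30, TRUE),
                          y = sample(1:6, 30, TRUE),
                          z = rnorm(30))
  cmt <- spearman_matrix(with_ties)
  expect_equal(cmt$r["x", "y"],
               cor(rank(with_ties$x), rank(with_ties$y)), tolerance = 1e-12)
  expect_equal(cmt$r, t(cmt$r))
  expect_equal(unname(diag(cmt$r)), rep(1, 3))
  # invariance under strictly monotone transforms
  tr <- with_ties; tr$z <- exp(tr$z)
  expect_equal(spearman_matrix(tr)$r["x", "z"], cmt$r["x", "z"])
  # constant variable and suppression
  con <- data.frame(a = rnorm(10), b = rep(2, 10), c = rnorm(10))
  expect_warning(cmc <- spearman_matrix(con), "constant")
  expect_true(is.na(cmc$r["a", "b"]))
  sup <- spearman_matrix(with_ties, suppress_vars = "z")
  expect_true(all(is.na(sup$r["z", c("x", "y")])))
  expect_equal(sup$r["x", "y"], cmt$r["x", "y"])
})

test_that("two-way ANOVA matches hand-computed sums of squares when balanced", {
  # balanced 2 x 3 design, 2 replicates per cell
  d <- expand.grid(geno = c("ctrl", "rnls"), wod = c("2", "4", "6"),
                   rep = 1:2)
  d$y <- c(1, 5, 2, 7, 3, 9,
           2, 6, 3, 8, 4, 10)
  res <- two_way_anova_bonferroni(d, "y", "geno", "wod")
  # hand computation: cell means, marginal means, grand mean
  gm <- mean(d$y)
  ss_a <- 6 * sum((tapply(d$y, d$geno, mean) - gm)^2)
  ss_b <- 4 * sum((tapply(d$y, d$wod, mean) - gm)^2)
  cellm <- tapply(d$y, interaction(d$geno, d$wod), mean)
  margs <- expand.grid(geno = c("ctrl", "rnls"), wod = c("2", "4", "6"))
  pred <- tapply(d$y, d$geno, mean)[margs$geno] +
    tapply(d$y, d$wod, mean)[margs$wod] - gm
  ss_ab <- 2 * sum((cellm[interaction(margs$geno, margs$wod)] - pred)^2)
  tab <- res$anova
  expect_equal(tab$sum_sq[tab$term == "geno"], ss_a, tolerance = 1e-9)
  expect_equal(tab$sum_sq[tab$term == "wod"], ss_b, tolerance = 1e-9)
  expect_equal(tab$sum_sq[tab$term == "geno:wod"], ss_ab, tolerance = 1e-9)
  # Bonferroni: raw p multiplied by the number of timepoints, capped at 1
  expect_equal(res$contrasts$p_bonferroni,
               pmin(1, res$contrasts$p * 3))
  d_missing <- d[!(d$geno == "rnls" & d$wod == "6"), ]
  expect_error(two_way_anova_bonferroni(d_missing, "y", "geno", "wod"),
               "empty cell")
})
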