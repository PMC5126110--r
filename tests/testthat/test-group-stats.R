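test_that("spearman_rho handles monotone, reversed, tied and hand-worked cases", {
  x <- c(1, 3, 7, 20, 55)
  expect_equal(spearman_rho(x, exp(x)), 1)
  expect_equal(spearman_rho(x, -x^3), -1)
  expect_equal(spearman_rho(1:5, c(2, 1, 4, 3, 5)), 0.8)  # sum(d^2) = 4
  expect_equal(spearman_rho(c(1, 1, 2, 3), c(4, 4, 5, 6)),
               stats::cor(c(1, 1, 2, 3), c(4, 4, 5, 6), method = "spearman"))
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:4, 1:5), "equal length")
})

test_that("spearman_rho is invariant under strictly monotone transforms", {
  set.seed(31)
  for (i in 1:20) {
    x <- stats::rnorm(30)
    y <- stats::rnorm(30)
    r0 <- spearman_rho(x, y)
    expect_equal(spearman_rho(exp(x), y), r0)
    expect_equal(spearman_rho(x, stats::qlogis(stats::pnorm(y))), r0,
                 tolerance = 1e-12)
  }
})

test_that("the t approximation reproduces the published peak statistics", {
  t_id <- 0.521 * sqrt(50 / (1 - 0.521^2))
  expect_equal(round(t_id, 2), round(4.317, 2))
  t_ctrl <- 0.547 * sqrt(41 / (1 - 0.547^2))
  expect_equal(round(t_ctrl, 2), round(4.181, 2))
  set.seed(5)
  x <- stats::rnorm(52); y <- stats::rnorm(52)
  st <- spearman_test(x, y)
  expect_equal(st$df, 50L)
  expect_equal(st$statistic, st$rho * sqrt(50 / (1 - st$rho^2)))
  expect_equal(st$p, 2 * stats::pt(-abs(st$statistic), 50))
  st0 <- spearman_test(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9) * 0 +
                         c(5, 6, 1, 2, 9, 10, 3, 4, 7, 8))
  expect_lt(abs(st0$statistic), 1)              # near-null case stays small
  expect_warning(spearman_test(1:5, (1:5)^2), "infinite")
})

test_that("bootstrap CIs are seeded, degenerate-safe and sign-robust", {
  x <- 1:20
  ci <- suppressWarnings(bootstrap_rho_ci(x, x + 0, n_boot = 200, seed = 1))
  expect_equal(ci$ci_lower, 1)
  expect_equal(ci$ci_upper, 1)
  expect_true(ci$robust)
  set.seed(77)
  a <- stats::rnorm(30); b <- a + stats::rnorm(30)
  c1 <- bootstrap_rho_ci(a, b, n_boot = 300, seed = 4)
  c2 <- bootstrap_rho_ci(a, b, n_boot = 300, seed = 4)
  expect_identical(c1$boot_rhos, c2$boot_rhos)
  expect_true(c1$ci_lower <= c1$rho && c1$rho <= c1$ci_upper)
  expect_error(bootstrap_rho_ci(1:4, 1:4), "at least 5")
})

test_that("bootstrap CI coverage is near nominal for a moderate correlation", {
  rho <- 0.5
  cover <- sapply(1:120, function(r) {
    set.seed(4000 + r)
    z <- stats::rnorm(50)
    x <- z + stats::rnorm(50)
    y <- z + stats::rnorm(50)                   # true Pearson 0.5
    true_s <- 6 / pi * asin(0.5 / 2)            # Spearman of bivariate normal
    ci <- bootstrap_rho_ci(x, y, n_boot = 200, seed = r)
    ci$ci_lower <= true_s && true_s <= ci$ci_upper
  })
  expect_gt(mean(cover), 0.85)
  expect_lt(mean(cover), 1)
})

test_that("rank-sum test matches the reference implementation and separates shifts", {
  set.seed(11)
  a <- stats::rnorm(50); b <- stats::rnorm(45)
  r <- ranksum_test(a, b)
  w <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(r$p, w$p.value, tolerance = 1e-12)
  same <- ranksum_test(a, a)
  expect_gt(same$p, 0.9)
  shifted <- ranksum_test(a, a + 5)
  expect_lt(shifted$p, 0.001)
  expect_equal(ranksum_test(rep(1, 10), rep(1, 8))$z, 0)
  expect_error(ranksum_test(numeric(0), 1:3), "non-empty")
})

test_that("rank-sum type-I error is near nominal", {
  rej <- sapply(1:400, function(r) {
    set.seed(50000 + r)
    ranksum_test(stats::rnorm(50), stats::rnorm(50))$p < 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("type-II GLM detects a planted ISI slope and is calibrated under the null", {
  mg <- tiny_montage()
  power <- sapply(1:60, function(r) {
    set.seed(6000 + r)
    n_id <- 52; n_ctrl <- 43
    isi <- c(sample(8:28, n_id, TRUE), sample(0:7, n_ctrl, TRUE))
    coh <- data.frame(id = sprintf("S%02d", 1:95),
                      group = factor(rep(c("ID", "CTRL"), c(n_id, n_ctrl)),
                                     levels = c("CTRL", "ID")),
                      isi = isi)
    y <- 0.62 + 0.004 * isi + stats::rnorm(95, sd = 0.03)
    glm_type2(y, coh)$p[2] < 0.05               # the isi term
  })
  expect_gte(mean(power), 0.8)
  null_p <- sapply(1:400, function(r) {
    set.seed(90000 + r)
    coh <- data.frame(id = 1:60,
                      group = factor(rep(c("ID", "CTRL"), each = 30)),
                      isi = c(sample(8:28, 30, TRUE), sample(0:7, 30, TRUE)))
    glm_type2(stats::rnorm(60), coh)$p
  })
  rates <- rowMeans(null_p < 0.05)
  expect_true(all(rates > 0.02 & rates < 0.09))
  expect_error(glm_type2(stats::rnorm(10),
                         data.frame(id = 1:10, group = factor(rep("ID", 10)),
                                    isi = 1:10)),
               "single group")
})

test_that("GLM p-values are invariant to ISI recentering without an interaction", {
  set.seed(13)
  coh <- data.frame(id = 1:80, group = factor(rep(c("ID", "CTRL"), each = 40)),
                    isi = c(sample(8:28, 40, TRUE), sample(0:7, 40, TRUE)))
  y <- 0.6 + 0.003 * coh$isi + stats::rnorm(80, sd = 0.02)
  g1 <- glm_type2(y, coh)
  coh2 <- coh; coh2$isi <- coh$isi - mean(coh$isi)
  g2 <- glm_type2(y, coh2)
  expect_equal(g1$p[2:3], g2$p[2:3], tolerance = 1e-9)
})

test_that("condition contrasts detect planted EO elevation and respect ordering", {
  mg <- tiny_montage()
  bands <- two_bands()
  spec <- cohort_spec(n_id = 20, n_ctrl = 16, noise_sd = 0.02, seed = 3)
  ec <- generate_cohort_h(spec, mg, bands, condition = "EC")
  h_eo <- unclass(ec$h) + 0.03
  hm_eo <- h_matrix(h_eo, condition = "EO")
  cc <- condition_contrast(hm_eo, ec$h)
  expect_true(all(cc$median_diff > 0))
  expect_true(all(cc$p < 0.01))
  same <- condition_contrast(ec$h, ec$h)
  expect_true(all(same$p == 1))
  expect_true(all(same$median_diff == 0))
  ord <- c(10:1, 11:36)
  hm1 <- h_matrix(h_eo[ord, , ], condition = "EO")
  hm2 <- h_matrix(unclass(ec$h)[ord, , ], condition = "EC")
  cc2 <- condition_contrast(hm1, hm2)
  expect_equal(cc$p, cc2$p, tolerance = 1e-12)
  expect_error(condition_contrast(hm1, ec$h), "participant")
})

test_that("within-group correlations exceed the pooled one for offset groups", {
  set.seed(17)
  n <- 60
  grp <- rep(c("ID", "CTRL"), each = n / 2)
  isi <- c(sample(8:28, n / 2, TRUE), sample(0:7, n / 2, TRUE))
  # both groups span the same H range over their own ISI range, so the
  # pooled gradient is diluted while within-group slopes stay steep
  y <- 0.6 + 0.2 * ifelse(grp == "ID", (isi - 8) / 20, isi / 7) +
    stats::rnorm(n, sd = 0.02)
  coh <- data.frame(id = 1:n, group = factor(grp), isi = isi)
  res <- within_vs_across_correlation(coh, y, n_boot = 200, seed = 5)
  expect_true(all(res$within > res$pooled))
  y2 <- 0.6 + 0.005 * isi + stats::rnorm(n, sd = 0.02)
  res2 <- within_vs_across_correlation(coh, y2, n_boot = 200, seed = 5)
  expect_lt(abs(mean(res2$within) - res2$pooled), 0.35)
  res3 <- within_vs_across_correlation(coh, y2, n_boot = 200, seed = 5)
  expect_identical(res2$boot_diff, res3$boot_diff)
})
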