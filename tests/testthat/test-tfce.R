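test_that("an isolated bin converges to the closed-form height integral", {
  mg <- tiny_montage()
  adj <- bin_adjacency(mg, 2)
  tm <- matrix(0, 9, 2)
  tm[5, 1] <- 2
  enh <- tfce_enhance(tm, adj, tfce_params(n_steps = 100))
  expect_equal(enh[5, 1], 8 / 3, tolerance = 0.01)  # 1^0.66 * int_0^2 h^2 dh
  enh2 <- tfce_enhance(tm, adj, tfce_params(n_steps = 1000))
  expect_equal(enh2[5, 1], 8 / 3, tolerance = 1e-4)
})

test_that("a uniform map on a fully connected graph follows N^0.66 t^3/3", {
  mg <- generate_montage(6, "grid", neighbor_radius = 10)  # all-to-all
  adj <- bin_adjacency(mg, 1)
  t0 <- 1.5
  tm <- matrix(t0, 6, 1)
  enh <- tfce_enhance(tm, adj, tfce_params(n_steps = 2000))
  expect_equal(unname(enh[1, 1]), 6^0.66 * t0^3 / 3, tolerance = 1e-3)
})

test_that("fast enhancement equals the brute-force threshold loop exactly", {
  skip_if_not_installed("igraph")
  mg <- generate_montage(16, "grid")
  adj <- bin_adjacency(mg, 2)
  set.seed(23)
  for (i in 1:5) {
    tm <- matrix(stats::rnorm(32), 16, 2)
    for (steps in c(25L, 100L)) {
      fast <- tfce_enhance(tm, adj, tfce_params(n_steps = steps))
      slow <- brute_tfce(tm, adj, steps)
      expect_equal(fast, slow, tolerance = 1e-12,
                   label = sprintf("map %d, %d steps", i, steps))
    }
  }
})

test_that("enhancement is sign-symmetric and zero-preserving", {
  mg <- tiny_montage()
  adj <- bin_adjacency(mg, 3)
  expect_true(all(tfce_enhance(matrix(0, 9, 3), adj) == 0))
  set.seed(29)
  tm <- matrix(stats::rnorm(27), 9, 3)
  e1 <- tfce_enhance(tm, adj)
  e2 <- tfce_enhance(-tm, adj)
  expect_equal(e1, -e2, tolerance = 1e-14)
  expect_true(all(e1 * tm >= 0))                # enhancement keeps the sign
})

test_that("bin adjacency combines montage neighbours with the band chain", {
  mg <- tiny_montage()
  adj <- bin_adjacency(mg, 3)
  expect_length(adj$neighbors, 27L)
  # centre electrode (E05) in the middle band: 4 spatial + 2 spectral
  expect_setequal(adj$neighbors[[5 + 9]], c(c(2, 4, 6, 8) + 9, 5, 5 + 18))
  # corner electrode (E01) in the first band: 2 spatial + 1 spectral
  expect_setequal(adj$neighbors[[1]], c(2, 4, 1 + 9))
})

test_that("spatio-spectral neighbours are symmetric and irreflexive", {
  adj <- bin_adjacency(tiny_montage(), 5)
  for (i in seq_along(adj$neighbors)) {
    expect_false(i %in% adj$neighbors[[i]])
    for (j in adj$neighbors[[i]]) {
      expect_true(i %in% adj$neighbors[[j]])
    }
  }
})

test_that("the correlation map matches per-bin tests and flags constant bins", {
  mg <- tiny_montage()
  spec <- cohort_spec(n_id = 30, n_ctrl = 1, seed = 15)
  ch <- generate_cohort_h(spec, mg, two_bands())
  i <- ch$cohort$group == "ID"
  sub <- h_matrix(unclass(ch$h)[i, , , drop = FALSE], condition = "EO")
  sm <- correlation_stat_map(sub, ch$cohort$isi[i])
  st <- spearman_test(ch$cohort$isi[i], sub[, 3, 2])
  expect_equal(sm$rho[3, 2], st$rho)
  expect_equal(sm$t[3, 2], st$statistic)
  expect_equal(sm$df, 28L)
  hconst <- unclass(sub)
  hconst[, 1, 1] <- 0.7
  expect_warning(smc <- correlation_stat_map(h_matrix(hconst), ch$cohort$isi[i]),
                 "constant")
  expect_true(smc$flagged[1, 1])
  expect_equal(smc$t[1, 1], 0)
})

test_that("permutation nulls are seed-stable and corrected p values behave", {
  mg <- tiny_montage()
  spec <- cohort_spec(n_id = 40, n_ctrl = 2, seed = 19)
  ch <- generate_cohort_h(spec, mg, two_bands())
  i <- ch$cohort$group == "ID"
  sub <- h_matrix(unclass(ch$h)[i, , , drop = FALSE], condition = "EO")
  adj <- bin_adjacency(mg, 2)
  pars <- tfce_params(n_perm = 150, seed = 8)
  n1 <- permutation_null(sub, ch$cohort$isi[i], adj, pars)
  n2 <- permutation_null(sub, ch$cohort$isi[i], adj, pars)
  expect_identical(n1, n2)
  expect_length(n1, 150L)
  # monotonicity and bounds of the add-one estimator
  enh <- matrix(seq(0, max(n1) * 1.1, length.out = 18), 9, 2)
  p <- corrected_pvalues(enh, n1)
  expect_true(all(diff(as.numeric(p)) <= 0))
  expect_equal(p[9, 2], 1 / 151)                # exceeds every null draw
  expect_true(all(p > 0 & p <= 1))
  med_bin <- matrix(stats::median(n1), 1, 1)
  expect_equal(corrected_pvalues(med_bin, n1)[1, 1], 0.5, tolerance = 0.05)
})

test_that("null quantiles agree between shorter and longer permutation runs", {
  mg <- tiny_montage()
  spec <- cohort_spec(n_id = 45, n_ctrl = 2, seed = 27)
  ch <- generate_cohort_h(spec, mg, default_bands())
  i <- ch$cohort$group == "ID"
  sub <- h_matrix(unclass(ch$h)[i, , , drop = FALSE], condition = "EO")
  adj <- bin_adjacency(mg, 5)
  isi <- ch$cohort$isi[i]
  nA <- permutation_null(sub, isi, adj, tfce_params(n_perm = 150, seed = 1))
  nB <- permutation_null(sub, isi, adj, tfce_params(n_perm = 1000, seed = 2))
  qa <- stats::quantile(nA, c(0.5, 0.9))
  qb <- stats::quantile(nB, c(0.5, 0.9))
  expect_lt(max(abs(qa - qb) / qb), 0.25)       # within Monte-Carlo error
})

test_that("summaries count extents and locate peaks on a hand-checked map", {
  mg <- tiny_montage()
  r <- structure(list(
    rho = matrix(0.3, 9, 2, dimnames = list(mg$labels, c("theta", "alpha"))),
    t = matrix(1, 9, 2, dimnames = list(mg$labels, c("theta", "alpha"))),
    t_tfce = matrix(c(5, 9, 3, rep(1, 6), rep(2, 9)), 9, 2,
                    dimnames = list(mg$labels, c("theta", "alpha"))),
    p = matrix(c(0.01, 0.001, 0.04, 0.06, 0.08, rep(0.5, 4), rep(0.2, 9)),
               9, 2, dimnames = list(mg$labels, c("theta", "alpha"))),
    null_max = 1:99 / 10, n = 52,
    params = tfce_params(n_perm = 150, seed = 1)),
    class = "tfce_result")
  s <- summarize_spatiospectral(r, alpha = 0.05)
  expect_equal(s$extent, c(3L, 0L))             # manual count below 0.05
  expect_equal(s$marginal, c(2L, 0L))           # 0.06 and 0.08
  expect_equal(s$peak_electrode[1], "E02")
  expect_equal(s$peak_p[1], 0.001)
  expect_equal(s$peak_t_tfce[1], 9)
})

test_that("negating the association flips t maps but not |t_tfce| or p", {
  mg <- tiny_montage()
  spec <- cohort_spec(n_id = 35, n_ctrl = 2, seed = 33,
                      effect_mask = list(ID = data.frame(electrode = "E05",
                                                         band = "theta")),
                      slope_per_isi_point = 0.004)
  ch <- generate_cohort_h(spec, mg, two_bands())
  i <- ch$cohort$group == "ID"
  sub <- h_matrix(unclass(ch$h)[i, , , drop = FALSE], condition = "EO")
  adj <- bin_adjacency(mg, 2)
  pars <- tfce_params(n_perm = 150, seed = 3)
  isi <- ch$cohort$isi[i]
  r1 <- tfce_correlation(sub, isi, adj = adj, params = pars)
  r2 <- tfce_correlation(sub, -isi, adj = adj, params = pars)
  expect_equal(r1$t, -r2$t, tolerance = 1e-10)
  expect_equal(abs(r1$t_tfce), abs(r2$t_tfce), tolerance = 1e-10)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
})
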