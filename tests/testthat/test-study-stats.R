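test_that("derived indices follow eta = G/H and Tiffeneau = FEV_0.1/FVC", {
  tab <- tibble::tibble(g_cmh2o_ml = 3.6, h_cmh2o_ml = 18,
                        fev01_ml = 0.75 * 1.2, fvc_ml = 1.2)
  out <- derive_indices(tab)
  expect_equal(out$eta, 0.2)
  expect_equal(out$tiffeneau, 0.75)

  tab$h_cmh2o_ml <- 0
  expect_error(derive_indices(tab), "domain error")
  expect_error(derive_indices(tibble::tibble(g_cmh2o_ml = 1)), "missing")
})

test_that("pearson_cor matches hand values and cor.test", {
  x <- c(1, 2, 3)
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_cor(x, -x)$r, -1)
  r <- pearson_cor(x, c(1, 2, 4))
  expect_equal(r$r, 3 / sqrt(2 * 14 / 3), tolerance = 1e-9)
  expect_equal(r$r, 0.98198, tolerance = 1e-4)

  set.seed(14)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- rnorm(n) + 0.5 * x
    ours <- pearson_cor(x, y)
    ref <- cor.test(x, y)
    expect_equal(ours$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$n, n)
  }
})

test_that("pearson_cor is symmetric and affine-equivariant", {
  set.seed(15)
  x <- rnorm(30); y <- rnorm(30) + x
  r <- pearson_cor(x, y)$r
  expect_equal(pearson_cor(y, x)$r, r, tolerance = 1e-12)
  expect_equal(pearson_cor(3 * x + 7, y)$r, r, tolerance = 1e-12)
  expect_equal(pearson_cor(x, -2 * y + 1)$r, -r, tolerance = 1e-12)

  expect_error(pearson_cor(1:2, 2:3), "insufficient")
  expect_error(pearson_cor(rep(1, 5), rnorm(5)), "degenerate")

  # complete-case pairing and subset filtering
  xm <- c(x, NA); ym <- c(y, 5)
  expect_equal(pearson_cor(xm, ym)$n, 30)
  expect_equal(pearson_cor(xm, ym, subset = c(rep(TRUE, 10), rep(FALSE, 21)))$n,
               10)
})

test_that("Sidak adjustment is exact, monotone and Bonferroni to first order", {
  expect_equal(sidak_adjust(0.2, 1), 0.2)
  expect_equal(sidak_adjust(0.05, 3), 1 - 0.95^3)
  expect_equal(sidak_adjust(0.05, 3), 0.142625)
  expect_equal(sidak_adjust(0, 10), 0)
  expect_equal(sidak_adjust(1, 5), 1)

  p <- seq(0, 1, by = 0.05)
  for (m in c(1, 2, 6, 20)) {
    expect_true(all(diff(sidak_adjust(p, m)) >= 0))
  }
  expect_true(all(sidak_adjust(0.03, 1:10) == cummax(sidak_adjust(0.03, 1:10))))
  for (pp in c(1e-5, 1e-3, 0.01)) {
    for (m in c(2, 5, 10)) {
      expect_lte(abs(sidak_adjust(pp, m) - m * pp), (m * pp)^2)
    }
  }
})

test_that("group summaries match a brute-force per-cell loop", {
  tab <- tibble::tibble(group = "a", week = 1, v = c(1, 2, 3))
  s <- group_summaries(tab, "v")
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$n, 3L)

  single <- group_summaries(tibble::tibble(group = "a", week = 1, v = 5), "v")
  expect_true(is.na(single$sd))

  set.seed(16)
  tab <- tibble::tibble(group = sample(c("a", "b"), 200, TRUE),
                        week = sample(c(0, 1, 5), 200, TRUE),
                        v = rnorm(200))
  s <- group_summaries(tab, "v")
  for (i in seq_len(nrow(s))) {
    cell <- tab$v[tab$group == s$group[i] & tab$week == s$week[i]]
    expect_equal(s$mean[i], sum(cell) / length(cell))
    expect_equal(s$n[i], length(cell))
    expect_equal(s$sd[i], sqrt(sum((cell - mean(cell))^2) / (length(cell) - 1)))
  }
})

test_that("correlation_table pools the requested group's endpoint rows", {
  tab <- derive_indices(simulate_study(study_design(seed = 5)))
  ct <- correlation_table(tab, data.frame(x = "non_aerated_ml",
                                          y = "serum_spd_ng_ml", m = 6))
  expect_equal(ct$n, 32)
  expect_gte(ct$adjusted_p, ct$p)
  ctc <- correlation_table(tab, data.frame(x = "non_aerated_ml",
                                           y = "serum_spd_ng_ml"),
                           group = "control")
  expect_equal(ctc$n, 24)
})

test_that("the delegated mixed model behaves sanely at the boundaries", {
  # strong simulated effect: detected
  fit <- fit_longitudinal_model(simulate_study(study_design(seed = 8)))
  expect_lt(fit$interaction_p, 0.05)
  expect_gte(fit$interaction_p, 0)

  # identical data in both groups: interaction estimate is null, p ~ 1
  tab <- simulate_study(study_design(seed = 9), trajectory_model(
    na_effect = 0, ae_dip = 0, ae_overshoot = 0))
  ctrl <- tab[tab$group == "control", ]
  mirrored <- ctrl
  mirrored$group <- "silica"
  mirrored$animal_id <- sub("C", "S", mirrored$animal_id)
  fit0 <- fit_longitudinal_model(rbind(ctrl, mirrored))
  expect_gt(fit0$interaction_p, 0.999)

  # Sidak-adjusted per-week contrasts are available on request
  fitc <- fit_longitudinal_model(simulate_study(study_design(seed = 8)),
                                 contrasts = TRUE)
  expect_true(!is.null(fitc$contrasts))

  expect_error(fit_longitudinal_model(tab[tab$group == "control", ]),
               "delegation error")
})
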