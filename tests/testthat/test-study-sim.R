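test_that("the default design reproduces the study bookkeeping", {
  d <- study_design()
  expect_equal(d$scan_weeks, c(0, 1, 2, 3, 4, 5, 7, 9, 11, 13, 15))
  tab <- simulate_study(d)
  # 6+6+6+6 control endpoint animals, all present at baseline
  expect_equal(sum(tab$week == 0 & tab$group == "control"), 24)
  # silica endpoint cohorts sum to 6+10+8+8 = 32
  end_rows <- !is.na(tab$endpoint_week) & tab$week == tab$endpoint_week
  expect_equal(sum(end_rows & tab$group == "silica"), 32)
  expect_equal(sum(end_rows & tab$group == "control"), 24)
  # endpoint readouts only at sacrifice rows
  expect_true(all(is.na(tab$ic_ml[!end_rows])))
  expect_true(all(!is.na(tab$ic_ml[end_rows])))
  # monotone missingness: no scans past sacrifice
  expect_true(all(tab$week <= tab$endpoint_week | is.na(tab$endpoint_week)))
  # per-animal counts: animal sacrificed at week 5 has scans 0..5 only
  w5 <- tab[tab$endpoint_week %in% 5, ]
  expect_true(all(tapply(w5$week, w5$animal_id, max) == 5))

  # scanned-only extras run the full schedule
  d2 <- study_design(extra_control = 2, extra_silica = 2, seed = 4)
  tab2 <- simulate_study(d2)
  extras <- tab2[is.na(tab2$endpoint_week), ]
  expect_equal(length(unique(extras$animal_id)), 4)
  expect_true(all(table(extras$animal_id) == length(d2$scan_weeks)))

  expect_error(study_design(endpoint_weeks = c(1, 6), n_control = c(6, 6),
                            n_silica = c(6, 6)), "subset")
})

test_that("identical seeds give bit-identical study tables", {
  a <- simulate_study(study_design(seed = 123))
  b <- simulate_study(study_design(seed = 123))
  expect_identical(a, b)
  c2 <- simulate_study(study_design(seed = 124))
  expect_false(identical(a$aerated_ml, c2$aerated_ml))
})

test_that("simulated trajectories show the disease shape", {
  # large scanned-only arms give tight longitudinal group means
  d <- study_design(extra_control = 60, extra_silica = 150, seed = 17)
  tab <- simulate_study(d)
  mn <- function(g, w, v) mean(tab[[v]][tab$group == g & tab$week == w])

  # non-aerated: week-1 peak over baseline and over control
  expect_gt(mn("silica", 1, "non_aerated_ml"), mn("silica", 0, "non_aerated_ml"))
  expect_gt(mn("silica", 1, "non_aerated_ml"), mn("control", 1, "non_aerated_ml"))
  for (w in c(5, 9, 15)) {
    expect_gt(mn("silica", w, "non_aerated_ml"),
              mn("control", w, "non_aerated_ml"))
  }
  # plateau: means at weeks 5..15 mutually within the between-animal SD
  traj <- trajectory_model()
  plateau <- sapply(c(5, 7, 9, 11, 13, 15),
                    function(w) mn("silica", w, "non_aerated_ml"))
  between_sd <- traj$na_effect * traj$na_plateau * traj$sd_severity
  expect_lt(diff(range(plateau)), between_sd)

  # aerated: transient dip then late overshoot
  expect_lt(mn("silica", 1, "aerated_ml"), mn("silica", 0, "aerated_ml"))
  expect_gt(mn("silica", 15, "aerated_ml"), mn("silica", 0, "aerated_ml"))

  # total volume strictly increasing weeks 1..15
  tot <- sapply(c(1, 2, 3, 4, 5, 7, 9, 11, 13, 15),
                function(w) mn("silica", w, "total_ml"))
  expect_true(all(diff(tot) > 0))

  # controls flat up to a small aging drift
  ctrl <- sapply(c(0, 5, 15), function(w) mn("control", w, "non_aerated_ml"))
  expect_lt(diff(range(ctrl)), 0.02)

  # mean lung density rises with disease
  expect_gt(mn("silica", 5, "mean_lung_density_hu"),
            mn("control", 5, "mean_lung_density_hu"))
})

test_that("endpoint links converge to their target correlations", {
  endp <- endpoint_model()
  big <- study_design(n_control = rep(50, 4), n_silica = rep(500, 4),
                      seed = 1)
  targets <- c(ic_ml = 0.6612, eta = 0.4027, tiffeneau = -0.7764,
               bal_protein_mg_ml = 0.5557, serum_spd_ng_ml = 0.8445,
               oh_proline_ug = 0.4187)
  xs <- c(ic_ml = "aerated_ml", eta = "total_ml",
          tiffeneau = "non_aerated_ml", bal_protein_mg_ml = "non_aerated_ml",
          serum_spd_ng_ml = "non_aerated_ml", oh_proline_ug = "non_aerated_ml")
  # average the n = 2000 sample correlation over a few replicates
  rs <- sapply(1:5, function(s) {
    tab <- derive_indices(simulate_study(
      study_design(n_control = rep(50, 4), n_silica = rep(500, 4), seed = s),
      endp = endp))
    ct <- correlation_table(tab, data.frame(x = unname(xs), y = names(xs)))
    stats::setNames(ct$r, ct$y)
  })
  for (nm in names(targets)) {
    expect_lt(abs(mean(rs[nm, ]) - targets[nm]), 0.03,
              label = paste("deviation of mean r for", nm))
  }
})

test_that("week-15 silica neutrophil fraction averages 20% of scored cells", {
  pcts <- sapply(1:60, function(s) {
    tab <- simulate_study(study_design(seed = s))
    w15 <- tab$group == "silica" & tab$week == 15 & !is.na(tab$neutrophil_pct)
    expect_equal(sum(w15), 8)
    mean(tab$neutrophil_pct[w15])
  })
  expect_lt(abs(mean(pcts) - 20), 2)
})

test_that("study tables round-trip through CSV", {
  tab <- simulate_study(study_design(seed = 2))
  path <- tempfile(fileext = ".csv")
  write_study_table(tab, path)
  back <- read_study_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)
  unlink(path)
})
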