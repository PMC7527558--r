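hu_vol <- function(values, voxel = 0.05) {
  calibrated_volume(array(values, c(length(values), 1, 1)), voxel)
}
full_voi <- function(vol) array(TRUE, dim(vol))

test_that("extract classifies at -223 HU with ties non-aerated", {
  v <- hu_vol(rep(-1000, 1000), voxel = 0.05)
  b <- extract_biomarkers(v, full_voi(v))
  expect_equal(b$aerated_volume, 1000 * 0.05^3 / 1000)
  expect_equal(b$aerated_volume, 1.25e-4)
  expect_equal(b$non_aerated_volume, 0)
  expect_equal(b$mean_lung_density, -1000)

  hus <- c(-1000, -900, -500, -300, -224, -223, -222, -100, 0, 50)
  v10 <- hu_vol(hus)
  b10 <- extract_biomarkers(v10, full_voi(v10))
  vv <- 0.05^3 / 1000
  expect_equal(b10$aerated_volume, 5 * vv)
  expect_equal(b10$non_aerated_volume, 5 * vv)
  expect_equal(b10$mean_lung_density, -341.9)

  # threshold above every voxel: everything aerated
  ball <- extract_biomarkers(v10, full_voi(v10), threshold = 1e6)
  expect_equal(ball$aerated_volume, ball$total_volume)
  expect_equal(ball$non_aerated_volume, 0)
})

test_that("aerated + non-aerated equals total exactly, always", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(50:500, 1)
    v <- hu_vol(runif(n, -1100, 200), voxel = runif(1, 0.05, 0.3))
    voi <- array(runif(n) < 0.8, dim(v))
    if (!any(voi)) next
    b <- extract_biomarkers(v, voi, threshold = runif(1, -800, 0))
    expect_identical(b$aerated_volume + b$non_aerated_volume, b$total_volume)
    expect_equal(b$total_volume, b$n_voxels * attr(v, "voxel_size")^3 / 1000)
    expect_gte(b$mean_lung_density, min(v[voi]))
    expect_lte(b$mean_lung_density, max(v[voi]))
  }
})

test_that("class volumes are monotone in the threshold with constant sum", {
  # aerated voxels are those strictly below the threshold, so raising the
  # threshold can only grow the aerated class and shrink the non-aerated one
  set.seed(8)
  v <- hu_vol(runif(2000, -1100, 100))
  voi <- full_voi(v)
  sweeps <- lapply(seq(-1000, 0, by = 50), function(th)
    extract_biomarkers(v, voi, th))
  aer <- vapply(sweeps, `[[`, numeric(1), "aerated_volume")
  naer <- vapply(sweeps, `[[`, numeric(1), "non_aerated_volume")
  tot <- vapply(sweeps, `[[`, numeric(1), "total_volume")
  expect_true(all(diff(aer) >= 0))
  expect_true(all(diff(naer) <= 0))
  expect_equal(tot, rep(tot[1], length(tot)))
})

test_that("doubling voxel size scales volumes by 8 and not density", {
  set.seed(9)
  hus <- runif(500, -1000, 100)
  b1 <- extract_biomarkers(hu_vol(hus, 0.1), full_voi(hu_vol(hus, 0.1)))
  b2 <- extract_biomarkers(hu_vol(hus, 0.2), full_voi(hu_vol(hus, 0.2)))
  expect_equal(b2$total_volume, 8 * b1$total_volume)
  expect_equal(b2$aerated_volume, 8 * b1$aerated_volume)
  expect_equal(b2$mean_lung_density, b1$mean_lung_density)
})

test_that("zero-noise phantoms are recovered exactly through the pipeline", {
  pspec <- small_pspec(noise_sd = 0, grid = 64)
  tspec <- thorax_spec(lung_volume_mL = 0.5, lesion_fraction = 0.2,
                       lung_hu = -500, lesion_hu = 0, seed = 6)
  m <- fit_hu_mapping(133, 9)
  th <- make_thorax_phantom(pspec, tspec, m)
  calib <- apply_hu_mapping(th$volume, m, pspec$voxel_size)
  b <- extract_biomarkers(calib, voi_from_labels(th$labels))
  expect_equal(b$aerated_volume, th$ground_truth$aerated_mL)
  expect_equal(b$non_aerated_volume, th$ground_truth$lesion_mL)
  expect_equal(b$total_volume, th$ground_truth$total_mL)
})

test_that("volumes survive 25 HU-equivalent noise to within 1%", {
  m <- fit_hu_mapping(133, 9)
  noise_gs <- 25 / m$slope  # ~3.1 grayscale units = 25 HU
  pspec <- phantom_spec(grid_shape = c(64, 64, 64), voxel_size = 0.3,
                        noise_sd = noise_gs, seed = 21)
  tspec <- thorax_spec(lung_volume_mL = 0.5, lesion_fraction = 0.2,
                       lung_hu = -500, lesion_hu = 30, seed = 6)
  th <- make_thorax_phantom(pspec, tspec, m)
  calib <- apply_hu_mapping(th$volume, m, pspec$voxel_size)
  b <- extract_biomarkers(calib, voi_from_labels(th$labels))
  expect_equal(b$aerated_volume, th$ground_truth$aerated_mL,
               tolerance = 0.01)
  expect_equal(b$non_aerated_volume, th$ground_truth$lesion_mL,
               tolerance = 0.01)
  expect_identical(b$total_volume, b$aerated_volume + b$non_aerated_volume)
})

test_that("label and slab VOIs implement the delineation rules", {
  th <- make_thorax_phantom(small_pspec(noise_sd = 0, grid = 64),
                            thorax_spec(lesion_fraction = 0.1, seed = 2))
  lab <- thorax_labels()
  voi <- voi_from_labels(th$labels)
  expect_equal(sum(voi), sum(th$labels == lab[["lung_aerated"]]) +
                 sum(th$labels == lab[["lesion"]]))
  expect_false(any(voi & th$labels == lab[["heart_vessels"]]))

  aer_only <- voi_from_labels(th$labels, include = "lung_aerated",
                              exclude = integer(0))
  expect_equal(sum(aer_only), sum(th$labels == lab[["lung_aerated"]]))

  # slab covering everything equals the label VOI
  nz <- dim(th$labels)[3]
  expect_equal(sum(voi_from_slab(th$labels, 1, nz)), sum(voi))
  half <- voi_from_slab(th$labels, 1, nz %/% 2)
  expect_lte(sum(half), sum(voi))
  # single-slice slab counts that slice's lung voxels (brute force per slice)
  k <- nz %/% 2
  one <- voi_from_slab(th$labels, k, k + 1)
  expect_equal(sum(one), sum(voi[, , k:(k + 1)]))

  expect_error(voi_from_slab(th$labels, 30, 10), "range error")
  all_tissue <- th$labels
  all_tissue[all_tissue == lab[["background"]]] <- lab[["soft_tissue"]]
  expect_error(voi_from_labels(all_tissue, include = "background"),
               "empty VOI")
  expect_error(voi_from_labels(th$labels, include = "lesion",
                               exclude = "lesion"), "overlap")
})

test_that("misaligned or uncalibrated inputs are rejected", {
  v <- hu_vol(rep(-500, 10))
  expect_error(extract_biomarkers(v, array(TRUE, c(5, 1, 1))), "alignment")
  expect_error(extract_biomarkers(array(-500, c(10, 1, 1)), full_voi(v)),
               "calibrated_volume")
})

test_that("longitudinal table assembly enforces keys and round-trips CSV", {
  v <- hu_vol(runif(100, -900, 0))
  b <- extract_biomarkers(v, full_voi(v))
  recs <- list(
    list(animal = "A1", group = "control", week = 0, biomarkers = b),
    list(animal = "A1", group = "control", week = 1, biomarkers = b),
    list(animal = "A2", group = "silica", week = 0, biomarkers = b))
  tab <- longitudinal_table(recs)
  expect_equal(nrow(tab), 3)

  expect_error(longitudinal_table(c(recs, recs[1])), "integrity")

  path <- tempfile(fileext = ".csv")
  readr::write_csv(tab, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)
  unlink(path)
})
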