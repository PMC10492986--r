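test_that("tissue_mask handles degenerate and clean inputs", {
  zero <- matrix(0, 32, 32)
  m <- tissue_mask(zero, threshold = 0.5)
  expect_false(any(m))
  expect_identical(attr(m, "flags"), "empty_tissue_mask")

  img <- matrix(0, 32, 32)
  img[8:24, 8:24] <- 100
  m2 <- tissue_mask(img, threshold = 200)   # above image max
  expect_false(any(m2))
  expect_length(attr(tissue_mask(img), "flags"), 0)

  # phantom body: Otsu mask area within 1% of the drawn body pixel count
  ph <- generate_phantom(tiny_phantom_spec(background_noise_sd = 0.03, seed = 2L))
  m3 <- tissue_mask(ph$stack$combined_signal[, , 1])
  drawn <- sum(ph$truth$labels[, , 1] != 0L)
  expect_lt(abs(sum(m3) - drawn) / drawn, 0.01)

  expect_error(tissue_mask(matrix(c(1, NA), 2, 2)),
               class = "bodycomp3_validation_error")
})

test_that("tissue_mask drops lateral components and fills small holes", {
  img <- matrix(0, 48, 48)
  img[10:40, 10:30] <- 100         # body
  img[20:25, 40:45] <- 100         # disconnected lateral component (arm)
  img[20:22, 15:17] <- 0           # small enclosed hole
  m <- tissue_mask(img, threshold = 50, max_hole_area = 100)
  expect_false(any(m[20:25, 40:45]))
  expect_true(all(m[20:22, 15:17]))
  # hole above the fill limit stays open
  m2 <- tissue_mask(img, threshold = 50, max_hole_area = 5)
  expect_false(any(m2[20:22, 15:17]))
})

test_that("fat_mask is the thresholded fat fraction within tissue", {
  ph <- generate_phantom(tiny_phantom_spec())
  ff <- ph$stack$fat_fraction[, , 1]
  tis <- ph$truth$labels[, , 1] != 0L
  expect_identical(fat_mask(ff, tis, 0), tis)             # threshold 0
  expect_false(any(fat_mask(ff, tis, 1)))                 # above max ff 0.85
  # noise-free ring at ff 0.85 + blob 0.8, threshold 0.5 -> exactly fat labels
  expect_identical(fat_mask(ff, tis, 0.5), ph$truth$labels[, , 1] >= 2L)
  expect_error(fat_mask(ff, tis, 1.5), class = "bodycomp3_validation_error")
  expect_error(fat_mask(ff, matrix(FALSE, 96, 96)),
               class = "bodycomp3_validation_error")
})

test_that("radial tracing recovers annulus radii within one pixel at every ray", {
  ph <- generate_phantom(annulus_spec())
  fat <- ph$truth$labels[, , 1] == 2L
  tis <- ph$truth$labels[, , 1] != 0L
  bnd <- trace_subcutaneous_boundaries(fat, tis, n_rays = 360L)
  # true radii in pixels: outer 150/3 = 50, inner 120/3 = 40
  expect_lte(max(abs(bnd$r_outer - 50)), 1)
  expect_lte(max(abs(bnd$r_inner - 40)), 1)
  expect_length(bnd$flags, 0)
})

test_that("fat filling the whole body collapses the inner boundary (flagged)", {
  ph <- generate_phantom(annulus_spec(interior_ff = 0.9))  # no visceral cavity
  fat <- ph$stack$fat_fraction[, , 1] >= 0.5
  tis <- ph$truth$labels[, , 1] != 0L
  bnd <- trace_subcutaneous_boundaries(fat, tis)
  expect_true("no_visceral_cavity" %in% bnd$flags)
  sm <- split_compartments(fat, tis, bnd)
  expect_lt(sum(sm$vat_mask) / sum(fat), 0.01)
})

test_that("a 10-degree gap in the ring is interpolated across", {
  ph <- generate_phantom(annulus_spec())
  fat <- ph$truth$labels[, , 1] == 2L
  tis <- ph$truth$labels[, , 1] != 0L
  cen <- colMeans(which(tis, arr.ind = TRUE))
  ang <- atan2(row(fat) - cen[1], col(fat) - cen[2])
  fat_gap <- fat & !(ang > 0 & ang < (10 * pi / 180))
  bnd <- trace_subcutaneous_boundaries(fat_gap, tis, n_rays = 360L)
  expect_gt(bnd$n_missing, 0)
  # interpolated boundaries keep the ring radii sensible across the gap
  # (rays clipping the wedge edge may be off; the bulk must stay tight)
  expect_lt(unname(quantile(abs(bnd$r_inner - 40), 0.95)), 2)
  sm <- split_compartments(fat_gap, tis, bnd)
  expect_lt(abs(sum(sm$sat_mask) - sum(fat_gap)) / sum(fat_gap), 0.03)
})

test_that("split_compartments assigns ring to SAT, blobs to VAT, boundary to SAT", {
  ph <- generate_phantom(tiny_phantom_spec())
  lab <- ph$truth$labels[, , 1]
  fat <- lab >= 2L
  tis <- lab != 0L
  sm <- split_compartments(fat, tis, trace_subcutaneous_boundaries(fat, tis))
  expect_false(any(sm$sat_mask & sm$vat_mask))            # disjoint
  expect_true(all(fat[sm$sat_mask | sm$vat_mask]))        # subset of fat
  # generator labels as oracle: every blob pixel VAT, every ring pixel SAT
  expect_gt(sum(sm$vat_mask & lab == 3L) / sum(lab == 3L), 0.95)
  expect_gt(sum(sm$sat_mask & lab == 2L) / sum(lab == 2L), 0.95)

  # stated convention: a fat pixel exactly on the inner boundary is SAT
  n <- 11L
  all_fat <- matrix(TRUE, n, n)
  bnd <- structure(class = "sat_boundaries", list(
    angles = seq(0, 2 * pi, length.out = 73L)[-73L],
    r_outer = rep(5, 72L), r_inner = rep(3, 72L), centroid = c(6, 6),
    flags = character()))
  sm2 <- split_compartments(all_fat, all_fat, bnd)
  expect_true(sm2$sat_mask[6, 9])     # distance exactly 3 -> SAT
  expect_true(sm2$vat_mask[6, 8])     # distance 2 -> VAT
  bad <- bnd; bad$r_inner <- rep(-1, 72L)
  expect_error(split_compartments(all_fat, all_fat, bad),
               class = "bodycomp3_validation_error")
})

test_that("volumes sums masks to liters and enforces the NAT identity", {
  # 1 slice, 1000 SAT pixels of 3x3x10 mm -> 0.09 L
  m <- matrix(FALSE, 50, 50)
  m[1:40, 1:25] <- TRUE             # exactly 1000 pixels
  sm <- structure(class = "slice_masks", list(
    tissue_mask = m, fat_mask = m, sat_mask = m,
    vat_mask = matrix(FALSE, 50, 50), boundaries = NULL, flags = character()))
  res <- volumes(list(sm), c(3, 3, 10))
  expect_equal(res$sat_volume_l, 0.09, tolerance = 1e-12)

  empty <- structure(class = "slice_masks", list(
    tissue_mask = m, fat_mask = matrix(FALSE, 50, 50),
    sat_mask = matrix(FALSE, 50, 50), vat_mask = matrix(FALSE, 50, 50),
    boundaries = NULL, flags = character()))
  res2 <- volumes(list(empty), c(3, 3, 10))
  expect_equal(res2$sat_volume_l, 0)
  expect_equal(res2$nat_volume_l, res2$total_tissue_volume_l)

  bad <- sm; bad$tissue_mask <- matrix(TRUE, 10, 10)
  expect_error(volumes(list(sm, bad), c(3, 3, 10)),
               class = "bodycomp3_validation_error")
})

test_that("multi-slice phantom volumes recover ground truth within 5%", {
  ph <- generate_phantom(phantom_spec(
    slice_count = 3L, image_size = 112L, voxel_dims = c(3.5, 3.5, 10),
    outer_semiaxes = c(160, 120), sat_thickness = 30, sat_asymmetry = 0.2,
    inner_lobes = list(n = 5L, amp_mm = 8),
    vat_blobs = list(list(center = c(30, 10), radius = 24, fat_fraction = 0.8),
                     list(center = c(-45, -15), radius = 18, fat_fraction = 0.75)),
    slice_scale = c(0.95, 1, 0.97)))
  seg <- segment_stack(ph$stack)
  expect_lt(abs(seg$sat_volume_l - ph$truth$sat_volume_l) / ph$truth$sat_volume_l, 0.05)
  expect_lt(abs(seg$vat_volume_l - ph$truth$vat_volume_l) / ph$truth$vat_volume_l, 0.05)
  expect_equal(seg$total_tissue_volume_l,
               seg$sat_volume_l + seg$vat_volume_l + seg$nat_volume_l,
               tolerance = 1e-12)
})

test_that("recovery holds on noisy phantoms and under rotation", {
  base <- generate_phantom(tiny_phantom_spec(seed = 9L))
  noisy <- generate_phantom(tiny_phantom_spec(background_noise_sd = 0.05, seed = 9L))
  seg_n <- segment_stack(noisy$stack)
  expect_lt(abs(seg_n$sat_volume_l - noisy$truth$sat_volume_l) /
              noisy$truth$sat_volume_l, 0.10)
  expect_lt(abs(seg_n$vat_volume_l - noisy$truth$vat_volume_l) /
              noisy$truth$vat_volume_l, 0.10)

  rot_spec <- function(rot) phantom_spec(
    slice_count = 1L, image_size = 128L, voxel_dims = c(3, 3, 10),
    outer_semiaxes = c(160, 120), sat_thickness = 28,
    vat_blobs = list(list(center = c(30, 10), radius = 26, fat_fraction = 0.8)),
    rotation_deg = rot)
  seg0 <- segment_stack(generate_phantom(rot_spec(0))$stack)
  seg30 <- segment_stack(generate_phantom(rot_spec(30))$stack)
  expect_lt(abs(seg30$sat_volume_l - seg0$sat_volume_l) / seg0$sat_volume_l, 0.02)
  expect_lt(abs(seg30$vat_volume_l - seg0$vat_volume_l) / seg0$vat_volume_l, 0.02)
})

test_that("raising the fat-fraction threshold never increases volumes", {
  ph <- generate_phantom(tiny_phantom_spec(background_noise_sd = 0.05, seed = 4L))
  prev <- c(Inf, Inf, Inf)
  for (thr in c(0.3, 0.5, 0.7)) {
    seg <- segment_stack(ph$stack, ff_threshold = thr)
    fatv <- seg$sat_volume_l + seg$vat_volume_l
    cur <- c(fatv, seg$sat_volume_l, seg$vat_volume_l)
    expect_true(all(cur <= prev + 1e-12))
    prev <- cur
  }
})

test_that("label maps and per-slice areas are written", {
  ph <- generate_phantom(tiny_phantom_spec())
  seg <- segment_stack(ph$stack)
  dir <- withr::local_tempdir()
  paths <- write_segmentation(seg, dir)
  lab <- read_nifti(paths[["labels"]])$img
  expect_setequal(unique(as.vector(lab)), 0:3)
  areas <- read.csv(paths[["areas"]])
  expect_equal(sum(areas$sat_mm2) * seg$voxel_dims[3] / 1e6, seg$sat_volume_l,
               tolerance = 1e-9)
})
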