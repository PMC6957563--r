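# ROI statistics and volume integration.

test_that("PSC interaction F equals the squared paired t on the contrast", {
  d <- design_spec(n_subjects = 21)
  psc <- gen_psc(d, psc_model_params(), stats::rnorm(21, 69, 50), 10)
  an <- psc_interaction_test(psc, phase = "I")
  one <- psc[psc$phase == "I", ]
  nn <- net_neg_int(one, value = "psc")
  tt <- paired_t(nn$per_subject$net, rep(0, 21))
  fi <- an[an$effect == "polarity:probe_type", ]
  expect_equal(fi$F, tt$t^2, tolerance = 1e-10)
  expect_equal(fi$p, tt$p, tolerance = 1e-10)

  # identical cells per subject -> all F = 0
  flat <- one
  flat$psc <- ave(flat$psc, flat$subject)
  an0 <- psc_interaction_test(flat)
  expect_true(all(an0$F < 1e-18))
})

test_that("stronger built-in interactions are rejected more often", {
  d <- design_spec(n_subjects = 21)
  rate <- function(extra) {
    cm <- default_psc_cell_means()
    cm$mean[cm$polarity == "negative" & cm$probe_type == "linguistic"] <-
      0.20 + extra
    rej <- 0
    for (i in 1:40) {
      psc <- gen_psc(d, psc_model_params(cell_means = cm, rho = 0),
                     stats::rnorm(21, 69, 50), 600 + i)
      an <- psc_interaction_test(psc, phase = "I")
      if (an$p[an$effect == "polarity:probe_type"] <= 0.05) rej <- rej + 1
    }
    rej / 40
  }
  r <- c(rate(0), rate(0.05), rate(0.12))
  expect_true(all(diff(r) >= 0))
  expect_gt(r[3], 0.9)
})

test_that("behavior-BOLD correlation matches hand cases", {
  expect_equal(behavior_bold_correlation(c(1, 2, 3, 4), c(1, 2, 3, 4))$r, 1)
  expect_equal(behavior_bold_correlation(c(1, 2, 3, 4), c(2, 4, 6, 8))$r, 1)
  expect_equal(behavior_bold_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4))$r, 0.8,
               tolerance = 1e-12)
  expect_warning(r0 <- behavior_bold_correlation(c(1, 1, 1), c(1, 2, 3)),
                 "zero variance")
  expect_true(r0$degenerate)
  # one-tailed p is half the two-tailed p for a positive r
  a <- c(1, 2, 3, 5, 4, 6); b <- c(2, 1, 4, 5, 6, 5)
  p1 <- behavior_bold_correlation(a, b, tail = "greater")$p
  p2 <- behavior_bold_correlation(a, b, tail = "two.sided")$p
  expect_equal(p1, p2 / 2, tolerance = 1e-12)
})

test_that("conjunction implements voxelwise AND with grid checks", {
  a <- gen_volume(c(8, 8, 8), blobs = list(
    list(type = "box", lower = c(0, 0, 0), upper = c(3, 3, 0))))
  expect_equal(attr(conjunction(a, a), "count"), sum(a$data))

  b <- gen_volume(c(8, 8, 8), blobs = list(
    list(type = "box", lower = c(5, 5, 5), upper = c(7, 7, 7))))
  expect_equal(attr(conjunction(a, b), "count"), 0)

  c3 <- gen_volume(c(8, 8, 8), blobs = list(
    list(type = "box", lower = c(2, 2, 0), upper = c(4, 2, 0))))  # shares 2 voxels
  shared <- sum(a$data * c3$data)
  expect_equal(attr(conjunction(a, c3), "count"), shared)

  other <- gen_volume(c(9, 8, 8))
  expect_error(conjunction(a, other), "incompatible grids")
})

test_that("overlap fractions reproduce constructed fixtures", {
  # A: 10 voxels, F: 20 voxels, sharing exactly 5 at 1 mm
  A <- gen_volume(c(20, 20, 20), blobs = list(
    list(type = "box", lower = c(0, 0, 0), upper = c(9, 0, 0))))   # 10 voxels
  F_ <- gen_volume(c(20, 20, 20), blobs = list(
    list(type = "box", lower = c(5, 0, 0), upper = c(14, 1, 0))))  # 20 voxels
  ov <- overlap_fractions(F_, A, target_res = 1)
  expect_equal(ov$n_shared, 5)
  expect_equal(ov$pct_anatomical, 50)
  expect_equal(ov$pct_functional, 25)

  ident <- overlap_fractions(A, A)
  expect_equal(ident$pct_anatomical, 100)
  expect_equal(ident$pct_functional, 100)

  B <- gen_volume(c(20, 20, 20), blobs = list(
    list(type = "box", lower = c(0, 10, 10), upper = c(9, 10, 10))))
  dis <- overlap_fractions(F_, B)
  expect_equal(dis$pct_anatomical, 0)
  expect_equal(dis$pct_functional, 0)

  expect_error(overlap_fractions(gen_volume(c(5, 5, 5)), A), "empty mask")
})

test_that("overlap is symmetric with percents exchanged", {
  A <- gen_volume(c(15, 15, 15), blobs = list(
    list(type = "sphere", center = c(5, 5, 5), radius = 3)))
  F_ <- gen_volume(c(15, 15, 15), blobs = list(
    list(type = "sphere", center = c(7, 5, 5), radius = 4)))
  o1 <- overlap_fractions(F_, A)
  o2 <- overlap_fractions(A, F_)
  expect_equal(o1$pct_anatomical, o2$pct_functional)
  expect_equal(o1$pct_functional, o2$pct_anatomical)
})

test_that("nearest-neighbor resampling approximately conserves mask volume", {
  s <- gen_volume(c(12, 12, 12), affine = diag(c(2, 2, 2, 1)), blobs = list(
    list(type = "sphere", center = c(5.5, 5.5, 5.5), radius = 3.7)))
  r <- resample_volume(s, 1)
  v_in <- sum(s$data != 0) * 8
  v_out <- sum(r$data != 0) * 1
  expect_lt(abs(v_out - v_in) / v_in, 0.10)
})

test_that("peak probability reads the documented voxel", {
  m <- gen_volume(c(10, 10, 10))
  m$data[4, 5, 6] <- 0.91  # 0-based (3, 4, 5)
  expect_equal(peak_probability(c(3, 4, 5), m), 0.91)
  expect_equal(peak_probability(c(0, 0, 0), m), 0)
  # boundary at index 3.5 rounds half-up to voxel 4 (0-based)
  m$data[5, 5, 6] <- 0.2
  expect_equal(peak_probability(c(3.5, 4, 5), m), 0.2)
  expect_error(peak_probability(c(50, 0, 0), m), "outside the grid")
})

test_that("center of mass is the weighted voxel-center mean", {
  single <- gen_volume(c(6, 6, 6), blobs = list(
    list(type = "voxels", index = rbind(c(2, 3, 4)))))
  expect_equal(center_of_mass(single), c(2, 3, 4))

  two <- gen_volume(c(12, 6, 6), blobs = list(
    list(type = "voxels", index = rbind(c(0, 0, 0), c(10, 0, 0)))))
  expect_equal(center_of_mass(two)[1], 5)

  w <- gen_volume(c(6, 6, 6))
  w$data[1, 1, 1] <- 1; w$data[5, 1, 1] <- 3  # x = 0 (w 1), x = 4 (w 3)
  expect_equal(center_of_mass(w)[1], 3)

  # translation equivariance
  t_aff <- diag(4); t_aff[1:3, 4] <- c(10, -5, 2)
  wt <- volume_grid(w$data, t_aff)
  expect_equal(center_of_mass(wt), center_of_mass(w) + c(10, -5, 2))

  expect_error(center_of_mass(gen_volume(c(3, 3, 3))), "all-zero")
})

test_that("threshold_roi masks by probability with support semantics", {
  m <- gen_volume(c(3, 1, 1))
  m$data[, 1, 1] <- c(0.2, 0.5, 0.9)
  expect_equal(sum(threshold_roi(m, 0.4)$data), 2)
  expect_equal(sum(threshold_roi(m, 0)$data), 3)   # support of the map
  expect_warning(empty <- threshold_roi(m, 0.95), "empty mask")
  expect_equal(sum(empty$data), 0)
})

test_that("volumes round-trip through NIfTI with their affine", {
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- c(-20, -30, -15)
  v <- volume_grid(array(runif(4 * 5 * 6), c(4, 5, 6)), aff)
  tf <- tempfile(fileext = ".nii")
  write_volume(v, tf)
  v2 <- read_volume(tf)
  expect_equal(dim(v2$data), dim(v$data))
  expect_equal(v2$data, v$data, tolerance = 1e-6)
  expect_equal(v2$affine, v$affine, tolerance = 1e-5, ignore_attr = TRUE)
  unlink(tf)
})

test_that("the correlation stage recovers the generator's coupling", {
  d <- design_spec(n_subjects = 400)
  beh <- stats::rnorm(400, 69, 50)
  psc <- gen_psc(d, psc_model_params(rho = 0.6), beh, 12)
  r <- behavior_bold_correlation(beh, psc_net_effects(psc, "II"))
  expect_lt(abs(r$r - 0.6), 0.1)
})
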