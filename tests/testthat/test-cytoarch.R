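# GLI profiles, feature vectors, the sliding Mahalanobis procedure,
# volumetry and probabilistic maps.

test_that("extract_profiles honors geometry and the count contract", {
  img <- matrix(0.4, 120, 200)
  contours <- list(outer = cbind(x = c(20, 160), y = c(20, 20)),
                   inner = cbind(x = c(20, 160), y = c(100, 100)))
  pf <- extract_profiles(img, contours, spacing = 14)  # L = 140 -> 11 profiles
  expect_equal(nrow(pf), floor(140 / 14) + 1)
  expect_true(all(abs(pf - 0.4) < 1e-12))

  pf2 <- extract_profiles(img, contours, spacing = 13)  # floor(140/13)+1 = 11
  expect_equal(nrow(pf2), 11)

  bad <- list(outer = cbind(x = c(20, 160), y = c(2, 2)),
              inner = cbind(x = c(20, 160), y = c(119, 200)))
  expect_error(extract_profiles(img, bad, spacing = 14), "leaves the image")
})

test_that("profile features match hand-computed moments", {
  f <- profile_features(c(0, 0, 1, 0, 0))
  expect_equal(unname(f[1, "amp.mean"]), 0.2)
  expect_equal(unname(f[1, "amp.centroid"]), 50)
  expect_equal(unname(f[1, "amp.sd"]), 0)
  expect_equal(unname(f[1, "amp.skew"]), 0)
  expect_equal(unname(f[1, "der.mean"]), 0.008)
  expect_equal(unname(f[1, "der.centroid"]), 50)
  expect_equal(unname(f[1, "der.sd"]), 25)
  expect_equal(unname(f[1, "der.skew"]), 0)
  expect_equal(unname(f[1, "der.kurt"]), 1)

  # symmetric unimodal profile: centroid at 50% depth, no skew
  d <- seq(0, 100, length.out = 101)
  sym <- exp(-(d - 50)^2 / (2 * 15^2))
  fs <- profile_features(sym)
  expect_equal(unname(fs[1, "amp.centroid"]), 50, tolerance = 1e-6)
  expect_equal(unname(fs[1, "amp.skew"]), 0, tolerance = 1e-6)

  # constant profile: derivative moments collapse to zero, amplitude defined
  fc <- profile_features(rep(0.3, 50))
  expect_equal(unname(fc[1, "amp.mean"]), 0.3)
  expect_equal(unname(fc[1, "der.mean"]), 0)
  expect_equal(unname(fc[1, "der.sd"]), 0)
})

test_that("standardized features ignore amplitude rescaling and are idempotent", {
  set.seed(5)
  prof <- matrix(runif(30 * 60, 0.2, 0.8), 30)
  f1 <- standardize_features(profile_features(prof))
  f2 <- standardize_features(profile_features(prof * 1.7))
  expect_equal(f1, f2, tolerance = 1e-9)
  expect_equal(standardize_features(f1), f1, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("sliding Mahalanobis matches hand computation in one dimension", {
  X <- matrix(c(0, 0, 1, 1, 1, 2), ncol = 1)
  suppressWarnings(dp <- sliding_mahalanobis(X, 3))
  expect_equal(dp$position, 4)
  # pooled var = ((2)(1/3)+(2)(1/3))/4 = 1/3; D2 = 1 / (1/3) = 3
  expect_equal(dp$d2, 3, tolerance = 1e-12)
})

test_that("identical blocks give D2 = 0", {
  set.seed(3)
  block <- matrix(rnorm(5 * 3), 5, 3)
  X <- rbind(block, block)
  suppressWarnings(dp <- sliding_mahalanobis(X, 5))
  expect_equal(dp$d2[dp$position == 6], 0, tolerance = 1e-12)
})

test_that("sliding Mahalanobis equals the brute-force reference", {
  set.seed(11)
  X <- matrix(rnorm(40 * 6), 40, 6)
  X[21:40, 1] <- X[21:40, 1] + 2
  dp <- sliding_mahalanobis(X, 10)
  ref <- naive_sliding_mahalanobis(X, 10)
  expect_equal(dp$position, ref$position)
  expect_lt(max(abs(dp$d2 - ref$d2) / pmax(abs(ref$d2), 1e-12)), 1e-10)
})

test_that("D2 at the border grows with template separation", {
  base <- gli_template(seq(0, 100, length.out = 100), "granular")
  other <- gli_template(seq(0, 100, length.out = 100), "dysgranular")
  d2_at_border <- sapply(c(0.25, 0.5, 1), function(s) {
    mix <- (1 - s) * base + s * other
    spec <- histology_phantom_spec(templates = list("granular", mix),
                                   noise_sd = 0.05)
    ph <- gen_histology_phantom(spec, 99)  # same seed: noise field fixed
    ft <- standardize_features(profile_features(
      extract_profiles(ph$image, ph$contours, ph$spacing)))
    dp <- sliding_mahalanobis(ft, 12)
    dp$d2[dp$position == 41]
  })
  expect_true(all(diff(d2_at_border) > 0))
})

test_that("border detection recovers one and two template switches", {
  ph <- gen_histology_phantom(histology_phantom_spec(), 11)
  ft <- profile_features(extract_profiles(ph$image, ph$contours, ph$spacing))
  bc <- find_borders(ft)
  expect_equal(nrow(bc), 1)
  expect_lte(abs(bc$position - 41), 2)

  spec2 <- histology_phantom_spec(
    templates = list("granular", "dysgranular", "granular"),
    borders = c(30, 55))
  ph2 <- gen_histology_phantom(spec2, 17)
  ft2 <- profile_features(extract_profiles(ph2$image, ph2$contours, ph2$spacing))
  bc2 <- find_borders(ft2)
  expect_equal(nrow(bc2), 2)
  expect_true(!is.unsorted(bc2$position))
  expect_lte(abs(bc2$position[1] - 30), 2)
  expect_lte(abs(bc2$position[2] - 55), 2)

  # homogeneous phantom: empty call set is the expected outcome
  ph0 <- gen_histology_phantom(
    histology_phantom_spec(templates = list("granular"), borders = integer(0)), 23)
  ft0 <- profile_features(extract_profiles(ph0$image, ph0$contours, ph0$spacing))
  expect_equal(nrow(find_borders(ft0)), 0)
})

test_that("GLI images survive a 16-bit TIFF round trip", {
  ph <- gen_histology_phantom(histology_phantom_spec(width_px = 60, height_px = 40,
                                                     ribbon_top = 6, ribbon_bottom = 35,
                                                     n_traverses = 5, margin_px = 5,
                                                     borders = 3L), 2)
  tf <- tempfile(fileext = ".tif")
  write_gli_image(ph$image, tf)
  img2 <- read_gli_image(tf)
  expect_equal(dim(img2), dim(ph$image))
  expect_lt(max(abs(unclass(img2) - unclass(ph$image))), 1 / 65535 + 1e-6)
  unlink(tf)
})

test_that("Cavalieri volumes follow the section arithmetic", {
  expect_equal(area_volume(10, thickness_um = 1000, interval = 1, shrinkage = 1), 10)
  v1 <- area_volume(c(2, 4), thickness_um = 20, interval = 15, shrinkage = 1)
  expect_equal(area_volume(c(2, 4), thickness_um = 20, interval = 15, shrinkage = 2),
               2 * v1)
  expect_equal(area_volume(c(1, 2, 3), thickness_um = 20, interval = 15), 1.8)
  expect_error(area_volume(numeric(0)), class = "negmap_invalid_parameter")
})

test_that("probabilistic maps count overlap and conserve volume", {
  base <- gen_volume(c(10, 10, 10), blobs = list(
    list(type = "box", lower = c(2, 2, 2), upper = c(6, 6, 6))))
  masks <- c(replicate(9, base, simplify = FALSE), list(gen_volume(c(10, 10, 10))))
  masks[[10]]$data[4:8, 4:8, 4:8] <- 1  # shifted by one voxel
  pm <- build_prob_map(masks)
  expect_equal(pm$data[3, 3, 3], 0.9)       # present in 9 of 10
  expect_equal(pm$data[4, 4, 4], 1)         # present in all ten
  vox_vol <- abs(det(pm$affine[1:3, 1:3]))
  mean_vol <- mean(sapply(masks, function(m) sum(m$data != 0) * vox_vol))
  expect_identical(sum(pm$data) * vox_vol, mean_vol)  # conservation, exact

  ident <- build_prob_map(replicate(10, base, simplify = FALSE))
  expect_true(all(ident$data[base$data != 0] == 1))

  shifted <- volume_grid(base$data, diag(c(2, 1, 1, 1)))
  expect_error(build_prob_map(list(base, shifted)), "not aligned")
})

test_that("asymmetry test behaves like a calibrated paired t", {
  expect_equal(asymmetry_test(c(400, 420, 410), c(400, 420, 410))$t, 0)
  expect_equal(asymmetry_test(c(400, 420, 410), c(400, 420, 410))$p, 1)
  l <- c(421, 350, 500, 390, 460); r <- c(354, 330, 480, 410, 420)
  expect_equal(asymmetry_test(l, r)$t, -asymmetry_test(r, l)$t)

  set.seed(100)
  rej <- 0; nsim <- 400
  for (i in seq_len(nsim)) {
    L <- rnorm(10, 420, 140); R <- L + rnorm(10, 0, 60)
    if (asymmetry_test(L, R)$p <= 0.05) rej <- rej + 1
  }
  expect_gte(rej / nsim, 0.02)
  expect_lte(rej / nsim, 0.09)
})
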