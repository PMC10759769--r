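test_that("region profiles reproduce the reported means at full separation", {
  p <- make_region_profiles(separation = 1, noise_scale = 1)
  expect_named(p, c("Talesh", "Langarud", "Rasht"))
  expect_equal(p$Langarud$physchem_means[["ssc"]], 20.96)
  expect_equal(p$Langarud$physchem_means[["ta"]], 0.55)
  expect_equal(p$Rasht$physchem_means[["firmness"]], 1.20)
  expect_equal(p$Talesh$physchem_means[["ph"]], 3.83)
  expect_equal(region_codes(c("Talesh", "Langarud", "Rasht")), 1:3)
})

test_that("separation interpolates toward the grand mean and orders sensor gains", {
  p0 <- make_region_profiles(separation = 0)
  grand_ssc <- (20.96 + 18.63 + 17.40) / 3
  for (lbl in region_labels()) {
    expect_equal(p0[[lbl]]$physchem_means[["ssc"]], grand_ssc)
  }
  gains0 <- sapply(p0, function(x) x$sensor_gain)
  expect_true(all(abs(gains0[, "Langarud"] - gains0[, "Rasht"]) < 1e-12))

  p1 <- make_region_profiles(separation = 1)
  gains1 <- sapply(p1, function(x) x$sensor_gain)
  expect_true(all(gains1[, "Langarud"] >= gains1[, "Talesh"]))
  expect_true(all(gains1[, "Langarud"] >= gains1[, "Rasht"]))

  expect_error(make_region_profiles(separation = -1), "non-negative")
  expect_error(make_region_profiles(noise_scale = -0.1), "non-negative")
})

test_that("physicochemical sampling enforces the BAR identity and truncation", {
  p <- make_region_profiles(separation = 1, noise_scale = 0)
  set.seed(1)
  r <- sample_physchem(p$Langarud)
  expect_equal(r[["ssc"]], 20.96)
  expect_equal(r[["ta"]], 0.55)
  expect_equal(r[["bar"]], 20.96 / 0.55)
  expect_silent(validate_physchem(r))

  pn <- make_region_profiles(separation = 1, noise_scale = 1)
  set.seed(7)
  for (i in 1:50) {
    rec <- sample_physchem(pn[[sample(region_labels(), 1)]])
    expect_lt(abs(rec[["bar"]] * rec[["ta"]] - rec[["ssc"]]), 1e-9)
    expect_true(all(rec > 0))
    expect_true(rec[["ph"]] >= 2 && rec[["ph"]] <= 7)
  }
  # identical RNG state gives identical records
  set.seed(123); a <- sample_physchem(pn$Rasht)
  set.seed(123); b <- sample_physchem(pn$Rasht)
  expect_identical(a, b)
  # truncation floors extreme draws at 10% of the mean
  px <- make_region_profiles(separation = 1, noise_scale = 50)
  set.seed(5)
  recs <- replicate(40, sample_physchem(px$Talesh))
  expect_true(all(recs[setdiff(rownames(recs), "bar"), ] >=
                    0.1 * px$Talesh$physchem_means[setdiff(physchem_fields(), "bar")] - 1e-9))
})

test_that("whole-fruit rendering matches the requested ellipse", {
  sc <- scene_spec(image_size = 1600, fruit_axes = c(400, 300), noise_sd = 0)
  set.seed(1)
  out <- render_whole_fruit(sc)
  expect_equal(dim(out$image), c(1600, 1600, 3))
  # exact ellipse area within 1%
  expect_lt(abs(sum(out$mask) - pi * 400 * 300) / (pi * 400 * 300), 0.01)
  # no-noise: every fruit pixel equals the skin colour exactly
  for (ch in 1:3) {
    expect_true(all(out$image[, , ch][out$mask] == sc$base_colors$skin[ch]))
  }
  # aspect of the best-fit moment ellipse
  pts <- which(out$mask, arr.ind = TRUE)
  ev <- eigen(cov(pts), only.values = TRUE)$values
  expect_lt(abs(sqrt(ev[1] / ev[2]) - 400 / 300), 0.02 * 400 / 300)
  # oversized fruit rejected
  expect_error(scene_spec(image_size = 600, fruit_axes = c(400, 300)),
               "larger than image")
})

test_that("middle-cut rendering partitions the section with ordered ExG levels", {
  sc <- small_scene(noise_sd = 2)
  set.seed(2)
  out <- render_middle_cut(sc)
  m <- out$masks
  expect_s3_class(m, "region_masks")
  expect_identical(m$outer | m$core | m$locule, m$section)
  expect_false(any(m$outer & m$core) || any(m$outer & m$locule) ||
                 any(m$core & m$locule))
  exg <- exg_transform(out$image)
  expect_gt(mean(exg[m$outer]), mean(exg[m$core]))
  expect_gt(mean(exg[m$core]), mean(exg[m$locule]))
  # locule area rate identity against the partition
  expect_equal(locule_area_rate(m),
               (sum(m$section) - sum(m$outer) - sum(m$core)) / sum(m$section))
  # bad geometry rejected
  expect_error(scene_spec(image_size = 400, core_axes = c(120, 96)),
               "locule bound")
})

test_that("noiseless e-nose curves follow the closed-form protocol", {
  p <- make_region_profiles(separation = 1, noise_scale = 0)
  rec <- sample_physchem(p$Langarud)
  s <- simulate_enose_sample(p$Langarud, rec)
  proto <- enose_protocol()
  expect_length(s$curves, 13)
  expect_identical(s$times, as.numeric(1:220))
  for (cv in s$curves) {
    expect_true(all(cv$voltages > 0))
    # peak of each noiseless curve lies in the injection phase (120, 160]
    tmax <- cv$times[which.max(cv$voltages)]
    expect_true(tmax > 120 && tmax <= 160)
    # baseline is flat at V0
    norm <- normalize_curve(cv)
    expect_true(all(abs(norm$values[cv$times <= 120]) < 1e-9))
  }
  # closed-form MSR at the window end
  feats <- extract_enose_features(s)
  consts <- kiwifuse:::.sensor_array_constants()
  zc <- kiwifuse:::.ssc_latent_constants()
  z <- (rec[["ssc"]] - zc[["center"]]) / zc[["scale"]]
  expected <- p$Langarud$sensor_gain * (1 + p$Langarud$kappa * z) *
    (1 - exp(-20 / consts$tau))
  expect_equal(unname(feats), unname(expected), tolerance = 1e-6)
})

test_that("Langarud aroma amplitudes dominate Rasht at full separation", {
  p <- make_region_profiles(separation = 1, noise_scale = 0)
  f_lan <- extract_enose_features(
    simulate_enose_sample(p$Langarud, sample_physchem(p$Langarud)))
  f_ras <- extract_enose_features(
    simulate_enose_sample(p$Rasht, sample_physchem(p$Rasht)))
  expect_true(all(f_lan > f_ras))
})

test_that("dataset generation is deterministic, counted and validated", {
  cfg <- dataset_config(n_per_region = 3, seed = 11, image_size = 160)
  ds1 <- generate_dataset(cfg)
  ds2 <- generate_dataset(cfg)
  expect_length(ds1, 9)
  expect_equal(as.integer(table(dataset_labels(ds1))), rep(3L, 3))
  expect_identical(lapply(ds1, function(s) s$cut_image),
                   lapply(ds2, function(s) s$cut_image))
  expect_identical(lapply(ds1, function(s) s$physchem),
                   lapply(ds2, function(s) s$physchem))
  expect_identical(lapply(ds1, function(s) s$enose),
                   lapply(ds2, function(s) s$enose))
  expect_error(dataset_config(n_per_region = 2), ">= 3")
  # truth masks tile the section for every sample
  for (s in ds1) {
    m <- s$truth_masks
    expect_identical(m$outer | m$core | m$locule, m$section)
  }
})

test_that("dataset round-trips through the on-disk formats", {
  ds <- generate_dataset(dataset_config(n_per_region = 3, seed = 5,
                                        image_size = 160))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir, masks = TRUE)
  expect_true(file.exists(file.path(dir, "enose_curves.csv")))
  expect_true(file.exists(file.path(dir, "physchem.csv")))
  expect_true(file.exists(file.path(dir, "images", "Talesh_001_whole.png")))
  # curves survive the long-format CSV round trip
  back <- read_enose_csv(file.path(dir, "enose_curves.csv"))
  expect_length(back, 9)
  orig <- ds[[1]]$enose
  got <- back[[ds[[1]]$sample_id]]
  expect_equal(got$curves$MQ2$voltages, orig$curves$MQ2$voltages,
               tolerance = 1e-12)
  # images survive 8-bit PNG quantisation
  img <- read_rgb_png(file.path(dir, "images", "Talesh_001_cut.png"))
  expect_equal(dim(img), dim(ds[[1]]$cut_image))
  expect_lt(max(abs(img - round(ds[[1]]$cut_image))), 0.51)
})
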