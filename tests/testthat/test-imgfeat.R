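test_that("centre crop keeps the exact central block", {
  img <- array(seq_len(2000 * 2000 * 3), dim = c(2000, 2000, 3))
  cr <- crop_center(img, 1600)
  expect_equal(dim(cr), c(1600, 1600, 3))
  expect_identical(cr, img[201:1800, 201:1800, , drop = FALSE])
  same <- crop_center(img[1:1600, 1:1600, , drop = FALSE], 1600)
  expect_identical(same, img[1:1600, 1:1600, , drop = FALSE])
  expect_error(crop_center(img[1:1000, 1:1000, , drop = FALSE], 1600), "smaller")
  # odd margin uses floor division
  m <- matrix(1:25, 5, 5)
  expect_identical(crop_center(m, 2), m[2:3, 2:3])
})

test_that("ExG transform matches the 2G - R - B definition", {
  px <- function(r, g, b) flat_image(1, c(r, g, b))
  expect_equal(as.numeric(exg_transform(px(100, 200, 50))), 250)
  expect_equal(as.numeric(exg_transform(px(77, 77, 77))), 0)
  expect_equal(as.numeric(exg_transform(px(255, 0, 0))), -255)
  img <- flat_image(4, c(10, 20, 30))
  expect_true(all(exg_transform(img) == 0 + 2 * 20 - 10 - 30))
})

test_that("masking zeroes background and preserves foreground bytes", {
  set.seed(3)
  img <- array(runif(6 * 6 * 3, 0, 255), dim = c(6, 6, 3))
  expect_identical(apply_mask(img, matrix(TRUE, 6, 6)), img)
  expect_true(all(apply_mask(img, matrix(FALSE, 6, 6)) == 0))
  chk <- matrix((row(matrix(0, 6, 6)) + col(matrix(0, 6, 6))) %% 2 == 0, 6, 6)
  out <- apply_mask(img, chk)
  for (ch in 1:3) {
    expect_identical(out[, , ch][chk], img[, , ch][chk])
    expect_true(all(out[, , ch][!chk] == 0))
  }
  expect_error(apply_mask(img, matrix(TRUE, 5, 6)), "shapes differ")
})

test_that("colour means agree with conversion definitions and a brute-force loop", {
  red <- flat_image(8, c(255, 0, 0))
  mask <- matrix(TRUE, 8, 8)
  cm <- compute_color_means(red, mask)
  expect_equal(unname(cm[c("r", "g", "b", "h", "s", "v")]),
               c(255, 0, 0, 0, 1, 1))
  ref <- reference_lab(c(255, 0, 0))
  expect_lt(abs(cm[["l_star"]] - ref[["l"]]), 0.5)
  expect_lt(abs(cm[["a_star"]] - ref[["a"]]), 0.5)
  expect_lt(abs(cm[["b_star"]] - ref[["b"]]), 0.5)

  gray <- flat_image(8, c(128, 128, 128))
  cg <- compute_color_means(gray, mask)
  expect_equal(cg[["s"]], 0)
  expect_lt(abs(cg[["a_star"]]), 0.5)
  expect_lt(abs(cg[["b_star"]]), 0.5)

  # independent per-pixel accumulation oracle on a noisy image
  set.seed(9)
  img <- array(runif(12 * 12 * 3, 0, 255), dim = c(12, 12, 3))
  m <- matrix(runif(144) > 0.4, 12, 12)
  acc <- c(r = 0, g = 0, b = 0); n <- 0
  for (i in 1:12) for (j in 1:12) if (m[i, j]) {
    acc <- acc + img[i, j, ]; n <- n + 1
  }
  cm2 <- compute_color_means(img, m)
  expect_equal(unname(cm2[c("r", "g", "b")]), unname(acc / n), tolerance = 1e-9)
  expect_error(compute_color_means(img, matrix(FALSE, 12, 12)), "empty")
})

test_that("morphology follows the disk, square and ellipse conventions", {
  n <- 450
  g <- outer((1:n - 225)^2, (1:n - 225)^2, "+")
  disk <- g <= 200^2
  md <- compute_morphology(disk)
  expect_equal(md[["area"]], sum(disk))
  expect_gt(md[["roundness"]], 0.95); expect_lt(md[["roundness"]], 1.05)
  expect_gte(md[["aspect_ratio"]], 1.0); expect_lt(md[["aspect_ratio"]], 1.02)

  sq <- matrix(FALSE, 300, 300); sq[51:250, 51:250] <- TRUE
  ms <- compute_morphology(sq)
  expect_lt(abs(ms[["roundness"]] - pi / 4), 0.02)

  yy <- matrix(1:500, 500, 500); xx <- t(yy)
  ell <- ((xx - 250) / 200)^2 + ((yy - 250) / 100)^2 <= 1
  me <- compute_morphology(ell)
  expect_lt(abs(me[["aspect_ratio"]] - 2), 0.05)
  expect_error(compute_morphology(matrix(FALSE, 5, 5)), "empty")
})

test_that("whole-fruit segmentation recovers the rendered ellipse", {
  sc <- small_scene()
  set.seed(4)
  out <- render_whole_fruit(sc)
  mask <- segment_whole_fruit(out$image)
  expect_gte(iou(mask, out$mask), 0.98)
  # isolated small blobs are removed by opening + largest component
  noisy <- out$image
  set.seed(8)
  for (k in 1:5) {
    r0 <- sample(10:60, 1); c0 <- sample(10:60, 1)
    noisy[r0:(r0 + 5), c0:(c0 + 5), 1:3] <- 0
  }
  mask2 <- segment_whole_fruit(noisy)
  expect_gte(iou(mask2, mask), 0.999)
  # uniform image has no fruit
  expect_error(segment_whole_fruit(flat_image(64, c(200, 200, 200))),
               class = "kiwifuse_segmentation_error")
})

test_that("middle-cut segmentation recovers all four tissue masks", {
  sc <- small_scene()
  set.seed(5)
  out <- render_middle_cut(sc)
  masks <- segment_middle_cut(out$image)
  expect_gte(iou(masks$section, out$masks$section), 0.95)
  expect_gte(iou(masks$outer, out$masks$outer), 0.95)
  expect_gte(iou(masks$core, out$masks$core), 0.95)
  expect_gte(iou(masks$locule, out$masks$locule), 0.90)
  # exact partition by construction
  expect_identical(masks$outer | masks$core | masks$locule, masks$section)
})

test_that("a scene without a locule ring fails segmentation naming the locule", {
  # core colour painted over the whole interior: no distinct locule tissue
  sc <- scene_spec(image_size = 400, noise_sd = 2,
                   base_colors = list(background = c(246, 248, 253),
                                      skin = c(121, 85, 46),
                                      outer = c(150, 190, 60),
                                      locule = c(235, 230, 210),
                                      core = c(235, 230, 210)))
  set.seed(6)
  out <- render_middle_cut(sc)
  err <- tryCatch(segment_middle_cut(out$image), error = identity)
  expect_s3_class(err, "kiwifuse_segmentation_error")
  expect_match(conditionMessage(err), "locule")
})

test_that("locule area rate is the locule share of the section", {
  sec <- matrix(FALSE, 40, 40); sec[1:30, 1:40] <- TRUE   # 1200 px
  loc <- matrix(FALSE, 40, 40); loc[1:10, 1:30] <- TRUE   # 300 px
  core <- matrix(FALSE, 40, 40); core[11:20, 1:30] <- TRUE
  outr <- sec & !loc & !core
  m <- region_masks(sec, outr, core, loc)
  expect_equal(locule_area_rate(m), 300 / 1200)
  # empty locule is a valid boundary case of the ratio
  m0 <- region_masks(sec, sec & !core, core, sec & FALSE)
  expect_equal(locule_area_rate(m0), 0)
})

test_that("feature extraction yields 46 ordered, reproducible features", {
  sc <- small_scene()
  set.seed(10)
  whole <- render_whole_fruit(sc)
  cut <- render_middle_cut(sc)
  f1 <- extract_image_features(whole$image, cut$image)
  expect_length(f1, 46)
  expect_identical(names(f1), image_feature_names())
  expect_true(all(is.finite(f1)))
  f2 <- extract_image_features(whole$image, cut$image)
  expect_identical(f1, f2)
  # compositional consistency of the whole-fruit colour block
  wmask <- segment_whole_fruit(whole$image)
  wcol <- compute_color_means(whole$image, wmask)
  expect_equal(unname(f1[1:9]), unname(wcol))
})

test_that("features are robust to 90-degree rotation of the scene", {
  sc <- small_scene()
  set.seed(11)
  cut <- render_middle_cut(sc)
  rot <- function(img) {
    out <- array(0, dim = dim(img))
    for (ch in 1:3) out[, , ch] <- t(img[dim(img)[1]:1, , ch])
    out
  }
  m1 <- segment_middle_cut(cut$image)
  m2 <- segment_middle_cut(rot(cut$image))
  expect_lt(abs(sum(m2$section) - sum(m1$section)) / sum(m1$section), 0.01)
  expect_lt(abs(sum(m2$locule) - sum(m1$locule)) / sum(m1$locule), 0.01)
  c1 <- compute_color_means(cut$image, m1$locule)
  c2 <- compute_color_means(rot(cut$image), m2$locule)
  expect_lt(max(abs(c1[c("r", "g", "b")] - c2[c("r", "g", "b")])), 1)
})

test_that("enlarging the locule ring increases the locule area rate", {
  rates <- sapply(c(0.45, 0.55, 0.65), function(frac) {
    sc <- scene_spec(image_size = 400, locule_outer_fraction = frac,
                     noise_sd = 0)
    locule_area_rate(render_middle_cut(sc)$masks)
  })
  expect_true(all(diff(rates) > 0))
})
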