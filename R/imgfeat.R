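# ---- internal mask utilities (EBImage-backed) -------------------------------

.as_ebi <- function(mask) EBImage::Image(mask * 1)

.seg_error <- function(region, msg) {
  stop(structure(class = c("kiwifuse_segmentation_error", "error", "condition"),
                 list(message = sprintf("segmentation failure [%s]: %s", region, msg),
                      call = sys.call(-1))))
}

# Opening radius follows the 5 px convention at the 1600 px working scale.
.opening_radius <- function(mask) max(1L, round(5 * min(dim(mask)) / 1600))

.open_mask <- function(mask, radius = .opening_radius(mask)) {
  brush <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  EBImage::imageData(EBImage::opening(.as_ebi(mask), brush)) > 0.5
}

.largest_component <- function(mask) {
  if (!any(mask)) return(mask)
  lab <- EBImage::imageData(EBImage::bwlabel(.as_ebi(mask)))
  tab <- tabulate(lab[lab > 0])
  lab == which.max(tab)
}

.fill_holes <- function(mask) {
  EBImage::imageData(EBImage::fillHull(.as_ebi(mask))) > 0.5
}

# Otsu threshold of a numeric vector (any range), via the 256-level
# histogram criterion; returns the threshold on the original scale.
.otsu_threshold <- function(values) {
  rng <- range(values)
  if (diff(rng) == 0) return(rng[1])
  v01 <- (values - rng[1]) / diff(rng)
  t01 <- EBImage::otsu(EBImage::Image(matrix(v01, ncol = 1L)), range = c(0, 1))
  rng[1] + t01 * diff(rng)
}

# Of the two classes of a thresholded image, background is the one holding
# the majority of the four image corners.
.foreground_by_corners <- function(class_mask) {
  n <- dim(class_mask)
  corners <- class_mask[cbind(c(1, 1, n[1], n[1]), c(1, n[2], 1, n[2]))]
  if (sum(corners) >= 2) !class_mask else class_mask
}

# ---- exported operations ----------------------------------------------------

#' Crop the centred square block of an image
#'
#' Retains the central `size` x `size` block, using floor division for odd
#' margins (a 2000-pixel side cropped to 1600 keeps offsets 200..1799 in
#' 0-based indexing).
#'
#' @param image Matrix or 3-d array (height x width x channels).
#' @param size Side of the square crop in pixels.
#' @return The cropped image, same number of channels.
#' @export
crop_center <- function(image, size) {
  d <- dim(image)
  if (d[1] < size || d[2] < size) {
    stop(sprintf("image (%d x %d) is smaller than the %d px crop", d[1], d[2], size))
  }
  r0 <- floor((d[1] - size) / 2)
  c0 <- floor((d[2] - size) / 2)
  rows <- (r0 + 1):(r0 + size)
  cols <- (c0 + 1):(c0 + size)
  if (length(d) == 2L) image[rows, cols] else image[rows, cols, , drop = FALSE]
}

#' Excess-green (ExG) transform
#'
#' Per-pixel `2*G - R - B` on raw 0-255 channels; the result lies in
#' [-510, 510]. Green tissue maps strongly positive, red tissue strongly
#' negative, and achromatic pixels to ~0.
#'
#' @param image RGB array (0-255).
#' @return Numeric matrix of signed ExG values.
#' @export
exg_transform <- function(image) {
  2 * image[, , 2] - image[, , 1] - image[, , 3]
}

#' Mask an RGB image
#'
#' Zeroes every background pixel (logical AND of image and mask), leaving
#' foreground pixels untouched.
#'
#' @param image RGB array.
#' @param mask Logical matrix of matching height/width.
#' @return Masked RGB array.
#' @export
apply_mask <- function(image, mask) {
  d <- dim(image)
  if (!identical(d[1:2], dim(mask))) stop("image and mask shapes differ")
  image * array(rep(as.numeric(mask), d[3]), dim = d)
}

#' Segment the whole fruit from its background
#'
#' Grayscale conversion (ITU-R 601 luma weights), Otsu thresholding,
#' morphological opening with a disc structuring element (radius 5 px at
#' the 1600 px scale, scaled with image size), retention of the largest
#' connected component, and hole filling. The fruit is identified as the
#' thresholded class not holding the image corners.
#'
#' @param image RGB array (0-255).
#' @return Logical fruit mask.
#' @export
segment_whole_fruit <- function(image) {
  gray <- 0.2989 * image[, , 1] + 0.5870 * image[, , 2] + 0.1140 * image[, , 3]
  thr <- .otsu_threshold(as.vector(gray))
  cls <- gray > thr
  fruit <- .foreground_by_corners(cls)
  if (!any(fruit) || all(fruit)) .seg_error("whole", "no foreground after thresholding")
  fruit <- .largest_component(.open_mask(fruit))
  if (!any(fruit)) .seg_error("whole", "foreground vanished after opening")
  .fill_holes(fruit)
}

#' Segment the middle-cut section into outer pericarp, core and locule
#'
#' Implements the cross-section pipeline: (1) section mask by Otsu
#' thresholding of the hue channel (hue rotated by 0.5 beforehand so red
#' hues near the 0/1 wrap form a single mode), cleaned by opening, largest
#' component and hole filling; (2) within the section, Otsu on the ExG
#' image separates the strongly green outer pericarp (highest ExG class);
#' (3) a second Otsu split of the remainder assigns the near-zero-ExG
#' central class to the core (cleaned by opening and largest component);
#' (4) the locule ring is the section minus outer and core. The two
#' remainder subclasses are accepted as distinct tissues only when their
#' ExG means differ by more than three pooled standard deviations;
#' otherwise the remainder is taken as core alone and the locule is
#' reported missing.
#'
#' @param image RGB array (0-255).
#' @return A [region_masks()] object (partition invariant enforced).
#' @export
segment_middle_cut <- function(image) {
  d <- dim(image)
  rgbm <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
                as.vector(image[, , 3]))
  hsv <- rgb2hsv(rgbm, maxColorValue = 255)
  h_rot <- matrix((hsv["h", ] + 0.5) %% 1, d[1], d[2])
  sat <- matrix(hsv["s", ], d[1], d[2])
  thr <- .otsu_threshold(as.vector(h_rot))
  cls <- h_rot > thr
  # fruit tissue is saturated; the background is near-neutral
  fruit <- if (mean(sat[cls]) >= mean(sat[!cls])) cls else !cls
  if (!any(fruit) || all(fruit)) .seg_error("section", "hue threshold found no fruit")
  section <- .fill_holes(.largest_component(.open_mask(fruit)))
  if (!any(section)) .seg_error("section", "section vanished after cleanup")

  exg <- exg_transform(image)
  t1 <- .otsu_threshold(exg[section])
  outer_m <- section & exg > t1
  if (!any(outer_m)) .seg_error("outer", "no high-ExG class inside the section")
  remainder <- section & !outer_m

  t2 <- .otsu_threshold(exg[remainder])
  hi <- remainder & exg > t2
  lo <- remainder & !hi
  m_hi <- mean(exg[hi]); m_lo <- mean(exg[lo])
  s_pool <- sqrt((var(exg[hi]) + var(exg[lo])) / 2)
  if (!is.finite(s_pool) || abs(m_hi - m_lo) <= 3 * s_pool) {
    # remainder is one tissue: the near-zero-ExG core; no locule ring
    .seg_error("locule", "no distinct locule class between outer and core")
  }
  core_raw <- if (abs(m_hi) <= abs(m_lo)) hi else lo
  core <- .largest_component(.open_mask(core_raw))
  if (!any(core)) .seg_error("core", "core vanished after cleanup")
  core <- .fill_holes(core) & !outer_m

  locule <- section & !outer_m & !core
  if (!any(locule)) .seg_error("locule", "locule empty after subtraction")
  region_masks(section, outer_m, core, locule)
}

#' Morphological features of a binary mask
#'
#' Area (true-pixel count), roundness `4*pi*A / P^2` with the perimeter
#' measured on the outer boundary contour (8-connected chain smoothed by a
#' 7-point circular moving average, which removes the digitisation
#' staircase so an ideal disk scores ~1), and the aspect ratio
#' (major/minor axis) of the moment-equivalent ellipse.
#'
#' @param mask Logical matrix with at least one true pixel.
#' @return Named vector `c(area, roundness, aspect_ratio)`.
#' @export
compute_morphology <- function(mask) {
  if (!any(mask)) stop("empty mask")
  area <- sum(mask)
  per <- .perimeter_contour(mask)
  roundness <- if (per > 0) 4 * pi * area / per^2 else NA_real_
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) < 2) {
    aspect <- 1
  } else {
    ev <- eigen(cov(pts), symmetric = TRUE, only.values = TRUE)$values
    aspect <- if (ev[2] <= 0) Inf else sqrt(ev[1] / ev[2])
  }
  c(area = area, roundness = roundness, aspect_ratio = aspect)
}

# Outer-boundary perimeter: trace the 8-connected contour of the largest
# object, smooth the closed polygon with a 7-point circular moving
# average, and sum the segment lengths. Falls back to the raw chain
# length for very small contours.
.perimeter_contour <- function(mask, half_window = 3L) {
  oc <- EBImage::ocontour(.as_ebi(.largest_component(mask)))[[1]]
  n <- nrow(oc)
  if (n < 2) return(0)
  k <- half_window
  if (n <= 2 * k + 1) {
    d <- diff(rbind(oc, oc[1, , drop = FALSE]))
    return(sum(sqrt(rowSums(d^2))))
  }
  w <- rep(1 / (2 * k + 1), 2 * k + 1)
  sm <- vapply(1:2, function(j) {
    v <- c(oc[(n - k + 1):n, j], oc[, j], oc[1:k, j])
    as.numeric(stats::filter(v, w))[(k + 1):(n + k)]
  }, numeric(n))
  d <- diff(rbind(sm, sm[1, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

#' Mean colour descriptors over a masked region
#'
#' Means over mask pixels only, in three colour spaces: raw RGB (0-255),
#' HSV from the standard hexcone conversion (each component in [0, 1]),
#' and CIELAB via sRGB -> CIEXYZ (D65) -> CIELAB (L* in [0, 100], a*/b*
#' native).
#'
#' @param image RGB array (0-255).
#' @param mask Logical matrix, at least one true pixel.
#' @return Named vector `c(r, g, b, h, s, v, l_star, a_star, b_star)`.
#' @export
compute_color_means <- function(image, mask) {
  if (!identical(dim(image)[1:2], dim(mask))) stop("image and mask shapes differ")
  if (!any(mask)) stop("empty mask")
  r <- image[, , 1][mask]; g <- image[, , 2][mask]; b <- image[, , 3][mask]
  hsv <- rgb2hsv(rbind(r, g, b), maxColorValue = 255)
  lab <- convertColor(cbind(r, g, b) / 255, from = "sRGB", to = "Lab")
  c(r = mean(r), g = mean(g), b = mean(b),
    h = mean(hsv["h", ]), s = mean(hsv["s", ]), v = mean(hsv["v", ]),
    l_star = mean(lab[, 1]), a_star = mean(lab[, 2]), b_star = mean(lab[, 3]))
}

#' Locule area rate
#'
#' Ratio of the locule area to the middle-cut section area, in [0, 1).
#'
#' @param masks A [region_masks()] object.
#' @return Scalar fraction.
#' @export
locule_area_rate <- function(masks) {
  stopifnot(inherits(masks, "region_masks"))
  sec <- sum(masks$section)
  if (sec == 0) stop("empty section mask")
  sum(masks$locule) / sec
}

#' Names of the 46 visual features, in extraction order
#'
#' Whole-fruit colour means (9) and morphology (3); section morphology
#' (3); outer pericarp colour means (9); locule colour means (9); locule
#' area rate (1); core colour means (9) and morphology (3).
#'
#' @return Character vector of length 46.
#' @export
image_feature_names <- function() {
  color9 <- c("r", "g", "b", "h", "s", "v", "l_star", "a_star", "b_star")
  morph3 <- c("area", "roundness", "aspect_ratio")
  c(paste0("whole_", color9), paste0("whole_", morph3),
    paste0("section_", morph3),
    paste0("outer_", color9),
    paste0("locule_", color9),
    "locule_area_rate",
    paste0("core_", color9), paste0("core_", morph3))
}

#' Extract the 46-element visual feature vector
#'
#' Runs the full image pipeline on one whole-fruit image and one
#' middle-cut image: centre crop, whole-fruit segmentation with colour and
#' morphology measurement, cross-section segmentation into outer pericarp,
#' locule and core with per-tissue colour means, section and core
#' morphology, and the locule area rate. Features are returned in the
#' fixed order of [image_feature_names()].
#'
#' @param whole_image,cut_image RGB arrays (0-255).
#' @param crop_size Centre-crop side in pixels (default 1600); images
#'   already at or below this size are used whole (square assumed).
#' @return Named numeric vector of length 46.
#' @export
extract_image_features <- function(whole_image, cut_image, crop_size = 1600) {
  prep <- function(img) {
    sz <- min(dim(img)[1:2], crop_size)
    crop_center(img, sz)
  }
  whole <- prep(whole_image)
  cut <- prep(cut_image)

  wmask <- segment_whole_fruit(whole)
  wcol <- compute_color_means(whole, wmask)
  wmorph <- compute_morphology(wmask)

  masks <- segment_middle_cut(cut)
  smorph <- compute_morphology(masks$section)
  ocol <- compute_color_means(cut, masks$outer)
  lcol <- compute_color_means(cut, masks$locule)
  lrate <- locule_area_rate(masks)
  ccol <- compute_color_means(cut, masks$core)
  cmorph <- compute_morphology(masks$core)

  out <- c(wcol, wmorph, smorph, ocol, lcol, lrate, ccol, cmorph)
  names(out) <- image_feature_names()
  stopifnot(length(out) == 46L, all(is.finite(out)))
  out
}
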