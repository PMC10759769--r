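#' Scene geometry and colours for the synthetic fruit renderer
#'
#' Describes one square synthetic scene: image size, fruit and core ellipse
#' semi-axes (pixels), the fraction of the fruit axes bounding the locule
#' ring, base colours, and per-channel Gaussian pixel noise. Geometry
#' defaults scale linearly with `image_size` so the same scene can be
#' rendered at reduced resolution for fast tests.
#'
#' The cut-scene background is an off-white with a slight cool tint
#' (matte white card under chamber lighting is never perfectly neutral);
#' the tint keeps the hue channel of background pixels stable, which the
#' hue-threshold segmentation of [segment_middle_cut()] relies on. Base
#' tissue colours are chosen so that the gaps between the per-tissue ExG
#' (2G - R - B) levels exceed four times the ExG noise standard deviation
#' at the default `noise_sd`, guaranteeing threshold separability.
#'
#' @param image_size Side of the square image in pixels (default 1600).
#' @param fruit_axes Semi-major/semi-minor fruit axes in pixels.
#' @param core_axes Semi-axes of the pale core ellipse.
#' @param locule_outer_fraction Fraction of the fruit axes bounding the
#'   outside of the red locule ring.
#' @param base_colors Named list of RGB triplets (0-255): `background`,
#'   `skin`, `outer`, `locule`, `core`.
#' @param noise_sd Per-channel Gaussian intensity noise sd (default 3).
#' @param streak_amp,streak_n Amplitude (intensity units) and angular count
#'   of the radial luminance streaks textured into the locule ring. The
#'   streak offset is added to all three channels equally, so it does not
#'   perturb ExG.
#' @return A `kiwi_scene` list.
#' @export
scene_spec <- function(image_size = 1600,
                       fruit_axes = round(image_size * c(0.375, 0.300)),
                       core_axes = round(image_size * c(0.106, 0.085)),
                       locule_outer_fraction = 0.62,
                       base_colors = list(
                         background = c(246, 248, 253),
                         skin = c(121, 85, 46),
                         outer = c(150, 190, 60),
                         locule = c(180, 55, 40),
                         core = c(235, 230, 210)
                       ),
                       noise_sd = 3,
                       streak_amp = 10,
                       streak_n = 24) {
  scene <- list(image_size = as.integer(image_size),
                fruit_axes = as.numeric(fruit_axes),
                core_axes = as.numeric(core_axes),
                locule_outer_fraction = locule_outer_fraction,
                base_colors = base_colors,
                noise_sd = noise_sd,
                streak_amp = streak_amp,
                streak_n = streak_n)
  class(scene) <- "kiwi_scene"
  validate_scene(scene)
  scene
}

#' Validate a scene specification
#'
#' Enforces the geometric ordering core < locule bound < fruit (component
#' wise), colour ranges, and that the fruit fits in the image.
#'
#' @param scene A `kiwi_scene`.
#' @return The scene, invisibly; errors on violation.
#' @export
validate_scene <- function(scene) {
  stopifnot(inherits(scene, "kiwi_scene"))
  locule_bound <- scene$locule_outer_fraction * scene$fruit_axes
  if (!all(scene$core_axes < locule_bound)) {
    stop("core axes must be strictly inside the locule bound")
  }
  if (!all(locule_bound < scene$fruit_axes)) {
    stop("locule bound must be strictly inside the fruit axes")
  }
  if (scene$image_size < 2 * max(scene$fruit_axes)) {
    stop("fruit larger than image: image_size must be >= 2 x semi-major axis")
  }
  cols <- unlist(scene$base_colors)
  if (any(cols < 0 | cols > 255)) stop("base colours must lie in [0, 255]")
  if (scene$noise_sd < 0) stop("noise_sd must be >= 0")
  invisible(scene)
}

# Elliptical mask centred in a size x size grid; a, b are the semi-axes
# along columns (x) and rows (y).
.ellipse_mask <- function(size, a, b) {
  c0 <- (size + 1) / 2
  u <- ((seq_len(size) - c0) / a)^2
  v <- ((seq_len(size) - c0) / b)^2
  outer(v, u, "+") <= 1  # rows = y, cols = x
}

# Paint a flat colour onto the three channel planes where mask is TRUE.
.paint <- function(img, mask, rgb) {
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- rgb[ch]
    img[, , ch] <- plane
  }
  img
}

.add_noise_clip <- function(img, noise_sd) {
  if (noise_sd > 0) {
    img <- img + array(rnorm(length(img), sd = noise_sd), dim = dim(img))
  }
  img[img < 0] <- 0
  img[img > 255] <- 255
  img
}

#' Render a synthetic whole-fruit image
#'
#' An ellipse of skin colour centred on a uniform background, with additive
#' Gaussian pixel noise. The returned mask is the exact rendered ellipse.
#'
#' @param scene A `kiwi_scene` (see [scene_spec()]).
#' @return List with `image` (height x width x 3 array, 0-255) and `mask`
#'   (logical matrix).
#' @export
render_whole_fruit <- function(scene) {
  validate_scene(scene)
  n <- scene$image_size
  mask <- .ellipse_mask(n, scene$fruit_axes[1], scene$fruit_axes[2])
  img <- array(0, dim = c(n, n, 3))
  img <- .paint(img, !mask, scene$base_colors$background)
  img <- .paint(img, mask, scene$base_colors$skin)
  img <- .add_noise_clip(img, scene$noise_sd)
  list(image = img, mask = mask)
}

#' Ground-truth region masks of a middle-cut scene
#'
#' Bundle the four binary masks of a cross-section image. The three tissue
#' masks must be pairwise disjoint and tile the section exactly.
#'
#' @param section,outer,core,locule Logical matrices of identical dimension.
#' @return A `region_masks` list.
#' @export
region_masks <- function(section, outer, core, locule) {
  masks <- list(section = section, outer = outer, core = core, locule = locule)
  dims <- vapply(masks, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(dims)) != 1L) stop("mask dimensions differ")
  if (any(outer & core) || any(outer & locule) || any(core & locule)) {
    stop("outer, core and locule must be pairwise disjoint")
  }
  if (!identical(outer | core | locule, section)) {
    stop("outer, core and locule must tile the section exactly")
  }
  structure(masks, class = "region_masks")
}

#' Render a synthetic middle-cut (cross-section) image
#'
#' Concentric layout on a uniform background: a green-yellow outer pericarp
#' annulus (strongly positive ExG), a red locule ring (strongly negative
#' ExG) textured with radial luminance streaks, and a pale near-zero-ExG
#' core ellipse. The returned [region_masks()] are the exact rendered
#' geometry.
#'
#' @param scene A `kiwi_scene` (see [scene_spec()]).
#' @return List with `image` (array, 0-255) and `masks` (a `region_masks`).
#' @export
render_middle_cut <- function(scene) {
  validate_scene(scene)
  n <- scene$image_size
  section <- .ellipse_mask(n, scene$fruit_axes[1], scene$fruit_axes[2])
  lb <- scene$locule_outer_fraction * scene$fruit_axes
  locule_out <- .ellipse_mask(n, lb[1], lb[2])
  core <- .ellipse_mask(n, scene$core_axes[1], scene$core_axes[2])
  outer_m <- section & !locule_out
  locule <- locule_out & !core
  masks <- region_masks(section, outer_m, core, locule)

  img <- array(0, dim = c(n, n, 3))
  img <- .paint(img, !section, scene$base_colors$background)
  img <- .paint(img, outer_m, scene$base_colors$outer)
  img <- .paint(img, locule, scene$base_colors$locule)
  img <- .paint(img, core, scene$base_colors$core)

  if (scene$streak_amp > 0 && any(locule)) {
    c0 <- (n + 1) / 2
    idx <- which(locule, arr.ind = TRUE)
    theta <- atan2(idx[, 1] - c0, idx[, 2] - c0)
    streak <- scene$streak_amp * sin(scene$streak_n * theta)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[locule] <- plane[locule] + streak
      img[, , ch] <- plane
    }
  }
  img <- .add_noise_clip(img, scene$noise_sd)
  list(image = img, masks = masks)
}

# Scene specialised to a region profile: applies the profile's colour
# shifts and (random) shape jitter. Used by generate_dataset().
.scene_for_profile <- function(profile, image_size, noise_sd = 3) {
  jit <- function(k) 1 + profile$shape_jitter * profile$noise_scale * runif(k, -1, 1)
  base <- scene_spec(image_size = image_size, noise_sd = noise_sd)
  cols <- base$base_colors
  cols$locule <- pmin(pmax(cols$locule + profile$locule_color_shift, 0), 255)
  cols$skin <- pmin(pmax(cols$skin + profile$skin_color_shift, 0), 255)
  scene_spec(image_size = image_size,
             fruit_axes = base$fruit_axes * jit(2),
             core_axes = base$core_axes * jit(2),
             locule_outer_fraction = base$locule_outer_fraction * jit(1),
             base_colors = cols,
             noise_sd = noise_sd * ifelse(profile$noise_scale > 0,
                                          profile$noise_scale, 0))
}
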