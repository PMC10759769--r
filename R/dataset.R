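# Run code with a temporarily seeded RNG, restoring the caller's stream.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Configuration of a synthetic dataset
#'
#' @param n_per_region Samples per region (>= 3, needed for stratified
#'   splitting downstream).
#' @param seed Integer seed; the dataset is a pure function of the config.
#' @param separation Non-negative scalar scaling between-region differences
#'   (1 reproduces the reported regional means; 0 removes all regional
#'   structure).
#' @param noise_scale Non-negative scalar scaling all within-region noise.
#' @param image_size Side of the rendered square images in pixels. The
#'   default 1600 matches the working crop of the acquisition convention;
#'   smaller values render the same scene at reduced resolution.
#' @return A `kiwi_dataset_config` list.
#' @export
dataset_config <- function(n_per_region = 15, seed = 1, separation = 1,
                           noise_scale = 1, image_size = 1600) {
  if (n_per_region < 3) stop("n_per_region must be >= 3")
  if (separation < 0 || noise_scale < 0) {
    stop("separation and noise_scale must be non-negative")
  }
  structure(list(n_per_region = as.integer(n_per_region),
                 seed = as.integer(seed),
                 separation = separation,
                 noise_scale = noise_scale,
                 image_size = as.integer(image_size)),
            class = "kiwi_dataset_config")
}

#' Generate a labelled synthetic kiwifruit dataset
#'
#' Draws `3 * n_per_region` samples (regions interleaved in code order).
#' Each sample holds a whole-fruit image, a middle-cut image with
#' ground-truth tissue masks, a 13-channel e-nose acquisition, a
#' physicochemical record, the region label, and a sample id. The result
#' is fully reproducible from the config alone.
#'
#' @param config A [dataset_config()].
#' @param transform Optional function applied to each `kiwi_sample` as it
#'   is generated; its return value is stored in place of the sample.
#'   Pass a feature extractor here to stream large datasets without
#'   holding every full-resolution image in memory (a 1600 px sample
#'   occupies ~120 MB). The transform must not consume random numbers, or
#'   reproducibility across transforms is lost.
#' @param ... Passed to [make_region_profiles()] (e.g. `kappa`).
#' @return List of `kiwi_sample` objects (or transformed values) with
#'   attribute `config`.
#' @export
generate_dataset <- function(config, transform = NULL, ...) {
  stopifnot(inherits(config, "kiwi_dataset_config"))
  profiles <- make_region_profiles(separation = config$separation,
                                   noise_scale = config$noise_scale, ...)
  samples <- .with_seed(config$seed, {
    out <- list()
    for (lbl in region_labels()) {
      prof <- profiles[[lbl]]
      for (i in seq_len(config$n_per_region)) {
        physchem <- sample_physchem(prof)
        scene <- .scene_for_profile(prof, config$image_size)
        whole <- render_whole_fruit(scene)
        cut <- render_middle_cut(scene)
        nose <- simulate_enose_sample(prof, physchem)
        s <- structure(list(
          sample_id = sprintf("%s_%03d", lbl, i),
          label = lbl,
          whole_image = whole$image,
          cut_image = cut$image,
          truth_masks = cut$masks,
          enose = nose,
          physchem = physchem
        ), class = "kiwi_sample")
        if (!is.null(transform)) s <- transform(s)
        out[[length(out) + 1L]] <- s
      }
    }
    out
  })
  attr(samples, "config") <- config
  samples
}

#' Region labels of a dataset
#'
#' @param samples List of `kiwi_sample` objects.
#' @return Factor with levels in region code order.
#' @export
dataset_labels <- function(samples) {
  factor(vapply(samples, function(s) s$label, ""), levels = region_labels())
}

#' Write a synthetic dataset to disk
#'
#' External consumption formats: 8-bit RGB PNG images (`<id>_whole.png`,
#' `<id>_cut.png`), single-channel 0/255 PNG truth masks, one long-format
#' CSV of e-nose curves (`sample_id,sensor_id,t_s,voltage`), and one CSV of
#' physicochemical records with a `region` column.
#'
#' @param samples Output of [generate_dataset()].
#' @param dir Output directory (created if absent).
#' @param masks Also write the four truth-mask PNGs per sample (default
#'   FALSE).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(samples, dir, masks = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img_dir <- file.path(dir, "images")
  dir.create(img_dir, showWarnings = FALSE)
  curve_rows <- vector("list", length(samples))
  phys_rows <- vector("list", length(samples))
  for (k in seq_along(samples)) {
    s <- samples[[k]]
    png::writePNG(s$whole_image / 255,
                  file.path(img_dir, paste0(s$sample_id, "_whole.png")))
    png::writePNG(s$cut_image / 255,
                  file.path(img_dir, paste0(s$sample_id, "_cut.png")))
    if (masks) {
      for (nm in names(s$truth_masks)) {
        png::writePNG(s$truth_masks[[nm]] * 1,
                      file.path(img_dir, paste0(s$sample_id, "_mask_", nm, ".png")))
      }
    }
    curve_rows[[k]] <- do.call(rbind, lapply(s$enose$curves, function(cv) {
      data.frame(sample_id = s$sample_id, sensor_id = cv$sensor_id,
                 t_s = cv$times, voltage = cv$voltages)
    }))
    phys_rows[[k]] <- data.frame(sample_id = s$sample_id, region = s$label,
                                 t(s$physchem))
  }
  write.csv(do.call(rbind, curve_rows), file.path(dir, "enose_curves.csv"),
            row.names = FALSE)
  write.csv(do.call(rbind, phys_rows), file.path(dir, "physchem.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read e-nose curves from a long-format CSV
#'
#' Inverse of the curve file written by [write_dataset()]: expects columns
#' `sample_id,sensor_id,t_s,voltage`.
#'
#' @param path CSV path.
#' @return Named list of [enose_sample()] objects, one per `sample_id`, in
#'   file order.
#' @export
read_enose_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "sensor_id", "t_s", "voltage")
  if (!all(need %in% names(df))) {
    stop("curve CSV must have columns: ", paste(need, collapse = ","))
  }
  ids <- unique(df$sample_id)
  out <- lapply(ids, function(id) {
    d <- df[df$sample_id == id, ]
    curves <- lapply(unique(d$sensor_id), function(sid) {
      ds <- d[d$sensor_id == sid, ]
      ord <- order(ds$t_s)
      sensor_curve(sid, ds$t_s[ord], ds$voltage[ord])
    })
    enose_sample(curves)
  })
  names(out) <- ids
  out
}

#' Read an RGB image from a PNG file
#'
#' @param path PNG path.
#' @return Height x width x 3 numeric array scaled to 0-255.
#' @export
read_rgb_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
  img[, , 1:3, drop = FALSE] * 255
}
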